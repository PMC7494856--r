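test_that("read graph components match a union-find oracle", {
  panel <- toy_panel(12)
  fr <- dplyr::bind_rows(
    frag_tbl("a", c(1, 2), c(0, 1)),
    frag_tbl("b", c(2, 3), c(1, 0)),
    frag_tbl("c", c(5, 6), c(0, 0)),
    frag_tbl("d", 9, 1)
  )
  g <- build_read_graph(fr, panel)
  comps <- split(g$membership$snp_id, g$membership$component)
  expect_equal(unname(lapply(comps, sort)), list(c(1L, 2L, 3L), c(5L, 6L), 9L))
  # randomized comparison against an independent union-find
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(6:20, 1)
    fr <- dplyr::bind_rows(purrr::map(1:sample(4:15, 1), function(i) {
      k <- sample(1:3, 1)
      frag_tbl(sprintf("f%d", i), sample.int(n, k), sample(0:1, k, TRUE))
    }))
    g <- build_read_graph(fr, toy_panel(n))
    got <- unname(lapply(split(g$membership$snp_id, g$membership$component), sort))
    want <- unname(lapply(oracle_components(fr), sort))
    expect_equal(sort(vapply(got, paste, collapse = ",", "")),
                 sort(vapply(want, paste, collapse = ",", "")))
  }
})

test_that("joint blocks add within-gene links but never bridge genes", {
  panel <- toy_panel(6)
  assessments <- tibble::tibble(
    snp_id = 1:6, gene_id = rep(c("g1", "g2"), each = 3),
    c0 = 0L, c1 = 0L, prob_concordant = 0.999,
    phaseable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  genes <- tibble::tibble(gene_id = c("g1", "g2"))
  # no linking reads: each gene's phaseable SNPs form one block
  g <- build_read_graph(empty_frags <- frag_tbl("x", 1, 0)[0, ], panel)
  blocks <- build_joint_blocks(g, genes, assessments, panel)
  expect_equal(sort(blocks$snp_id[blocks$block == 1]), 1:3)
  expect_equal(sort(blocks$snp_id[blocks$block == 2]), 4:5)
  # a contiguity edge merges with the gene clique transitively
  fr <- frag_tbl("a", c(3, 4), c(0, 1))
  g2 <- build_read_graph(fr, panel)
  blocks2 <- build_joint_blocks(g2, genes, assessments, panel)
  expect_equal(sort(blocks2$snp_id[blocks2$block == 1]), 1:5)
})

test_that("fragment log likelihood matches direct mixture arithmetic", {
  # unbiased single-SNP fragment: constant in the phase
  v0 <- read_log_likelihood(0L, 0.1, 0L, 0.5)
  v1 <- read_log_likelihood(0L, 0.1, 1L, 0.5)
  expect_equal(v0, v1)
  # error-free match with uniform bias: one branch survives with weight 1/2
  expect_equal(exp(read_log_likelihood(c(0L, 1L), c(0, 0), c(0L, 1L), 0.5)),
               0.5)
  # two-SNP agreement under bias: 0.8 * 0.9^2 + 0.2 * 0.1^2
  expect_equal(exp(read_log_likelihood(c(0L, 1L), c(0.1, 0.1), c(0L, 1L), 0.8)),
               0.8 * 0.81 + 0.2 * 0.01)
})

test_that("phase prior counts parallel and switched pairs; pairs sum to one", {
  expect_equal(phase_log_prior(c(0L, 1L, 0L, 1L), 0.5), 3 * log(0.5))
  expect_equal(phase_log_prior(rep(0L, 4), 0.9), 3 * log(0.9))
  expect_equal(phase_log_prior(c(0L, 0L, 1L), 0.8), 2 * log(0.8) + 0 + log(0.2) - log(0.8))
  # the prior normalizes over complement pairs (h0, h1 are one haplotype)
  for (rho in c(0.5, 0.7, 0.95)) {
    n <- 6
    total <- 0
    for (mask in 0:(2^n - 1)) {
      h0 <- as.integer(intToBits(mask)[1:n])
      if (h0[1] == 1L) next # one representative per complement pair
      total <- total + exp(phase_log_prior(h0, rho))
    }
    expect_equal(total, 1)
  }
})

test_that("relative likelihood is complement-symmetric only without bias", {
  fr <- dplyr::bind_rows(
    frag_tbl("a", c(1, 2), c(0, 1), err = 0.05),
    frag_tbl("b", 2, 1, err = 0.05),
    frag_tbl("c", 3, 0, err = 0.05)
  )
  h <- c(0L, 1L, 0L)
  rl <- relative_likelihood(h, fr, NULL, 0.5, 1:3)
  rl_c <- relative_likelihood(1L - h, fr, NULL, 0.5, 1:3)
  expect_equal(rl, rl_c)
  biases <- tibble::tibble(frag_id = c("b", "c"), b0 = 0.85, b1 = 0.15)
  rl_b <- relative_likelihood(h, fr, biases, 0.5, 1:3)
  rl_bc <- relative_likelihood(1L - h, fr, biases, 0.5, 1:3)
  expect_false(isTRUE(all.equal(rl_b, rl_bc)))
})

test_that("relative likelihood agrees with a straight-line oracle", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:7, 1)
    fr <- dplyr::bind_rows(purrr::map(1:sample(2:10, 1), function(i) {
      k <- sample(1:min(3, n), 1)
      frag_tbl(sprintf("f%d", i), sort(sample.int(n, k)),
               sample(0:1, k, TRUE), err = runif(1, 0.001, 0.3))
    }))
    ids <- unique(fr$frag_id)
    b0 <- stats::setNames(runif(length(ids), 0.5, 0.95), ids)
    biases <- tibble::tibble(frag_id = ids, b0 = unname(b0), b1 = 1 - unname(b0))
    rho <- sample(c(0.5, 0.8), 1)
    h0 <- sample(0:1, n, TRUE)
    expect_equal(relative_likelihood(h0, fr, biases, rho, 1:n),
                 oracle_rl(h0, fr, as.list(b0), rho, 1:n),
                 tolerance = 1e-12)
  }
})

test_that("phase_block recovers a dominant fragment and handles empty evidence", {
  fr <- frag_tbl("a", 1:5, c(0, 1, 1, 0, 1), err = 0.01)
  ph <- phase_block(1:5, fr)
  expect_equal(ph$h0, c(0L, 1L, 1L, 0L, 1L))
  expect_equal(ph$h1, 1L - ph$h0)
  expect_null(phase_block(1:3, fr[0, ]))
  expect_error(phase_block(1L, fr), "at least 2")
})

test_that("canonical orientation: h0 starts with 0 when evidence is symmetric", {
  fr <- frag_tbl("a", 1:3, c(1, 0, 1), err = 0.02)
  ph <- phase_block(1:3, fr)
  expect_equal(ph$h0[1], 0L)
  expect_equal(ph$h0, c(0L, 1L, 0L))
})

test_that("beam search attains the exhaustive optimum on random mixed blocks", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    fr <- dplyr::bind_rows(purrr::map(1:sample(3:14, 1), function(i) {
      k <- sample(1:3, 1)
      s <- sample.int(n - k + 1L, 1)
      frag_tbl(sprintf("f%d", i), s:(s + k - 1L), sample(0:1, k, TRUE),
               err = runif(1, 0.001, 0.2))
    }))
    ids <- unique(fr$frag_id)
    biases <- tibble::tibble(frag_id = ids,
                             b0 = sample(c(0.5, 0.75, 0.9), length(ids), TRUE))
    biases$b1 <- 1 - biases$b0
    beam <- phase_block(1:n, fr, biases, exhaustive_cutoff = 0)
    exact <- phase_block(1:n, fr, biases, exhaustive_cutoff = 12)
    expect_equal(attr(beam, "log_rl"), attr(exact, "log_rl"), tolerance = 1e-9)
  }
})

test_that("under size-1 reads, constant error and uniform prior the search returns H+", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    cnt <- tibble::tibble(snp_id = 1:n, c0 = rpois(n, 10), c1 = rpois(n, 3))
    reads <- dplyr::bind_rows(purrr::map(1:n, function(s) {
      tot <- cnt$c0[s] + cnt$c1[s]
      if (tot == 0) return(NULL)
      frag_tbl(sprintf("s%d_%d", s, 1:tot), rep(s, tot),
               c(rep(0, cnt$c0[s]), rep(1, cnt$c1[s])), err = 0.05)
    }))
    ids <- unique(reads$frag_id)
    biases <- tibble::tibble(frag_id = ids, b0 = 0.8, b1 = 0.2)
    ph <- phase_block(1:n, reads, biases)
    hplus <- concordant_solution(cnt)$h0
    rl_ph <- relative_likelihood(ph$h0, reads, biases, 0.5, 1:n)
    rl_hp <- relative_likelihood(hplus, reads, biases, 0.5, 1:n)
    expect_equal(rl_ph, rl_hp, tolerance = 1e-9)
  }
})

test_that("phase_all keeps blocks within chromosomes, SNPs unique, reruns identical", {
  scene <- simulate_scene(simulation_config(
    n_genes = 5, coverage = 40, seed = 61,
    frag_size_probs = c("1" = 0.4, "2" = 0.4, "3" = 0.2)))
  restricted <- restrict_reads(
    dplyr::filter(scene$fragments, !is.na(gene_id)), seed = 3)
  dhe <- estimate_dhe(restricted, scene$genes)
  assess <- assess_concordance(restricted, dhe)
  biases <- assign_read_biases(scene$fragments, dhe, assess)
  b1 <- phase_all(scene$panel, scene$fragments, scene$genes, dhe, assess, biases)
  b2 <- phase_all(scene$panel, scene$fragments, scene$genes, dhe, assess, biases)
  expect_identical(b1, b2)
  expect_false(any(duplicated(b1$snp_id)))
  per_block_chrom <- tapply(b1$chrom, b1$block_id, function(x) length(unique(x)))
  expect_true(all(per_block_chrom == 1L))
  # every truth SNP pair sharing a block stays together in the output:
  # multi-SNP fragments' SNPs land in one block
  frags <- scene$fragments
  for (fid in sample(unique(frags$frag_id), 50)) {
    s <- frags$snp_id[frags$frag_id == fid]
    blk <- unique(b1$block_id[b1$snp_id %in% s])
    if (length(s) > 1 && all(s %in% b1$snp_id)) {
      expect_length(blk, 1L)
    }
  }
})

test_that("phase_all returns an empty table without evidence", {
  panel <- toy_panel(4)
  out <- phase_all(panel, frag_tbl("x", 1, 0)[0, ])
  expect_equal(nrow(out), 0L)
})

test_that("singleton components are suppressed", {
  panel <- toy_panel(4)
  fr <- dplyr::bind_rows(
    frag_tbl("a", c(1, 2), c(0, 1)),
    frag_tbl("b", 4, 0)
  )
  out <- phase_all(panel, fr)
  expect_equal(sort(unique(out$snp_id)), c(1L, 2L))
})
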