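test_that("restrict_reads keeps size-1 fragments, yields size-1 output, and is seed-deterministic", {
  fr <- dplyr::bind_rows(
    frag_tbl("a", 1, 0),
    frag_tbl("b", c(2, 3, 4), c(1, 0, 1)),
    frag_tbl("c", c(1, 5), c(0, 0))
  )
  r1 <- restrict_reads(fr, seed = 9)
  expect_equal(sort(unique(r1$frag_id)), c("a", "b", "c"))
  expect_true(all(table(r1$frag_id) == 1L))
  expect_equal(r1$snp_id[r1$frag_id == "a"], 1L) # size-1 passes through
  expect_equal(restrict_reads(fr, seed = 9), r1)
})

test_that("restriction picks each covered SNP uniformly", {
  fr <- frag_tbl("x", c(10, 20, 30), c(0, 0, 0))
  set.seed(123)
  picks <- replicate(9000, restrict_reads(fr)$snp_id)
  freq <- table(picks) / length(picks)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("allele counts tally restricted reads and reject multi-SNP fragments", {
  fr <- dplyr::bind_rows(
    frag_tbl("a", 5, 0), frag_tbl("b", 5, 0), frag_tbl("c", 5, 1),
    frag_tbl("d", 7, 1)
  )
  counts <- compute_allele_counts(fr)
  expect_equal(counts$c0[counts$snp_id == 5], 2L)
  expect_equal(counts$c1[counts$snp_id == 5], 1L)
  expect_equal(counts$c1[counts$snp_id == 7], 1L)
  expect_equal(nrow(compute_allele_counts(fr[0, ])), 0L)
  expect_error(compute_allele_counts(frag_tbl("m", c(1, 2), c(0, 0))),
               "size-1")
})

test_that("forward likelihood matches closed forms", {
  one <- frag_tbl("r1", 1, 0, err = 0)
  for (b in c(0.5, 0.7, 0.9, 1)) {
    expect_equal(forward_likelihood(one, b, log = FALSE), 0.5)
  }
  two <- dplyr::bind_rows(one, frag_tbl("r2", 1, 0, err = 0))
  expect_equal(forward_likelihood(two, 0.9, log = FALSE),
               0.5 * 0.9^2 + 0.5 * 0.1^2)
  expect_error(forward_likelihood(one, 0.4), "beta")
  expect_error(forward_likelihood(one, 0.9, rho = 1), "rho")
})

test_that("forward likelihood equals brute-force haplotype enumeration", {
  set.seed(2024)
  for (rep in 1:40) {
    n <- sample(1:8, 1)
    reads <- random_restricted(n, sample(1:25, 1), err = runif(1, 0, 0.2))
    beta <- runif(1, 0.5, 1)
    rho <- sample(c(0.5, 0.7, 0.9), 1)
    got <- forward_likelihood(reads, beta, rho, snp_order = 1:n, log = FALSE)
    want <- oracle_forward(reads, beta, rho, 1:n)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("maximize_beta matches a dense grid search", {
  fr <- tibble::tibble(
    frag_id = sprintf("r%d", 1:100), chrom = "chr1", snp_id = 1L,
    allele = c(rep(0L, 90), rep(1L, 10)), errprob = 0,
    gene_id = NA_character_, barcode = NA_character_
  )
  fit <- maximize_beta(fr)
  grid <- seq(0.5, 1, by = 1e-4)
  fvals <- 0.5 * (grid^90 * (1 - grid)^10 + grid^10 * (1 - grid)^90)
  expect_equal(fit$beta, grid[which.max(fvals)], tolerance = 2e-4)
  expect_equal(fit$log_lik, log(max(fvals)), tolerance = 1e-8)
})

test_that("balanced counts give beta = 0.5 and the f-value matches the grid max", {
  set.seed(55)
  fr <- tibble::tibble(
    frag_id = sprintf("r%d", 1:80), chrom = "chr1",
    snp_id = rep(1:2, each = 40),
    allele = rep(c(0L, 1L), 40), errprob = 0,
    gene_id = NA_character_, barcode = NA_character_
  )
  fit <- maximize_beta(fr)
  expect_equal(fit$beta, 0.5, tolerance = 1e-6)
  # property: returned f-value within 1e-8 of a grid maximum, random cases
  for (rep in 1:10) {
    reads <- random_restricted(sample(1:4, 1), sample(10:60, 1),
                               err = runif(1, 0.001, 0.1))
    fit <- maximize_beta(reads)
    grid <- seq(0.5, 1 - 1e-6, length.out = 2001)
    gv <- vapply(grid, function(b) forward_likelihood(reads, b), double(1))
    expect_gte(fit$log_lik, max(gv) - 1e-8)
  }
})

test_that("beta recovery improves with coverage", {
  set.seed(808)
  err_by_n <- vapply(c(20, 100, 500), function(N) {
    errs <- vapply(1:30, function(i) {
      reads <- tibble::tibble(
        frag_id = sprintf("r%d", 1:N), chrom = "chr1",
        snp_id = sample(1:5, N, replace = TRUE),
        allele = NA_integer_, errprob = 0.01,
        gene_id = NA_character_, barcode = NA_character_
      )
      h0 <- sample(0:1, 5, replace = TRUE)
      origin <- rbinom(N, 1, 1 - 0.8)
      hap <- ifelse(origin == 0, h0[reads$snp_id], 1 - h0[reads$snp_id])
      flip <- runif(N) < 0.01
      reads$allele <- as.integer(ifelse(flip, 1 - hap, hap))
      abs(maximize_beta(reads)$beta - 0.8)
    }, double(1))
    mean(errs)
  }, double(1))
  expect_true(all(diff(err_by_n) < 0))
})

test_that("concordance probability follows the closed form and is monotone", {
  expect_equal(concordance_probability(7, 7, 0.9, 0.1), 0.5)
  expect_equal(concordance_probability(5, 3, 0.9, 0.1), 81 / 82)
  expect_equal(concordance_probability(4, 4, 0.5, 0.5), 0.5)
  # two-hypothesis Bayes oracle: posterior of majority vs minority solution
  for (case in list(c(9, 2, 0.85), c(12, 12, 0.7), c(3, 30, 0.95))) {
    c0 <- case[1]; c1 <- case[2]; g0 <- case[3]; g1 <- 1 - g0
    lik_plus <- g0^max(c0, c1) * g1^min(c0, c1)
    lik_minus <- g0^min(c0, c1) * g1^max(c0, c1)
    expect_equal(concordance_probability(c0, c1, g0, g1),
                 lik_plus / (lik_plus + lik_minus))
  }
  # monotone in the count gap and in the rate ratio
  p_gap <- concordance_probability(10 + 0:5, 10, 0.8, 0.2)
  expect_true(all(diff(p_gap) >= 0))
  g0s <- seq(0.55, 0.95, by = 0.1)
  p_ratio <- concordance_probability(8, 3, g0s, 1 - g0s)
  expect_true(all(diff(p_ratio) >= 0))
})

test_that("coverage-based concordance: closed forms, Chernoff bound, monotonicity", {
  expect_equal(concordance_probability_by_coverage(1, 0.87)$prob, 0.87)
  expect_equal(concordance_probability_by_coverage(0, 0.9)$prob, 0.5)
  # symmetric binomial
  n <- 11
  expect_equal(concordance_probability_by_coverage(n, 0.5)$prob,
               sum(choose(n, 6:11)) / 2^n)
  # exact tail dominates the Chernoff bound and grows with N
  set.seed(66)
  for (rep in 1:25) {
    N <- sample(1:10000, 1)
    g0 <- runif(1, 0.51, 0.99)
    res <- concordance_probability_by_coverage(N, g0, normal_cutoff = Inf)
    expect_gte(res$prob, res$lower_bound)
  }
  g0 <- 0.7
  tails <- concordance_probability_by_coverage(seq(1, 201, by = 4), g0,
                                               normal_cutoff = Inf)$prob
  expect_true(all(diff(tails) >= -1e-12))
})

test_that("non-uniform expression screen: closed forms and normal approximation", {
  # one-sided extremes: p = 2^(1-N)
  for (N in c(5, 10, 20)) {
    expect_equal(nonuniform_expression_test(tibble::tibble(c0 = 0, c1 = N)),
                 2^(1 - N))
  }
  # perfectly balanced -> capped at 1
  expect_equal(nonuniform_expression_test(tibble::tibble(c0 = 7, c1 = 7)), 1)
  expect_equal(nonuniform_expression_test(tibble::tibble(c0 = 0, c1 = 0)), 1)
  # gene scope pools per-SNP minority/majority counts
  counts <- tibble::tibble(c0 = c(9, 1), c1 = c(2, 8))
  m <- 3; M <- 17; N <- 20
  expect_equal(nonuniform_expression_test(counts, "gene"),
               pbinom(m, N, 0.5) + pbinom(M - 1, N, 0.5, lower.tail = FALSE))
  # per-SNP scope returns one value per row
  expect_length(nonuniform_expression_test(counts, "snp"), 2L)
  # normal approximation close to the exact sum at N = 1000
  set.seed(12)
  for (rep in 1:20) {
    m <- sample(350:499, 1); M <- 1000 - m
    exact <- nonuniform_expression_test(tibble::tibble(c0 = m, c1 = M),
                                        normal_cutoff = Inf)
    approx <- nonuniform_expression_test(tibble::tibble(c0 = m, c1 = M),
                                         normal_cutoff = 10)
    expect_lt(abs(approx - exact), 1e-3)
  }
})

test_that("screen holds its nominal type-I error under uniform expression", {
  set.seed(314)
  N <- 60
  x <- rbinom(4000, N, 0.5)
  p <- vapply(x, function(xi)
    nonuniform_expression_test(tibble::tibble(c0 = xi, c1 = N - xi)),
    double(1))
  expect_lte(mean(p <= 0.01), 0.01)
})

test_that("the majority-allele solution maximizes relative likelihood for size-1 reads", {
  counts <- tibble::tibble(snp_id = 1:2, c0 = c(10, 90), c1 = c(90, 10))
  sol <- concordant_solution(counts)
  expect_equal(sol$h0, c(1L, 0L))
  expect_equal(sol$h1, 1L - sol$h0)
  # ties flagged and assigned 0
  tied <- concordant_solution(tibble::tibble(snp_id = 1, c0 = 4, c1 = 4))
  expect_true(tied$tie)
  expect_equal(tied$h0, 0L)
  # exhaustive oracle: H+ attains the maximum RL over all phases (<= 8 SNPs)
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    cnt <- tibble::tibble(snp_id = 1:n,
                          c0 = rpois(n, 12), c1 = rpois(n, 4))
    beta <- runif(1, 0.6, 0.95); eps <- runif(1, 0, 0.2)
    b0 <- beta # constant bias across reads
    reads <- dplyr::bind_rows(purrr::map(1:n, function(s) {
      k0 <- cnt$c0[s]; k1 <- cnt$c1[s]
      if (k0 + k1 == 0) return(NULL)
      frag_tbl(sprintf("s%d_%d", s, seq_len(k0 + k1)),
               rep(s, k0 + k1), c(rep(0, k0), rep(1, k1)), err = eps)
    }))
    b0_map <- stats::setNames(rep(b0, length(unique(reads$frag_id))),
                              unique(reads$frag_id))
    best <- oracle_best_phase(reads, as.list(b0_map), 0.5, 1:n)
    hplus <- concordant_solution(cnt)$h0
    rl_hplus <- oracle_rl(hplus, reads, as.list(b0_map), 0.5, 1:n)
    expect_equal(rl_hplus, best$log_rl, tolerance = 1e-9)
  }
})

test_that("read biases mix the uniform prior with the estimated gene bias", {
  dhe <- tibble::tibble(gene_id = c("g1", "g2"), beta = c(0.8, 0.9),
                        eligible = c(TRUE, FALSE))
  assessments <- tibble::tibble(
    snp_id = c(1L, 2L, 3L), gene_id = c("g1", "g1", "g2"),
    c0 = 0L, c1 = 0L, prob_concordant = c(0.999, 0.999, 0.999),
    phaseable = c(TRUE, FALSE, FALSE)
  )
  fr <- dplyr::bind_rows(
    frag_tbl("a", 1, 0, gene = "g1"),   # eligible gene, phaseable SNP
    frag_tbl("b", 2, 1, gene = "g1"),   # non-phaseable SNP
    frag_tbl("c", 3, 0, gene = "g2"),   # ineligible gene
    frag_tbl("d", 1, 0)                 # no gene
  )
  b <- assign_read_biases(fr, dhe, assessments, p_uniform = 0)
  expect_equal(b$b0[b$frag_id == "a"], 0.8)
  expect_equal(b$b0[b$frag_id == "b"], 0.5)
  expect_equal(b$b0[b$frag_id == "c"], 0.5)
  expect_equal(b$b0[b$frag_id == "d"], 0.5)
  expect_equal(b$b1, 1 - b$b0)
  # the mixture prior shrinks the bias toward 0.5; p = 1 kills it
  b_half <- assign_read_biases(fr, dhe, assessments, p_uniform = 0.5)
  expect_equal(b_half$b0[b_half$frag_id == "a"], 0.5 * 0.5 + 0.5 * 0.8)
  b_one <- assign_read_biases(fr, dhe, assessments, p_uniform = 1)
  expect_true(all(b_one$b0 == 0.5))
})

test_that("estimate_dhe screens genes by depth and imbalance", {
  set.seed(42)
  scene <- simulate_scene(simulation_config(
    n_genes = 6, coverage = 80, beta_values = c(0.5, 0.85), seed = 510))
  restricted <- restrict_reads(
    dplyr::filter(scene$fragments, !is.na(gene_id)), seed = 1)
  dhe <- estimate_dhe(restricted, scene$genes)
  expect_s3_class(dhe, "dhe_fit")
  merged <- dplyr::inner_join(dhe, scene$gene_truth, by = "gene_id",
                              suffix = c("", "_true"))
  # strongly biased genes are recovered and flagged; uniform genes are not
  biased <- merged[merged$beta_true == 0.85, ]
  expect_true(all(biased$eligible))
  expect_true(all(abs(biased$beta - 0.85) < 0.08))
  unif <- merged[merged$beta_true == 0.5, ]
  expect_true(all(!unif$eligible))
  # gamma identities
  est <- merged[!is.na(merged$beta), ]
  expect_equal(est$gamma0 + est$gamma1, rep(1, nrow(est)))
  expect_true(all(est$gamma0 >= est$gamma1))
})
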