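# Independent straight-line oracles used to cross-check the package's
# log-space / vectorised implementations, plus small fixture builders.

# Build a fragment table quickly.
frag_tbl <- function(id, snps, alleles, err = 0.01, gene = NA_character_,
                     barcode = NA_character_, chrom = "chr1") {
  tibble::tibble(
    frag_id = id, chrom = chrom, snp_id = as.integer(snps),
    allele = as.integer(alleles),
    errprob = rep_len(err, length(snps)),
    gene_id = gene, barcode = barcode
  )
}

# A panel with n SNPs at regular positions.
toy_panel <- function(n, chrom = "chr1", spacing = 100L, start = 1000L) {
  tibble::tibble(
    snp_id = seq_len(n), chrom = chrom,
    pos = start + spacing * (seq_len(n) - 1L),
    ref = "A", alt = "G", index = seq_len(n) - 1L
  )
}

# Brute-force marginal likelihood of restricted reads given beta: sum over
# every haplotype assignment of prior times per-read emission products.
oracle_forward <- function(restricted, beta, rho, snp_order) {
  n <- length(snp_order)
  sidx <- match(restricted$snp_id, snp_order)
  p_match <- beta * (1 - restricted$errprob) + (1 - beta) * restricted$errprob
  p_mism <- (1 - beta) * (1 - restricted$errprob) + beta * restricted$errprob
  total <- 0
  for (mask in 0:(2^n - 1)) {
    h0 <- as.integer(intToBits(mask)[seq_len(n)])
    pr <- 0.5
    if (n >= 2) pr <- pr * prod(ifelse(h0[-1] == h0[-n], rho, 1 - rho))
    lik <- prod(ifelse(restricted$allele == h0[sidx], p_match, p_mism))
    total <- total + pr * lik
  }
  total
}

# Straight-line relative likelihood: prior times per-fragment two-origin
# mixtures, computed in plain probability space.
oracle_rl <- function(h0, fragments, b0_map, rho, snp_order) {
  n <- length(snp_order)
  pr <- 1
  if (n >= 2) {
    for (j in 2:n) pr <- pr * (if (h0[j] == h0[j - 1]) rho else 1 - rho)
  }
  total <- pr
  for (fid in unique(fragments$frag_id)) {
    d <- fragments[fragments$frag_id == fid, ]
    b0 <- if (fid %in% names(b0_map)) b0_map[[fid]] else 0.5
    p0 <- 1; p1 <- 1
    for (i in seq_len(nrow(d))) {
      s <- match(d$snp_id[i], snp_order)
      e <- d$errprob[i]
      if (d$allele[i] == h0[s]) {
        p0 <- p0 * (1 - e); p1 <- p1 * e
      } else {
        p0 <- p0 * e; p1 <- p1 * (1 - e)
      }
    }
    total <- total * (b0 * p0 + (1 - b0) * p1)
  }
  log(total)
}

# Exhaustive argmax of oracle_rl over all assignments (small n only).
oracle_best_phase <- function(fragments, b0_map, rho, snp_order) {
  n <- length(snp_order)
  best <- -Inf; best_h <- NULL
  for (mask in 0:(2^n - 1)) {
    h0 <- as.integer(intToBits(mask)[seq_len(n)])
    v <- oracle_rl(h0, fragments, b0_map, rho, snp_order)
    if (v > best) { best <- v; best_h <- h0 }
  }
  list(h0 = best_h, log_rl = best)
}

# Union-find connected components over SNPs co-covered by fragments.
oracle_components <- function(fragments) {
  ids <- sort(unique(fragments$snp_id))
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (fid in unique(fragments$frag_id)) {
    s <- fragments$snp_id[fragments$frag_id == fid]
    for (i in seq_along(s)[-1]) {
      ra <- find(s[1]); rb <- find(s[i])
      if (ra != rb) parent[[as.character(rb)]] <- ra
    }
  }
  roots <- vapply(ids, find, numeric(1))
  split(ids, roots)
}

# Random restricted (size-1) read set over n SNPs.
random_restricted <- function(n_snps, n_reads, err = 0.01) {
  tibble::tibble(
    frag_id = sprintf("r%d", seq_len(n_reads)), chrom = "chr1",
    snp_id = sample.int(n_snps, n_reads, replace = TRUE),
    allele = sample(0:1, n_reads, replace = TRUE),
    errprob = rep_len(err, n_reads),
    gene_id = NA_character_, barcode = NA_character_
  )
}
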