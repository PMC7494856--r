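#' Restrict each fragment to one uniformly chosen SNP
#'
#' Produces the restricted read set R': every fragment covering more than
#' one SNP is replaced by its restriction to a single covered SNP chosen
#' uniformly at random; size-1 fragments pass through unchanged. All output
#' fragments have size 1, so the per-SNP read sets are mutually independent —
#' the conditional-independence assumption the expression-bias HMM needs.
#' Uses R's RNG; call `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param fragments Fragment table (see [fragments]).
#' @param seed Optional integer seed applied before sampling.
#' @return A fragment table in which every fragment has exactly one row.
#' @export
restrict_reads <- function(fragments, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(fragments) == 0L) return(fragments)
  fr <- arrange(fragments, .data$frag_id, .data$snp_id)
  idx <- split(seq_len(nrow(fr)), factor(fr$frag_id, levels = unique(fr$frag_id)))
  pick <- vapply(idx, function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
  fr[sort(pick), , drop = FALSE]
}

#' Tally restricted reads into per-SNP allele counts
#'
#' @param restricted Restricted fragment table from [restrict_reads()]
#'   (every fragment must have size 1).
#' @return A tibble with columns `snp_id`, `c0`, `c1` — the number of
#'   restricted reads carrying the reference / alternative allele at each
#'   covered SNP.
#' @export
compute_allele_counts <- function(restricted) {
  if (nrow(restricted) && anyDuplicated(restricted$frag_id)) {
    abort("compute_allele_counts() expects size-1 fragments; run restrict_reads() first")
  }
  restricted |>
    group_by(.data$snp_id) |>
    summarise(c0 = sum(.data$allele == 0L), c1 = sum(.data$allele == 1L),
              .groups = "drop") |>
    arrange(.data$snp_id)
}

# Per-SNP log emission terms for the two hidden states.
# State k in {0, 1} is the allele carried by the higher-expressed haplotype
# H0 at that SNP. A read showing allele a is emitted with probability
#   beta (1 - eps) + (1 - beta) eps  if a == k   (came from H0, or errored from H1)
#   (1 - beta)(1 - eps) + beta eps   otherwise.
emission_logs <- function(restricted, beta, snp_order) {
  match_p <- beta * (1 - restricted$errprob) + (1 - beta) * restricted$errprob
  mism_p <- (1 - beta) * (1 - restricted$errprob) + beta * restricted$errprob
  # state 0: match iff allele == 0; state 1: match iff allele == 1
  l0 <- ifelse(restricted$allele == 0L, log(match_p), log(mism_p))
  l1 <- ifelse(restricted$allele == 1L, log(match_p), log(mism_p))
  f <- factor(restricted$snp_id, levels = snp_order)
  e0 <- vapply(split(l0, f), sum, double(1))
  e1 <- vapply(split(l1, f), sum, double(1))
  rbind(e0, e1)
}

#' HMM forward likelihood of a gene's restricted reads given an expression bias
#'
#' Computes `f(beta) = P[R' | beta, eps]` for one gene: the probability of
#' the restricted (size-1) reads under expression bias `beta`, marginalised
#' over all haplotypes of the gene with the forward algorithm. Hidden states
#' are the two possible phase assignments at each SNP, transitions stay
#' parallel with probability `rho` and switch with `1 - rho`, the initial
#' state is uniform, and emissions multiply per-read probabilities. Work is
#' done in log space and is linear in the number of SNPs and reads.
#'
#' @param restricted Restricted fragment table (size-1 fragments) for one
#'   gene; `errprob` supplies the per-read error rates.
#' @param beta Candidate expression bias in `[0.5, 1]`.
#' @param rho Parallel-phase prior in `[0.5, 1)` (0.5 = uniform prior).
#' @param snp_order SNP ids of the gene in genomic order. Defaults to the
#'   sorted covered SNPs; pass the gene's full SNP list when `rho > 0.5` so
#'   uncovered SNPs still separate their neighbours in the prior.
#' @param log Return the log likelihood (default) or the raw probability.
#' @return A scalar (log-)likelihood.
#' @export
forward_likelihood <- function(restricted, beta, rho = 0.5, snp_order = NULL,
                               log = TRUE) {
  if (beta < 0.5 || beta > 1) abort("`beta` must lie in [0.5, 1]")
  if (rho < 0.5 || rho >= 1) abort("`rho` must lie in [0.5, 1)")
  if (is.null(snp_order)) snp_order <- sort(unique(restricted$snp_id))
  if (!length(snp_order)) return(if (log) 0 else 1)
  em <- emission_logs(restricted, beta, snp_order)
  lr <- base::log(rho); ls <- base::log1p(-rho)
  alpha <- base::log(0.5) + em[, 1L]
  for (j in seq_along(snp_order)[-1L]) {
    alpha <- c(
      logadd(alpha[1L] + lr, alpha[2L] + ls),
      logadd(alpha[1L] + ls, alpha[2L] + lr)
    ) + em[, j]
  }
  ll <- logsumexp(alpha)
  if (log) ll else exp(ll)
}

#' Maximum-likelihood expression bias of a gene
#'
#' Maximises the forward likelihood [forward_likelihood()] over
#' `beta` in `[0.5, 1]`. `f` has a unique interior maximum on that interval,
#' so Newton-Raphson on the derivative of `log f` (numeric derivatives,
#' initialised at the moment estimate `M / (m + M)` from the pooled
#' majority/minority counts) converges quickly; if it leaves the domain or
#' meets non-negative curvature the maximiser falls back to a bracketed
#' scalar search ([stats::optimize()]), and the boundary values are compared
#' explicitly. A uniform prior on `beta` makes the posterior mode equal the
#' likelihood mode.
#'
#' @inheritParams forward_likelihood
#' @param tol Convergence tolerance on `beta`.
#' @return A one-row tibble: `beta`, `log_lik`, `converged`, `method`.
#' @export
maximize_beta <- function(restricted, rho = 0.5, snp_order = NULL, tol = 1e-9) {
  if (nrow(restricted) == 0L) abort("maximize_beta() needs at least one read")
  if (is.null(snp_order)) snp_order <- sort(unique(restricted$snp_id))
  g <- function(b) forward_likelihood(restricted, b, rho, snp_order, log = TRUE)
  counts <- compute_allele_counts(restricted)
  m <- sum(pmin(counts$c0, counts$c1)); M <- sum(pmax(counts$c0, counts$c1))
  b <- clamp(M / max(m + M, 1L), 0.5 + 1e-6, 1 - 1e-6)
  h <- 1e-5
  lo <- 0.5 + h; hi <- 1 - h
  method <- "newton"; converged <- FALSE
  for (iter in seq_len(50L)) {
    gp <- g(clamp(b + h, lo, 1)); gm <- g(clamp(b - h, 0.5, hi)); g0 <- g(b)
    d1 <- (gp - gm) / (2 * h)
    d2 <- (gp - 2 * g0 + gm) / h^2
    if (!is.finite(d1) || !is.finite(d2) || d2 >= 0) break
    step <- d1 / d2
    b_new <- b - step
    if (b_new <= 0.5 || b_new >= 1) break
    if (abs(b_new - b) < tol) { b <- b_new; converged <- TRUE; break }
    b <- b_new
  }
  if (!converged) {
    opt <- optimize(g, c(0.5, 1), maximum = TRUE, tol = max(tol, 1e-10))
    b <- opt$maximum; method <- "bracketed"; converged <- TRUE
  }
  # the optimum may sit on the boundary
  cand <- c(b, 0.5, 1)
  vals <- vapply(cand, function(x) suppressWarnings(g(x)), double(1))
  vals[!is.finite(vals)] <- -Inf
  best <- which.max(vals)
  tibble(beta = cand[best], log_lik = vals[best],
         converged = converged, method = method)
}

#' Probability of concordant expression at a SNP
#'
#' The posterior probability that the observed majority allele at a SNP lies
#' on the gene's higher-expressed haplotype, given the error-adjusted
#' expression rates `gamma0 >= gamma1`:
#' `1 / (1 + (gamma1 / gamma0)^|c0 - c1|)`. Balanced counts (or
#' `gamma0 == gamma1`) carry no information and give 0.5.
#'
#' @param c0,c1 Restricted-read allele counts at the SNP (vectorised).
#' @param gamma0,gamma1 Error-adjusted expression rates
#'   `gamma_i = beta_i (1 - eps) + (1 - beta_i) eps`.
#' @return Probability in `[0.5, 1]`.
#' @export
concordance_probability <- function(c0, c1, gamma0, gamma1 = 1 - gamma0) {
  d <- abs(c0 - c1)
  ratio <- gamma1 / gamma0
  out <- ifelse(gamma0 == gamma1, 0.5, 1 / (1 + ratio^d))
  ifelse(d == 0, 0.5, out)
}

#' Probability of concordant expression from coverage alone
#'
#' Given `n` restricted reads at a SNP and error-adjusted rate `gamma0`, the
#' probability that the majority of reads shows the higher-expressed
#' haplotype's allele is the binomial tail
#' `P[X >= ceil((n+1)/2)]` with `X ~ Binomial(n, gamma0)`, together with its
#' Chernoff lower bound `1 - exp(-n (gamma0 - 1/2)^2 / (2 gamma0))`, which
#' shows the probability approaching 1 exponentially in coverage. Above
#' `normal_cutoff` reads a normal approximation (with continuity correction)
#' replaces the exact sum.
#'
#' @param n Number of restricted reads covering the SNP (vectorised).
#' @param gamma0 Error-adjusted rate of the higher-expressed haplotype.
#' @param normal_cutoff Coverage beyond which the normal approximation is
#'   used (default 1000).
#' @return A tibble with columns `prob` (the tail) and `lower_bound`
#'   (Chernoff); `n = 0` returns 0.5 by convention.
#' @export
concordance_probability_by_coverage <- function(n, gamma0, normal_cutoff = 1000) {
  k <- ceiling((n + 1) / 2)
  exact <- pbinom(k - 1, n, gamma0, lower.tail = FALSE)
  sd <- sqrt(n * gamma0 * (1 - gamma0))
  approx <- pnorm((k - 0.5 - n * gamma0) / ifelse(sd > 0, sd, 1),
                  lower.tail = FALSE)
  prob <- ifelse(n == 0, 0.5, ifelse(n > normal_cutoff, approx, exact))
  chern <- ifelse(n == 0 | gamma0 <= 0.5, 0,
                  1 - exp(-n * (gamma0 - 0.5)^2 / (2 * gamma0)))
  tibble(prob = prob, lower_bound = chern)
}

#' Two-sided binomial screen against uniform expression
#'
#' Upper-bounds the probability that the observed allelic imbalance arose
#' under uniform expression (`beta = 0.5`). For a gene, the pooled
#' minority/majority counts are `m = sum_s min(c0, c1)` and
#' `M = sum_s max(c0, c1)`; for a single SNP, `m`/`M` are that SNP's counts.
#' The bound is the two-sided binomial tail
#' `sum_{i<=m} C(N,i)/2^N + sum_{i>=M} C(N,i)/2^N` with `N = m + M`, capped
#' at 1; a normal approximation is used beyond `normal_cutoff`.
#'
#' @param counts Allele-count table from [compute_allele_counts()] (or any
#'   tibble with `c0`, `c1`).
#' @param scope `"gene"` (pool counts over SNPs, one p-value) or `"snp"`
#'   (one p-value per row).
#' @inheritParams concordance_probability_by_coverage
#' @return A single p-value bound for `scope = "gene"`, or a vector (one per
#'   SNP row) for `scope = "snp"`. `N = 0` returns 1.
#' @export
nonuniform_expression_test <- function(counts, scope = c("gene", "snp"),
                                       normal_cutoff = 1000) {
  scope <- match.arg(scope)
  if (scope == "gene") {
    m <- sum(pmin(counts$c0, counts$c1))
    M <- sum(pmax(counts$c0, counts$c1))
  } else {
    m <- pmin(counts$c0, counts$c1)
    M <- pmax(counts$c0, counts$c1)
  }
  binom_two_sided(m, M, normal_cutoff)
}

binom_two_sided <- function(m, M, normal_cutoff = 1000) {
  N <- m + M
  exact <- pbinom(m, N, 0.5) + pbinom(M - 1, N, 0.5, lower.tail = FALSE)
  sd <- sqrt(N / 4)
  approx <- pnorm((m + 0.5 - N / 2) / ifelse(sd > 0, sd, 1)) +
    pnorm((M - 0.5 - N / 2) / ifelse(sd > 0, sd, 1), lower.tail = FALSE)
  p <- ifelse(N > normal_cutoff, approx, exact)
  ifelse(N == 0, 1, pmin(p, 1))
}

#' Majority-allele haplotype pair for a gene
#'
#' Builds `H+`: the haplotype that collects the majority allele at every
#' SNP (its complement `H-` collects the minority alleles). Under size-1
#' reads, constant error `< 0.5` and a uniform phase prior, `H+` maximises
#' the relative likelihood, so this is the closed-form expression-only
#' solution. Ties (`c0 == c1`) are assigned allele 0 and flagged — they
#' carry no phasing information.
#'
#' @param counts Allele-count table (`snp_id`, `c0`, `c1`).
#' @return A tibble with `snp_id`, `h0` (majority allele), `h1`, and `tie`.
#' @export
concordant_solution <- function(counts) {
  counts |>
    mutate(
      h0 = as.integer(.data$c1 > .data$c0),
      h1 = 1L - .data$h0,
      tie = .data$c0 == .data$c1
    ) |>
    select("snp_id", "h0", "h1", "tie")
}

#' Estimate per-gene expression bias and eligibility
#'
#' Runs the full per-gene differential-haplotypic-expression workflow on the
#' restricted read set: genes with at least `min_gene_reads` restricted
#' reads get a maximum-likelihood `beta` ([maximize_beta()]), a non-uniform
#' expression p-value bound ([nonuniform_expression_test()]), and
#' error-adjusted rates `gamma0`/`gamma1` computed with the gene's mean read
#' error rate. A gene is `eligible` (usable for expression-based phasing)
#' when it was estimated and its p-value is at most `alpha`.
#'
#' @param restricted Restricted fragment table (size-1) with `gene_id` tags.
#' @param genes Gene table from [read_gene_model()].
#' @param rho Parallel-phase prior for the HMM.
#' @param alpha Significance level of the non-uniformity screen
#'   (default 0.01).
#' @param min_gene_reads Minimum restricted reads for a gene to be estimated
#'   (default 10).
#' @param normal_cutoff Passed to [nonuniform_expression_test()].
#' @return A tibble of class `dhe_fit`, one row per non-inert gene:
#'   `gene_id`, `n_reads`, `n_snps`, `beta`, `log_lik`, `pvalue`,
#'   `eligible`, `epsilon`, `gamma0`, `gamma1`.
#' @export
estimate_dhe <- function(restricted, genes, rho = 0.5, alpha = 0.01,
                         min_gene_reads = 10, normal_cutoff = 1000) {
  active <- genes[!genes$inert, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(active)), function(i) {
    g <- active[i, ]
    fr <- filter(restricted, !is.na(.data$gene_id), .data$gene_id == g$gene_id)
    n_reads <- nrow(fr)
    base_row <- tibble(
      gene_id = g$gene_id, n_reads = n_reads, n_snps = g$n_snps,
      beta = NA_real_, log_lik = NA_real_, pvalue = NA_real_,
      eligible = FALSE, epsilon = NA_real_,
      gamma0 = NA_real_, gamma1 = NA_real_
    )
    if (n_reads < min_gene_reads) return(base_row)
    fit <- maximize_beta(fr, rho = rho, snp_order = g$snp_ids[[1L]])
    counts <- compute_allele_counts(fr)
    pval <- nonuniform_expression_test(counts, "gene", normal_cutoff)
    eps <- mean(fr$errprob)
    g0 <- fit$beta * (1 - eps) + (1 - fit$beta) * eps
    mutate(base_row,
           beta = fit$beta, log_lik = fit$log_lik, pvalue = pval,
           eligible = pval <= alpha, epsilon = eps,
           gamma0 = g0, gamma1 = 1 - g0)
  })
  out <- bind_rows(rows)
  class(out) <- c("dhe_fit", class(out))
  out
}

#' Per-SNP concordance assessment
#'
#' For every SNP of every estimated gene, computes the probability that its
#' observed majority allele is concordant with the gene's higher-expressed
#' haplotype ([concordance_probability()]) and flags it `phaseable` when the
#' gene is eligible and that probability reaches `min_concordance`. Only
#' phaseable SNPs receive expression-based phasing.
#'
#' @param restricted Restricted fragment table with `gene_id` tags.
#' @param dhe Per-gene fit from [estimate_dhe()].
#' @param min_concordance Phaseability threshold (default 0.99).
#' @return A tibble: `snp_id`, `gene_id`, `c0`, `c1`, `prob_concordant`,
#'   `phaseable`.
#' @export
assess_concordance <- function(restricted, dhe, min_concordance = 0.99) {
  fr <- filter(restricted, !is.na(.data$gene_id))
  if (nrow(fr) == 0L) {
    return(tibble(snp_id = integer(), gene_id = character(), c0 = integer(),
                  c1 = integer(), prob_concordant = double(),
                  phaseable = logical()))
  }
  counts <- fr |>
    group_by(.data$gene_id, .data$snp_id) |>
    summarise(c0 = sum(.data$allele == 0L), c1 = sum(.data$allele == 1L),
              .groups = "drop")
  out <- left_join(counts,
                   select(dhe, "gene_id", "eligible", "gamma0", "gamma1"),
                   by = "gene_id")
  out |>
    mutate(
      prob_concordant = ifelse(
        is.na(.data$gamma0), 0.5,
        concordance_probability(.data$c0, .data$c1, .data$gamma0, .data$gamma1)),
      phaseable = !is.na(.data$eligible) & .data$eligible &
        .data$prob_concordant >= min_concordance
    ) |>
    select("snp_id", "gene_id", "c0", "c1", "prob_concordant", "phaseable") |>
    arrange(.data$snp_id)
}

#' Assign expected haplotype-origin biases to fragments
#'
#' A fragment whose covered SNPs all lie in one eligible gene and are all
#' phaseable receives the mixture bias
#' `b0 = p_uniform * 0.5 + (1 - p_uniform) * beta_hat` (the gene is
#' uniformly expressed with prior probability `p_uniform`, and biased at its
#' estimated rate otherwise); every other fragment gets the non-informative
#' `(0.5, 0.5)`. `b0` is the expected probability that the fragment
#' originated from the higher-expressed haplotype.
#'
#' @param fragments Full (unrestricted) fragment table with `gene_id` tags.
#' @param dhe Per-gene fit from [estimate_dhe()].
#' @param assessments Per-SNP table from [assess_concordance()].
#' @param p_uniform Mixture prior on uniform expression (default 0.5).
#' @return A tibble: `frag_id`, `b0`, `b1` with `b0 + b1 = 1`, `b0 >= 0.5`.
#' @export
assign_read_biases <- function(fragments, dhe, assessments, p_uniform = 0.5) {
  frags <- distinct(fragments, .data$frag_id, .keep_all = TRUE)
  if (nrow(fragments) == 0L) {
    return(tibble(frag_id = character(), b0 = double(), b1 = double()))
  }
  ok_snps <- assessments$snp_id[assessments$phaseable]
  eligible_genes <- dhe$gene_id[dhe$eligible]
  beta_of <- setNames(dhe$beta, dhe$gene_id)
  per_frag <- fragments |>
    group_by(.data$frag_id) |>
    summarise(
      gene_id = .data$gene_id[1L],
      all_phaseable = all(.data$snp_id %in% ok_snps),
      .groups = "drop"
    )
  per_frag |>
    mutate(
      biased = !is.na(.data$gene_id) & .data$gene_id %in% eligible_genes &
        .data$all_phaseable,
      b0 = ifelse(.data$biased,
                  p_uniform * 0.5 + (1 - p_uniform) * unname(beta_of[.data$gene_id]),
                  0.5),
      b1 = 1 - .data$b0
    ) |>
    select("frag_id", "b0", "b1")
}
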