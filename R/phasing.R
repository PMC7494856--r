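#' Build the contiguity read graph
#'
#' One vertex per SNP covered by at least one fragment; an edge joins two
#' SNPs co-covered by a fragment. Connected components of this graph are the
#' blocks that pure sequence-contiguity phasing can resolve.
#'
#' @param fragments Fragment table (see [fragments]).
#' @param panel SNP panel (supplies genomic order for component numbering).
#' @return A list of class `read_graph`: `edges` (tibble `from`/`to` of snp
#'   ids), `membership` (tibble `snp_id`/`component`, components numbered in
#'   genomic order).
#' @export
build_read_graph <- function(fragments, panel) {
  edges <- fragment_edges(fragments)
  vertices <- sort(unique(c(fragments$snp_id, edges$from, edges$to)))
  membership <- graph_components(vertices, edges, panel)
  structure(list(edges = edges, membership = membership),
            class = "read_graph")
}

# consecutive-SNP edges within each multi-SNP fragment (a path suffices for
# connectivity)
fragment_edges <- function(fragments) {
  if (nrow(fragments) == 0L) return(tibble(from = integer(), to = integer()))
  fr <- arrange(fragments, .data$frag_id, .data$snp_id)
  per <- split(fr$snp_id, factor(fr$frag_id, levels = unique(fr$frag_id)))
  per <- per[lengths(per) >= 2L]
  if (!length(per)) return(tibble(from = integer(), to = integer()))
  bind_rows(purrr::map(per, function(s) tibble(from = s[-length(s)], to = s[-1L])))
}

graph_components <- function(vertices, edges, panel) {
  if (!length(vertices)) return(tibble(snp_id = integer(), component = integer()))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(vertices))
  )
  comp <- igraph::components(g)$membership
  mem <- tibble(snp_id = as.integer(names(comp)), component = as.integer(comp))
  # renumber components by the genomic position of their first SNP
  pos_of <- setNames(panel$pos, as.character(panel$snp_id))
  chr_of <- setNames(panel$chrom, as.character(panel$snp_id))
  ord <- mem |>
    mutate(pos = unname(pos_of[as.character(.data$snp_id)]),
           chrom = unname(chr_of[as.character(.data$snp_id)])) |>
    group_by(.data$component) |>
    summarise(chrom = .data$chrom[1L], first = min(.data$pos), .groups = "drop") |>
    arrange(.data$chrom, .data$first) |>
    mutate(new = row_number())
  relabel <- setNames(ord$new, ord$component)
  mem |>
    mutate(component = unname(relabel[as.character(.data$component)])) |>
    arrange(.data$component, .data$snp_id)
}

#' Build the joint phasing blocks (contiguity + expression evidence)
#'
#' Augments the contiguity read graph with an edge clique over each eligible
#' gene's phaseable SNPs (expression imbalance links all of a gene's usable
#' SNPs, regardless of read span) and returns the connected components of
#' the union. Expression evidence never links two distinct genes — their
#' biases are independent.
#'
#' @param graph A `read_graph` from [build_read_graph()].
#' @param genes Gene table, or `NULL` for contiguity-only phasing.
#' @param assessments Per-SNP table from [assess_concordance()], or `NULL`.
#' @param panel SNP panel.
#' @return A tibble `snp_id` / `block` (blocks numbered in genomic order).
#' @export
build_joint_blocks <- function(graph, genes = NULL, assessments = NULL, panel) {
  edges <- graph$edges
  extra <- tibble(from = integer(), to = integer())
  if (!is.null(genes) && !is.null(assessments) && nrow(assessments)) {
    ok <- assessments[assessments$phaseable, , drop = FALSE]
    per_gene <- split(ok$snp_id, ok$gene_id)
    per_gene <- per_gene[lengths(per_gene) >= 2L]
    if (length(per_gene)) {
      extra <- bind_rows(purrr::map(per_gene, function(s) {
        s <- sort(s); tibble(from = s[-length(s)], to = s[-1L])
      }))
    }
  }
  all_edges <- bind_rows(edges, extra)
  vertices <- sort(unique(c(graph$membership$snp_id, all_edges$from, all_edges$to)))
  mem <- graph_components(vertices, all_edges, panel)
  rename(mem, block = "component")
}

#' Log likelihood of one fragment under a phase
#'
#' The two-origin mixture: the fragment came from haplotype `H0` with
#' probability `b0` (its alleles then agree with `h0` up to per-base error)
#' or from `H1` with probability `b1`. For an unbiased single-SNP fragment
#' this is constant in `h0` — such reads only inform phasing when their gene
#' is differentially expressed.
#'
#' @param alleles,errprobs The fragment's observed alleles and error
#'   probabilities, aligned.
#' @param h_at `h0` restricted to the fragment's SNPs (same order).
#' @param b0,b1 The fragment's haplotype-origin bias.
#' @return Scalar log probability.
#' @export
read_log_likelihood <- function(alleles, errprobs, h_at, b0, b1 = 1 - b0) {
  match0 <- alleles == h_at
  a0 <- sum(ifelse(match0, log1p(-errprobs), log(errprobs)))
  a1 <- sum(ifelse(match0, log(errprobs), log1p(-errprobs)))
  logadd(log(b0) + a0, log(b1) + a1)
}

#' Log prior of a phase under the parallel-bias model
#'
#' Adjacent SNP pairs are independently parallel (`00`/`11`) with
#' probability `rho` and switched with `1 - rho`; `rho = 0.5` is the uniform
#' prior over phases.
#'
#' @param h0 Binary haplotype vector.
#' @param rho Parallel bias in `[0.5, 1)`.
#' @return Scalar log prior probability (0 for length-1 phases).
#' @export
phase_log_prior <- function(h0, rho = 0.5) {
  n <- length(h0)
  if (n <= 1L) return(0)
  par <- sum(h0[-1L] == h0[-n])
  par * log(rho) + (n - 1L - par) * log1p(-rho)
}

#' Log relative likelihood of a phase
#'
#' `log RL(h0) = sum_r log P[r | h0, biases, eps] + log P[h0]` — the
#' posterior up to the `h0`-independent normaliser, the quantity the block
#' search maximises.
#'
#' @param h0 Binary haplotype vector over `snp_order`.
#' @param fragments Fragment table restricted to the block.
#' @param biases Bias table from [assign_read_biases()] (missing fragments
#'   default to `(0.5, 0.5)`).
#' @param rho Parallel-bias prior.
#' @param snp_order SNP ids of the block in genomic order.
#' @return Scalar log relative likelihood.
#' @export
relative_likelihood <- function(h0, fragments, biases = NULL, rho = 0.5,
                                snp_order = sort(unique(fragments$snp_id))) {
  stopifnot(length(h0) == length(snp_order))
  h_of <- setNames(h0, as.character(snp_order))
  b0_of <- bias_lookup(fragments, biases)
  total <- phase_log_prior(h0, rho)
  if (nrow(fragments)) {
    fr <- arrange(fragments, .data$frag_id, .data$snp_id)
    for (d in split(fr, factor(fr$frag_id, levels = unique(fr$frag_id)))) {
      b0 <- b0_of[[d$frag_id[1L]]]
      total <- total + read_log_likelihood(
        d$allele, d$errprob, unname(h_of[as.character(d$snp_id)]), b0)
    }
  }
  total
}

bias_lookup <- function(fragments, biases) {
  ids <- unique(fragments$frag_id)
  b <- setNames(rep(0.5, length(ids)), ids)
  if (!is.null(biases) && nrow(biases)) {
    hit <- intersect(ids, biases$frag_id)
    b[hit] <- biases$b0[match(hit, biases$frag_id)]
  }
  as.list(b)
}

# Exhaustive maximisation of RL over all 2^n phases, vectorised over
# candidates. Returns the best h0, its log RL, and (optionally) the full
# score vector.
enumerate_phases <- function(fragments, biases, rho, snp_order, scores = FALSE) {
  n <- length(snp_order)
  H <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  storage.mode(H) <- "integer"
  if (n >= 2L) {
    par <- rowSums(H[, -1L, drop = FALSE] == H[, -n, drop = FALSE])
    score <- par * log(rho) + (n - 1L - par) * log1p(-rho)
  } else {
    score <- rep(0, nrow(H))
  }
  b0_of <- bias_lookup(fragments, biases)
  if (nrow(fragments)) {
    fr <- arrange(fragments, .data$frag_id, .data$snp_id)
    col_of <- setNames(seq_along(snp_order), as.character(snp_order))
    for (d in split(fr, factor(fr$frag_id, levels = unique(fr$frag_id)))) {
      a0 <- 0; a1 <- 0
      for (k in seq_len(nrow(d))) {
        j <- col_of[[as.character(d$snp_id[k])]]
        hit <- H[, j] == d$allele[k]
        e <- d$errprob[k]
        a0 <- a0 + ifelse(hit, log1p(-e), log(e))
        a1 <- a1 + ifelse(hit, log(e), log1p(-e))
      }
      b0 <- b0_of[[d$frag_id[1L]]]
      score <- score + logadd(log(b0) + a0, log(1 - b0) + a1)
    }
  }
  best <- which.max(score)
  out <- list(h0 = H[best, ], log_rl = score[best])
  if (scores) out$all <- list(H = H, score = score)
  out
}

# Beam search over SNPs in order. Candidates carry their partial phase, the
# accumulated score of closed fragments + prior, and per-open-fragment
# partial log products for the two origin branches.
beam_phases <- function(fragments, biases, rho, snp_order, beam_width,
                        prune_ratio) {
  n <- length(snp_order)
  col_of <- setNames(seq_along(snp_order), as.character(snp_order))
  b0_of <- bias_lookup(fragments, biases)
  frag_info <- list()
  if (nrow(fragments)) {
    fr <- arrange(fragments, .data$frag_id, .data$snp_id)
    frag_info <- purrr::map(
      split(fr, factor(fr$frag_id, levels = unique(fr$frag_id))),
      function(d) {
        j <- unname(col_of[as.character(d$snp_id)])
        o <- order(j)
        list(cols = j[o], allele = d$allele[o], err = d$errprob[o],
             lb0 = log(b0_of[[d$frag_id[1L]]]),
             lb1 = log(1 - b0_of[[d$frag_id[1L]]]))
      })
  }
  starts <- lapply(seq_len(n), function(t)
    which(vapply(frag_info, function(f) f$cols[1L] == t, logical(1))))
  cands <- list(list(h = integer(), score = 0, a0 = numeric(0), a1 = numeric(0),
                     open = integer()))
  for (t in seq_len(n)) {
    nxt <- list()
    for (cand in cands) {
      for (v in 0:1) {
        c2 <- cand
        c2$h <- c(c2$h, v)
        if (t > 1L) {
          c2$score <- c2$score +
            if (v == c2$h[t - 1L]) log(rho) else log1p(-rho)
        }
        opening <- starts[[t]]
        if (length(opening)) {
          c2$open <- c(c2$open, opening)
          c2$a0 <- c(c2$a0, rep(0, length(opening)))
          c2$a1 <- c(c2$a1, rep(0, length(opening)))
        }
        keep <- rep(TRUE, length(c2$open))
        for (oi in seq_along(c2$open)) {
          f <- frag_info[[c2$open[oi]]]
          k <- match(t, f$cols)
          if (!is.na(k)) {
            e <- f$err[k]
            hit <- v == f$allele[k]
            c2$a0[oi] <- c2$a0[oi] + if (hit) log1p(-e) else log(e)
            c2$a1[oi] <- c2$a1[oi] + if (hit) log(e) else log1p(-e)
            if (k == length(f$cols)) {
              c2$score <- c2$score + logadd(f$lb0 + c2$a0[oi], f$lb1 + c2$a1[oi])
              keep[oi] <- FALSE
            }
          }
        }
        c2$open <- c2$open[keep]; c2$a0 <- c2$a0[keep]; c2$a1 <- c2$a1[keep]
        nxt[[length(nxt) + 1L]] <- c2
      }
    }
    # dominance merging: two candidates with the same open-fragment partial
    # states and the same last allele have identical futures — keep the
    # better-scoring one. This makes the search exact whenever the number of
    # distinct states fits within the beam.
    key <- vapply(nxt, function(c2) {
      paste(c2$h[t],
            paste(c2$open, collapse = ","),
            paste(sprintf("%.12g", c(c2$a0, c2$a1)), collapse = ","))
    }, character(1))
    score_now <- vapply(nxt, function(c2) c2$score, double(1))
    best_of <- tapply(seq_along(nxt), key, function(ix) ix[which.max(score_now[ix])])
    nxt <- nxt[sort(unname(best_of))]
    # optimistic potential: upper bound each open fragment by closing it now
    pot <- vapply(nxt, function(c2) {
      extra <- 0
      for (oi in seq_along(c2$open)) {
        f <- frag_info[[c2$open[oi]]]
        extra <- extra + logadd(f$lb0 + c2$a0[oi], f$lb1 + c2$a1[oi])
      }
      c2$score + extra
    }, double(1))
    ord <- order(pot, decreasing = TRUE)
    keep <- ord[pot[ord] >= pot[ord[1L]] + log(prune_ratio)]
    keep <- head(keep, beam_width)
    cands <- nxt[keep]
  }
  scores <- vapply(cands, function(c2) c2$score, double(1))
  best <- which.max(scores)
  list(h0 = cands[[best]]$h, log_rl = scores[best])
}

#' Phase one block by maximum relative likelihood
#'
#' Finds the haplotype assignment of maximal relative likelihood for a
#' block's SNPs given its fragments and their origin biases. Blocks of at
#' most `exhaustive_cutoff` SNPs are solved by full enumeration; larger
#' blocks use a branch-and-prune beam search over SNPs in genomic order
#' (each candidate prefix is extended by both alleles, scored incrementally,
#' and pruned below `prune_ratio` of the current best, capped at
#' `beam_width` candidates). When the evidence cannot distinguish a phase
#' from its complement (no expression bias, uniform prior) the returned
#' orientation is canonicalised so `h0` starts with 0.
#'
#' @param block_snps SNP ids of the block, in genomic order.
#' @param fragments Fragments covering the block.
#' @param biases Bias table from [assign_read_biases()] (`NULL` = unbiased).
#' @param rho Parallel-bias prior.
#' @param beam_width,prune_ratio,exhaustive_cutoff Search parameters
#'   (defaults 128, 0.01, 12).
#' @return A tibble with one row per SNP (`snp_id`, `h0`, `h1`) and
#'   attributes `log_rl` and `method`, or `NULL` when the block has no
#'   evidence at all.
#' @export
phase_block <- function(block_snps, fragments, biases = NULL, rho = 0.5,
                        beam_width = 128, prune_ratio = 0.01,
                        exhaustive_cutoff = 12) {
  if (length(block_snps) < 2L) abort("a block needs at least 2 SNPs")
  fragments <- filter(fragments, .data$snp_id %in% block_snps)
  if (nrow(fragments) == 0L) return(NULL)
  snp_order <- block_snps
  if (length(snp_order) <= exhaustive_cutoff) {
    res <- enumerate_phases(fragments, biases, rho, snp_order)
    method <- "exhaustive"
  } else {
    res <- beam_phases(fragments, biases, rho, snp_order, beam_width, prune_ratio)
    method <- "beam"
  }
  h0 <- res$h0
  # canonical orientation when the complement is equally likely
  rl_comp <- relative_likelihood(1L - h0, fragments, biases, rho, snp_order)
  if (abs(rl_comp - res$log_rl) < 1e-9 && h0[1L] == 1L) h0 <- 1L - h0
  out <- tibble(snp_id = snp_order, h0 = as.integer(h0),
                h1 = 1L - as.integer(h0))
  attr(out, "log_rl") <- res$log_rl
  attr(out, "method") <- method
  out
}

#' Phase every block of the joint read graph
#'
#' Builds the contiguity graph, augments it with expression-evidence links,
#' and phases each resulting block of two or more SNPs with [phase_block()].
#' Singleton components are suppressed (a one-SNP phase is vacuous). Output
#' is deterministic given the inputs.
#'
#' @param panel SNP panel.
#' @param fragments Fragment table.
#' @param genes,dhe,assessments,biases Expression-evidence inputs (all
#'   `NULL` for contiguity-only phasing).
#' @param rho,beam_width,prune_ratio,exhaustive_cutoff Passed to
#'   [phase_block()].
#' @return A block table: `block_id`, `snp_id`, `h0`, `h1`, `chrom`, `pos`,
#'   `evidence` (`+`-joined tags from `contig`, `dase`, `barcode`).
#' @export
phase_all <- function(panel, fragments, genes = NULL, dhe = NULL,
                      assessments = NULL, biases = NULL, rho = 0.5,
                      beam_width = 128, prune_ratio = 0.01,
                      exhaustive_cutoff = 12) {
  graph <- build_read_graph(fragments, panel)
  blocks_map <- build_joint_blocks(graph, genes, assessments, panel)
  empty <- tibble(block_id = integer(), snp_id = integer(), h0 = integer(),
                  h1 = integer(), chrom = character(), pos = integer(),
                  evidence = character())
  if (nrow(blocks_map) == 0L) return(empty)
  pos_of <- setNames(panel$pos, as.character(panel$snp_id))
  sizes <- table(blocks_map$block)
  keep_blocks <- as.integer(names(sizes)[sizes >= 2L])
  frag_sizes <- fragments |>
    group_by(.data$frag_id) |>
    summarise(size = dplyr::n(), .groups = "drop")
  out <- list()
  next_id <- 0L
  for (b in sort(keep_blocks)) {
    snps <- blocks_map$snp_id[blocks_map$block == b]
    snps <- snps[order(pos_of[as.character(snps)])]
    bf <- filter(fragments, .data$snp_id %in% snps)
    ph <- phase_block(snps, bf, biases, rho, beam_width, prune_ratio,
                      exhaustive_cutoff)
    if (is.null(ph)) next
    attr(ph, "log_rl") <- NULL
    attr(ph, "method") <- NULL
    next_id <- next_id + 1L
    tags <- character()
    bsizes <- frag_sizes$size[frag_sizes$frag_id %in% unique(bf$frag_id)]
    if (any(bsizes >= 2L)) tags <- c(tags, "contig")
    if (!is.null(assessments) &&
        sum(assessments$phaseable & assessments$snp_id %in% snps) >= 2L) {
      tags <- c(tags, "dase")
    }
    if (any(startsWith(unique(bf$frag_id), "bx:"))) tags <- c(tags, "barcode")
    if (!length(tags)) tags <- "contig"
    out[[next_id]] <- mutate(ph,
      block_id = next_id,
      chrom = panel$chrom[match(.data$snp_id, panel$snp_id)],
      pos = panel$pos[match(.data$snp_id, panel$snp_id)],
      evidence = paste(tags, collapse = "+")
    )
  }
  if (!length(out)) return(empty)
  select(bind_rows(out), "block_id", "snp_id", "h0", "h1", "chrom", "pos",
         "evidence")
}
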