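#' Tidy a phasing fit
#'
#' One row per phased SNP with its block, haplotype alleles and evidence
#' tags.
#'
#' @param x A `phase_fit` from [run_phase()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phase_fit <- function(x, ...) {
  as_tibble(x$blocks)
}

#' One-row summary of a phasing fit
#'
#' @inheritParams tidy.phase_fit
#' @return A one-row tibble of pipeline counters and metrics.
#' @export
glance.phase_fit <- function(x, ...) {
  dplyr::bind_cols(x$counters,
                   select(x$metrics, dplyr::any_of(c("total_span_kb",
                                                     "switch_error_rate"))))
}

#' Tidy a per-gene expression-bias fit
#'
#' @param x A `dhe_fit` from [estimate_dhe()].
#' @param ... Unused.
#' @return The per-gene tibble.
#' @export
tidy.dhe_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dhe_fit")
  out
}

#' One-row summary of a per-gene expression-bias fit
#'
#' @inheritParams tidy.dhe_fit
#' @return A one-row tibble: genes seen, estimated and eligible, and the
#'   mean estimated bias among eligible genes.
#' @export
glance.dhe_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_estimated = sum(!is.na(x$beta)),
    n_eligible = sum(x$eligible),
    mean_beta_eligible = if (any(x$eligible)) mean(x$beta[x$eligible]) else NA_real_
  )
}

#' Plot phased blocks along the genome
#'
#' Each block is a horizontal segment at its genomic span, coloured by the
#' evidence that built it; points mark the phased SNPs.
#'
#' @param object A `phase_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_fit <- function(object, ...) {
  b <- object$blocks
  if (nrow(b) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No phased blocks") +
             ggplot2::theme_minimal())
  }
  seg <- b |>
    group_by(.data$block_id, .data$chrom, .data$evidence) |>
    summarise(start = min(.data$pos), end = max(.data$pos), .groups = "drop")
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = factor(.data$block_id),
                                       yend = factor(.data$block_id),
                                       colour = .data$evidence),
                          linewidth = 2) +
    ggplot2::geom_point(data = b,
                        ggplot2::aes(x = .data$pos, y = factor(.data$block_id)),
                        size = 0.8, colour = "grey20") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "block", colour = "evidence") +
    ggplot2::theme_minimal()
}

#' Plot per-gene expression-bias estimates
#'
#' Estimated bias against read depth, with eligibility indicated.
#'
#' @param object A `dhe_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dhe_fit <- function(object, ...) {
  d <- filter(as_tibble(object), !is.na(.data$beta))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_reads, y = .data$beta,
                                  colour = .data$eligible)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "restricted reads (log scale)",
                  y = expression(hat(beta)), colour = "eligible") +
    ggplot2::theme_minimal()
}
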