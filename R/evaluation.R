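#' Switch-error rate and completeness of a predicted phase
#'
#' Compares predicted blocks to an oriented truth haplotype. Within each
#' block, SNPs with truth are taken in genomic order; each consecutive pair
#' is assessable, and a switch is recorded when the predicted relative
#' orientation of the pair (parallel vs switched) differs from the truth's.
#' This is the minimal number of chromosome switches needed to reconcile
#' prediction and truth, pooled over blocks, and is invariant under
#' complementing any block. Truth SNPs absent from the prediction are not
#' penalised — completeness is reported separately as `n_snps_phased`.
#'
#' @param blocks Block table from [phase_all()] (or [read_blocks()]).
#' @param truth Tibble with truth haplotypes: either `snp_id` + `h0`, or
#'   `chrom` + `pos` + `h0` (the allele on one chromosome copy; which copy
#'   is arbitrary).
#' @return A one-row tibble: `n_snps_phased`, `n_blocks`, `switch_errors`,
#'   `assessable_pairs`, `switch_error_rate` (percent; `NaN` when no pair is
#'   assessable).
#' @export
switch_error_rate <- function(blocks, truth) {
  if (nrow(blocks) == 0L) {
    return(tibble(n_snps_phased = 0L, n_blocks = 0L, switch_errors = 0L,
                  assessable_pairs = 0L, switch_error_rate = NaN))
  }
  if ("snp_id" %in% names(truth)) {
    joined <- left_join(blocks, select(truth, "snp_id", truth_h0 = "h0"),
                        by = "snp_id")
  } else {
    joined <- left_join(blocks,
                        select(truth, "chrom", "pos", truth_h0 = "h0"),
                        by = c("chrom", "pos"))
  }
  sw <- 0L; pairs <- 0L
  for (b in split(joined, joined$block_id)) {
    b <- arrange(b, .data$pos)
    b <- filter(b, !is.na(.data$truth_h0))
    if (nrow(b) < 2L) next
    pred_par <- b$h0[-nrow(b)] == b$h0[-1L]
    true_par <- b$truth_h0[-nrow(b)] == b$truth_h0[-1L]
    sw <- sw + sum(pred_par != true_par)
    pairs <- pairs + length(pred_par)
  }
  tibble(
    n_snps_phased = length(unique(blocks$snp_id)),
    n_blocks = length(unique(blocks$block_id)),
    switch_errors = sw,
    assessable_pairs = pairs,
    switch_error_rate = if (pairs > 0L) 100 * sw / pairs else NaN
  )
}

#' Block span and SNP counts
#'
#' The reporting companion to [switch_error_rate()]: total SNPs phased and
#' the summed genomic span of blocks (last minus first SNP position, in
#' kilobases).
#'
#' @param blocks Block table.
#' @param panel SNP panel (used when `pos` is absent from `blocks`).
#' @return A one-row tibble: `n_snps_phased`, `n_blocks`, `total_span_kb`.
#' @export
block_span_and_counts <- function(blocks, panel = NULL) {
  if (nrow(blocks) == 0L) {
    return(tibble(n_snps_phased = 0L, n_blocks = 0L, total_span_kb = 0))
  }
  if (!"pos" %in% names(blocks)) {
    blocks <- left_join(blocks, select(panel, "snp_id", "pos"), by = "snp_id")
  }
  spans <- blocks |>
    group_by(.data$block_id) |>
    summarise(span = max(.data$pos) - min(.data$pos), .groups = "drop")
  tibble(
    n_snps_phased = length(unique(blocks$snp_id)),
    n_blocks = nrow(spans),
    total_span_kb = sum(spans$span) / 1000
  )
}

#' Read a truth haplotype file
#'
#' Accepts either the simulator's tab-separated truth text (`chrom`, `pos`,
#' `h0`, `h1`) or a phased VCF whose pipe-separated genotypes provide the
#' orientation.
#'
#' @param path Truth file.
#' @return A tibble `chrom`, `pos`, `h0`.
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")[, 1L]
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    phased <- grepl("|", gt, fixed = TRUE)
    tibble(
      chrom = fix$CHROM[phased],
      pos = as.integer(fix$POS[phased]),
      h0 = as.integer(substr(gt[phased], 1L, 1L))
    )
  } else {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    tibble(chrom = as.character(d$chrom), pos = as.integer(d$pos),
           h0 = as.integer(d$h0))
  }
}
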