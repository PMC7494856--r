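#' Read the heterozygous SNP panel from a VCF
#'
#' Builds the ordered panel of biallelic heterozygous SNPs that phasing
#' operates on. Multi-allelic records, homozygous genotypes, indels and
#' records with missing genotypes are skipped (and counted); any pre-existing
#' phase in the genotype (`0|1` vs `0/1`) is ignored.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample Sample name to read the genotype from. Defaults to the first
#'   sample in the file; an unknown name is an error.
#'
#' @return A tibble with one row per panel SNP and columns `snp_id` (1-based
#'   global rank), `chrom`, `pos` (1-based), `ref`, `alt`, and `index` (dense
#'   0-based rank within the chromosome). The number of skipped records is
#'   attached as attribute `n_skipped`.
#' @export
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "dasephase")
#' read_het_snps(vcf)
read_het_snps <- function(path, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    warn("VCF has no variant records; returning an empty panel")
    out <- tibble(
      snp_id = integer(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), index = integer()
    )
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(sample)) {
    sample <- colnames(gt_mat)[1L]
  } else if (!sample %in% colnames(gt_mat)) {
    abort(sprintf("sample '%s' not present in VCF (has: %s)",
                  sample, paste(colnames(gt_mat), collapse = ", ")))
  }
  gt <- gt_mat[, sample]
  # normalise separators and ignore any pre-existing phase
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  is_het <- vapply(alleles, function(a) {
    length(a) == 2L && !anyNA(suppressWarnings(as.integer(a))) &&
      sort(as.integer(a))[1] == 0L && sort(as.integer(a))[2] == 1L
  }, logical(1))
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  keep <- !is.na(gt) & is_het & is_snp
  out <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  out <- arrange(out, .data$chrom, .data$pos)
  out <- distinct(out, .data$chrom, .data$pos, .keep_all = TRUE)
  out <- mutate(out, snp_id = row_number(), .before = 1)
  out <- mutate(group_by(out, .data$chrom), index = row_number() - 1L)
  out <- ungroup(out)
  attr(out, "n_skipped") <- sum(!keep)
  out
}
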