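#' Read a gene model and attach panel SNPs to genes
#'
#' Imports gene and exon features from a GTF/GFF file, merges each gene's
#' exons into non-overlapping intervals, and records which panel SNPs fall
#' inside any exon. Genes without a single exonic heterozygous SNP are kept
#' but flagged inert (they can never contribute expression-imbalance
#' evidence). Exon records lacking a gene identifier are skipped with a
#' warning.
#'
#' @param path Path to a GTF/GFF2/GFF3 file with `exon` features.
#' @param panel SNP panel from [read_het_snps()].
#' @param gene_key Attribute holding the gene identifier (default `gene_id`).
#'
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `exons` (list
#'   column of tibbles with 0-based half-open `start`/`end`), `snp_ids` (list
#'   column of panel `snp_id`s in exons, in genomic order), `n_snps`, and
#'   `inert`.
#' @export
read_gene_model <- function(path, panel, gene_key = "gene_id") {
  gr <- rtracklayer::import(path)
  feat <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!"type" %in% names(feat)) abort("annotation has no feature type column")
  exons <- feat[feat$type == "exon", , drop = FALSE]
  if (!gene_key %in% names(exons)) {
    abort(sprintf("annotation has no '%s' attribute", gene_key))
  }
  no_id <- is.na(exons[[gene_key]]) | exons[[gene_key]] == ""
  if (any(no_id)) {
    warn(sprintf("skipping %d exon record(s) without %s", sum(no_id), gene_key))
    exons <- exons[!no_id, , drop = FALSE]
  }
  if (nrow(exons) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  exons = list(), snp_ids = list(),
                  n_snps = integer(), inert = logical()))
  }
  # rtracklayer gives 1-based closed intervals; internal convention is
  # 0-based half-open.
  ex <- tibble(
    gene_id = as.character(exons[[gene_key]]),
    chrom = as.character(exons$seqnames),
    start = as.integer(exons$start) - 1L,
    end = as.integer(exons$end)
  )
  per_gene <- split(ex, ex$gene_id)
  rows <- purrr::map(per_gene, function(g) {
    merged <- merge_intervals(g$start, g$end)
    snps <- panel[panel$chrom == g$chrom[1L], , drop = FALSE]
    if (nrow(snps)) {
      p0 <- snps$pos - 1L # 0-based point coordinate
      inside <- vapply(p0, function(p) any(p >= merged$start & p < merged$end),
                       logical(1))
      ids <- snps$snp_id[inside]
    } else {
      ids <- integer()
    }
    tibble(
      gene_id = g$gene_id[1L], chrom = g$chrom[1L],
      exons = list(merged), snp_ids = list(ids),
      n_snps = length(ids), inert = length(ids) == 0L
    )
  })
  arrange(bind_rows(rows), .data$chrom, purrr::map_int(.data$exons, ~ min(.x$start)))
}

# Merge possibly overlapping half-open intervals.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}
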