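#' Extract allele observations from aligned reads
#'
#' Walks every aligned read (SAM or BAM) over the heterozygous SNP panel and
#' records, for each panel SNP covered by an aligned base, the observed
#' allele (0 = ref base, 1 = alt base) together with an error probability
#' derived from the base quality (`10^(-Q/10)`, clamped to `[1e-6, 0.49]`).
#' Bases matching neither genotype allele are treated as absent, so a
#' fragment never carries an allele outside the genotype. CIGAR splice (`N`)
#' and indel operators are honoured, which lets spliced RNA-seq reads link
#' SNPs across introns. Paired mates sharing a read name are merged into one
#' fragment; reads covering no panel SNP are dropped.
#'
#' @param path SAM or BAM file. SAM input is converted (and
#'   coordinate-sorted) on the fly; BAM input must be coordinate-sorted.
#' @param panel SNP panel from [read_het_snps()].
#' @param genes Optional gene table from [read_gene_model()]; when given,
#'   fragments whose SNPs all lie in one gene are tagged with its `gene_id`.
#' @param min_mapq,min_baseq Mapping- and base-quality filters (defaults 20
#'   and 10). Duplicate, secondary and supplementary alignments are always
#'   skipped.
#' @param barcode_tag SAM tag holding a linked-read barcode (default `BX`).
#' @param mate_conflict What to do when merged mates disagree at a shared
#'   SNP: drop that locus (default) or drop the whole fragment.
#'
#' @return A fragment table (see [fragments]).
#' @export
extract_fragments <- function(path, panel, genes = NULL,
                              min_mapq = 20, min_baseq = 10,
                              barcode_tag = "BX",
                              mate_conflict = c("drop-locus", "drop-fragment")) {
  mate_conflict <- match.arg(mate_conflict)
  if (nrow(panel) == 0L) return(empty_fragments())
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai"))) {
      ok <- tryCatch({ Rsamtools::indexBam(bam); TRUE },
                     error = function(e) FALSE)
      if (!ok) abort("BAM must be coordinate-sorted (indexing failed)")
    }
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isDuplicate = FALSE, isSupplementaryAlignment = FALSE
    ),
    what = c("qname", "mapq", "seq", "qual"),
    tag = barcode_tag
  )
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(aln)
  pass <- is.na(mc$mapq) | mc$mapq >= min_mapq
  aln <- aln[pass]; mc <- S4Vectors::mcols(aln)
  if (length(aln) == 0L) return(empty_fragments())

  cig <- GenomicAlignments::cigar(aln)
  ref_rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = GenomicAlignments::start(aln), ops = c("M", "=", "X"))
  qry_rng <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  nseg <- lengths(ref_rng)
  seg_aln <- rep(seq_along(aln), nseg)
  refR <- unlist(ref_rng, use.names = FALSE)
  qryR <- unlist(qry_rng, use.names = FALSE)
  seg_gr <- GenomicRanges::GRanges(
    rep(as.character(GenomicAlignments::seqnames(aln)), nseg), refR)
  snp_gr <- GenomicRanges::GRanges(panel$chrom,
                                   IRanges::IRanges(panel$pos, panel$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, seg_gr)
  if (length(hits) == 0L) return(empty_fragments())

  snp_i <- S4Vectors::queryHits(hits)
  seg_i <- S4Vectors::subjectHits(hits)
  aln_i <- seg_aln[seg_i]
  qpos <- IRanges::start(qryR)[seg_i] + (panel$pos[snp_i] - IRanges::start(refR)[seg_i])
  seqs <- as.character(mc$seq)[aln_i]
  quals <- as.character(mc$qual)[aln_i]
  base <- substr(seqs, qpos, qpos)
  q <- vapply(seq_along(qpos),
              function(i) utf8ToInt(substr(quals[i], qpos[i], qpos[i])) - 33L,
              integer(1))
  allele <- dplyr::case_when(
    base == panel$ref[snp_i] ~ 0L,
    base == panel$alt[snp_i] ~ 1L,
    TRUE ~ NA_integer_
  )
  bc <- if (barcode_tag %in% names(mc)) as.character(mc[[barcode_tag]])[aln_i]
        else rep(NA_character_, length(aln_i))
  obs <- tibble(
    frag_id = mc$qname[aln_i],
    chrom = panel$chrom[snp_i],
    snp_id = panel$snp_id[snp_i],
    allele = allele,
    errprob = phred_to_error(q),
    barcode = bc,
    baseq = q
  )
  obs <- filter(obs, !is.na(.data$allele), .data$baseq >= min_baseq)
  if (nrow(obs) == 0L) return(empty_fragments())

  # merge mates / duplicate coverage of the same locus within a read pair
  merged <- obs |>
    group_by(.data$frag_id, .data$chrom, .data$snp_id) |>
    summarise(
      n0 = sum(.data$allele == 0L), n1 = sum(.data$allele == 1L),
      errprob = min(.data$errprob),
      barcode = if (any(!is.na(.data$barcode))) .data$barcode[!is.na(.data$barcode)][1L]
                else NA_character_,
      .groups = "drop"
    )
  conflict <- merged$n0 > 0L & merged$n1 > 0L
  if (mate_conflict == "drop-fragment") {
    bad <- unique(merged$frag_id[conflict])
    merged <- filter(merged, !.data$frag_id %in% bad)
  } else {
    merged <- merged[!conflict, , drop = FALSE]
  }
  out <- merged |>
    mutate(allele = as.integer(.data$n1 > 0L), gene_id = NA_character_) |>
    select("frag_id", "chrom", "snp_id", "allele", "errprob", "gene_id", "barcode") |>
    arrange(.data$chrom, .data$snp_id, .data$frag_id)
  if (!is.null(genes)) out <- tag_fragment_genes(out, genes)
  assert_fragments(out)
  out
}
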