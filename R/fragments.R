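#' Fragment tables
#'
#' Fragments (reads, read pairs, or barcode groups) are represented in long
#' form: one row per observed allele, with columns `frag_id`, `chrom`,
#' `snp_id` (global panel id), `allele` (0 = ref, 1 = alt), `errprob`
#' (probability the opposite allele was sequenced), and optional `gene_id`
#' and `barcode` tags. Loci a fragment does not cover simply have no row; a
#' fragment's size is its number of rows.
#'
#' @name fragments
NULL

#' Write fragments to the plain-text exchange format
#'
#' One fragment per line: id, chromosome, comma-separated
#' `index:allele:errprob` triples (per-chromosome 0-based panel index), then
#' optional `barcode=` / `gene=` fields. This format is the test vehicle and
#' lets fragments be prepared by external extractors.
#'
#' @param fragments Fragment table (see [fragments]).
#' @param panel SNP panel from [read_het_snps()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, panel, path) {
  assert_fragments(fragments)
  if (nrow(fragments) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  idx <- setNames(panel$index, as.character(panel$snp_id))
  fr <- fragments
  fr$pidx <- idx[as.character(fr$snp_id)]
  fr <- arrange(fr, .data$frag_id, .data$pidx)
  per <- split(fr, factor(fr$frag_id, levels = unique(fr$frag_id)))
  lines <- vapply(per, function(d) {
    triples <- paste(d$pidx, d$allele, formatC(d$errprob, format = "g", digits = 8),
                     sep = ":", collapse = ",")
    extra <- character()
    bc <- if ("barcode" %in% names(d)) d$barcode[1L] else NA_character_
    gn <- if ("gene_id" %in% names(d)) d$gene_id[1L] else NA_character_
    if (!is.na(bc)) extra <- c(extra, paste0("barcode=", bc))
    if (!is.na(gn)) extra <- c(extra, paste0("gene=", gn))
    paste(c(d$frag_id[1L], d$chrom[1L], triples, extra), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read fragments from the plain-text exchange format
#'
#' @inheritParams write_fragments
#' @param path Input file path.
#' @return A fragment table (see [fragments]).
#' @export
read_fragments <- function(path, panel) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_fragments())
  key <- paste(panel$chrom, panel$index, sep = "\r")
  id_of <- setNames(panel$snp_id, key)
  rows <- purrr::map(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) abort(sprintf("malformed fragment line: '%s'", paste(f, collapse = "\t")))
    trip <- strsplit(strsplit(f[3L], ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    pidx <- vapply(trip, function(t) as.integer(t[1L]), integer(1))
    allele <- vapply(trip, function(t) as.integer(t[2L]), integer(1))
    err <- vapply(trip, function(t) as.numeric(t[3L]), double(1))
    snp <- id_of[paste(f[2L], pidx, sep = "\r")]
    if (anyNA(snp)) abort(sprintf("fragment '%s' references SNP index absent from panel", f[1L]))
    extra <- f[-(1:3)]
    bc <- sub("^barcode=", "", grep("^barcode=", extra, value = TRUE))
    gn <- sub("^gene=", "", grep("^gene=", extra, value = TRUE))
    tibble(
      frag_id = f[1L], chrom = f[2L], snp_id = unname(snp),
      allele = allele, errprob = err,
      gene_id = if (length(gn)) gn[1L] else NA_character_,
      barcode = if (length(bc)) bc[1L] else NA_character_
    )
  })
  out <- bind_rows(rows)
  assert_fragments(out)
  out
}

#' Merge fragments that share a barcode
#'
#' Fragments carrying the same barcode on the same chromosome are collapsed
#' into one pseudo-fragment, pooling their allele observations: this is how
#' linked-read (e.g. 10X) evidence spans SNPs no single read covers. At a SNP
#' observed several times within a group, the majority allele is kept with
#' the smallest contributing error probability; an exact tie drops the locus.
#' Fragments without a barcode pass through unchanged. The operation is
#' idempotent.
#'
#' @param fragments Fragment table (see [fragments]).
#' @return A fragment table; merged pseudo-fragments are named
#'   `bx:<chrom>:<barcode>`.
#' @export
merge_barcoded_fragments <- function(fragments) {
  if (nrow(fragments) == 0L || !"barcode" %in% names(fragments) ||
      all(is.na(fragments$barcode))) {
    return(fragments)
  }
  tagged <- filter(fragments, !is.na(.data$barcode))
  plain <- filter(fragments, is.na(.data$barcode))
  merged <- tagged |>
    group_by(.data$chrom, .data$barcode, .data$snp_id) |>
    summarise(
      n0 = sum(.data$allele == 0L), n1 = sum(.data$allele == 1L),
      errprob = min(.data$errprob),
      gene_id = if (dplyr::n_distinct(.data$gene_id) == 1L) .data$gene_id[1L] else NA_character_,
      .groups = "drop"
    ) |>
    filter(.data$n0 != .data$n1) |>
    mutate(
      allele = as.integer(.data$n1 > .data$n0),
      frag_id = paste("bx", .data$chrom, .data$barcode, sep = ":")
    ) |>
    select("frag_id", "chrom", "snp_id", "allele", "errprob", "gene_id", "barcode")
  # a merged fragment spanning several genes carries no single gene tag
  multi <- merged |>
    group_by(.data$frag_id) |>
    summarise(one_gene = dplyr::n_distinct(.data$gene_id) == 1L, .groups = "drop")
  merged <- left_join(merged, multi, by = "frag_id") |>
    mutate(gene_id = ifelse(.data$one_gene, .data$gene_id, NA_character_)) |>
    select(-"one_gene")
  bind_rows(plain, merged) |> arrange(.data$frag_id, .data$snp_id)
}

#' Tag fragments with the gene whose exonic SNPs they cover
#'
#' A fragment receives a `gene_id` only when *all* of its covered SNPs belong
#' to a single gene's exonic SNP set; fragments straddling two genes keep
#' their contiguity evidence but get no gene (distinct genes have independent
#' expression biases, so no per-gene bias applies to them).
#'
#' @param fragments Fragment table.
#' @param genes Gene table from [read_gene_model()].
#' @return The fragment table with `gene_id` filled in.
#' @export
tag_fragment_genes <- function(fragments, genes) {
  if (nrow(fragments) == 0L || nrow(genes) == 0L) return(fragments)
  snp2gene <- tibble(
    snp_id = unlist(genes$snp_ids),
    gid = rep(genes$gene_id, lengths(genes$snp_ids))
  )
  # a SNP inside two overlapping genes is ambiguous -> no tag through it
  dup <- snp2gene$snp_id[duplicated(snp2gene$snp_id)]
  snp2gene$gid[snp2gene$snp_id %in% dup] <- NA_character_
  snp2gene <- distinct(snp2gene, .data$snp_id, .keep_all = TRUE)
  fr <- left_join(select(fragments, -dplyr::any_of("gene_id")), snp2gene, by = "snp_id")
  tag <- fr |>
    group_by(.data$frag_id) |>
    summarise(
      gene_id = if (all(!is.na(.data$gid)) && dplyr::n_distinct(.data$gid) == 1L)
        .data$gid[1L] else NA_character_,
      .groups = "drop"
    )
  left_join(select(fr, -"gid"), tag, by = "frag_id")
}
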