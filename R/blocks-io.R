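#' Write phased blocks as HapCUT-style text
#'
#' Each block is emitted as a `BLOCK:` header followed by one line per SNP
#' (panel id, haplotype-0 allele, haplotype-1 allele, chromosome, position)
#' and a `********` terminator — the de-facto exchange format of read-backed
#' phasers. [read_blocks()] parses it back bit-exactly.
#'
#' @param blocks Block table from [phase_all()]: columns `block_id`,
#'   `snp_id`, `h0`, `h1`, `chrom`, `pos`, `evidence`.
#' @param panel SNP panel (used to fill `chrom`/`pos` if absent).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, panel, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# dasephase phased blocks", con)
  if (nrow(blocks) == 0L) return(invisible(path))
  if (!all(c("chrom", "pos") %in% names(blocks))) {
    blocks <- left_join(blocks, select(panel, "snp_id", "chrom", "pos"),
                        by = "snp_id")
  }
  for (b in split(blocks, blocks$block_id)) {
    b <- arrange(b, .data$pos)
    ev <- if ("evidence" %in% names(b)) b$evidence[1L] else "contig"
    writeLines(sprintf("BLOCK: id %d len %d evidence %s",
                       b$block_id[1L], nrow(b), ev), con)
    writeLines(sprintf("%d\t%d\t%d\t%s\t%d",
                       b$snp_id, b$h0, b$h1, b$chrom, b$pos), con)
    writeLines("********", con)
  }
  invisible(path)
}

#' Parse HapCUT-style block text written by [write_blocks()]
#'
#' @param path Input file path.
#' @return A block table (`block_id`, `snp_id`, `h0`, `h1`, `chrom`, `pos`,
#'   `evidence`).
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); cur_id <- NA_integer_; cur_ev <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, "BLOCK:")) {
      f <- strsplit(ln, "\\s+")[[1]]
      cur_id <- as.integer(f[which(f == "id") + 1L])
      cur_ev <- f[which(f == "evidence") + 1L]
    } else if (ln != "********") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- tibble(
        block_id = cur_id, snp_id = as.integer(f[1]),
        h0 = as.integer(f[2]), h1 = as.integer(f[3]),
        chrom = f[4], pos = as.integer(f[5]), evidence = cur_ev
      )
    }
  }
  if (!length(out)) {
    return(tibble(block_id = integer(), snp_id = integer(), h0 = integer(),
                  h1 = integer(), chrom = character(), pos = integer(),
                  evidence = character()))
  }
  bind_rows(out)
}

#' Write a phased VCF
#'
#' Emits the full panel as a minimal VCF in which every phased SNP carries a
#' pipe-separated genotype `h0|h1` and a `PS` tag equal to the position of
#' its block's first SNP; unphased panel SNPs are written `0/1`.
#'
#' @inheritParams write_blocks
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(blocks, panel, path, sample = "SAMPLE") {
  ph <- if (nrow(blocks)) {
    blocks |>
      group_by(.data$block_id) |>
      mutate(ps = min(.data$pos)) |>
      ungroup() |>
      select("snp_id", "h0", "h1", "ps")
  } else {
    tibble(snp_id = integer(), h0 = integer(), h1 = integer(), ps = integer())
  }
  v <- left_join(panel, ph, by = "snp_id")
  gt <- ifelse(is.na(v$h0), "0/1",
               sprintf("%d|%d:%d", v$h0, v$h1, v$ps))
  fmt <- ifelse(is.na(v$h0), "GT", "GT:PS")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=dasephase",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set (position of first SNP in block)">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  ), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\t%s\t%s",
                     v$chrom, v$pos, v$ref, v$alt, fmt, gt), con)
  invisible(path)
}
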