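#' Configuration for the scene simulator
#'
#' Bundles the generative parameters of a synthetic phasing scene. The
#' defaults describe a well-covered RNA-seq experiment over a panel of
#' expressed genes: per-gene expression bias drawn uniformly from
#' `{0.5, 0.6, 0.7, 0.8, 0.9}` (the point mass at 0.5 gives non-biased
#' genes), mean restricted coverage of 100 reads per SNP, 1% base error,
#' and mostly single-SNP fragments with a tail of multi-SNP ones.
#'
#' @param n_genes Number of genes.
#' @param snps_per_gene Integer range (min, max) of heterozygous SNPs per
#'   gene.
#' @param n_exons,exon_length,intron_length Integer ranges for the exon
#'   layout (bp).
#' @param intergenic Gap between consecutive genes (bp).
#' @param beta_values Expression-bias values sampled uniformly per gene
#'   (all in `[0.5, 1]`).
#' @param coverage Mean number of reads per SNP.
#' @param frag_size_probs Named numeric vector: probability that a fragment
#'   covers 1, 2, ... consecutive SNPs.
#' @param base_error Per-base sequencing error rate `eps` (allele flipped
#'   with this probability).
#' @param barcode_rate Fraction of fragments carrying a barcode tag
#'   (grouped within their gene).
#' @param cross_gene_reads Number of extra fragments per adjacent gene pair
#'   that span the two genes (for testing the no-cross-gene-bias rule).
#' @param truth_rho Parallel bias used when drawing the truth haplotype
#'   (0.5 = uniform).
#' @param chrom Chromosome name.
#' @param seed RNG seed fixing the full scene.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 20, snps_per_gene = c(3L, 8L),
                              n_exons = c(2L, 4L), exon_length = c(150L, 400L),
                              intron_length = c(500L, 2000L),
                              intergenic = 5000L,
                              beta_values = c(0.5, 0.6, 0.7, 0.8, 0.9),
                              coverage = 100,
                              frag_size_probs = c("1" = 0.6, "2" = 0.3, "3" = 0.1),
                              base_error = 0.01, barcode_rate = 0,
                              cross_gene_reads = 0L, truth_rho = 0.5,
                              chrom = "chr1", seed = 42L) {
  if (n_genes < 1L) abort("need at least one gene")
  if (any(beta_values < 0.5 | beta_values > 1)) {
    abort("`beta_values` must lie in [0.5, 1]")
  }
  if (base_error < 0 || base_error >= 0.5) abort("`base_error` must lie in [0, 0.5)")
  if (coverage <= 0) abort("`coverage` must be positive")
  if (abs(sum(frag_size_probs) - 1) > 1e-8) abort("`frag_size_probs` must sum to 1")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a ground-truthed phasing scene
#'
#' Draws a full scene under the model the phaser assumes: genes with exon
#' structure and exonic heterozygous SNPs, a truth haplotype per SNP, a
#' per-gene expression bias `beta`, and reads that each pick the
#' higher-expressed haplotype with probability `beta`, cover a contiguous
#' run of the gene's SNPs, and report each allele flipped with probability
#' `base_error`. Everything is reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, the scene's VCF, GTF,
#'   fragment text and truth text are written there (and a SAM file when
#'   `write_sam = TRUE`).
#' @param write_sam Also emit a coordinate-sorted SAM file whose alignments
#'   reproduce the fragments (spliced CIGARs across introns).
#' @return A list of class `truth_scene`: `panel`, `genes`, `truth`
#'   (`chrom`, `pos`, `snp_id`, `h0`, `h1`), `gene_truth` (`gene_id`,
#'   `beta`), `fragments`, `config`, and `files` (paths, when written).
#' @export
simulate_scene <- function(config, dir = NULL, write_sam = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rint <- function(rng) if (rng[1] >= rng[2]) as.integer(rng[1]) else
    sample(seq.int(rng[1], rng[2]), 1L)

  cursor <- 1000L
  gene_rows <- list(); snp_rows <- list(); frag_rows <- list()
  gene_truth <- list()
  frag_n <- 0L

  for (gi in seq_len(config$n_genes)) {
    gid <- sprintf("g%03d", gi)
    k <- rint(config$n_exons)
    ex_s <- integer(k); ex_e <- integer(k)
    p <- cursor
    for (j in seq_len(k)) {
      len <- rint(config$exon_length)
      ex_s[j] <- p; ex_e[j] <- p + len
      p <- ex_e[j] + rint(config$intron_length)
    }
    cursor <- ex_e[k] + config$intergenic
    n_snps <- rint(config$snps_per_gene)
    exonic <- unlist(lapply(seq_len(k), function(j) seq.int(ex_s[j], ex_e[j] - 1L)))
    pos0 <- sort(sample(exonic, min(n_snps, length(exonic))))
    n_snps <- length(pos0)
    ref <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1), USE.NAMES = FALSE)
    h0 <- integer(n_snps)
    h0[1L] <- rbinom(1L, 1L, 0.5)
    if (n_snps > 1L) {
      for (j in 2:n_snps) {
        h0[j] <- if (runif(1) < config$truth_rho) h0[j - 1L] else 1L - h0[j - 1L]
      }
    }
    beta <- sample(config$beta_values, 1L)
    gene_truth[[gi]] <- tibble(gene_id = gid, beta = beta, n_snps = n_snps)
    snp_rows[[gi]] <- tibble(
      chrom = config$chrom, pos = pos0 + 1L, ref = ref, alt = alt,
      gene_id = gid, h0 = h0, h1 = 1L - h0
    )
    gene_rows[[gi]] <- tibble(
      gene_id = gid, chrom = config$chrom,
      exons = list(tibble(start = ex_s, end = ex_e)),
      first = ex_s[1L]
    )

    sizes <- as.integer(names(config$frag_size_probs))
    mean_size <- sum(sizes * config$frag_size_probs)
    n_reads <- max(1L, round(config$coverage * n_snps / mean_size))
    n_bc <- max(1L, ceiling(n_reads / 10))
    for (ri in seq_len(n_reads)) {
      frag_n <- frag_n + 1L
      sz <- min(sample(sizes, 1L, prob = config$frag_size_probs), n_snps)
      start <- sample.int(n_snps - sz + 1L, 1L)
      cov <- start:(start + sz - 1L)
      origin <- rbinom(1L, 1L, 1 - beta) # 0 = higher-expressed haplotype
      hap <- if (origin == 0L) h0[cov] else 1L - h0[cov]
      flip <- runif(sz) < config$base_error
      obs <- ifelse(flip, 1L - hap, hap)
      bc <- if (config$barcode_rate > 0 && runif(1) < config$barcode_rate) {
        sprintf("%s-bc%03d", gid, sample.int(n_bc, 1L))
      } else NA_character_
      frag_rows[[frag_n]] <- tibble(
        frag_id = sprintf("r%06d", frag_n), chrom = config$chrom,
        gene_i = gi, snp_local = cov, allele = as.integer(obs),
        errprob = clamp(config$base_error, 1e-6, 0.49),
        gene_id = gid, barcode = bc
      )
    }
  }

  panel <- bind_rows(snp_rows) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(snp_id = row_number(), .before = 1)
  panel <- mutate(group_by(panel, .data$chrom), index = row_number() - 1L)
  panel <- ungroup(panel)

  # resolve local SNP indices to global snp ids
  per_gene_ids <- split(panel$snp_id, panel$gene_id)
  fragments <- bind_rows(frag_rows)
  if (nrow(fragments)) {
    fragments$snp_id <- vapply(seq_len(nrow(fragments)), function(i) {
      per_gene_ids[[sprintf("g%03d", fragments$gene_i[i])]][fragments$snp_local[i]]
    }, integer(1))
    fragments <- select(fragments, "frag_id", "chrom", "snp_id", "allele",
                        "errprob", "gene_id", "barcode")
  } else {
    fragments <- empty_fragments()
  }

  # optional fragments straddling adjacent genes (no gene tag applies)
  if (config$cross_gene_reads > 0L && config$n_genes > 1L) {
    for (gi in seq_len(config$n_genes - 1L)) {
      a <- per_gene_ids[[sprintf("g%03d", gi)]]
      b <- per_gene_ids[[sprintf("g%03d", gi + 1L)]]
      for (ci in seq_len(config$cross_gene_reads)) {
        frag_n <- frag_n + 1L
        snps <- c(a[length(a)], b[1L])
        hap_side <- rbinom(1L, 1L, 0.5)
        tru <- panel$h0[match(snps, panel$snp_id)]
        hap <- if (hap_side == 0L) tru else 1L - tru
        flip <- runif(2) < config$base_error
        fragments <- bind_rows(fragments, tibble(
          frag_id = sprintf("r%06d", frag_n), chrom = config$chrom,
          snp_id = snps, allele = as.integer(ifelse(flip, 1L - hap, hap)),
          errprob = clamp(config$base_error, 1e-6, 0.49),
          gene_id = NA_character_, barcode = NA_character_
        ))
      }
    }
  }

  genes <- bind_rows(gene_rows) |>
    arrange(.data$first) |>
    select(-"first")
  genes$snp_ids <- purrr::map(genes$gene_id, ~ sort(per_gene_ids[[.x]]))
  genes$n_snps <- lengths(genes$snp_ids)
  genes$inert <- genes$n_snps == 0L

  truth <- select(panel, "chrom", "pos", "snp_id", "h0", "h1")
  panel_out <- select(panel, "snp_id", "chrom", "pos", "ref", "alt", "index")
  scene <- structure(list(
    panel = panel_out, genes = genes, truth = truth,
    gene_truth = bind_rows(gene_truth), fragments = fragments,
    config = config, files = list()
  ), class = "truth_scene")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      vcf = file.path(dir, "scene.vcf"),
      gtf = file.path(dir, "scene.gtf"),
      fragments = file.path(dir, "scene.frags.txt"),
      truth = file.path(dir, "scene.truth.tsv")
    )
    write_scene_vcf(scene, files$vcf)
    write_scene_gtf(scene, files$gtf)
    write_fragments(scene$fragments, scene$panel, files$fragments)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (write_sam) {
      files$sam <- file.path(dir, "scene.sam")
      write_scene_sam(scene, files$sam)
    }
    scene$files <- files
  }
  scene
}

write_scene_vcf <- function(scene, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=dasephase-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSIM"
  ), con)
  p <- scene$panel
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0/1",
                     p$chrom, p$pos, p$ref, p$alt), con)
  invisible(path)
}

write_scene_gtf <- function(scene, path) {
  con <- file(path, "wt"); on.exit(close(con))
  for (i in seq_len(nrow(scene$genes))) {
    g <- scene$genes[i, ]
    ex <- g$exons[[1L]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gene_id, g$gene_id)
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\t%s",
                       g$chrom, min(ex$start) + 1L, max(ex$end), attrs), con)
    writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t+\t.\t%s",
                       g$chrom, ex$start + 1L, ex$end, attrs), con)
  }
  invisible(path)
}

# Emit the scene's fragments as spliced alignments. Only bases at panel SNP
# positions are meaningful (others are 'A'); CIGARs jump introns with N.
write_scene_sam <- function(scene, path) {
  p <- scene$panel
  frs <- split(scene$fragments, scene$fragments$frag_id)
  qv <- max(2L, min(40L, as.integer(round(-10 * log10(
    max(scene$config$base_error, 1e-4))))))
  qchar <- intToUtf8(qv + 33L)
  recs <- purrr::map(frs, function(d) {
    d <- arrange(d, .data$snp_id)
    gid <- d$gene_id[1L]
    snp_pos <- p$pos[match(d$snp_id, p$snp_id)]
    p1 <- min(snp_pos); p2 <- max(snp_pos)
    if (!is.na(gid)) {
      ex <- scene$genes$exons[[match(gid, scene$genes$gene_id)]]
      segs <- tibble(start = pmax(ex$start + 1L, p1), end = pmin(ex$end, p2))
      segs <- segs[segs$start <= segs$end, , drop = FALSE]
    } else {
      segs <- tibble(start = snp_pos, end = snp_pos)
    }
    lens <- segs$end - segs$start + 1L
    gaps <- if (nrow(segs) > 1L) segs$start[-1L] - segs$end[-nrow(segs)] - 1L
            else integer()
    cigar <- paste0(lens[1L], "M")
    if (length(gaps)) {
      for (j in seq_along(gaps)) {
        cigar <- paste0(cigar, gaps[j], "N", lens[j + 1L], "M")
      }
    }
    seq_chars <- rep("A", sum(lens))
    offs <- cumsum(c(0L, head(lens, -1L)))
    for (k in seq_len(nrow(d))) {
      sp <- snp_pos[k]
      j <- which(segs$start <= sp & segs$end >= sp)[1L]
      qpos <- offs[j] + (sp - segs$start[j]) + 1L
      row <- match(d$snp_id[k], p$snp_id)
      seq_chars[qpos] <- if (d$allele[k] == 0L) p$ref[row] else p$alt[row]
    }
    tibble(
      qname = d$frag_id[1L], pos = p1,
      line = sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s%s",
                     d$frag_id[1L], d$chrom[1L], p1, cigar,
                     paste(seq_chars, collapse = ""),
                     strrep(qchar, sum(lens)),
                     if (!is.na(d$barcode[1L]))
                       paste0("\tBX:Z:", d$barcode[1L]) else "")
    )
  })
  recs <- arrange(bind_rows(recs), .data$pos, .data$qname)
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", scene$config$chrom, max(p$pos) + 10000L)
  ), con)
  writeLines(recs$line, con)
  invisible(path)
}

#' Summarise a simulated scene
#'
#' Per-gene bookkeeping used by test assertions: true `beta`, SNP and
#' fragment counts, and pooled allele-observation tallies.
#'
#' @param scene A `truth_scene` from [simulate_scene()].
#' @return A tibble with one row per gene.
#' @export
scene_report <- function(scene) {
  if (nrow(scene$gene_truth) == 0L) {
    return(tibble(gene_id = character(), beta = double(), n_snps = integer(),
                  n_fragments = integer(), n_obs = integer(),
                  c0 = integer(), c1 = integer()))
  }
  counts <- scene$fragments |>
    filter(!is.na(.data$gene_id)) |>
    group_by(.data$gene_id) |>
    summarise(
      n_fragments = dplyr::n_distinct(.data$frag_id),
      n_obs = dplyr::n(),
      c0 = sum(.data$allele == 0L), c1 = sum(.data$allele == 1L),
      .groups = "drop"
    )
  out <- left_join(scene$gene_truth, counts, by = "gene_id")
  out |>
    mutate(dplyr::across(c("n_fragments", "n_obs", "c0", "c1"),
                         ~ ifelse(is.na(.x), 0L, .x)))
}
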