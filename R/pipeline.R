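#' Pipeline configuration
#'
#' Collects every tunable parameter of the phasing pipeline with its
#' default. All thresholds are exposed here and documented in the methods
#' vignette.
#'
#' @param p_uniform Mixture prior that a gene is uniformly expressed
#'   (default 0.5).
#' @param rho Parallel-phase prior (default 0.5 = uniform).
#' @param alpha_nonuniform Significance level of the non-uniform expression
#'   screen (default 0.01).
#' @param min_concordance Minimum concordance probability for a SNP to be
#'   phaseable by expression evidence (default 0.99).
#' @param min_gene_reads Minimum restricted reads for a gene to enter bias
#'   estimation (default 10).
#' @param normal_approx_cutoff Coverage beyond which binomial tails use the
#'   normal approximation (default 1000).
#' @param beam_width,prune_ratio,exhaustive_cutoff Block-search parameters
#'   (defaults 128, 0.01, 12).
#' @param min_mapq,min_baseq Alignment extraction filters (defaults 20, 10).
#' @param dase_enabled Use expression evidence (requires an annotation).
#' @param seed Seed for the read-restriction draw (default 42).
#' @return A list of class `phase_config`.
#' @export
phase_config <- function(p_uniform = 0.5, rho = 0.5, alpha_nonuniform = 0.01,
                         min_concordance = 0.99, min_gene_reads = 10,
                         normal_approx_cutoff = 1000, beam_width = 128,
                         prune_ratio = 0.01, exhaustive_cutoff = 12,
                         min_mapq = 20, min_baseq = 10, dase_enabled = TRUE,
                         seed = 42L) {
  structure(as.list(environment()), class = "phase_config")
}

#' Run the full phasing pipeline
#'
#' Orchestrates the end-to-end run: read the heterozygous panel, extract or
#' load fragments (pooling multiple alignment files for joint DNA+RNA
#' phasing), merge barcode groups, and — when expression evidence is
#' enabled and an annotation is given — restrict reads, estimate per-gene
#' expression bias, screen genes and SNPs, and assign fragment biases.
#' Joint blocks are then phased by maximum relative likelihood and written
#' out; when a truth phase is supplied, switch-error metrics are computed.
#'
#' @param vcf Path to the genotype VCF.
#' @param alignments Character vector of SAM/BAM paths (optional).
#' @param fragment_files Character vector of fragment-text paths (optional;
#'   at least one evidence source is required).
#' @param annotation Optional GTF/GFF path (required for expression
#'   evidence).
#' @param truth Optional truth haplotype file (simulator TSV or phased VCF).
#' @param out_dir Optional output directory for the block text, phased VCF,
#'   per-gene diagnostics and metrics TSVs.
#' @param config A [phase_config()].
#' @param sample VCF sample name (default: first).
#' @return A list of class `phase_fit`: `blocks`, `panel`, `dhe`,
#'   `assessments`, `metrics`, `counters` (per-stage tallies), `config`.
#' @export
run_phase <- function(vcf, alignments = NULL, fragment_files = NULL,
                      annotation = NULL, truth = NULL, out_dir = NULL,
                      config = phase_config(), sample = NULL) {
  if (is.null(alignments) && is.null(fragment_files)) {
    abort("at least one evidence source (alignments or fragment files) is required")
  }
  panel <- read_het_snps(vcf, sample = sample)
  genes <- if (!is.null(annotation)) read_gene_model(annotation, panel) else NULL
  if (config$dase_enabled && is.null(genes)) {
    inform("no annotation given: expression evidence disabled")
  }
  frs <- list()
  for (a in alignments %||% character()) {
    frs[[length(frs) + 1L]] <- extract_fragments(
      a, panel, genes, min_mapq = config$min_mapq, min_baseq = config$min_baseq)
  }
  for (f in fragment_files %||% character()) {
    fr <- read_fragments(f, panel)
    if (!is.null(genes)) fr <- tag_fragment_genes(fr, genes)
    frs[[length(frs) + 1L]] <- fr
  }
  # distinct ids per source so pooled files cannot collide
  fragments <- bind_rows(purrr::imap(frs, function(fr, i) {
    mutate(fr, frag_id = paste0("s", i, ":", .data$frag_id))
  }))
  if (nrow(fragments) == 0L) fragments <- empty_fragments()
  fragments <- merge_barcoded_fragments(fragments)

  dhe <- NULL; assessments <- NULL; biases <- NULL
  use_dase <- config$dase_enabled && !is.null(genes)
  if (use_dase) {
    gene_frs <- filter(fragments, !is.na(.data$gene_id))
    restricted <- restrict_reads(gene_frs, seed = config$seed)
    dhe <- estimate_dhe(restricted, genes,
                        rho = config$rho, alpha = config$alpha_nonuniform,
                        min_gene_reads = config$min_gene_reads,
                        normal_cutoff = config$normal_approx_cutoff)
    assessments <- assess_concordance(restricted, dhe,
                                      min_concordance = config$min_concordance)
    biases <- assign_read_biases(fragments, dhe, assessments,
                                 p_uniform = config$p_uniform)
  }

  blocks <- phase_all(panel, fragments,
                      genes = if (use_dase) genes else NULL,
                      dhe = dhe, assessments = assessments, biases = biases,
                      rho = config$rho, beam_width = config$beam_width,
                      prune_ratio = config$prune_ratio,
                      exhaustive_cutoff = config$exhaustive_cutoff)

  metrics <- block_span_and_counts(blocks, panel)
  if (!is.null(truth)) {
    tr <- if (is.character(truth)) read_truth(truth) else truth
    se <- switch_error_rate(blocks, tr)
    metrics <- dplyr::bind_cols(metrics,
                                select(se, "switch_errors", "assessable_pairs",
                                       "switch_error_rate"))
  }
  counters <- tibble(
    n_snps_panel = nrow(panel),
    n_fragments = dplyr::n_distinct(fragments$frag_id),
    n_genes = if (!is.null(genes)) nrow(genes) else 0L,
    n_genes_eligible = if (!is.null(dhe)) sum(dhe$eligible) else 0L,
    n_snps_phaseable = if (!is.null(assessments)) sum(assessments$phaseable) else 0L,
    n_blocks = metrics$n_blocks,
    n_snps_phased = metrics$n_snps_phased
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_blocks(blocks, panel, file.path(out_dir, "blocks.txt"))
    write_phased_vcf(blocks, panel, file.path(out_dir, "phased.vcf"))
    if (!is.null(dhe)) {
      utils::write.table(dhe, file.path(out_dir, "genes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  structure(list(blocks = blocks, panel = panel, dhe = dhe,
                 assessments = assessments, metrics = metrics,
                 counters = counters, config = config),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("<phase_fit>\n")
  cat(sprintf("  %d SNPs in panel, %d phased in %d block(s)\n",
              x$counters$n_snps_panel, x$counters$n_snps_phased,
              x$counters$n_blocks))
  if (!is.null(x$dhe)) {
    cat(sprintf("  %d/%d genes eligible for expression evidence\n",
                sum(x$dhe$eligible), nrow(x$dhe)))
  }
  if ("switch_error_rate" %in% names(x$metrics)) {
    cat(sprintf("  switch-error rate: %.2f%% (%d/%d pairs)\n",
                x$metrics$switch_error_rate, x$metrics$switch_errors,
                x$metrics$assessable_pairs))
  }
  invisible(x)
}
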