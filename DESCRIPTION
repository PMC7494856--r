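Package: dasephase
Title: Diploid Haplotype Phasing from Read Contiguity and Allelic Expression Imbalance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phases heterozygous SNPs of a diploid individual into haplotype
    blocks by combining two lines of evidence from sequencing reads: sequence
    contiguity (reads or barcode groups spanning several SNPs) and differential
    haplotypic expression (DHE) in RNA-seq data, which links variants through a
    gene-wide allelic imbalance even when every read covers a single SNP. The
    per-gene expression bias is estimated by maximum likelihood with a
    two-state hidden Markov model over the gene's SNPs, genes and SNPs are
    screened with binomial tests for usable imbalance, and each phasing block
    is solved by a relative-likelihood search (exhaustive for small blocks,
    beam otherwise). Includes readers for VCF/GTF/SAM/BAM, a HapCUT-style
    block writer, switch-error evaluation against a truth phase, and a
    ground-truthed scene simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    rlang,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
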