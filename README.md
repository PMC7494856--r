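# dasephase

Read-backed haplotype phasing for diploid genomes that uses **two** lines of
evidence: classical sequence contiguity (reads, read pairs and barcode
groups spanning several heterozygous SNPs) and **allelic expression
imbalance** in RNA-seq data, which links all usable SNPs of a gene — even
when every read covers a single SNP.

The package is aimed at researchers who already have aligned reads (RNA-seq,
exome/WGS, or linked reads) and a genotype VCF for one individual, and want
phased haplotype blocks plus the diagnostics that say *why* each block was
phased.

## The model in brief

A phase over a block of heterozygous SNPs is a pair of complementary binary
haplotypes H = (H₀, H₁). Each fragment *r* contributes a two-origin mixture
likelihood

P[r | H] = Σᵢ bᵢʳ · Π_{s ∈ A(r,Hᵢ)} (1 − ε_{r,s}) · Π_{s ∈ D(r,Hᵢ)} ε_{r,s},

where ε_{r,s} is the per-base error probability and b₀ʳ is the probability
that *r* originated from H₀. For fragments of genes with **differential
haplotypic expression** (DHE) — the gene emits reads from its
higher-expressed haplotype with probability β > 0.5 — the bias b₀ʳ is set to
the mixture p·0.5 + (1 − p)·β̂, which is what lets single-SNP reads phase.
β̂ is the maximum-likelihood bias computed per gene with a two-state hidden
Markov model over the gene's SNPs (forward algorithm + Newton–Raphson).
Genes must pass a two-sided binomial screen against uniform expression
(α = 0.01) and each SNP a concordance-probability screen
(1/(1 + (γ₁/γ₀)^|C⁰−C¹|) ≥ 0.99, γᵢ = βᵢ(1−ϵ) + (1−βᵢ)ϵ) before expression
evidence is used. Blocks are the connected components of the joint read
graph (contiguity edges plus within-gene expression links) and each block is
solved by maximising the relative likelihood — exhaustively for small
blocks, by beam search with dominance merging otherwise. Accuracy against a
truth phase is reported as the switch-error rate: the percentage of
consecutive assessable SNP pairs whose predicted relative orientation
disagrees with the truth.

## Worked example

Every function is testable without external data through the built-in scene
simulator, which draws genes, truth haplotypes, per-gene expression biases
and reads from the generative model described above:

```r
library(dasephase)

scene <- simulate_scene(
  simulation_config(n_genes = 6, coverage = 80, base_error = 0.01, seed = 7),
  dir = tempdir()
)
fit <- run_phase(scene$files$vcf,
                 fragment_files = scene$files$fragments,
                 annotation = scene$files$gtf,
                 truth = scene$files$truth,
                 config = phase_config(seed = 7))
fit
#> <phase_fit>
#>   31 SNPs in panel, 31 phased in 6 block(s)
#>   6/6 genes eligible for expression evidence
#>   switch-error rate: 0.00% (0/25 pairs)
```

All 31 panel SNPs are phased into one block per gene; all six genes show
significant allelic imbalance, so their fragments carried expression
biases; and every assessable consecutive SNP pair agrees with the simulated
truth (0 switch errors over 25 pairs). `tidy(fit)` returns the per-SNP block
table, `glance(fit)` the one-row summary, and `autoplot(fit)` /
`autoplot(fit$dhe)` draw the blocks and the per-gene bias estimates.

With real data the call is the same, pointing at your files:

```r
run_phase("calls.vcf", alignments = c("rna.bam", "exome.bam"),
          annotation = "gencode.gtf", out_dir = "phased")
```

or from a shell via the bundled wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dasephase-phase.R", package="dasephase"))')" \
  --vcf calls.vcf --bam rna.bam --gff gencode.gtf --out phased
```

Outputs: HapCUT-style `blocks.txt`, a phased VCF with `PS` tags, per-gene
diagnostics (`genes.tsv`) and metrics (`metrics.tsv`).

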