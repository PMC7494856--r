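---
title: "Expression-aware haplotype phasing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-aware haplotype phasing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasephase)
library(dplyr)
```

## The problem

A diploid genome carries two copies of every chromosome. Genotyping tells us
*which* two alleles an individual carries at each heterozygous SNP, but not
*how* the alleles are distributed over the two chromosome copies. Phasing
reconstructs that assignment: two complementary binary haplotypes
$H = (H_0, H_1)$ over the ordered panel of biallelic heterozygous SNPs
(0 = reference allele, 1 = alternative).

Read-backed phasers traditionally rely on **sequence contiguity**: a read (or
read pair, or barcode group) that covers two or more heterozygous SNPs links
them onto one chromosome copy. The reach of this evidence is bounded by the
fragment length, and a read that covers a single SNP contributes nothing. In
RNA-seq data, however, most fragments cover exactly one SNP — and RNA-seq
carries a second, longer-range signal. Many genes are expressed unequally
from their two haplotypes (**differential haplotypic expression**, DHE). If a
gene emits reads from its higher-expressed haplotype with probability
$\beta > 0.5$, then at every SNP of that gene the allele sitting on the
higher-expressed haplotype is over-represented in the read pile-up
(**differential allele-specific expression**, DASE). Collecting the majority
allele at each SNP of the gene therefore reconstructs the gene's haplotype —
using only single-SNP reads, across arbitrarily long introns and
SNP-free exonic stretches.

`dasephase` combines both signals in one relative-likelihood framework:
contiguity evidence from reads, pairs and barcode groups, plus expression
evidence from genes with measurable DHE, and searches for the
maximum-likelihood phase of every block.

## The model

### Fragments and the likelihood of a phase

Each fragment $r$ is a sparse vector over SNPs with entries in $\{0, 1, -\}$
and a per-locus error probability $\varepsilon_{r,s}$ (the probability the
opposite allele was read). Given a phase $h_0$ and the probability $b_0^r$
that fragment $r$ originated from haplotype $H_0$, the fragment likelihood is
a two-origin mixture:

$$P[r \mid H] = \sum_{i \in \{0,1\}} b_i^r
  \prod_{s \in A(r, H_i)} (1 - \varepsilon_{r,s})
  \prod_{s \in D(r, H_i)} \varepsilon_{r,s},$$

where $A$ and $D$ are the loci where $r$ agrees/disagrees with $H_i$. The
phase prior allows a parallel bias $\rho \ge 0.5$: adjacent SNPs are
independently parallel with probability $\rho$ and switched with $1 - \rho$
($\rho = 0.5$ is the uniform prior, the default). The product of fragment
likelihoods and the prior is the **relative likelihood** `relative_likelihood()`
— the posterior up to a constant — which the block search maximises.

For an unbiased ($b_0 = 0.5$) single-SNP fragment this mixture is constant in
$h_0$; only when $b_0 > 0.5$ do single-SNP reads carry phasing information.
That is exactly what the expression model supplies.

### Estimating the expression bias

For one gene, reads are first **restricted**: every multi-SNP fragment is
cut down to one uniformly chosen covered SNP (`restrict_reads()`). This
sacrifices a little contiguity information *for the estimation step only*
(the block search later uses the full fragments) but makes the per-SNP read
sets conditionally independent, which turns the marginal likelihood of the
restricted reads given $\beta$ into a two-state hidden Markov chain over the
gene's SNPs: the hidden state at SNP $s$ is which allele $H_0$ carries,
transitions stay parallel with probability $\rho$, and each restricted read
at $s$ is emitted with probability
$\beta(1-\varepsilon) + (1-\beta)\varepsilon$ if it matches the state and
$(1-\beta)(1-\varepsilon) + \beta\varepsilon$ otherwise. The forward
algorithm (`forward_likelihood()`) evaluates $f(\beta)$ in time linear in
SNPs and reads, and $f$ has a unique interior maximum on $[0.5, 1]$, so
Newton–Raphson started at the moment estimate $M/(m+M)$ — with a bracketed
golden-section fallback and explicit boundary comparison — finds the MLE
(`maximize_beta()`).

### Screening: which genes and SNPs are usable

Expression evidence is only trusted where it is strong enough to orient a
SNP correctly:

* **Non-uniformity screen** (`nonuniform_expression_test()`): a two-sided
  binomial bound on the pooled minority/majority counts
  $m = \sum_s \min(C^0_s, C^1_s)$, $M = \sum_s \max(C^0_s, C^1_s)$ under
  $\beta = 0.5$. A gene is eligible when this p-value bound is at most
  $\alpha$ (default 0.01).
* **Concordance screen** (`concordance_probability()`): the posterior
  probability that a SNP's majority allele lies on the higher-expressed
  haplotype, $1 / (1 + (\gamma_1/\gamma_0)^{|C^0_s - C^1_s|})$ with
  $\gamma_i = \beta_i(1-\epsilon) + (1-\beta_i)\epsilon$. A SNP is phaseable
  when this reaches `min_concordance` (default 0.99). Balanced counts give
  0.5 — no information — so tied SNPs are never phased on expression alone.

`concordance_probability_by_coverage()` gives the prospective version: with
$N$ reads the probability that the majority allele is concordant is the
binomial tail $P[X \ge \lceil (N+1)/2 \rceil]$, $X \sim B(N, \gamma_0)$,
bounded below by the Chernoff bound
$1 - \exp(-N(\gamma_0 - \tfrac12)^2 / 2\gamma_0)$ — concordance improves
exponentially with coverage, which is why the expression signal is most
valuable in well-covered libraries.

Fragments whose SNPs all lie in one eligible gene and are all phaseable
receive the mixture bias $b_0 = p \cdot 0.5 + (1-p)\hat\beta$, where $p$
(default 0.5) is the prior that the gene is in truth uniformly expressed;
all other fragments get $b_0 = 0.5$ (`assign_read_biases()`). Fragments
spanning two genes keep their contiguity evidence but receive no bias, since
distinct genes have independent expression.

### Blocks and the search

The contiguity read graph joins SNPs co-covered by a fragment; expression
evidence adds a clique over each eligible gene's phaseable SNPs, never
between genes. Connected components of the joint graph are the phasing
blocks. Each block is solved by maximising the relative likelihood:
exhaustively for blocks of at most `exhaustive_cutoff` SNPs (default 12),
otherwise by a beam search in genomic SNP order with dominance merging
(candidates with identical open-fragment states keep only the best scorer,
which makes the search exact whenever the state space fits the beam), a
beam cap (`beam_width`, default 128) and relative pruning (`prune_ratio`,
default 0.01). Under size-1 reads, constant error and a uniform prior, the
optimum is provably the majority-allele haplotype $H^+$
(`concordant_solution()`), which the test suite verifies by enumeration.

When no bias breaks the complement symmetry, a block and its complement
score identically; the reported orientation is then canonicalised so `h0`
starts with 0. One-SNP components are suppressed — a single-SNP "phase"
says nothing.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rho` | 0.5 | prior probability that adjacent SNPs are phased in parallel; 0.5 = uniform prior |
| `p_uniform` | 0.5 | prior that a gene is uniformly expressed; shrinks assigned biases toward 0.5 |
| `alpha_nonuniform` | 0.01 | significance level of the non-uniformity screen |
| `min_concordance` | 0.99 | minimum concordance probability for a SNP to be expression-phaseable |
| `min_gene_reads` | 10 | restricted reads required before a gene's bias is estimated |
| `normal_approx_cutoff` | 1000 | coverage above which binomial tails use a normal approximation (with continuity correction); below it exact sums are cheap |
| `beam_width`, `prune_ratio`, `exhaustive_cutoff` | 128, 0.01, 12 | block-search controls; the cutoff keeps small blocks provably optimal |
| `min_mapq`, `min_baseq` | 20, 10 | alignment extraction filters; duplicates/secondary/supplementary are always skipped |
| `seed` | 42 | fixes the single read-restriction draw |

Defaults for the screens are deliberately conservative: an expression-phased
SNP placed on the wrong haplotype costs a switch error, while a skipped SNP
merely goes unphased; with genome-scale panels a per-SNP failure rate must
be well below $10^{-2}$ for block-level accuracy, hence
`min_concordance = 0.99` and `alpha = 0.01`. Restriction is performed once
per run with a fixed seed rather than averaged over draws: the estimate is
already tight at the coverages where expression evidence passes the screens,
and a single draw keeps the pipeline deterministic.

## Numerical choices

* All likelihoods are carried in log space; mixtures use a stable
  `log(a + b)` on log inputs. Error probabilities of 0 are accepted in the
  model functions (closed-form tests use them), while extraction clamps
  Phred-derived probabilities to $[10^{-6}, 0.49]$ so logs stay finite and an
  "error" is never likelier than the call.
* `maximize_beta()` uses numeric first/second differences of $\log f$
  (step $10^{-5}$); any sign trouble in the curvature or a step outside
  $(0.5, 1)$ triggers the bracketed fallback. Boundary values $f(0.5)$ and
  $f(1)$ are compared explicitly so boundary maxima are returned as such.
* Ties: equal allele counts at a SNP are assigned allele 0 on $H^+$ and
  flagged, mate conflicts at a shared SNP drop the locus (mirroring the
  "absent" semantics of unreadable bases), and barcode-group conflicts are
  resolved by majority with ties dropped.
* The Chernoff exponent is evaluated at the error-adjusted rate $\gamma_0$,
  and the bound is verified numerically against the exact tail in the test
  suite across $N \le 10^4$.

## The simulator: what it does and does not emulate

`simulate_scene()` draws scenes from exactly the generative model the
method assumes: genes laid out with exon/intron structure, exonic
heterozygous SNPs, truth haplotypes drawn uniformly (or with parallel bias
for prior tests), one bias $\beta$ per gene from a configurable set
(default $\{0.5, 0.6, 0.7, 0.8, 0.9\}$, the point mass at 0.5 providing
non-DHE genes), reads that pick the higher-expressed haplotype with
probability $\beta$, cover a contiguous run of the gene's SNPs (size
distribution configurable down to all-singleton), and flip each reported
allele with probability $\varepsilon$. Optional extras: barcode grouping,
fragments straddling adjacent genes, and a spliced SAM rendering of the
fragments for the alignment extractor.

It does **not** emulate isoform mixtures, GC or mappability bias,
position-dependent error profiles, transcriptional bursting, or
reference-alignment artefacts. Passing tests on simulated scenes therefore
demonstrate the correctness of the inference given the model's assumptions —
not robustness to every failure mode of real RNA-seq. On real data the
screens (`alpha`, `min_concordance`) are the guardrails, and DNA evidence
can be pooled in to anchor blocks.

Default problem sizes used in the checked examples — 20 genes, per-SNP
coverage 100, $\varepsilon = 0.01$, several hundred reads per estimated
gene — are typical of a well-covered RNA-seq library restricted to
expressed genes, and keep every simulation exactly reproducible from one
seed.

## Design decisions

* **Per-gene representative error rate.** The closed-form screens use
  $\gamma_i$ computed with the mean $\varepsilon$ over the gene's restricted
  reads; per-read errors remain in the HMM and in the block search.
* **Restricted vs full fragments.** $R'$ exists solely to estimate $\beta$;
  the block search consumes the full fragments so no contiguity evidence is
  lost.
* **No re-estimation of $\beta$ after phasing.** An EM-style loop would
  couple the estimate to the phase it later informs; the one-pass design
  keeps the screens honest and the pipeline deterministic.
* **Orientation.** When expression evidence orients a block, `h0` is the
  higher-expressed haplotype; otherwise orientation is arbitrary and
  canonicalised.
* **Sequential execution.** The command-line wrapper accepts `--threads`
  for interface compatibility, but blocks are processed sequentially;
  block independence makes the output contract (identical results
  regardless of scheduling) trivially true.

## Limitations

* Diploid only; polyploid search is out of scope.
* One isoform per gene is assumed: with multiple differentially expressed
  isoforms the per-SNP bias need not be constant across a gene, and the
  gene-level $\beta$ model can be mis-specified.
* $\varepsilon$ is taken from base qualities (or the simulator), not
  re-estimated from data.
* Genes sharing a SNP (overlapping annotation) make the gene tag ambiguous;
  such SNPs pass through without expression evidence.

## A worked example

```{r example}
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
glance(fit)
tidy(fit) |> head()
glance(fit$dhe)
```

```{r plots, fig.width = 6, fig.height = 3}
autoplot(fit)
autoplot(fit$dhe)
```
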