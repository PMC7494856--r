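# Numerically stable log(sum(exp(x))); -Inf entries are handled exactly.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(a + b) given la = log(a), lb = log(b)
logadd <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log1p(exp(pmin(la, lb) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Phred quality -> error probability, clamped so downstream logs stay finite
# and an "error" is never more likely than the call itself.
phred_to_error <- function(q) {
  pmin(pmax(10^(-q / 10), 1e-6), 0.49)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Empty fragment table with the canonical long layout: one row per
# (fragment, SNP) observation.
empty_fragments <- function() {
  tibble(
    frag_id = character(), chrom = character(), snp_id = integer(),
    allele = integer(), errprob = double(),
    gene_id = NA_character_, barcode = NA_character_
  )[0, ]
}

assert_fragments <- function(fragments, arg = "fragments") {
  need <- c("frag_id", "chrom", "snp_id", "allele", "errprob")
  missing <- setdiff(need, names(fragments))
  if (length(missing)) {
    abort(sprintf("`%s` lacks column(s): %s", arg, paste(missing, collapse = ", ")))
  }
  if (nrow(fragments)) {
    if (!all(fragments$allele %in% c(0L, 1L))) {
      abort(sprintf("`%s` contains alleles outside {0, 1}", arg))
    }
    if (any(fragments$errprob <= 0 | fragments$errprob >= 0.5)) {
      abort(sprintf("`%s` contains error probabilities outside (0, 0.5)", arg))
    }
  }
  invisible(fragments)
}
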