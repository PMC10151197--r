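#' @keywords internal
"_PACKAGE"

NUCLEOTIDES <- c("A", "C", "G", "T")

# Watson-Crick complement of single-nucleotide allele codes (vectorized).
allele_complement <- function(a) chartr("ACGT", "TGCA", a)

# A/T and C/G pairs are strand-ambiguous.
is_palindromic_pair <- function(ea, oa) allele_complement(ea) == oa

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Two-sided normal p-value from an estimate and its standard error.
z_pval <- function(est, se) 2 * stats::pnorm(-abs(est / se))

# Format numerics for TSV output so that a read round-trip is bit-faithful.
num_chr <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "."
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
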