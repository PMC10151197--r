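#' Effective number of independent tests from a phenotypic correlation matrix
#'
#' Principal-component procedure for relaxing Bonferroni correction across a
#' family of correlated phenotypes: square the correlation matrix
#' element-wise, eigendecompose it, and let n be the smallest number of
#' leading eigenvalues whose cumulative sum reaches `var_target` of the
#' trace. The number of individual tests within the squared matrix is
#' T = n(n - 1)/2 and the effective number of tests is sqrt(T), giving the
#' corrected per-test threshold alpha / sqrt(T). For a family of 13
#' effectively independent phenotypes this yields T = 78, sqrt(T) = 8.83 and
#' a threshold of 0.006 (3 dp) at alpha = 0.05.
#'
#' @param corr symmetric correlation matrix with unit diagonal, entries in
#'   [-1, 1].
#' @param var_target cumulative variance-explained target (default 0.995).
#' @param alpha family-wise level (default 0.05).
#' @return An object of class `effective_tests_result` with fields
#'   `n_components`, `n_tests`, `m_eff`, `alpha`, `threshold`. In the
#'   degenerate perfectly-correlated case (n = 1, T = 0) the threshold falls
#'   back to `alpha` with a warning.
#' @export
effective_tests <- function(corr, var_target = 0.995, alpha = 0.05) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || !isSymmetric(unname(corr), tol = 1e-8)) {
    stop("correlation matrix must be square and symmetric")
  }
  if (any(abs(corr) > 1 + 1e-8)) stop("correlation entries must lie in [-1, 1]")
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("correlation diagonal must be 1")
  sq <- corr^2
  ev <- eigen(sq, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev)
  n <- which(cum >= var_target * sum(ev))[1]
  n_tests <- n * (n - 1) / 2
  m_eff <- sqrt(n_tests)
  if (m_eff == 0) {
    warning("single effective component; threshold falls back to alpha")
    threshold <- alpha
  } else {
    threshold <- alpha / m_eff
  }
  structure(list(n_components = n, n_tests = n_tests, m_eff = m_eff,
                 alpha = alpha, threshold = threshold,
                 eigenvalues = ev, var_target = var_target),
            class = "effective_tests_result")
}

#' @export
print.effective_tests_result <- function(x, ...) {
  cat(sprintf(paste0("<effective_tests_result> n = %d components, ",
                     "T = %g tests, sqrt(T) = %.2f\n"),
              x$n_components, x$n_tests, x$m_eff))
  cat(sprintf("  corrected threshold: %.3f (alpha = %g)\n", x$threshold, x$alpha))
  invisible(x)
}

#' Read / write a phenotypic correlation matrix as square TSV
#'
#' Square tab-delimited layout with a header row and a leading name column.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_corr_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, quote = "", comment.char = "")
  as.matrix(raw)
}

#' @rdname read_corr_matrix
#' @param corr matrix to write.
#' @export
write_corr_matrix <- function(corr, path) {
  out <- data.frame(phenotype = rownames(corr), corr, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
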