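#' Analytic power for a two-sample IVW Mendelian randomization test
#'
#' Normal approximation for the IVW z-test: with outcome-GWAS sample size n,
#' instrument strength R^2 (variance of the exposure explained by the
#' instruments) and causal effect `effect`, the noncentrality is
#' lambda = |effect| * sqrt(n * r2 * v), where v = 1 for a continuous
#' outcome and K(1 - K) for a binary outcome with case fraction K (effects on
#' the log odds-ratio scale). Two-sided power includes the opposite-tail
#' term, so power equals alpha exactly at effect = 0.
#'
#' @param effect causal effect (SD units, or log OR for binary outcomes).
#' @param n outcome-GWAS sample size.
#' @param r2 variance of the exposure explained by the instruments, in (0,1).
#' @param alpha significance level (default 0.05).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param case_fraction case fraction K for binary outcomes.
#' @return power in [0, 1].
#' @export
mr_power <- function(effect, n, r2, alpha = 0.05,
                     outcome_type = c("continuous", "binary"),
                     case_fraction = NULL) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(r2 > 0, r2 < 1, n > 0, alpha > 0, alpha < 1)
  v <- if (outcome_type == "binary") {
    if (is.null(case_fraction) || case_fraction <= 0 || case_fraction >= 1) {
      stop("binary outcome needs case_fraction in (0, 1)")
    }
    case_fraction * (1 - case_fraction)
  } else 1
  lambda <- abs(effect) * sqrt(n * r2 * v)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(lambda - z) + stats::pnorm(-lambda - z)
}

#' Minimum detectable effect at a target power
#'
#' Smallest |effect| whose analytic power (see [mr_power()]) reaches
#' `power_target`, found by monotone bisection to absolute tolerance 1e-6.
#'
#' @inheritParams mr_power
#' @param power_target target power (default 0.8).
#' @return the minimum detectable effect (positive scale of `effect`).
#' @export
min_detectable_effect <- function(n, r2, alpha = 0.05, power_target = 0.8,
                                  outcome_type = c("continuous", "binary"),
                                  case_fraction = NULL) {
  outcome_type <- match.arg(outcome_type)
  pw <- function(eff) mr_power(eff, n, r2, alpha, outcome_type, case_fraction)
  hi <- 1
  while (pw(hi) < power_target) hi <- hi * 2
  lo <- 0
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= power_target) hi <- mid else lo <- mid
  }
  hi
}
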