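new_mr_estimate <- function(method, estimate, se, pval = NULL, n_snp,
                            outcome_type = "continuous", extras = list(),
                            ci_low = NULL, ci_high = NULL) {
  z <- stats::qnorm(0.975)
  structure(list(
    method = method, estimate = estimate, se = se,
    ci_low = ci_low %||% (estimate - z * se),
    ci_high = ci_high %||% (estimate + z * se),
    pval = pval %||% z_pval(estimate, se),
    n_snp = n_snp, outcome_type = outcome_type, extras = extras
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNPs)\n", x$method, x$n_snp))
  cat(sprintf("  estimate %.*f (se %.*f), 95%% CI [%.*f, %.*f], p = %.3g\n",
              digits, x$estimate, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, x$pval))
  if (identical(x$outcome_type, "binary")) {
    cat(sprintf("  OR %.*f, 95%% CI [%.*f, %.*f]\n",
                digits, exp(x$estimate), digits, exp(x$ci_low),
                digits, exp(x$ci_high)))
  }
  invisible(x)
}

#' Odds-ratio view of a binary-outcome MR estimate
#'
#' @param x an `mr_estimate` for a binary outcome (log odds-ratio scale).
#' @return named numeric: `or`, `or_ci_low`, `or_ci_high`.
#' @export
as_odds_ratio <- function(x) {
  stopifnot(inherits(x, "mr_estimate"))
  c(or = exp(x$estimate), or_ci_low = exp(x$ci_low), or_ci_high = exp(x$ci_high))
}

# Kept variants with usable exposure/outcome effects.
mr_data <- function(h, require_nonzero_exposure = FALSE) {
  k <- kept(h)
  if (require_nonzero_exposure) {
    zero <- k$beta_exp == 0
    if (all(zero)) stop("all exposure effects are zero")
    if (any(zero)) {
      warning(sum(zero), " variant(s) with zero exposure effect excluded ",
              "from ratio-based estimation")
      k <- k[!zero, , drop = FALSE]
    }
  }
  k
}

#' Per-variant ratio (Wald) estimates
#'
#' theta_j = beta_out / beta_exp with first-order standard error
#' se_out / |beta_exp|. Variants with a zero exposure effect are excluded
#' with a warning (error if none remain).
#'
#' @param h a `harmonized_set`.
#' @return data.frame with `variant_id`, `estimate`, `se`.
#' @export
ratio_estimates <- function(h) {
  k <- mr_data(h, require_nonzero_exposure = TRUE)
  data.frame(variant_id = k$variant_id,
             estimate = k$beta_out / k$beta_exp,
             se = k$se_out / abs(k$beta_exp))
}

#' Inverse-variance weighted causal estimate (multiplicative random effects)
#'
#' The IVW estimate is the weighted regression of outcome on exposure effects
#' through the origin with weights 1/se_out^2:
#' theta = sum(bx * by / se^2) / sum(bx^2 / se^2). Heterogeneity is measured
#' by Cochran's Q; under the multiplicative random-effects model the reported
#' standard error is the fixed-effect one inflated by
#' max(1, sqrt(Q / (n - 1))) — never smaller than the fixed-effect standard
#' error. With a single variant the estimate reduces to that variant's ratio
#' estimate.
#'
#' @param h a `harmonized_set`.
#' @param random_effects if `FALSE`, report the fixed-effect standard error
#'   (no dispersion floor); the default `TRUE` is the primary analysis model.
#' @return An `mr_estimate` with `extras$Q` (a `heterogeneity` object:
#'   `Q`, `df`, `pval`), `extras$se_fixed` and `extras$pval_fixed`.
#' @export
ivw <- function(h, random_effects = TRUE) {
  k <- mr_data(h)
  n <- nrow(k)
  if (n == 0) stop("no kept variants")
  w <- 1 / k$se_out^2
  sxx <- sum(w * k$beta_exp^2)
  if (sxx == 0) stop("all exposure effects are zero")
  est <- sum(w * k$beta_exp * k$beta_out) / sxx
  se_fixed <- 1 / sqrt(sxx)
  Q <- sum((k$beta_out - est * k$beta_exp)^2 / k$se_out^2)
  if (n >= 2) {
    df <- n - 1
    het <- structure(list(Q = Q, df = df,
                          pval = stats::pchisq(Q, df, lower.tail = FALSE)),
                     class = "heterogeneity")
    infl <- if (random_effects) max(1, sqrt(Q / df)) else 1
    se <- se_fixed * infl
  } else {
    het <- structure(list(Q = 0, df = NA_integer_, pval = NA_real_),
                     class = "heterogeneity")
    se <- se_fixed
  }
  new_mr_estimate("ivw-mre", est, se, n_snp = n,
                  outcome_type = attr(h, "outcome_type"),
                  extras = list(Q = het, se_fixed = se_fixed,
                                pval_fixed = z_pval(est, se_fixed)))
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %s df, p = %.3g\n", x$Q,
              format(x$df), x$pval))
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' One IVW (multiplicative random effects) fit per excluded variant, sorted
#' by variant id; used to identify influential instruments.
#'
#' @param h a `harmonized_set` with at least 2 kept variants.
#' @return data.frame with `excluded`, `estimate`, `se`, `pval`.
#' @export
leave_one_out <- function(h) {
  k <- mr_data(h)
  if (nrow(k) < 2) stop("leave-one-out requires at least 2 variants")
  ids <- sort(k$variant_id)
  rows <- lapply(ids, function(id) {
    sub <- k[k$variant_id != id, , drop = FALSE]
    fit <- ivw_on(sub, attr(h, "outcome_type") %||% "continuous")
    data.frame(excluded = id, estimate = fit$estimate, se = fit$se,
               pval = fit$pval)
  })
  do.call(rbind, rows)
}

# Internal: IVW refit on a plain kept-variant data.frame.
ivw_on <- function(k, outcome_type = "continuous", random_effects = TRUE) {
  hs <- harmonized_set(k$variant_id, k$beta_exp, k$se_exp, k$beta_out,
                       k$se_out, outcome_type = outcome_type)
  ivw(hs, random_effects = random_effects)
}

#' Per-variant (single-SNP) MR table
#'
#' Ratio estimates with normal 95% confidence intervals, the forest-plot
#' ingredient for post hoc single-variant analyses.
#'
#' @param h a `harmonized_set`.
#' @return data.frame with `variant_id`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `pval`.
#' @export
single_snp <- function(h) {
  r <- ratio_estimates(h)
  z <- stats::qnorm(0.975)
  data.frame(variant_id = r$variant_id, estimate = r$estimate, se = r$se,
             ci_low = r$estimate - z * r$se, ci_high = r$estimate + z * r$se,
             pval = z_pval(r$estimate, r$se))
}

#' Funnel-plot coordinates
#'
#' Pairs each variant-specific causal estimate with its precision (1/se);
#' symmetry about the IVW estimate is expected in the absence of directional
#' pleiotropy.
#'
#' @param h a `harmonized_set`.
#' @return data.frame with `variant_id`, `estimate`, `precision`.
#' @export
funnel_data <- function(h) {
  r <- ratio_estimates(h)
  data.frame(variant_id = r$variant_id, estimate = r$estimate,
             precision = 1 / r$se)
}
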