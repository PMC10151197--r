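#' MR-Egger regression
#'
#' Variants are oriented so that every exposure effect is positive (both
#' betas negated where needed), then outcome effects are regressed on
#' exposure effects with an intercept, weights 1/se_out^2. The slope is the
#' causal estimate; the intercept is the directional-pleiotropy test (a
#' nonzero intercept indicates an average pleiotropic effect, under the
#' InSIDE assumption). Standard errors are inflated by
#' max(1, sqrt(Q_egger / (n - 2))).
#'
#' @param h a `harmonized_set` with at least 3 kept variants (a
#'   method-not-applicable result with `NA` estimate is returned otherwise).
#' @return An `mr_estimate` with `extras$intercept`,
#'   `extras$intercept_se`, `extras$intercept_pval`, `extras$Q_egger`.
#' @export
egger <- function(h) {
  k <- mr_data(h)
  n <- nrow(k)
  if (n < 3) {
    return(new_mr_estimate("egger", NA_real_, NA_real_, pval = NA_real_,
                           n_snp = n, outcome_type = attr(h, "outcome_type"),
                           extras = list(applicable = FALSE)))
  }
  s <- ifelse(k$beta_exp < 0, -1, 1)
  x <- s * k$beta_exp
  y <- s * k$beta_out
  w <- 1 / k$se_out^2
  # weighted least squares with intercept, closed form
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (det <= 0) stop("degenerate exposure effects in MR-Egger")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  Q <- sum(w * resid^2)
  infl <- if (n > 2) max(1, sqrt(Q / (n - 2))) else 1
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(swxx / det) * infl
  new_mr_estimate("egger", slope, se_slope, n_snp = n,
                  outcome_type = attr(h, "outcome_type"),
                  extras = list(intercept = intercept, intercept_se = se_int,
                                intercept_pval = z_pval(intercept, se_int),
                                Q_egger = Q, applicable = TRUE))
}

# Weighted median of values `b` with weights `w`: the point where the
# cumulative weight of the sorted values crosses 0.5, linearly interpolated
# between bracketing order statistics.
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(b[1])
  if (cs[length(cs)] <= 0.5) return(b[length(b)])
  below <- max(which(cs < 0.5))
  b[below] + (b[below + 1] - b[below]) * (0.5 - cs[below]) /
    (cs[below + 1] - cs[below])
}

#' Weighted-median causal estimate
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Weights are the inverse-variance weights of the per-variant ratio
#' estimates; the standard error is obtained by parametric bootstrap,
#' resampling exposure and outcome effects from their normal sampling
#' distributions.
#'
#' @param h a `harmonized_set` with at least 2 kept variants.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(h, n_boot = 5000, seed = 1) {
  k <- mr_data(h, require_nonzero_exposure = TRUE)
  n <- nrow(k)
  if (n < 2) stop("weighted median requires at least 2 variants")
  theta <- k$beta_out / k$beta_exp
  se_r <- k$se_out / abs(k$beta_exp)
  est <- weighted_median_point(theta, 1 / se_r^2)
  boot <- with_seed(seed, {
    bx <- matrix(stats::rnorm(n * n_boot, k$beta_exp, k$se_exp), nrow = n)
    by <- matrix(stats::rnorm(n * n_boot, k$beta_out, k$se_out), nrow = n)
    vapply(seq_len(n_boot), function(i) {
      t_i <- by[, i] / bx[, i]
      s_i <- k$se_out / abs(bx[, i])
      ok <- is.finite(t_i) & is.finite(s_i) & s_i > 0
      weighted_median_point(t_i[ok], 1 / s_i[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted-median", est, se, n_snp = n,
                  outcome_type = attr(h, "outcome_type"),
                  extras = list(n_boot = n_boot))
}

#' Contamination-mixture causal estimate
#'
#' Profiles, over a grid of candidate causal effects theta, a likelihood in
#' which each variant's ratio estimate is either valid (normal about theta)
#' or contaminated (normal about zero with variance inflated by psi^2); each
#' variant contributes the larger of the two log-densities. The point
#' estimate maximizes the profile log-likelihood; the 95% confidence region
#' is the set of grid values within qchisq(0.95, 1)/2 of the maximum and may
#' be a union of disjoint intervals.
#'
#' @param h a `harmonized_set` with at least 2 kept variants.
#' @param psi dispersion of contaminated (pleiotropic) ratio estimates;
#'   `"auto"` (default) uses 1.5 times the SD of the ratio estimates.
#' @param grid_points grid resolution (default 10001).
#' @return An `mr_estimate`; `extras$ci_set` is a data.frame of the interval
#'   union, `extras$psi` the dispersion used. The headline `ci_low`/`ci_high`
#'   bound the interval containing the point estimate.
#' @export
contamination_mixture <- function(h, psi = "auto", grid_points = 10001) {
  k <- mr_data(h, require_nonzero_exposure = TRUE)
  n <- nrow(k)
  if (n < 2) stop("contamination mixture requires at least 2 variants")
  theta_j <- k$beta_out / k$beta_exp
  se_j <- k$se_out / abs(k$beta_exp)
  if (identical(psi, "auto")) psi <- 1.5 * stats::sd(theta_j)
  if (!is.finite(psi) || psi <= 0 || stats::sd(theta_j) == 0) {
    # degenerate: all ratio estimates identical
    est <- theta_j[1]
    se <- 1 / sqrt(sum(1 / se_j^2))
    return(new_mr_estimate("conmix", est, se, n_snp = n,
                           outcome_type = attr(h, "outcome_type"),
                           extras = list(psi = psi, degenerate = TRUE)))
  }
  lo <- min(theta_j) - 3 * max(se_j)
  hi <- max(theta_j) + 3 * max(se_j)
  grid <- seq(lo, hi, length.out = grid_points)
  ll_valid <- stats::dnorm(outer(grid, theta_j, "-"),
                           sd = rep(se_j, each = grid_points), log = TRUE)
  ll_contam <- stats::dnorm(matrix(theta_j, grid_points, n, byrow = TRUE),
                            sd = sqrt(rep(se_j^2, each = grid_points) + psi^2),
                            log = TRUE)
  ll <- rowSums(pmax(ll_valid, ll_contam))
  best <- which.max(ll)
  est <- grid[best]
  inside <- ll >= ll[best] - stats::qchisq(0.95, 1) / 2
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ci_set <- data.frame(low = grid[starts[runs$values]],
                       high = grid[ends[runs$values]])
  own <- ci_set$low <= est & est <= ci_set$high
  ci_low <- ci_set$low[own][1]
  ci_high <- ci_set$high[own][1]
  se <- (ci_high - ci_low) / (2 * stats::qnorm(0.975))
  new_mr_estimate("conmix", est, se, pval = z_pval(est, se), n_snp = n,
                  outcome_type = attr(h, "outcome_type"),
                  ci_low = ci_low, ci_high = ci_high,
                  extras = list(psi = psi, ci_set = ci_set,
                                log_lik = function(theta) {
                                  lv <- stats::dnorm(theta_j, theta, se_j, log = TRUE)
                                  lc <- stats::dnorm(theta_j, 0,
                                                     sqrt(se_j^2 + psi^2), log = TRUE)
                                  sum(pmax(lv, lc))
                                }))
}

# Leave-one-out IVW slopes (fixed-effect weights), vectorized.
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares, outlier and distortion tests
#'
#' The observed residual sum of squares uses leave-one-out IVW slopes:
#' RSS = sum_j (by_j - theta_(-j) * bx_j)^2. Its null distribution is built
#' by simulating exposure/outcome effects from normals centred on
#' (bx_j, theta_(-j) * bx_j) with the observed standard errors. The global
#' test p-value is the exceedance fraction; per-variant outlier p-values are
#' the exceedance of each simulated squared residual, Bonferroni-adjusted by
#' the number of variants. The outlier-corrected estimate is IVW on
#' non-outliers; the distortion test compares the raw-vs-corrected shift to
#' the shift obtained when random variant subsets of the same size are
#' removed.
#'
#' @param h a `harmonized_set` with at least 4 kept variants (a
#'   method-not-applicable result is returned otherwise).
#' @param n_sim null-simulation replicates (default 5000).
#' @param seed RNG seed.
#' @param outlier_alpha per-variant significance level after Bonferroni
#'   adjustment (default 0.05).
#' @param n_distortion resamples for the distortion test (default 1000; 0
#'   skips it).
#' @return list with `raw` and `corrected` `mr_estimate`s, `global_pval`,
#'   `outliers` (variant ids), `outlier_pvals`, `distortion_pval`.
#' @export
mr_presso <- function(h, n_sim = 5000, seed = 1, outlier_alpha = 0.05,
                      n_distortion = 1000) {
  k <- mr_data(h)
  n <- nrow(k)
  raw <- ivw_on(k, attr(h, "outcome_type") %||% "continuous")
  raw$method <- "presso-raw"
  if (n < 4) {
    return(list(raw = raw, corrected = NULL, global_pval = NA_real_,
                outliers = character(), outlier_pvals = NULL,
                distortion_pval = NA_real_, applicable = FALSE))
  }
  bx <- k$beta_exp; by <- k$beta_out
  sx <- k$se_exp; sy <- k$se_out
  w <- 1 / sy^2
  th_loo <- loo_slopes(bx, by, w)
  resid2_obs <- (by - th_loo * bx)^2
  rss_obs <- sum(resid2_obs)

  sim <- with_seed(seed, {
    exceed_global <- 0L
    exceed_var <- numeric(n)
    for (s in seq_len(n_sim)) {
      bxs <- stats::rnorm(n, bx, sx)
      bys <- stats::rnorm(n, th_loo * bx, sy)
      ths <- loo_slopes(bxs, bys, w)
      r2s <- (bys - ths * bxs)^2
      if (sum(r2s) >= rss_obs) exceed_global <- exceed_global + 1L
      exceed_var <- exceed_var + (r2s >= resid2_obs)
    }
    list(global = exceed_global / n_sim, var = exceed_var / n_sim)
  })
  outlier_pvals <- pmin(1, sim$var * n)  # Bonferroni
  out_idx <- which(outlier_pvals < outlier_alpha)
  outliers <- k$variant_id[out_idx]

  corrected <- NULL
  distortion_pval <- NA_real_
  if (length(out_idx) > 0 && length(out_idx) < n) {
    keep <- k[-out_idx, , drop = FALSE]
    corrected <- ivw_on(keep, attr(h, "outcome_type") %||% "continuous")
    corrected$method <- "presso-corrected"
    if (n_distortion > 0) {
      d_obs <- raw$estimate - corrected$estimate
      d_null <- with_seed(seed + 1L, {
        vapply(seq_len(n_distortion), function(i) {
          drop_i <- sample.int(n, length(out_idx))
          sub <- k[-drop_i, , drop = FALSE]
          wS <- 1 / sub$se_out^2
          raw$estimate -
            sum(wS * sub$beta_exp * sub$beta_out) / sum(wS * sub$beta_exp^2)
        }, numeric(1))
      })
      distortion_pval <- mean(abs(d_null) >= abs(d_obs))
    }
  }
  list(raw = raw, corrected = corrected, global_pval = sim$global,
       outliers = outliers, outlier_pvals = outlier_pvals,
       distortion_pval = distortion_pval, applicable = TRUE)
}

#' Steiger directionality test and filtering
#'
#' For each variant the variance explained in each trait is computed from the
#' squared z-statistic, r2 = z^2 / (z^2 + n_eff), with n_eff the sample size
#' for continuous traits and the effective sample size
#' 4 / (1/n_case + 1/n_control) for binary traits. A variant is flagged
#' `outcome-first` when it explains more variance in the outcome than in the
#' exposure; the filtered set excludes such variants.
#'
#' @param h a `harmonized_set` with per-variant sample sizes (`n_exp`,
#'   `n_out`, and case/control counts when the outcome is binary — missing
#'   counts for a binary trait are an error).
#' @return An object of class `steiger_report`: per-variant table with
#'   `r2_exp`, `r2_out` and `direction`; counts and `fraction_outcome_first`;
#'   `filtered`, the harmonized set with outcome-first variants removed.
#' @export
steiger_filter <- function(h) {
  k <- mr_data(h)
  if (any(is.na(k$n_exp)) || any(is.na(k$n_out))) {
    stop("Steiger filtering needs per-variant sample sizes for both traits")
  }
  n_eff <- function(n, ncase, nctrl, type) {
    if (identical(type, "binary")) {
      if (any(is.na(ncase)) || any(is.na(nctrl))) {
        stop("binary trait without case/control counts")
      }
      4 / (1 / ncase + 1 / nctrl)
    } else n
  }
  ne_exp <- n_eff(k$n_exp, k$n_case_exp %||% NA, k$n_control_exp %||% NA,
                  attr(h, "exposure_type") %||% "continuous")
  ne_out <- n_eff(k$n_out, k$n_case_out, k$n_control_out,
                  attr(h, "outcome_type") %||% "continuous")
  z_exp <- (k$beta_exp / k$se_exp)^2
  z_out <- (k$beta_out / k$se_out)^2
  r2_exp <- z_exp / (z_exp + ne_exp)
  r2_out <- z_out / (z_out + ne_out)
  outcome_first <- r2_out > r2_exp
  tab <- data.frame(variant_id = k$variant_id, r2_exp = r2_exp,
                    r2_out = r2_out,
                    direction = ifelse(outcome_first, "outcome-first",
                                       "exposure-first"))
  filt <- h[!(h$variant_id %in% k$variant_id[outcome_first]), , drop = FALSE]
  filt <- structure(filt, class = class(h),
                    exposure_id = attr(h, "exposure_id"),
                    outcome_id = attr(h, "outcome_id"),
                    exposure_type = attr(h, "exposure_type"),
                    outcome_type = attr(h, "outcome_type"))
  structure(list(table = tab,
                 n_snp = nrow(k),
                 n_outcome_first = sum(outcome_first),
                 fraction_outcome_first = sum(outcome_first) / nrow(k),
                 filtered = filt),
            class = "steiger_report")
}

#' @export
print.steiger_report <- function(x, ...) {
  cat(sprintf("<steiger_report> %d / %d variants outcome-first (%.1f%%)\n",
              x$n_outcome_first, x$n_snp, 100 * x$fraction_outcome_first))
  invisible(x)
}
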