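#' Multivariable IVW regression
#'
#' Weighted regression (weights 1/se_out^2, no intercept) of the outcome
#' associations on the exposure and mediator association columns of a
#' jointly-clumped instrument set. The exposure coefficient is its direct
#' effect on the outcome holding the mediator fixed; the mediator coefficient
#' is the mediator's direct effect. Standard errors are inflated by
#' max(1, sqrt(Q_mv / (n - 2))).
#'
#' An exposure column that is identically zero carries no information and is
#' dropped with a warning (its coefficient is reported as `NA`), so that a
#' degenerate two-column fit reduces to univariable IVW; rank deficiency
#' between non-zero columns is an error naming the collinear columns.
#'
#' @param h an `mv_harmonized_set` (see [harmonize_multi()]) with at least 3
#'   kept variants.
#' @return list of `mr_estimate`s: `exposure` (direct effect c') and
#'   `mediator` (direct effect b), each with `extras$Q_mv`.
#' @export
mvmr_ivw <- function(h) {
  k <- kept(h)
  n <- nrow(k)
  if (n < 3) stop("multivariable IVW requires at least 3 instruments")
  X <- cbind(exposure = k$beta_exp, mediator = k$beta_med)
  y <- k$beta_out
  w <- 1 / k$se_out^2
  zero_col <- apply(X, 2, function(col) all(col == 0))
  if (all(zero_col)) stop("both effect columns are identically zero")
  if (any(zero_col)) {
    warning("column(s) with all-zero effects dropped from multivariable fit: ",
            paste(colnames(X)[zero_col], collapse = ", "))
  }
  Xa <- X[, !zero_col, drop = FALSE]
  XtWX <- crossprod(Xa, w * Xa)
  if (abs(det(XtWX)) < .Machine$double.eps * max(abs(XtWX))^ncol(Xa) ||
      qr(XtWX)$rank < ncol(Xa)) {
    stop("rank-deficient instrument matrix; collinear columns: ",
         paste(colnames(Xa), collapse = ", "))
  }
  coefs <- solve(XtWX, crossprod(Xa, w * y))
  resid <- y - Xa %*% coefs
  Q <- sum(w * resid^2)
  df <- n - ncol(Xa)
  infl <- if (df > 0) max(1, sqrt(Q / df)) else 1
  vc <- solve(XtWX)
  ses <- sqrt(diag(vc)) * infl
  out <- list()
  for (nm in c("exposure", "mediator")) {
    if (nm %in% colnames(Xa)) {
      i <- match(nm, colnames(Xa))
      out[[nm]] <- new_mr_estimate(paste0("mvmr-ivw-", nm), coefs[i], ses[i],
                                   n_snp = n,
                                   outcome_type = attr(h, "outcome_type"),
                                   extras = list(Q_mv = Q, df = df))
    } else {
      out[[nm]] <- new_mr_estimate(paste0("mvmr-ivw-", nm), NA_real_, NA_real_,
                                   pval = NA_real_, n_snp = n,
                                   outcome_type = attr(h, "outcome_type"),
                                   extras = list(dropped_zero_column = TRUE))
    }
  }
  out
}

#' Difference-in-coefficients mediation decomposition
#'
#' Decomposes the total causal effect c (univariable IVW) into the direct
#' effect c' (multivariable IVW, mediator-adjusted) and the indirect effect
#' c - c'. The indirect-effect standard error uses the independence
#' approximation sqrt(se_total^2 + se_direct^2); the proportion mediated
#' (c - c')/c carries a delta-method standard error and is reported as
#' missing when |c| is below `tol`. For binary outcomes the decomposition is
#' on the log odds-ratio scale and, because the odds ratio is
#' non-collapsible, is approximate.
#'
#' @param total an `mr_estimate` of the total effect (univariable IVW).
#' @param direct an `mr_estimate` of the exposure's direct effect
#'   (`mvmr_ivw()$exposure`). Must be on the same outcome scale as `total`.
#' @param tol reporting tolerance on |c| below which the proportion mediated
#'   is undefined (default 1e-8).
#' @return An object of class `mediation_result` with fields `total`,
#'   `direct`, `indirect`, `proportion_mediated` (each estimate with se and
#'   95% CI where defined).
#' @export
mediation_decompose <- function(total, direct, tol = 1e-8) {
  stopifnot(inherits(total, "mr_estimate"), inherits(direct, "mr_estimate"))
  if (!identical(total$outcome_type, direct$outcome_type)) {
    stop("total and direct effects are on different outcome scales")
  }
  z <- stats::qnorm(0.975)
  ind <- total$estimate - direct$estimate
  se_ind <- sqrt(total$se^2 + direct$se^2)
  c_tot <- total$estimate
  if (abs(c_tot) < tol) {
    prop <- NA_real_
    se_prop <- NA_real_
  } else {
    prop <- ind / c_tot
    # delta method on (c, c'), independence approximation:
    # d/dc [(c - c')/c] = c'/c^2 ; d/dc' = -1/c
    se_prop <- sqrt((direct$estimate / c_tot^2)^2 * total$se^2 +
                      (1 / c_tot)^2 * direct$se^2)
  }
  structure(list(
    total = total, direct = direct,
    indirect = list(estimate = ind, se = se_ind,
                    ci_low = ind - z * se_ind, ci_high = ind + z * se_ind,
                    pval = z_pval(ind, se_ind)),
    proportion_mediated = list(estimate = prop, se = se_prop,
                               ci_low = if (is.na(prop)) NA_real_ else prop - z * se_prop,
                               ci_high = if (is.na(prop)) NA_real_ else prop + z * se_prop)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat("<mediation_result>\n")
  cat(sprintf("  total     %8.*f (se %.*f)\n", digits, x$total$estimate,
              digits, x$total$se))
  cat(sprintf("  direct    %8.*f (se %.*f)\n", digits, x$direct$estimate,
              digits, x$direct$se))
  cat(sprintf("  indirect  %8.*f (se %.*f)\n", digits, x$indirect$estimate,
              digits, x$indirect$se))
  if (!is.na(x$proportion_mediated$estimate)) {
    cat(sprintf("  proportion mediated %.*f (se %.*f)\n", digits,
                x$proportion_mediated$estimate, digits,
                x$proportion_mediated$se))
  } else {
    cat("  proportion mediated undefined (total effect near zero)\n")
  }
  invisible(x)
}
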