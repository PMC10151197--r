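#' Study-level configuration
#'
#' Thresholds, robust-method settings and seeds for [run_study()]. The
#' significance policy follows the bidirectional design: the primary
#' exposure-outcome pair is tested at `alpha_primary`, while the
#' mediator-family analyses (exposure vs each mediator, each mediator vs
#' outcome) use the multiplicity-corrected threshold derived from the
#' phenotypic correlation matrix via [effective_tests()].
#'
#' @param p_threshold instrument significance threshold (strict; default 5e-8).
#' @param clump_r2,clump_window_kb LD clumping parameters (defaults 0.001 and
#'   10 000 kb).
#' @param proxy_r2 minimum proxy r2 (default 0.8).
#' @param palindrome_maf palindromic ambiguity bound (default 0.42).
#' @param alpha_primary significance level for the exposure-outcome pair.
#' @param alpha family-wise level fed to [effective_tests()].
#' @param var_target variance-explained target for [effective_tests()].
#' @param sensitivity when to run the robust-method battery: only for pairs
#'   whose IVW p-value falls below the pair's threshold (`"significant"`,
#'   the default, as in the study design), `"always"`, or `"never"`.
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO null-simulation replicates.
#' @param n_distortion MR-PRESSO distortion-test resamples.
#' @param conmix_grid contamination-mixture grid resolution.
#' @param seed RNG seed governing all stochastic methods.
#' @return list of class `study_config`.
#' @export
study_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                         clump_window_kb = 10000, proxy_r2 = 0.8,
                         palindrome_maf = 0.42,
                         alpha_primary = 0.05, alpha = 0.05,
                         var_target = 0.995,
                         sensitivity = c("significant", "always", "never"),
                         n_boot = 5000, n_sim = 5000, n_distortion = 1000,
                         conmix_grid = 10001, seed = 1) {
  sensitivity <- match.arg(sensitivity)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, proxy_r2 = proxy_r2,
                 palindrome_maf = palindrome_maf,
                 alpha_primary = alpha_primary, alpha = alpha,
                 var_target = var_target, sensitivity = sensitivity,
                 n_boot = n_boot, n_sim = n_sim,
                 n_distortion = n_distortion, conmix_grid = conmix_grid,
                 seed = seed),
            class = "study_config")
}

# One univariable analysis (one direction of one pair): instrument
# selection, clumping, harmonization, IVW, and (policy permitting) the
# robust-method and diagnostic battery.
analyse_pair <- function(exp_ds, out_ds, ld, cfg, threshold) {
  instruments <- select_instruments(exp_ds, cfg$p_threshold)
  if (length(instruments) == 0) stop("no genome-wide-significant instruments")
  if (!is.null(ld)) {
    cand <- data.frame(variant_id = instruments,
                       pval = exp_ds$pval[match(instruments, exp_ds$variant_id)])
    instruments <- clump(cand, ld, r2_threshold = cfg$clump_r2,
                         window_kb = cfg$clump_window_kb)
  }
  if (length(instruments) == 0) stop("no instruments survive clumping")
  h <- harmonize_pair(exp_ds, out_ds, instruments, ld = ld,
                      palindrome_maf = cfg$palindrome_maf,
                      r2_proxy = cfg$proxy_r2)
  fit <- ivw(h)
  res <- list(exposure_id = trait_id(exp_ds), outcome_id = trait_id(out_ds),
              harmonized = h, ivw = fit, threshold = threshold,
              significant = fit$pval < threshold)
  run_battery <- switch(cfg$sensitivity,
                        significant = res$significant,
                        always = TRUE, never = FALSE)
  if (run_battery) {
    nk <- nrow(kept(h))
    res$egger <- egger(h)
    res$weighted_median <- if (nk >= 2) {
      weighted_median(h, n_boot = cfg$n_boot, seed = cfg$seed)
    }
    res$conmix <- if (nk >= 2) {
      contamination_mixture(h, grid_points = cfg$conmix_grid)
    }
    res$presso <- if (nk >= 4) {
      mr_presso(h, n_sim = cfg$n_sim, seed = cfg$seed,
                n_distortion = cfg$n_distortion)
    }
    res$leave_one_out <- if (nk >= 2) leave_one_out(h)
    res$single_snp <- single_snp(h)
    res$funnel <- funnel_data(h)
    st <- steiger_filter(h)
    res$steiger <- st
    res$ivw_steiger <- if (nrow(kept(st$filtered)) >= 1) ivw(st$filtered)
  }
  res
}

#' Run the full bidirectional MR study design
#'
#' For the exposure-outcome pair and for every exposure-mediator and
#' mediator-outcome pair, in both directions: instrument selection, LD
#' clumping, harmonization, IVW with multiplicative random effects and
#' Cochran's Q, and — per the sensitivity policy — the robust-method battery
#' (MR-Egger, weighted median, contamination mixture, MR-PRESSO),
#' leave-one-out, single-variant and funnel diagnostics, and
#' Steiger-filtered re-analysis. Then, per mediator, multivariable MR and
#' the mediation decomposition against the univariable total effect.
#' Mediator-family analyses are flagged at the multiplicity-corrected
#' threshold; the exposure-outcome pair at `alpha_primary`. A hard error in
#' one pair aborts that pair only and is recorded in the bundle's error
#' list.
#'
#' @param exposure,outcome [summary_dataset()]s (the outcome is typically
#'   binary).
#' @param mediators named list of [summary_dataset()]s.
#' @param ld optional [ld_reference()].
#' @param idp_corr optional phenotypic correlation matrix across the
#'   mediators, for the multiplicity correction; without it the corrected
#'   threshold equals `alpha`.
#' @param config a [study_config()].
#' @return An object of class `study_bundle`: per-direction analysis objects
#'   (`pairs`), a flat `results` table, `mediation` results, `meff`, the
#'   reproducibility `manifest` (config, seeds, package version, config
#'   hash) and `errors`.
#' @export
run_study <- function(exposure, outcome, mediators = list(), ld = NULL,
                      idp_corr = NULL, config = study_config()) {
  cfg <- config
  meff <- if (!is.null(idp_corr)) {
    effective_tests(idp_corr, var_target = cfg$var_target, alpha = cfg$alpha)
  }
  thr_family <- if (is.null(meff)) cfg$alpha else meff$threshold

  datasets <- c(list(exposure, outcome), unname(mediators))
  roles <- c("exposure", "outcome", rep("mediator", length(mediators)))
  ids <- vapply(datasets, trait_id, "")
  pair_plan <- list(c(1L, 2L))
  for (m in seq_along(mediators)) {
    pair_plan <- c(pair_plan, list(c(1L, 2L + m), c(2L + m, 2L)))
  }

  pairs <- list()
  errors <- list()
  for (pp in pair_plan) {
    thr <- if (all(pp %in% c(1L, 2L))) cfg$alpha_primary else thr_family
    for (dir in 1:2) {
      i <- pp[if (dir == 1) 1 else 2]
      j <- pp[if (dir == 1) 2 else 1]
      key <- paste(ids[i], ids[j], sep = "->")
      out <- tryCatch(analyse_pair(datasets[[i]], datasets[[j]], ld, cfg, thr),
                      error = function(e) e)
      if (inherits(out, "error")) {
        errors[[key]] <- conditionMessage(out)
      } else {
        pairs[[key]] <- out
      }
    }
  }

  mediation <- list()
  total_key <- paste(ids[1], ids[2], sep = "->")
  total_fit <- if (!is.null(pairs[[total_key]])) pairs[[total_key]]$ivw
  for (mn in names(mediators) %||% character()) {
    med <- mediators[[mn]]
    key <- paste0("mediation:", trait_id(med))
    out <- tryCatch({
      hm <- harmonize_multi(exposure, med, outcome, ld = ld,
                            p_threshold = cfg$p_threshold,
                            clump_r2 = cfg$clump_r2,
                            clump_window_kb = cfg$clump_window_kb,
                            palindrome_maf = cfg$palindrome_maf,
                            r2_proxy = cfg$proxy_r2)
      mv <- mvmr_ivw(hm)
      dec <- if (!is.null(total_fit)) mediation_decompose(total_fit, mv$exposure)
      list(mediator_id = trait_id(med), harmonized = hm, mvmr = mv,
           decomposition = dec)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      errors[[key]] <- conditionMessage(out)
    } else {
      mediation[[trait_id(med)]] <- out
    }
  }

  results <- study_results_table(pairs, ids)
  manifest <- list(
    traits = data.frame(trait_id = ids, role = roles),
    config = unclass(cfg),
    seed = cfg$seed,
    corrected_threshold = thr_family,
    package_version = as.character(utils::packageVersion("reservemr")),
    config_hash = rlang::hash(list(unclass(cfg), ids))
  )
  structure(list(pairs = pairs, results = results, mediation = mediation,
                 meff = meff, manifest = manifest, errors = errors),
            class = "study_bundle")
}

# Flatten per-pair fits into one results table.
study_results_table <- function(pairs, ids) {
  rows <- list()
  for (key in names(pairs)) {
    p <- pairs[[key]]
    add <- function(fit, method) {
      if (is.null(fit) || is.na(fit$estimate)) return(NULL)
      Q <- fit$extras[["Q"]]
      data.frame(analysis = key, exposure_id = p$exposure_id,
                 outcome_id = p$outcome_id, method = method,
                 n_snp = fit$n_snp, estimate = fit$estimate, se = fit$se,
                 ci_low = fit$ci_low, ci_high = fit$ci_high, pval = fit$pval,
                 Q = if (!is.null(Q)) Q$Q else NA_real_,
                 Q_pval = if (!is.null(Q)) Q$pval else NA_real_,
                 threshold = p$threshold,
                 significant = fit$pval < p$threshold)
    }
    rows[[length(rows) + 1L]] <- add(p$ivw, "ivw-mre")
    rows[[length(rows) + 1L]] <- add(p$egger, "egger")
    rows[[length(rows) + 1L]] <- add(p$weighted_median, "weighted-median")
    rows[[length(rows) + 1L]] <- add(p$conmix, "conmix")
    if (!is.null(p$presso)) {
      rows[[length(rows) + 1L]] <- add(p$presso$raw, "presso-raw")
      rows[[length(rows) + 1L]] <- add(p$presso$corrected, "presso-corrected")
    }
    rows[[length(rows) + 1L]] <- add(p$ivw_steiger, "ivw-steiger-filtered")
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d analyses, %d mediation fits, %d errors\n",
              length(x$pairs), length(x$mediation), length(x$errors)))
  if (length(x$errors) > 0) {
    for (k in names(x$errors)) cat(sprintf("  [failed] %s: %s\n", k, x$errors[[k]]))
  }
  invisible(x)
}

# Report estimates on the printed scale: odds ratios for binary outcomes,
# SD-unit betas otherwise; binary *exposures* are rescaled to a per-doubling
# (log 2) interpretation.
scaled_row <- function(fit, exposure_type, outcome_type) {
  mult <- if (identical(exposure_type, "binary")) log(2) else 1
  est <- fit$estimate * mult
  lo <- fit$ci_low * mult
  hi <- fit$ci_high * mult
  if (identical(outcome_type, "binary")) {
    data.frame(or = exp(est), or_ci_low = exp(lo), or_ci_high = exp(hi),
               beta = NA_real_, beta_ci_low = NA_real_, beta_ci_high = NA_real_)
  } else {
    data.frame(or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
               beta = est, beta_ci_low = lo, beta_ci_high = hi)
  }
}

#' Render the study bundle as plain TSV tables
#'
#' Writes the study's estimate tables: the primary-pair all-method table,
#' the bidirectional exposure-mediator and mediator-outcome IVW tables, the
#' mediation table (one unadjusted row plus one row per mediator, odds
#' ratios with 95% CIs) and a JSON manifest. Significance asterisks follow
#' the study's threshold policy. Output is deterministic given the bundle.
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
render_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- path
    path
  }
  res <- bundle$results
  ids <- bundle$manifest$traits
  primary <- paste(ids$trait_id[ids$role == "exposure"][1],
                   ids$trait_id[ids$role == "outcome"][1], sep = "->")
  if (nrow(res) > 0) {
    res$sig_mark <- ifelse(res$significant, "*", "")
    tsv(res[res$analysis %in% c(primary, rev_key(primary)), ],
        "primary_pair_estimates.tsv")
    med_ids <- ids$trait_id[ids$role == "mediator"]
    exp_id <- ids$trait_id[ids$role == "exposure"][1]
    out_id <- ids$trait_id[ids$role == "outcome"][1]
    em <- res$method == "ivw-mre" &
      (res$exposure_id == exp_id & res$outcome_id %in% med_ids |
         res$exposure_id %in% med_ids & res$outcome_id == exp_id)
    tsv(res[em, ], "exposure_mediator_estimates.tsv")
    mo <- res$method == "ivw-mre" &
      (res$exposure_id %in% med_ids & res$outcome_id == out_id |
         res$exposure_id == out_id & res$outcome_id %in% med_ids)
    tsv(res[mo, ], "mediator_outcome_estimates.tsv")
  }
  # mediation table: unadjusted row + one adjusted row per mediator
  med_rows <- list()
  tot <- if (!is.null(bundle$pairs[[primary]])) bundle$pairs[[primary]]$ivw
  if (!is.null(tot)) {
    med_rows[[1]] <- cbind(data.frame(adjustment = "None (univariable analysis)"),
                           scaled_row(tot, "continuous", tot$outcome_type),
                           data.frame(pval = tot$pval, n_snp = tot$n_snp,
                                      proportion_mediated = NA_real_))
  }
  for (mn in names(bundle$mediation)) {
    m <- bundle$mediation[[mn]]
    fit <- m$mvmr$exposure
    prop <- if (!is.null(m$decomposition)) {
      m$decomposition$proportion_mediated$estimate
    } else NA_real_
    med_rows[[length(med_rows) + 1L]] <-
      cbind(data.frame(adjustment = mn),
            scaled_row(fit, "continuous", fit$outcome_type),
            data.frame(pval = fit$pval, n_snp = fit$n_snp,
                       proportion_mediated = prop))
  }
  if (length(med_rows) > 0) {
    tsv(do.call(rbind, med_rows), "mediation_estimates.tsv")
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths[["manifest.json"]] <- manifest_path
  invisible(unlist(paths))
}

rev_key <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)[[1]]
  paste(parts[2], parts[1], sep = "->")
}
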