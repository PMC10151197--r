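#' Select genome-wide-significant instruments
#'
#' Returns all and only variants with p-value strictly below the threshold,
#' sorted by p ascending with ties broken lexicographically on variant id.
#'
#' @param ds a [summary_dataset()].
#' @param p_threshold significance threshold (default the conventional
#'   genome-wide 5e-8; the comparison is strict).
#' @return character vector of variant ids.
#' @export
select_instruments <- function(ds, p_threshold = 5e-8) {
  stopifnot(inherits(ds, "summary_dataset"))
  hit <- ds[ds$pval < p_threshold, c("variant_id", "pval")]
  hit <- hit[order(hit$pval, hit$variant_id), ]
  hit$variant_id
}

#' Greedy LD clumping
#'
#' Repeatedly accepts the remaining variant with the lowest p-value and
#' removes every remaining variant with r2 >= `r2_threshold` within
#' `window_kb` of it. Variants absent from the LD positions table are treated
#' as unlinked (with a warning). Output is the accepted set in acceptance
#' order; the result is invariant to the input order of equal-p candidates
#' (ties broken lexicographically).
#'
#' @param candidates data.frame with columns `variant_id`, `pval`.
#' @param ld an [ld_reference()].
#' @param r2_threshold clumping r2 ceiling (default 0.001).
#' @param window_kb physical window in kilobases (default 10 000).
#' @return character vector of retained variant ids.
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(is.data.frame(candidates),
            all(c("variant_id", "pval") %in% names(candidates)))
  if (nrow(candidates) == 0) return(character())
  ord <- order(candidates$pval, candidates$variant_id)
  ids <- as.character(candidates$variant_id[ord])
  window_bp <- window_kb * 1000
  kept <- character()
  while (length(ids) > 0) {
    idx <- ids[1]
    kept <- c(kept, idx)
    rest <- ids[-1]
    if (length(rest) == 0) break
    linked <- ld_r2(ld, idx, rest) >= r2_threshold &
      ld_in_window(ld, idx, rest, window_bp)
    ids <- rest[!linked]
  }
  kept
}

#' Find an LD proxy for a variant missing from the outcome dataset
#'
#' Returns the variant present in `outcome_ds` with maximal r2 to `target`,
#' subject to r2 > `r2_min`; ties are broken by smaller outcome p-value, then
#' lexicographic id. `NULL` if no variant qualifies.
#'
#' @param target variant id absent from `outcome_ds`.
#' @param outcome_ds a [summary_dataset()].
#' @param ld an [ld_reference()].
#' @param r2_min minimum r2 (strict; default 0.8).
#' @return list with `variant_id` and `r2`, or `NULL`.
#' @export
find_proxy <- function(target, outcome_ds, ld, r2_min = 0.8) {
  partners <- ld_partners(ld, target)
  partners <- partners[partners$r2 > r2_min &
                         partners$partner %in% outcome_ds$variant_id, ,
                       drop = FALSE]
  if (nrow(partners) == 0) return(NULL)
  pv <- outcome_ds$pval[match(partners$partner, outcome_ds$variant_id)]
  ord <- order(-partners$r2, pv, partners$partner)
  list(variant_id = partners$partner[ord[1]], r2 = partners$r2[ord[1]])
}

new_harmonized_set <- function(variants, exposure_ds, outcome_ds) {
  structure(variants,
            class = c("harmonized_set", "data.frame"),
            exposure_id = trait_id(exposure_ds),
            outcome_id = trait_id(outcome_ds),
            exposure_type = trait_type(exposure_ds),
            outcome_type = trait_type(outcome_ds))
}

#' Construct a harmonized variant set directly
#'
#' Programmatic constructor for an allele-aligned exposure/outcome variant
#' table, used when effects are already expressed for a common effect allele
#' (for example when building simulation scenarios). All variants are marked
#' as kept.
#'
#' @param variant_id,beta_exp,se_exp,beta_out,se_out equal-length vectors of
#'   aligned per-variant effects and standard errors.
#' @param n_exp,n_out per-variant (or scalar) GWAS sample sizes.
#' @param eaf_exp,eaf_out optional effect-allele frequencies.
#' @param exposure_id,outcome_id trait labels.
#' @param outcome_type,exposure_type `"continuous"` or `"binary"`.
#' @param n_case_out,n_control_out outcome case/control counts (binary).
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(variant_id, beta_exp, se_exp, beta_out, se_out,
                           n_exp = NA, n_out = NA,
                           eaf_exp = NA, eaf_out = NA,
                           exposure_id = "X", outcome_id = "Y",
                           exposure_type = "continuous",
                           outcome_type = "continuous",
                           n_case_out = NA, n_control_out = NA) {
  variants <- data.frame(
    variant_id = as.character(variant_id), source_id = as.character(variant_id),
    beta_exp = beta_exp, se_exp = se_exp, eaf_exp = eaf_exp,
    beta_out = beta_out, se_out = se_out, eaf_out = eaf_out,
    n_exp = n_exp, n_out = n_out,
    n_case_out = n_case_out, n_control_out = n_control_out,
    action = "kept", reason = NA_character_, proxy_r2 = NA_real_
  )
  structure(variants, class = c("harmonized_set", "data.frame"),
            exposure_id = exposure_id, outcome_id = outcome_id,
            exposure_type = exposure_type, outcome_type = outcome_type)
}

#' Kept variants of a harmonized set
#'
#' @param h a `harmonized_set` (or `mv_harmonized_set`).
#' @return The subset of rows whose harmonization action is not `dropped`.
#' @export
kept <- function(h) {
  h[h$action != "dropped", , drop = FALSE]
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d instruments, %d kept\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"),
              nrow(x), sum(x$action != "dropped")))
  acts <- table(x$action)
  cat("  actions:", paste(sprintf("%s=%d", names(acts), acts), collapse = ", "), "\n")
  invisible(x)
}

# Align one dataset's rows (indexed by `out_idx`) to reference allele codings.
# Returns per-row: status ("ok" / "palindromic-ambiguous" /
# "incompatible-alleles"), sign (+1/-1 applied to beta), flipped eaf, and
# whether a net label swap happened. Palindromic variants are oriented by
# allele-frequency agreement and declared ambiguous when min(eaf, 1 - eaf) >
# palindrome_maf in either dataset or when a frequency is missing.
align_alleles <- function(ref_ea, ref_oa, ref_eaf, ea, oa, eaf,
                          palindrome_maf = 0.42) {
  n <- length(ref_ea)
  status <- rep("ok", n)
  sign <- rep(1, n)
  eaf_out <- eaf

  pal <- is_palindromic_pair(ref_ea, ref_oa)
  direct <- ea == ref_ea & oa == ref_oa
  swapped <- ea == ref_oa & oa == ref_ea
  flipped <- allele_complement(ea) == ref_ea & allele_complement(oa) == ref_oa
  flipswap <- allele_complement(ea) == ref_oa & allele_complement(oa) == ref_ea
  incompatible <- !(direct | swapped | flipped | flipswap)
  status[incompatible] <- "incompatible-alleles"

  # Non-palindromic: labels identify the allele; a swap (direct or across
  # strands) negates the effect and complements the frequency.
  np_swap <- !pal & !incompatible & !direct & !flipped & (swapped | flipswap)
  sign[np_swap] <- -1
  eaf_out[np_swap] <- 1 - eaf[np_swap]

  # Palindromic: labels cannot resolve strand. First apply the label swap,
  # then use frequency agreement; ambiguous when the minor-allele frequency
  # exceeds the bound on either side.
  pal_ok <- pal & !incompatible
  if (any(pal_ok)) {
    idx <- which(pal_ok)
    lab_swap <- swapped[idx]  # for palindromes swapped == flipped
    s <- ifelse(lab_swap, -1, 1)
    e <- ifelse(lab_swap, 1 - eaf[idx], eaf[idx])
    maf_ref <- pmin(ref_eaf[idx], 1 - ref_eaf[idx])
    maf_oth <- pmin(eaf[idx], 1 - eaf[idx])
    ambiguous <- is.na(ref_eaf[idx]) | is.na(eaf[idx]) |
      maf_ref > palindrome_maf | maf_oth > palindrome_maf
    disagree <- !ambiguous & (ref_eaf[idx] - 0.5) * (e - 0.5) < 0
    s[disagree] <- -s[disagree]
    e[disagree] <- 1 - e[disagree]
    status[idx[ambiguous]] <- "palindromic-ambiguous"
    sign[idx] <- s
    eaf_out[idx] <- e
  }
  list(status = status, sign = sign, eaf = eaf_out)
}

#' Harmonize exposure and outcome datasets over an instrument list
#'
#' For each instrument: substitutes an LD proxy when the variant is absent
#' from the outcome dataset (the proxy must also be present in the exposure
#' dataset; its effects replace the instrument's and it is harmonized as
#' usual); matches alleles directly or after strand complementation; negates
#' the outcome effect and complements its frequency when the outcome is coded
#' on the swapped alleles; orients palindromic variants by allele-frequency
#' agreement, dropping them as ambiguous when min(eaf, 1 - eaf) >
#' `palindrome_maf` in either dataset (or when a needed frequency is
#' missing); drops incompatible allele pairs.
#'
#' @param exp_ds,out_ds [summary_dataset()]s for exposure and outcome.
#' @param instruments character vector of instrument variant ids drawn from
#'   `exp_ds`.
#' @param ld optional [ld_reference()] for proxy search.
#' @param palindrome_maf palindromic ambiguity bound on the minor-allele
#'   frequency (default 0.42).
#' @param r2_proxy minimum proxy r2 (default 0.8, strict).
#' @return A `harmonized_set`: one row per instrument with aligned
#'   `beta_exp`/`beta_out` (same effect allele), the `action` taken (`kept`,
#'   `sign-flipped`, `proxied`, `dropped`) and a drop `reason`. Errors if no
#'   instrument survives.
#' @export
harmonize_pair <- function(exp_ds, out_ds, instruments, ld = NULL,
                           palindrome_maf = 0.42, r2_proxy = 0.8) {
  stopifnot(inherits(exp_ds, "summary_dataset"),
            inherits(out_ds, "summary_dataset"))
  instruments <- as.character(instruments)
  if (!all(instruments %in% exp_ds$variant_id)) {
    stop("instrument(s) not present in the exposure dataset: ",
         paste(utils::head(setdiff(instruments, exp_ds$variant_id), 5),
               collapse = ", "))
  }
  used <- instruments
  source_id <- instruments
  proxy_r2 <- rep(NA_real_, length(instruments))
  reason <- rep(NA_character_, length(instruments))

  missing <- !(instruments %in% out_ds$variant_id)
  if (any(missing)) {
    for (i in which(missing)) {
      prx <- NULL
      if (!is.null(ld)) {
        # proxy must carry exposure effects too, and not duplicate an
        # existing instrument
        cand <- out_ds[out_ds$variant_id %in% exp_ds$variant_id &
                         !(out_ds$variant_id %in% used), , drop = FALSE]
        cand <- summary_dataset(as.data.frame(cand), trait_id(out_ds),
                                trait_type(out_ds), validate = FALSE)
        prx <- find_proxy(instruments[i], cand, ld, r2_min = r2_proxy)
      }
      if (is.null(prx)) {
        reason[i] <- "missing-in-outcome-no-proxy"
      } else {
        used[i] <- prx$variant_id
        proxy_r2[i] <- prx$r2
      }
    }
  }

  ei <- match(used, exp_ds$variant_id)
  oi <- match(used, out_ds$variant_id)
  ok <- is.na(reason)

  res <- data.frame(
    variant_id = used, source_id = source_id,
    beta_exp = exp_ds$beta[ei], se_exp = exp_ds$se[ei],
    eaf_exp = exp_ds$eaf[ei],
    beta_out = NA_real_, se_out = NA_real_, eaf_out = NA_real_,
    pval_exp = exp_ds$pval[ei], pval_out = NA_real_,
    n_exp = exp_ds$n[ei], n_out = NA_real_,
    n_case_exp = exp_ds$n_case[ei], n_control_exp = exp_ds$n_control[ei],
    n_case_out = NA_real_, n_control_out = NA_real_,
    action = NA_character_, reason = reason, proxy_r2 = proxy_r2
  )
  if (any(ok)) {
    io <- oi[ok]
    al <- align_alleles(exp_ds$effect_allele[ei[ok]], exp_ds$other_allele[ei[ok]],
                        exp_ds$eaf[ei[ok]],
                        out_ds$effect_allele[io], out_ds$other_allele[io],
                        out_ds$eaf[io], palindrome_maf = palindrome_maf)
    res$beta_out[ok] <- al$sign * out_ds$beta[io]
    res$se_out[ok] <- out_ds$se[io]
    res$eaf_out[ok] <- al$eaf
    res$pval_out[ok] <- out_ds$pval[io]
    res$n_out[ok] <- out_ds$n[io]
    res$n_case_out[ok] <- out_ds$n_case[io]
    res$n_control_out[ok] <- out_ds$n_control[io]
    res$reason[ok][al$status != "ok"] <- al$status[al$status != "ok"]
    act <- ifelse(al$sign < 0, "sign-flipped", "kept")
    act[!is.na(res$proxy_r2[ok])] <- "proxied"
    res$action[ok] <- ifelse(al$status == "ok", act, "dropped")
  }
  res$action[!is.na(res$reason)] <- "dropped"
  res$beta_out[res$action == "dropped"] <- NA_real_
  if (!any(res$action != "dropped")) stop("no harmonizable instruments")
  new_harmonized_set(res, exp_ds, out_ds)
}

#' Harmonize exposure, mediator and outcome for multivariable MR
#'
#' The instrument set is the union of genome-wide-significant variants for
#' the exposure or the mediator, clumped jointly on each variant's minimum
#' p-value across the two traits. Each kept variant carries effects for all
#' three traits aligned to the exposure dataset's effect allele; a variant is
#' kept only if harmonizable against both the mediator and the outcome.
#'
#' @param exp_ds,med_ds,out_ds [summary_dataset()]s.
#' @param ld an [ld_reference()] (used for joint clumping and proxy search).
#' @param p_threshold instrument significance threshold (strict).
#' @param clump_r2,clump_window_kb clumping parameters.
#' @param palindrome_maf,r2_proxy as [harmonize_pair()].
#' @return An object of class `mv_harmonized_set`: per-variant aligned
#'   `beta_exp`, `beta_med`, `beta_out` with standard errors.
#' @export
harmonize_multi <- function(exp_ds, med_ds, out_ds, ld = NULL,
                            p_threshold = 5e-8, clump_r2 = 0.001,
                            clump_window_kb = 10000,
                            palindrome_maf = 0.42, r2_proxy = 0.8) {
  sig_exp <- select_instruments(exp_ds, p_threshold)
  sig_med <- select_instruments(med_ds, p_threshold)
  pool <- union(sig_exp, sig_med)
  if (length(pool) == 0) stop("no instruments significant for either trait")
  p_exp <- exp_ds$pval[match(pool, exp_ds$variant_id)]
  p_med <- med_ds$pval[match(pool, med_ds$variant_id)]
  min_p <- pmin(p_exp, p_med, na.rm = TRUE)
  cand <- data.frame(variant_id = pool, pval = min_p)
  instruments <- if (is.null(ld)) {
    cand$variant_id[order(cand$pval, cand$variant_id)]
  } else {
    clump(cand, ld, r2_threshold = clump_r2, window_kb = clump_window_kb)
  }
  # variants must carry exposure effects; in practice all three synthetic
  # datasets share the variant universe
  instruments <- instruments[instruments %in% exp_ds$variant_id]
  h_out <- harmonize_pair(exp_ds, out_ds, instruments, ld = ld,
                          palindrome_maf = palindrome_maf, r2_proxy = r2_proxy)
  h_med <- harmonize_pair(exp_ds, med_ds, instruments, ld = ld,
                          palindrome_maf = palindrome_maf, r2_proxy = r2_proxy)
  m <- match(h_out$source_id, h_med$source_id)
  res <- as.data.frame(h_out)
  res$beta_med <- h_med$beta_out[m]
  res$se_med <- h_med$se_out[m]
  res$eaf_med <- h_med$eaf_out[m]
  res$n_med <- h_med$n_out[m]
  med_dropped <- h_med$action[m] == "dropped"
  drop_now <- med_dropped & res$action != "dropped"
  res$action[drop_now] <- "dropped"
  res$reason[drop_now] <- h_med$reason[m][drop_now]
  # keep only variants whose outcome record and mediator record refer to the
  # same (possibly proxied) variant
  mismatch <- res$variant_id != h_med$variant_id[m] & res$action != "dropped"
  res$action[mismatch] <- "dropped"
  res$reason[mismatch] <- "missing-in-outcome-no-proxy"
  if (!any(res$action != "dropped")) stop("no harmonizable instruments")
  structure(res, class = c("mv_harmonized_set", "harmonized_set", "data.frame"),
            exposure_id = trait_id(exp_ds), mediator_id = trait_id(med_ds),
            outcome_id = trait_id(out_ds),
            exposure_type = trait_type(exp_ds),
            mediator_type = trait_type(med_ds),
            outcome_type = trait_type(out_ds))
}
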