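#' Configuration for the three-trait GWAS simulator
#'
#' The generator emulates the statistical structure of a two-sample MR study
#' of a continuous exposure X (years of schooling, SD units), a continuous
#' mediator M (a brain imaging-derived phenotype, SD units) and a binary
#' outcome Y (late-onset Alzheimer's disease, log odds-ratio scale), under
#' the causal triple X -> M -> Y with a direct path X -> Y.
#'
#' Defaults are the package's reference study conditions: 332 exposure
#' instruments against GWAS sample sizes of ~1.13 million (exposure), 33 211
#' (mediator) and 63 926 with 34.4% cases (outcome); per-variant exposure
#' effects sized (sigma_gamma = 0.011) so the instrument set explains roughly
#' 1.3% of exposure variance; total exposure-outcome effect log(0.70) carried
#' entirely by the direct path (b = 0); 24 outcome-primary variants for
#' Steiger stress; 10% palindromic allele codings.
#'
#' @param J number of candidate exposure instruments.
#' @param n_x,n_m,n_y GWAS sample sizes for X, M, Y.
#' @param K case fraction of the binary outcome GWAS, in (0, 1).
#' @param a causal effect X -> M (SD per SD).
#' @param b causal effect M -> Y (log OR per SD).
#' @param c_prime direct effect X -> Y (log OR per SD).
#' @param sigma_gamma SD of true variant-exposure effects (per-allele,
#'   unit-variance trait scale).
#' @param prop_invalid fraction of the J exposure instruments with horizontal
#'   pleiotropy.
#' @param mu_alpha,sigma_alpha mean and SD of pleiotropic outcome effects,
#'   planted in the exposure-increasing orientation (`mu_alpha != 0` gives
#'   directional pleiotropy).
#' @param inside_violation correlation in [-1, 1] between pleiotropy magnitude
#'   and instrument strength (0 preserves the InSIDE assumption).
#' @param n_reverse count of outcome-primary variants (true exposure effect 0,
#'   outcome effect drawn at |z| ~ U(6, 12)); used to stress Steiger filtering.
#' @param n_mediator count of mediator-specific instruments (exposure effect
#'   0, mediator effect ~ N(0, sigma_delta^2)).
#' @param sigma_delta SD of mediator-specific effects.
#' @param ld_blocks optional list of `c(size, r2)` pairs; each block appends
#'   `size - 1` extra tag variants in LD with one of the candidate variants.
#' @param frac_palindromic fraction of variants assigned palindromic (A/T or
#'   C/G) allele pairs, with allele frequency drawn U(0.30, 0.50) so that the
#'   minor-allele-frequency 0.42 harmonization rule is exercised.
#' @param frac_strand_flipped,frac_allele_swapped default perturbation
#'   fractions consumed by [inject_harmonization_noise()].
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(J = 332,
                       n_x = 1131881, n_m = 33211, n_y = 63926,
                       K = 21982 / 63926,
                       a = 0.30, b = 0, c_prime = log(0.70),
                       sigma_gamma = 0.011,
                       prop_invalid = 0, mu_alpha = 0, sigma_alpha = 0,
                       inside_violation = 0,
                       n_reverse = 24, n_mediator = 20, sigma_delta = 0.08,
                       ld_blocks = NULL,
                       frac_palindromic = 0.10,
                       frac_strand_flipped = 0.10,
                       frac_allele_swapped = 0.10,
                       seed = 1) {
  cfg <- list(J = J, n_x = n_x, n_m = n_m, n_y = n_y, K = K,
              a = a, b = b, c_prime = c_prime, sigma_gamma = sigma_gamma,
              prop_invalid = prop_invalid, mu_alpha = mu_alpha,
              sigma_alpha = sigma_alpha, inside_violation = inside_violation,
              n_reverse = n_reverse, n_mediator = n_mediator,
              sigma_delta = sigma_delta, ld_blocks = ld_blocks,
              frac_palindromic = frac_palindromic,
              frac_strand_flipped = frac_strand_flipped,
              frac_allele_swapped = frac_allele_swapped, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ok <- function(cond, msg) if (!cond) stop("invalid simulation config: ", msg)
  ok(cfg$J >= 1, "J must be >= 1")
  ok(all(c(cfg$n_x, cfg$n_m, cfg$n_y) > 1), "sample sizes must exceed 1")
  ok(cfg$K > 0 && cfg$K < 1, "case fraction K must lie in (0, 1)")
  ok(cfg$prop_invalid >= 0 && cfg$prop_invalid <= 1, "prop_invalid in [0, 1]")
  ok(abs(cfg$inside_violation) <= 1, "inside_violation in [-1, 1]")
  ok(cfg$sigma_gamma > 0, "sigma_gamma must be positive")
  for (f in c("frac_palindromic", "frac_strand_flipped", "frac_allele_swapped")) {
    ok(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "in [0, 1]"))
  }
  ok(cfg$n_reverse >= 0 && cfg$n_mediator >= 0, "variant counts must be >= 0")
  if (!is.null(cfg$ld_blocks)) {
    for (bl in cfg$ld_blocks) {
      ok(length(bl) == 2 && bl[1] >= 1 && bl[2] >= 0 && bl[2] <= 1,
         "ld_blocks entries must be c(size >= 1, r2 in [0, 1])")
    }
    ok(length(cfg$ld_blocks) <= cfg$J, "more LD blocks than candidate variants")
  }
  invisible(cfg)
}

# Standard error of a per-allele effect on a unit-variance trait.
se_continuous <- function(p, n) 1 / sqrt(2 * p * (1 - p) * n)
# Large-sample log-OR standard error for a binary trait with case fraction K.
se_binary <- function(p, n, K) 1 / sqrt(2 * p * (1 - p) * n * K * (1 - K))

#' Simulate three-trait GWAS summary statistics with known causal truth
#'
#' Generates exposure, mediator and outcome summary datasets, an LD reference
#' and a truth object under the configured causal model. Per candidate variant
#' j with effect-allele frequency p_j ~ U(0.05, 0.5): gamma_j ~ N(0,
#' sigma_gamma^2); mediator effect a * gamma_j (+ delta_j for
#' mediator-specific variants); outcome effect c' * gamma_j + b * beta_Mj +
#' alpha_j, with pleiotropy alpha_j present for the invalid fraction.
#' Observed estimates add normal noise with standard errors determined by
#' allele frequency and sample size (binary outcome on the log-OR scale).
#'
#' @param config a [sim_config()].
#' @return list with elements `exposure`, `mediator`, `outcome`
#'   ([summary_dataset()]s), `ld` ([ld_reference()]) and `truth` (class
#'   `sim_truth`: per-variant true effects, class labels, and the generating
#'   parameters with `total_effect = c_prime + a * b`).
#' @export
simulate_triple <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n_invalid <- round(cfg$prop_invalid * cfg$J)
    class <- c(
      sample(c(rep("pleiotropic", n_invalid), rep("valid", cfg$J - n_invalid))),
      rep("reverse", cfg$n_reverse),
      rep("mediator-specific", cfg$n_mediator)
    )
    N0 <- length(class)

    p <- stats::runif(N0, 0.05, 0.5)
    pal <- stats::runif(N0) < cfg$frac_palindromic
    p[pal] <- stats::runif(sum(pal), 0.30, 0.50)

    gamma <- ifelse(class %in% c("valid", "pleiotropic"),
                    stats::rnorm(N0, 0, cfg$sigma_gamma), 0)
    delta <- ifelse(class == "mediator-specific",
                    stats::rnorm(N0, 0, cfg$sigma_delta), 0)

    # Directional pleiotropy is planted in the exposure-increasing
    # orientation; inside_violation couples its magnitude to |gamma_j|.
    alpha <- numeric(N0)
    inv <- class == "pleiotropic"
    if (any(inv)) {
      g_abs <- abs(gamma[inv])
      u <- if (stats::sd(g_abs) > 0) (g_abs - mean(g_abs)) / stats::sd(g_abs) else 0 * g_abs
      eps <- cfg$inside_violation * u +
        sqrt(1 - cfg$inside_violation^2) * stats::rnorm(sum(inv))
      alpha[inv] <- sign(gamma[inv]) * (cfg$mu_alpha + cfg$sigma_alpha * eps)
    }

    se_y0 <- se_binary(p, cfg$n_y, cfg$K)
    gamma_y_rev <- numeric(N0)
    rev <- class == "reverse"
    if (any(rev)) {
      gamma_y_rev[rev] <- sample(c(-1, 1), sum(rev), replace = TRUE) *
        stats::runif(sum(rev), 6, 12) * se_y0[rev]
    }

    beta_m_true <- cfg$a * gamma + delta
    beta_y_true <- cfg$c_prime * gamma + cfg$b * beta_m_true + alpha + gamma_y_rev

    block_id <- rep(NA_integer_, N0)
    # LD blocks: extra tag variants appended, tagging one candidate each.
    if (!is.null(cfg$ld_blocks) && length(cfg$ld_blocks) > 0) {
      heads <- seq_along(cfg$ld_blocks)
      for (bi in seq_along(cfg$ld_blocks)) {
        size <- cfg$ld_blocks[[bi]][1]
        r2 <- cfg$ld_blocks[[bi]][2]
        r <- sqrt(r2)
        block_id[heads[bi]] <- bi
        n_tag <- size - 1
        if (n_tag > 0) {
          h <- heads[bi]
          class <- c(class, rep("tag", n_tag))
          p <- c(p, rep(p[h], n_tag))
          pal <- c(pal, rep(FALSE, n_tag))
          gamma <- c(gamma, rep(r * gamma[h], n_tag))
          delta <- c(delta, rep(r * delta[h], n_tag))
          alpha <- c(alpha, rep(r * alpha[h], n_tag))
          gamma_y_rev <- c(gamma_y_rev, rep(r * gamma_y_rev[h], n_tag))
          beta_m_true <- c(beta_m_true, rep(r * beta_m_true[h], n_tag))
          beta_y_true <- c(beta_y_true, rep(r * beta_y_true[h], n_tag))
          block_id <- c(block_id, rep(bi, n_tag))
        }
      }
    }
    N <- length(class)
    id <- sprintf("rs%07d", seq_len(N))

    # Allele codings: palindromic variants get complementary pairs
    # (consistently across all three datasets); others a non-complementary pair.
    ea <- character(N); oa <- character(N)
    pal_choice <- sample(c("AT", "CG"), N, replace = TRUE)
    ea[pal] <- ifelse(pal_choice[pal] == "AT", "A", "C")
    oa[pal] <- allele_complement(ea[pal])
    nonpal_pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    pick <- sample.int(4L, N, replace = TRUE)
    for (k in 1:4) {
      sel <- !pal & pick == k
      ea[sel] <- nonpal_pairs[[k]][1]
      oa[sel] <- nonpal_pairs[[k]][2]
    }
    # randomize which allele is labelled the effect allele
    flip_lab <- stats::runif(N) < 0.5
    tmp <- ea[flip_lab]; ea[flip_lab] <- oa[flip_lab]; oa[flip_lab] <- tmp
    # frequency refers to the labelled effect allele
    eaf <- ifelse(flip_lab, 1 - p, p)
    het <- 2 * eaf * (1 - eaf)  # invariant under labelling

    se_x <- 1 / sqrt(het * cfg$n_x)
    se_m <- 1 / sqrt(het * cfg$n_m)
    se_y <- 1 / sqrt(het * cfg$n_y * cfg$K * (1 - cfg$K))
    sgn <- ifelse(flip_lab, -1, 1)

    mk_ds <- function(true_beta, se, tid, type, n, n_case = NA, n_control = NA,
                      unit = "") {
      beta_hat <- sgn * true_beta + stats::rnorm(N, 0, se)
      summary_dataset(data.frame(
        variant_id = id, effect_allele = ea, other_allele = oa, eaf = eaf,
        beta = beta_hat, se = se, pval = z_pval(beta_hat, se),
        n = n, n_case = n_case, n_control = n_control
      ), trait_id = tid, trait_type = type, unit = unit, validate = FALSE)
    }
    exposure <- mk_ds(gamma, se_x, "X", "continuous", cfg$n_x,
                      unit = "SD of exposure")
    mediator <- mk_ds(beta_m_true, se_m, "M", "continuous", cfg$n_m,
                      unit = "SD of mediator")
    n_case <- round(cfg$K * cfg$n_y)
    outcome <- mk_ds(beta_y_true, se_y, "Y", "binary", cfg$n_y,
                     n_case = n_case, n_control = cfg$n_y - n_case,
                     unit = "log OR")

    # Positions: block heads and singletons spaced 20 Mb apart on chrom 1
    # (beyond the clumping window); tags 1 kb from their head.
    anchor <- ifelse(is.na(block_id), seq_len(N), match(block_id, block_id))
    pos <- anchor * 2e7 + (seq_len(N) - anchor) * 1000
    positions <- data.frame(variant_id = id, chrom = "1", pos = pos)
    pair_list <- list()
    if (!is.null(cfg$ld_blocks) && length(cfg$ld_blocks) > 0) {
      for (bi in seq_along(cfg$ld_blocks)) {
        members <- id[which(!is.na(block_id) & block_id == bi)]
        r2 <- cfg$ld_blocks[[bi]][2]
        if (length(members) > 1) {
          cmb <- utils::combn(members, 2)
          pair_list[[bi]] <- data.frame(variant_id_a = cmb[1, ],
                                        variant_id_b = cmb[2, ], r2 = r2)
        }
      }
    }
    pairs <- if (length(pair_list) > 0) do.call(rbind, pair_list) else
      data.frame(variant_id_a = character(), variant_id_b = character(),
                 r2 = numeric())
    ld <- ld_reference(pairs, positions, window_bp = 1e7)

    truth <- structure(list(
      a = cfg$a, b = cfg$b, c_prime = cfg$c_prime,
      total_effect = cfg$c_prime + cfg$a * cfg$b,
      seed = cfg$seed,
      table = data.frame(variant_id = id, class = class, eaf = eaf,
                         gamma = sgn * gamma, delta = sgn * delta,
                         alpha = sgn * alpha,
                         gamma_y = sgn * gamma_y_rev,
                         beta_m = sgn * beta_m_true,
                         beta_y = sgn * beta_y_true,
                         block = block_id)
    ), class = "sim_truth")

    list(exposure = exposure, mediator = mediator, outcome = outcome,
         ld = ld, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("<sim_truth> a = %.4g, b = %.4g, c' = %.4g, ",
                     "total = %.4g; %d variants\n"),
              x$a, x$b, x$c_prime, x$total_effect, nrow(x$table)))
  print(table(x$table$class))
  invisible(x)
}

#' Perturb allele codings to exercise harmonization
#'
#' Applies, to disjoint random subsets of the records: (i) strand flips (both
#' alleles complemented; beta and eaf unchanged), (ii) allele swaps
#' (effect/other exchanged, beta negated, eaf complemented), and optionally
#' (iii) palindromic recoding (alleles set to an A/T or C/G pair and eaf moved
#' near 0.5). All perturbations are recorded in a sidecar log so tests can
#' verify that harmonization undoes them exactly.
#'
#' @param ds a [summary_dataset()].
#' @param frac_strand_flipped,frac_allele_swapped,frac_palindromic perturbation
#'   fractions in [0, 1].
#' @param palindrome_closeness palindromic recoding draws eaf in
#'   `0.5 +/- palindrome_closeness`.
#' @param seed RNG seed.
#' @return list with `dataset` (perturbed copy) and `log` (data.frame of
#'   `variant_id`, `perturbation`, original alleles/beta/eaf).
#' @export
inject_harmonization_noise <- function(ds, frac_strand_flipped = 0.1,
                                       frac_allele_swapped = 0.1,
                                       frac_palindromic = 0,
                                       palindrome_closeness = 0.05,
                                       seed = 1) {
  stopifnot(inherits(ds, "summary_dataset"))
  with_seed(seed, {
    n <- nrow(ds)
    out <- ds
    pool <- sample.int(n)
    n_fl <- round(frac_strand_flipped * n)
    n_sw <- round(frac_allele_swapped * n)
    n_pl <- round(frac_palindromic * n)
    if (n_fl + n_sw + n_pl > n) stop("perturbation fractions sum above 1")
    fl <- pool[seq_len(n_fl)]
    sw <- pool[n_fl + seq_len(n_sw)]
    pl <- pool[n_fl + n_sw + seq_len(n_pl)]

    log_rows <- list()
    note <- function(idx, what) {
      if (length(idx) == 0) return(NULL)
      data.frame(variant_id = ds$variant_id[idx], perturbation = what,
                 effect_allele = ds$effect_allele[idx],
                 other_allele = ds$other_allele[idx],
                 beta = ds$beta[idx], eaf = ds$eaf[idx])
    }
    log_rows$flip <- note(fl, "strand_flip")
    log_rows$swap <- note(sw, "allele_swap")
    log_rows$pal <- note(pl, "palindromic_recode")

    if (n_fl > 0) {
      out$effect_allele[fl] <- allele_complement(ds$effect_allele[fl])
      out$other_allele[fl] <- allele_complement(ds$other_allele[fl])
    }
    if (n_sw > 0) {
      ea <- out$effect_allele[sw]
      out$effect_allele[sw] <- out$other_allele[sw]
      out$other_allele[sw] <- ea
      out$beta[sw] <- -out$beta[sw]
      out$eaf[sw] <- 1 - out$eaf[sw]
    }
    if (n_pl > 0) {
      choice <- sample(c("A", "C"), n_pl, replace = TRUE)
      out$effect_allele[pl] <- choice
      out$other_allele[pl] <- allele_complement(choice)
      out$eaf[pl] <- stats::runif(n_pl, 0.5 - palindrome_closeness,
                                  0.5 + palindrome_closeness)
    }
    log <- do.call(rbind, log_rows)
    rownames(log) <- NULL
    list(dataset = out, log = log %||%
           data.frame(variant_id = character(), perturbation = character()))
  })
}

#' Synthetic phenotypic correlation matrix for 15 imaging-derived phenotypes
#'
#' A deterministic, positive-definite 15 x 15 correlation matrix emulating a
#' family of brain MRI phenotypes: moderate within-group correlations (cortical
#' macro-structure, cortical micro-structure, white matter tracts, subcortical
#' volumes), weak between-group correlations, and two nearly redundant pairs
#' (surface area with cortical volume; left with right hippocampal volume).
#' By construction 13 principal components of the element-wise squared matrix
#' explain 99.5% of its variance, so [effective_tests()] reproduces the
#' worked multiplicity chain n = 13, T = 78, sqrt(T) = 8.83.
#'
#' @return 15 x 15 named correlation matrix.
#' @export
simulate_idp_correlation <- function() {
  idp <- c("SA", "CortVol", "CT", "LGI", "MC", "IC",
           "FA_cortex", "MD_cortex", "ICVF", "ODI",
           "FA_wm", "MD_wm", "HC_left", "HC_right", "WMH")
  groups <- c(rep("macro", 6), rep("micro", 4), rep("wm", 2), rep("hc", 2), "wmh")
  p <- length(idp)
  R <- matrix(0.10, p, p, dimnames = list(idp, idp))
  for (g in unique(groups)) {
    sel <- groups == g
    R[sel, sel] <- 0.30
  }
  R["SA", "CortVol"] <- R["CortVol", "SA"] <- 0.995
  R["HC_left", "HC_right"] <- R["HC_right", "HC_left"] <- 0.995
  diag(R) <- 1
  R
}

#' Simulate a panel of correlated mediator GWAS over an existing variant set
#'
#' Builds one summary dataset per mediator phenotype on the same variant
#' universe as a [simulate_triple()] result: mediator k has true per-variant
#' effect `a[k] * gamma_j + delta_j` (the shared mediator-specific effects
#' instrument every panel member, mimicking global brain-structure variants),
#' and estimation noise is correlated across mediators according to `R`,
#' emulating phenotypes measured in one GWAS cohort. Panel mediators carry no
#' effect onto the simulated outcome, so the panel emulates a null-mediator
#' (no M -> Y path) study arm.
#'
#' @param sim result of [simulate_triple()].
#' @param a named vector of exposure-to-mediator effects (SD per SD); names
#'   become trait ids.
#' @param R phenotypic correlation matrix across the mediators (defaults to
#'   independence), dimension `length(a)`.
#' @param n_m mediator GWAS sample size.
#' @param seed RNG seed.
#' @return named list of [summary_dataset()]s.
#' @export
simulate_mediator_panel <- function(sim, a, R = NULL, n_m = 33211, seed = 1) {
  t <- sim$truth$table
  K <- length(a)
  if (is.null(names(a))) names(a) <- paste0("M", seq_len(K))
  if (is.null(R)) R <- diag(K)
  stopifnot(nrow(R) == K, ncol(R) == K)
  ref <- sim$exposure
  het <- 2 * ref$eaf * (1 - ref$eaf)
  se_m <- 1 / sqrt(het * n_m)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(nrow(t) * K), nrow(t), K) %*% chol(R)
    out <- list()
    for (k in seq_len(K)) {
      true_k <- a[k] * t$gamma + t$delta
      beta_hat <- true_k + se_m * Z[, k]
      out[[names(a)[k]]] <- summary_dataset(data.frame(
        variant_id = ref$variant_id, effect_allele = ref$effect_allele,
        other_allele = ref$other_allele, eaf = ref$eaf,
        beta = beta_hat, se = se_m, pval = z_pval(beta_hat, se_m),
        n = n_m, n_case = NA, n_control = NA
      ), trait_id = names(a)[k], trait_type = "continuous",
      unit = "SD of mediator", validate = FALSE)
    }
    out
  })
}
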