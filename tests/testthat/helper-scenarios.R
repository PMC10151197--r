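# Shared scenario builders for the test suite. All randomness is seeded.

# A small valid summary-statistics data.frame (hand-sized, exact values).
toy_records <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "T"),
    eaf = c(0.25, 0.40, 0.10),
    beta = c(0.02, -0.015, 0.05),
    se = c(0.004, 0.003, 0.01),
    pval = c(5.7e-7, 5.7e-7, 5.7e-7),
    n = c(10000, 10000, 10000),
    n_case = NA_real_, n_control = NA_real_
  )
}

# Random valid dataset for round-trip property tests.
random_dataset <- function(n, seed, trait_type = "continuous") {
  set.seed(seed)
  pairs <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                c("A", "T"), c("C", "G"))
  pick <- sample(length(pairs), n, replace = TRUE)
  ea <- vapply(pairs[pick], `[`, "", 1L)
  oa <- vapply(pairs[pick], `[`, "", 2L)
  beta <- rnorm(n, 0, 0.05)
  se <- runif(n, 0.001, 0.02)
  nn <- round(runif(n, 5000, 50000))
  rec <- data.frame(
    variant_id = sprintf("rs%06d", sample.int(1e6, n)),
    effect_allele = ea, other_allele = oa,
    eaf = runif(n, 0.01, 0.99), beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = nn,
    n_case = if (trait_type == "binary") round(nn * 0.4) else NA_real_,
    n_control = if (trait_type == "binary") nn - round(nn * 0.4) else NA_real_
  )
  summary_dataset(rec, trait_id = "T", trait_type = trait_type)
}

# Random aligned harmonized set for estimator-oracle tests.
random_hset <- function(J, seed, theta = 0.2, binary = FALSE) {
  set.seed(seed)
  bx <- rnorm(J, 0, 0.1)
  sx <- runif(J, 0.002, 0.01)
  sy <- runif(J, 0.005, 0.05)
  by <- theta * bx + rnorm(J, 0, sy)
  harmonized_set(sprintf("rs%03d", seq_len(J)), bx, sx, by, sy,
                 n_exp = 50000, n_out = 60000,
                 outcome_type = if (binary) "binary" else "continuous",
                 n_case_out = if (binary) 20000 else NA,
                 n_control_out = if (binary) 40000 else NA)
}

# Simulated triple harmonized over a given variant class selection.
sim_hset <- function(cfg, classes = NULL) {
  sim <- simulate_triple(cfg)
  ids <- if (is.null(classes)) sim$truth$table$variant_id else
    sim$truth$table$variant_id[sim$truth$table$class %in% classes]
  list(sim = sim, h = harmonize_pair(sim$exposure, sim$outcome, ids))
}

expect_rel_equal <- function(x, y, tol = 1e-10) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
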