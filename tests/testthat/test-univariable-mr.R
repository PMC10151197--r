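test_that("ratio estimates follow the Wald formula and exclude zero-gamma variants", {
  h <- harmonized_set("rs1", 0.1, 0.01, 0.05, 0.01)
  r <- ratio_estimates(h)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.1)
  h2 <- harmonized_set(c("rs1", "rs2"), c(0.1, 0), c(0.01, 0.01),
                       c(0, 0.05), c(0.01, 0.01))
  expect_warning(r2 <- ratio_estimates(h2), "zero exposure effect")
  expect_equal(r2$estimate, 0)
  h3 <- harmonized_set("rs1", 0, 0.01, 0.05, 0.01)
  expect_error(suppressWarnings(ratio_estimates(h3)), "zero")
})

test_that("IVW reduces to the ratio estimate for one variant and has Q = 0 when homogeneous", {
  h1 <- harmonized_set("rs1", 0.08, 0.01, 0.02, 0.004)
  f1 <- ivw(h1)
  expect_equal(f1$estimate, 0.25)
  expect_equal(f1$se, 0.05)
  # collinear variants: identical theta_j
  bx <- c(0.05, 0.1, 0.2)
  h2 <- harmonized_set(paste0("rs", 1:3), bx, 0.01, 0.4 * bx, c(0.01, 0.02, 0.01))
  f2 <- ivw(h2)
  expect_equal(f2$estimate, 0.4)
  expect_equal(f2$extras$Q$Q, 0)
  expect_equal(f2$se, f2$extras$se_fixed)
})

test_that("IVW and Egger match independent weighted-least-squares oracles", {
  for (seed in c(101, 102, 103, 104, 105)) {
    h <- random_hset(30, seed)
    f <- ivw(h)
    o <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
    expect_rel_equal(f$estimate, unname(coef(o)))
    expect_rel_equal(f$extras$se_fixed,
                     unname(sqrt(diag(vcov(o)) / summary(o)$sigma^2)))
    e <- egger(h)
    s <- sign(h$beta_exp)
    d <- data.frame(x = s * h$beta_exp, y = s * h$beta_out, w = 1 / h$se_out^2)
    oe <- lm(y ~ x, data = d, weights = d$w)
    expect_rel_equal(e$estimate, unname(coef(oe)[2]))
    expect_rel_equal(e$extras$intercept, unname(coef(oe)[1]))
    unscaled <- sqrt(diag(vcov(oe))) / summary(oe)$sigma
    q_scale <- max(1, sqrt(e$extras$Q_egger / (nrow(h) - 2)))
    expect_rel_equal(e$extras$intercept_se, unname(unscaled[1]) * q_scale)
  }
})

test_that("the multiplicative random-effects se is never below the fixed-effect se", {
  for (seed in 111:118) {
    h <- random_hset(15, seed, theta = runif(1, -0.5, 0.5))
    f <- ivw(h)
    expect_gte(f$se, f$extras$se_fixed)
  }
})

test_that("estimators are equivariant under relabeling and joint sign flips", {
  h <- random_hset(25, 120)
  flip <- harmonized_set(h$variant_id, -h$beta_exp, h$se_exp, -h$beta_out,
                         h$se_out)
  shuf <- h[sample(nrow(h)), , drop = FALSE]
  hs <- harmonized_set(shuf$variant_id, shuf$beta_exp, shuf$se_exp,
                       shuf$beta_out, shuf$se_out)
  expect_equal(ivw(flip)$estimate, ivw(h)$estimate)
  expect_equal(ivw(hs)$estimate, ivw(h)$estimate)
  expect_equal(egger(flip)$estimate, egger(h)$estimate)
  expect_equal(weighted_median(flip, n_boot = 50, seed = 1)$estimate,
               weighted_median(h, n_boot = 50, seed = 1)$estimate)
  expect_equal(contamination_mixture(flip, grid_points = 2001)$estimate,
               -(-contamination_mixture(h, grid_points = 2001)$estimate))
})

test_that("MR-Egger fits three collinear points through the origin exactly", {
  bx <- c(0.1, 0.2, 0.4)
  h <- harmonized_set(paste0("rs", 1:3), bx, 0.01, 0.3 * bx, 0.01)
  e <- egger(h)
  expect_equal(e$estimate, 0.3, tolerance = 1e-12)
  expect_equal(e$extras$intercept, 0, tolerance = 1e-12)
  # below the minimum variant count the method is not applicable
  expect_true(is.na(egger(harmonized_set(c("a", "b"), c(0.1, 0.2), 0.01,
                                         c(0.03, 0.06), 0.01))$estimate))
})

test_that("weighted median interpolates the 0.5 crossing and respects dominant weights", {
  h <- harmonized_set(paste0("rs", 1:3), c(1, 1, 1), 1e-6, c(1, 2, 3),
                      c(1, 1, 1))
  expect_equal(weighted_median(h, n_boot = 10, seed = 1)$estimate, 2)
  # one variant holding ~90% of the weight pins the estimate near its ratio
  h2 <- harmonized_set(paste0("rs", 1:4), c(1, 1, 1, 1), 1e-6,
                       c(0.1, 0.9, 1.1, 0.5), c(1, 1, 1, 1 / 3))
  est <- weighted_median(h2, n_boot = 10, seed = 1)$estimate
  expect_lt(abs(est - 0.5), 0.15)
})

test_that("contamination mixture agrees with IVW when all instruments are valid", {
  h <- random_hset(40, 130, theta = 0.25)
  cm <- contamination_mixture(h)
  f <- ivw(h)
  grid_step <- (cm$extras$ci_set$high[1] - cm$extras$ci_set$low[1]) / 100
  expect_lt(abs(cm$estimate - f$estimate), max(3 * f$se / 10, grid_step))
  expect_true(cm$ci_low <= cm$estimate && cm$estimate <= cm$ci_high)
  # likelihood at the true value beats values 5 se away
  ll <- cm$extras$log_lik
  expect_gt(ll(0.25), ll(0.25 + 5 * f$se))
  expect_gt(ll(0.25), ll(0.25 - 5 * f$se))
})

test_that("contamination mixture separates a causal cluster from nulls", {
  bx <- rep(0.2, 12)
  theta_j <- c(rep(0.5, 7), rep(0, 5))
  h <- harmonized_set(sprintf("rs%02d", 1:12), bx, 0.001, theta_j * bx,
                      0.004)
  cm <- contamination_mixture(h, psi = 1)
  expect_lt(abs(cm$estimate - 0.5), 0.05)
})

test_that("MR-PRESSO is deterministic given a seed and flags a planted outlier", {
  h <- random_hset(30, 140, theta = 0.3)
  p1 <- mr_presso(h, n_sim = 300, seed = 7, n_distortion = 50)
  p2 <- mr_presso(h, n_sim = 300, seed = 7, n_distortion = 50)
  expect_identical(p1$global_pval, p2$global_pval)
  expect_identical(p1$outlier_pvals, p2$outlier_pvals)

  k <- which.max(abs(h$beta_exp))
  h$beta_out[k] <- h$beta_out[k] + 10 * h$se_out[k]
  pr <- mr_presso(h, n_sim = 400, seed = 8, n_distortion = 50)
  expect_true(h$variant_id[k] %in% pr$outliers)
  expect_lt(abs(pr$corrected$estimate - 0.3), abs(pr$raw$estimate - 0.3))
  # below the minimum count the method is not applicable
  small <- harmonized_set(paste0("r", 1:3), c(0.1, 0.2, 0.3), 0.01,
                          c(0.03, 0.06, 0.09), 0.01)
  expect_false(isTRUE(mr_presso(small, n_sim = 10)$applicable))
})

test_that("Steiger directionality compares variance explained across traits", {
  n <- 10000
  h <- harmonized_set(c("rs1", "rs2"),
                      beta_exp = c(30, 1) / sqrt(n), se_exp = 1 / sqrt(n),
                      beta_out = c(1, 30) / sqrt(n), se_out = 1 / sqrt(n),
                      n_exp = n, n_out = n)
  st <- steiger_filter(h)
  expect_equal(st$table$direction, c("exposure-first", "outcome-first"))
  expect_equal(st$fraction_outcome_first, st$n_outcome_first / st$n_snp)
  expect_equal(nrow(kept(st$filtered)), 1)
  # binary outcome without case/control counts is an error
  hb <- harmonized_set("rs1", 0.1, 0.01, 0.05, 0.01, n_exp = n, n_out = n,
                       outcome_type = "binary")
  expect_error(steiger_filter(hb), "case/control")
})

test_that("leave-one-out reproduces the complementary ratio estimates at J = 2", {
  h <- harmonized_set(c("rs1", "rs2"), c(0.1, 0.2), 0.01, c(0.03, 0.08),
                      c(0.01, 0.02))
  tab <- leave_one_out(h)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$estimate[tab$excluded == "rs1"], 0.4)  # rs2 alone
  expect_equal(tab$estimate[tab$excluded == "rs2"], 0.3)  # rs1 alone
  # homogeneous data: every row within one fixed se of the full fit
  h2 <- random_hset(20, 150, theta = 0.2)
  f <- ivw(h2)
  tab2 <- leave_one_out(h2)
  expect_equal(nrow(tab2), 20)
  expect_true(all(abs(tab2$estimate - f$estimate) < f$extras$se_fixed))
})

test_that("funnel coordinates pair estimates with positive precision and centre on IVW", {
  h <- random_hset(30, 160, theta = 0.1)
  fd <- funnel_data(h)
  expect_true(all(fd$precision > 0))
  ss <- single_snp(h)
  expect_true(all(ss$ci_low <= ss$estimate & ss$estimate <= ss$ci_high))
  # weighted mean of funnel x-coordinates with IVW weights equals the IVW fit
  w <- (h$beta_exp / h$se_out)^2
  expect_equal(sum(w * fd$estimate) / sum(w), ivw(h)$estimate,
               tolerance = 1e-12)
})

test_that("binary outcomes are reported as odds ratios per SD of exposure", {
  h <- random_hset(10, 170, theta = log(0.7), binary = TRUE)
  f <- ivw(h)
  or <- as_odds_ratio(f)
  expect_equal(unname(or["or"]), exp(f$estimate))
  expect_true(or["or_ci_low"] < or["or"] & or["or"] < or["or_ci_high"])
})
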