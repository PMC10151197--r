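test_that("identical config and seed give identical output", {
  cfg <- sim_config(J = 60, seed = 99)
  a <- simulate_triple(cfg)
  b <- simulate_triple(cfg)
  expect_identical(as.data.frame(a$exposure), as.data.frame(b$exposure))
  expect_identical(as.data.frame(a$outcome), as.data.frame(b$outcome))
  expect_identical(a$truth$table, b$truth$table)
  expect_identical(a$ld$pairs, b$ld$pairs)
  d <- simulate_triple(sim_config(J = 60, seed = 100))
  expect_false(identical(a$exposure$beta, d$exposure$beta))
})

test_that("truth bookkeeping matches the configured variant architecture", {
  cfg <- sim_config(J = 97, prop_invalid = 0.31, n_reverse = 7, n_mediator = 5,
                    mu_alpha = 0.02, sigma_alpha = 0.01, seed = 2)
  t <- simulate_triple(cfg)$truth$table
  expect_equal(sum(t$class == "pleiotropic"), round(0.31 * 97))
  expect_equal(sum(t$class == "valid"), 97 - round(0.31 * 97))
  expect_equal(sum(t$class == "reverse"), 7)
  expect_equal(sum(t$class == "mediator-specific"), 5)
  # reverse-class variants have zero true exposure effect
  expect_true(all(t$gamma[t$class == "reverse"] == 0))
  # total effect recomputable from the stored parameters
  tr <- simulate_triple(cfg)$truth
  expect_identical(tr$total_effect, tr$c_prime + tr$a * tr$b)
})

test_that("under the global null the outcome p-values are uniform at the tail", {
  cfg <- sim_config(J = 200, a = 0, b = 0, c_prime = 0, prop_invalid = 0,
                    n_reverse = 0, n_mediator = 0, frac_palindromic = 0,
                    seed = 4)
  sim <- simulate_triple(cfg)
  frac <- mean(sim$outcome$pval < 0.05)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("observed exposure z-scores are calibrated against the truth", {
  cfg <- sim_config(J = 1000, n_x = 1e5, n_reverse = 0, n_mediator = 0,
                    frac_palindromic = 0, seed = 3)
  sim <- simulate_triple(cfg)
  z <- (sim$exposure$beta - sim$truth$table$gamma) / sim$exposure$se
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("a = 0 leaves valid instruments with zero true mediator effect", {
  cfg <- sim_config(J = 50, a = 0, n_mediator = 10, seed = 6)
  t <- simulate_triple(cfg)$truth$table
  expect_true(all(t$beta_m[t$class %in% c("valid", "pleiotropic")] == 0))
  expect_equal(t$beta_m[t$class == "mediator-specific"],
               t$delta[t$class == "mediator-specific"])
})

test_that("LD blocks append tag variants with scaled effects and stored r2", {
  cfg <- sim_config(J = 30, ld_blocks = list(c(3, 0.64), c(2, 0.25)),
                    n_reverse = 0, n_mediator = 0, frac_palindromic = 0,
                    seed = 8)
  sim <- simulate_triple(cfg)
  t <- sim$truth$table
  expect_equal(sum(t$class == "tag"), 3)
  b1 <- t[!is.na(t$block) & t$block == 1, ]
  head_row <- b1[b1$class != "tag", ]
  tag_rows <- b1[b1$class == "tag", ]
  expect_equal(abs(tag_rows$gamma), rep(0.8 * abs(head_row$gamma), 2))
  expect_equal(ld_r2(sim$ld, b1$variant_id[1], b1$variant_id[2]), 0.64)
  expect_equal(ld_r2(sim$ld, t$variant_id[10], t$variant_id[11]), 0)
})

test_that("noise injection with zero fractions is the identity", {
  ds <- random_dataset(30, 31)
  out <- inject_harmonization_noise(ds, 0, 0, 0, seed = 1)
  expect_identical(as.data.frame(out$dataset), as.data.frame(ds))
  expect_equal(nrow(out$log), 0)
})

test_that("allele swaps negate beta and complement eaf; strand flips do not", {
  ds <- random_dataset(40, 32)
  out <- inject_harmonization_noise(ds, frac_strand_flipped = 0.25,
                                    frac_allele_swapped = 0.25, seed = 5)
  log <- out$log
  expect_equal(nrow(log), 20)
  sw <- log$variant_id[log$perturbation == "allele_swap"]
  fl <- log$variant_id[log$perturbation == "strand_flip"]
  i <- match(sw, ds$variant_id); j <- match(sw, out$dataset$variant_id)
  expect_equal(out$dataset$beta[j], -ds$beta[i])
  expect_equal(out$dataset$eaf[j], 1 - ds$eaf[i])
  i <- match(fl, ds$variant_id); j <- match(fl, out$dataset$variant_id)
  expect_equal(out$dataset$beta[j], ds$beta[i])
  expect_equal(out$dataset$eaf[j], ds$eaf[i])
  expect_equal(out$dataset$effect_allele[j],
               chartr("ACGT", "TGCA", ds$effect_allele[i]))
})

test_that("palindromic recoding moves alleles to complementary pairs near eaf 0.5", {
  ds <- random_dataset(40, 33)
  out <- inject_harmonization_noise(ds, 0, 0, frac_palindromic = 0.25,
                                    palindrome_closeness = 0.03, seed = 7)
  pl <- out$log$variant_id[out$log$perturbation == "palindromic_recode"]
  j <- match(pl, out$dataset$variant_id)
  expect_true(all(out$dataset$other_allele[j] ==
                    chartr("ACGT", "TGCA", out$dataset$effect_allele[j])))
  expect_true(all(abs(out$dataset$eaf[j] - 0.5) <= 0.03 + 1e-12))
})
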