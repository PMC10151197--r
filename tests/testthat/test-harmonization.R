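test_that("instrument selection is strict at the threshold and matches a brute-force filter", {
  rec <- toy_records()
  rec$pval <- c(1e-9, 5e-8, 1e-3)
  ds <- summary_dataset(rec, "EA", validate = FALSE)
  expect_equal(select_instruments(ds, 5e-8), "rs1")
  expect_equal(select_instruments(summary_dataset(rec[0, ], "EA")), character())

  sim <- simulate_triple(sim_config(J = 120, seed = 41))
  got <- select_instruments(sim$exposure)
  oracle <- sim$exposure$variant_id[sim$exposure$pval < 5e-8]
  oracle <- oracle[order(sim$exposure$pval[match(oracle, sim$exposure$variant_id)],
                         oracle)]
  expect_identical(got, oracle)
})

test_that("clumping keeps the lower-p variant of a linked pair and all unlinked variants", {
  ld <- ld_reference(
    data.frame(variant_id_a = "rs1", variant_id_b = "rs2", r2 = 0.5),
    data.frame(variant_id = c("rs1", "rs2", "rs3"), chrom = "1",
               pos = c(1e6, 1.1e6, 2e6)))
  cand <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                     pval = c(1e-10, 1e-8, 1e-9))
  expect_equal(clump(cand, ld, 0.001, 10000), c("rs1", "rs3"))
  ld0 <- ld_reference(
    data.frame(variant_id_a = character(), variant_id_b = character(),
               r2 = numeric()),
    data.frame(variant_id = cand$variant_id, chrom = "1", pos = 1:3 * 1e6))
  expect_setequal(clump(cand, ld0, 0.001, 10000), cand$variant_id)
})

test_that("greedy clumping satisfies the retained/removed property oracle", {
  set.seed(50)
  sim <- simulate_triple(sim_config(
    J = 50, ld_blocks = rep(list(c(4, 0.6)), 8), n_reverse = 0,
    n_mediator = 0, frac_palindromic = 0, seed = 50))
  ds <- sim$exposure
  cand <- data.frame(variant_id = ds$variant_id, pval = ds$pval)
  keptv <- clump(cand, sim$ld, r2_threshold = 0.1, window_kb = 10000)
  # every retained pair is below the threshold (or out of window)
  for (i in seq_along(keptv)) {
    others <- keptv[-i]
    linked <- ld_r2(sim$ld, keptv[i], others) >= 0.1 &
      reservemr:::ld_in_window(sim$ld, keptv[i], others, 1e7)
    expect_false(any(linked))
  }
  # every removed variant is linked to a retained variant with a better p
  removed <- setdiff(cand$variant_id, keptv)
  pv <- function(id) cand$pval[match(id, cand$variant_id)]
  for (id in removed) {
    linked_better <- any(vapply(keptv, function(kk) {
      ld_r2(sim$ld, kk, id) >= 0.1 &&
        reservemr:::ld_in_window(sim$ld, kk, id, 1e7) &&
        (pv(kk) < pv(id) || (pv(kk) == pv(id) && kk < id))
    }, logical(1)))
    expect_true(linked_better, info = id)
  }
  # invariance to input ordering
  expect_identical(clump(cand[sample(nrow(cand)), ], sim$ld, 0.1, 10000), keptv)
})

test_that("proxy search returns the argmax r2 above threshold, matching brute force", {
  set.seed(60)
  ids <- sprintf("rs%02d", 1:12)
  cmb <- combn(ids, 2)
  pairs <- data.frame(variant_id_a = cmb[1, ], variant_id_b = cmb[2, ],
                      r2 = runif(ncol(cmb)))
  ld <- ld_reference(pairs, data.frame(variant_id = ids, chrom = "1",
                                       pos = seq_along(ids) * 1000))
  out_rec <- toy_records()[rep(1, 8), ]
  out_rec$variant_id <- ids[5:12]
  out_rec$pval <- runif(8)
  out_ds <- summary_dataset(out_rec, "Y", validate = FALSE)

  for (target in ids[1:4]) {
    got <- find_proxy(target, out_ds, ld, r2_min = 0.8)
    r2s <- ld_r2(ld, target, out_ds$variant_id)
    if (all(r2s <= 0.8)) {
      expect_null(got)
    } else {
      best <- max(r2s)
      expect_equal(got$r2, best)
      expect_true(got$variant_id %in% out_ds$variant_id[r2s == best])
    }
  }
  expect_null(find_proxy("rs01", out_ds, ld, r2_min = 1))
})

test_that("identically coded datasets harmonize to an identity; swapped codings are reversed", {
  sim <- simulate_triple(sim_config(J = 40, n_reverse = 0, n_mediator = 0,
                                    frac_palindromic = 0, seed = 70))
  ids <- sim$truth$table$variant_id
  h0 <- harmonize_pair(sim$exposure, sim$outcome, ids)
  expect_true(all(h0$action == "kept"))
  expect_equal(h0$beta_out, sim$outcome$beta)

  noisy <- inject_harmonization_noise(sim$outcome, frac_strand_flipped = 0.3,
                                      frac_allele_swapped = 0.3, seed = 71)
  h1 <- harmonize_pair(sim$exposure, noisy$dataset, ids)
  expect_true(all(h1$action %in% c("kept", "sign-flipped")))
  expect_equal(h1$beta_out[match(ids, h1$variant_id)], sim$outcome$beta)
  sw <- noisy$log$variant_id[noisy$log$perturbation == "allele_swap"]
  expect_true(all(h1$action[match(sw, h1$variant_id)] == "sign-flipped"))
})

test_that("ambiguous palindromic variants are dropped with the correct reason", {
  rec <- toy_records()
  rec$effect_allele <- c("A", "C", "A")
  rec$other_allele <- c("T", "G", "G")
  rec$eaf <- c(0.50, 0.30, 0.20)
  exp_ds <- summary_dataset(rec, "X", validate = FALSE)
  out <- rec
  out$beta <- rec$beta * 0.5
  out_ds <- summary_dataset(out, "Y", validate = FALSE)
  h <- harmonize_pair(exp_ds, out_ds, rec$variant_id)
  # rs1: palindromic with eaf 0.5 -> ambiguous; rs2: palindromic maf 0.3 kept
  expect_equal(h$action[h$source_id == "rs1"], "dropped")
  expect_equal(h$reason[h$source_id == "rs1"], "palindromic-ambiguous")
  expect_equal(h$action[h$source_id == "rs2"], "kept")
  expect_equal(h$action[h$source_id == "rs3"], "kept")

  # palindromic with missing outcome frequency is dropped (conservative)
  out$eaf[2] <- NA
  h2 <- harmonize_pair(exp_ds, summary_dataset(out, "Y", validate = FALSE),
                       rec$variant_id)
  expect_equal(h2$reason[h2$source_id == "rs2"], "palindromic-ambiguous")
})

test_that("incompatible allele pairs are dropped; all-dropped sets are an error", {
  rec <- toy_records()
  exp_ds <- summary_dataset(rec, "X", validate = FALSE)
  out <- rec
  out$other_allele <- c("C", "T", "C")  # rs1 and rs3 get foreign codings
  out_ds <- summary_dataset(out, "Y", validate = FALSE)
  h <- harmonize_pair(exp_ds, out_ds, rec$variant_id)
  expect_true(all(h$reason[h$action == "dropped"] == "incompatible-alleles"))
  out2 <- rec
  out2$effect_allele <- c("A", "C", "G")
  out2$other_allele <- c("T", "G", "C")  # palindromic codings at non-palindromic loci
  expect_error(
    harmonize_pair(exp_ds, summary_dataset(out2, "Y", validate = FALSE),
                   rec$variant_id),
    "no harmonizable")
})

test_that("harmonization is involution-safe", {
  sim <- simulate_triple(sim_config(J = 40, frac_palindromic = 0.2, seed = 73))
  ids <- sim$truth$table$variant_id
  noisy <- inject_harmonization_noise(sim$outcome, 0.3, 0.3, seed = 74)
  h1 <- harmonize_pair(sim$exposure, noisy$dataset, ids)
  k <- kept(h1)
  # rebuild datasets from the harmonized table (shared effect allele)
  exp2 <- summary_dataset(data.frame(
    variant_id = k$variant_id,
    effect_allele = sim$exposure$effect_allele[match(k$variant_id, sim$exposure$variant_id)],
    other_allele = sim$exposure$other_allele[match(k$variant_id, sim$exposure$variant_id)],
    eaf = k$eaf_exp, beta = k$beta_exp, se = k$se_exp, pval = k$pval_exp,
    n = k$n_exp, n_case = NA, n_control = NA), "X", validate = FALSE)
  out2 <- summary_dataset(data.frame(
    variant_id = k$variant_id,
    effect_allele = sim$exposure$effect_allele[match(k$variant_id, sim$exposure$variant_id)],
    other_allele = sim$exposure$other_allele[match(k$variant_id, sim$exposure$variant_id)],
    eaf = k$eaf_out, beta = k$beta_out, se = k$se_out, pval = k$pval_out,
    n = k$n_out, n_case = k$n_case_out, n_control = k$n_control_out),
    "Y", trait_type = "binary", validate = FALSE)
  h2 <- harmonize_pair(exp2, out2, k$variant_id)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_out, k$beta_out)
  expect_equal(h2$beta_exp, k$beta_exp)
})

test_that("missing outcome variants use proxies when available, else are dropped", {
  sim <- simulate_triple(sim_config(
    J = 20, ld_blocks = list(c(2, 0.9), c(2, 0.5)), n_reverse = 0,
    n_mediator = 0, frac_palindromic = 0, seed = 75))
  t <- sim$truth$table
  heads <- t$variant_id[c(1, 2)]
  tags <- t$variant_id[t$class == "tag"]
  out_sub <- sim$outcome[!(sim$outcome$variant_id %in% heads), ]
  out_ds <- summary_dataset(as.data.frame(out_sub), "Y", "binary",
                            validate = FALSE)
  h <- harmonize_pair(sim$exposure, out_ds, t$variant_id[1:20], ld = sim$ld)
  # head 1 has a tag at r2 0.9 > 0.8 -> proxied; head 2's tag is at 0.5 -> dropped
  r1 <- h[h$source_id == heads[1], ]
  expect_equal(r1$action, "proxied")
  expect_true(r1$variant_id %in% tags)
  expect_equal(r1$proxy_r2, 0.9)
  r2 <- h[h$source_id == heads[2], ]
  expect_equal(r2$action, "dropped")
  expect_equal(r2$reason, "missing-in-outcome-no-proxy")
  # kept count bookkeeping: instruments minus missing-without-proxy
  expect_equal(nrow(kept(h)), 20 - 1)
})

test_that("joint clumping for multivariable MR unions instruments on the minimum p", {
  # mediator with no significant variants: instrument set = univariable set
  sim <- simulate_triple(sim_config(J = 60, n_mediator = 0, n_reverse = 0,
                                    a = 0, b = 0, frac_palindromic = 0,
                                    seed = 80))
  null_med <- sim$mediator
  hm <- harmonize_multi(sim$exposure, null_med, sim$outcome, ld = sim$ld)
  expect_setequal(hm$source_id, select_instruments(sim$exposure))

  # two linked variants significant for different traits: smaller min-p wins
  rec <- toy_records()[1:2, ]
  rec$pval <- c(1e-12, 0.5)
  exp_ds <- summary_dataset(rec, "X", validate = FALSE)
  med <- rec; med$pval <- c(0.4, 1e-9)
  med_ds <- summary_dataset(med, "M", validate = FALSE)
  outc <- rec; outc$pval <- c(0.2, 0.3)
  out_ds <- summary_dataset(outc, "Y", validate = FALSE)
  ld <- ld_reference(
    data.frame(variant_id_a = "rs1", variant_id_b = "rs2", r2 = 0.9),
    data.frame(variant_id = c("rs1", "rs2"), chrom = "1", pos = c(1, 100)))
  hm2 <- harmonize_multi(exp_ds, med_ds, out_ds, ld = ld)
  expect_equal(hm2$source_id, "rs1")  # min-p 1e-12 beats 1e-9
})

test_that("multivariable harmonization aligns all three traits to one effect allele", {
  cfg <- sim_config(J = 50, n_mediator = 25, a = 0.3, b = -0.2,
                    c_prime = -0.25, n_m = 2e5, frac_palindromic = 0.1,
                    seed = 81)
  sim <- simulate_triple(cfg)
  med_noisy <- inject_harmonization_noise(sim$mediator, 0.2, 0.2, seed = 82)
  hm <- harmonize_multi(sim$exposure, med_noisy$dataset, sim$outcome,
                        ld = sim$ld)
  k <- kept(hm)
  t <- sim$truth$table
  i <- match(k$variant_id, t$variant_id)
  # harmonized mediator effects agree with the clean truth-scale dataset
  expect_equal(k$beta_med, sim$mediator$beta[match(k$variant_id,
                                                   sim$mediator$variant_id)])
  # and all three observed betas sit within 6 se of their true values
  expect_true(all(abs(k$beta_exp - t$gamma[i]) < 6 * k$se_exp))
  expect_true(all(abs(k$beta_med - t$beta_m[i]) < 6 * k$se_med))
  expect_true(all(abs(k$beta_out - t$beta_y[i]) < 6 * k$se_out))
})
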