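#!/usr/bin/env Rscript
# Generate the synthetic study inputs: exposure (years of schooling), binary
# outcome (late-onset Alzheimer's disease), a panel of 15 correlated brain
# imaging-derived mediator phenotypes, an LD reference and the phenotypic
# correlation matrix. Everything is written as plain TSV under results/data/.
suppressPackageStartupMessages(library(reservemr))

seed <- 20260925 %% 100000
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_triple(cfg)

R <- simulate_idp_correlation()
# exposure effects on the mediators: positive on cortical macro-structure,
# small negative on intracellular volume fraction and white matter
# hyperintensities, null elsewhere (the package's reference scenario)
a <- setNames(rep(0, 15), rownames(R))
a[c("SA", "CortVol", "IC", "LGI")] <- c(0.30, 0.29, 0.18, 0.21)
a[c("ICVF", "WMH")] <- c(-0.09, -0.14)
mediators <- simulate_mediator_panel(sim, a, R = R, n_m = cfg$n_m,
                                     seed = seed + 1)

write_sumstats(sim$exposure, "results/data/exposure.tsv")
write_sumstats(sim$outcome, "results/data/outcome.tsv")
for (nm in names(mediators)) {
  write_sumstats(mediators[[nm]], file.path("results/data",
                                            paste0("mediator_", nm, ".tsv")))
}
write_ld(sim$ld, "results/data/ld_pairs.tsv", "results/data/ld_positions.tsv")
write_corr_matrix(R, "results/data/idp_correlation.tsv")
utils::write.table(sim$truth$table, "results/data/truth_variants.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(a = sim$truth$a, b = sim$truth$b,
                          c_prime = sim$truth$c_prime,
                          total_effect = sim$truth$total_effect,
                          mediator_a = as.list(a), seed = seed),
                     "results/data/truth_params.json", auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("Simulated %d variants; true total effect on the outcome: OR %.2f per SD.\n",
            nrow(sim$truth$table), exp(sim$truth$total_effect)))
cat("Wrote exposure, outcome, 15 mediator GWAS, LD reference and correlation matrix to results/data/.\n")
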