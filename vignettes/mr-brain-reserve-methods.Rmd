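---
title: "Methods: two-sample MR with mediation for brain-reserve studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mediation for brain-reserve studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reservemr)
```

# The causal model

The package targets a three-node causal design: a continuous exposure X
(years of schooling, in SD units), a set of continuous mediator phenotypes
M₁…M_K (brain imaging-derived measures, SD units) and a binary outcome Y
(late-onset Alzheimer's disease, analysed on the log odds-ratio scale).
Three parameters describe each exposure–mediator–outcome triple:

- `a` — the effect of X on M (SD per SD),
- `b` — the effect of M on Y (log OR per SD),
- `c'` — the direct effect of X on Y not through M (log OR per SD),

so the total effect of X on Y is `c = c' + a·b`. Univariable MR estimates
`c`; multivariable MR adjusted for M estimates `c'`; their difference is the
indirect (mediated) effect, mirroring the difference-in-coefficients method
of classical mediation analysis.

All estimation is two-sample: variant–exposure and variant–outcome
associations come from separate GWAS, so estimation noise is independent
across the two sides, and the instruments are genetic variants selected for
genome-wide-significant association with the exposure.

# Estimators

## IVW with multiplicative random effects

With harmonized per-variant effects (γ̂_j, Γ̂_j) and outcome standard errors
σ_j, the IVW estimate is the weighted regression of Γ̂ on γ̂ through the
origin with weights 1/σ_j². Heterogeneity is summarised by Cochran's
Q = Σ_j (Γ̂_j − θ̂γ̂_j)²/σ_j²; the multiplicative random-effects standard
error is the fixed-effect one inflated by max(1, √(Q/(J−1))). The
dispersion is floored at one — the reported standard error is never smaller
than the fixed-effect standard error; under-dispersion is not rewarded.
This is the conventional choice for summary-data MR; the un-floored
behaviour is available via `ivw(h, random_effects = FALSE)`, whose
fixed-effect standard error and p-value are also always reported in
`extras` (they are the quantities the analytic power model describes; see
below). All Wald tests use the normal reference, the usual convention at
moderate-to-large instrument counts.

## Robust battery

*MR-Egger* re-orients every variant so γ̂_j > 0 and adds an intercept: the
slope is the causal estimate and the intercept estimates the average
directional pleiotropic effect under the InSIDE assumption. Standard errors
are inflated by max(1, √(Q_e/(J−2))). Orientation by the observed sign of
γ̂_j is only reliable for instruments whose sign is essentially certain; the
package applies Egger to genome-wide-significant instruments, for which
|γ̂_j/se| > 5.45 guarantees that.

*Weighted median* uses ratio-estimate precisions as weights and returns the
interpolated 0.5-crossing of the weighted empirical distribution; it is
consistent while valid instruments hold a weight majority. Its standard
error comes from a parametric bootstrap (default 5000 draws, seeded)
resampling (γ̂_j, Γ̂_j) from their sampling distributions.

*Contamination mixture* profiles, over a grid of candidate effects
(default 10 001 points spanning the ratio estimates ±3 max standard
errors), a likelihood in which each variant is the better of "valid"
(normal about θ) and "contaminated" (normal about 0 with variance inflated
by ψ²; ψ defaults to 1.5 × SD of the ratio estimates). The 95% confidence
set is the likelihood-ratio region and may be a union of intervals; the
headline interval is the member containing the maximiser.

*MR-PRESSO* measures the observed residual sum of squares about
leave-one-out IVW slopes, simulates its null distribution from the
estimated model (default 5000 replicates, seeded), and reports a global
p-value, Bonferroni-adjusted per-variant outlier p-values, the
outlier-corrected IVW estimate and a distortion test based on removing
random subsets of the outlier-set size (default 1000 resamples).

*Steiger directionality* computes per-variant variance explained as
r² = z²/(z² + n_eff), with n_eff = n for continuous traits and
4/(1/n_case + 1/n_control) for binary traits, flags variants explaining
more variance in the outcome than the exposure, and re-runs IVW on the
filtered set. A liability-scale r² for binary traits is deliberately not
implemented; the effective-sample-size approximation is the standard
summary-data route.

Zero-γ̂ instruments are excluded (with a warning) from ratio-based methods
(ratio table, weighted median, contamination mixture) but retained in the
IVW and Egger regressions, where they contribute through the origin /
intercept; the residual form of Q avoids dividing by γ̂.

## Multivariable MR and mediation

`mvmr_ivw()` regresses Γ̂ on the exposure and mediator effect columns with
weights 1/σ_j², no intercept, over the jointly clumped union of instruments
significant for either trait (clumping key: the minimum p across the two
traits, exactly as the univariable pipeline clumps on the exposure p). An
all-zero effect column is dropped with a warning so the degenerate fit
reduces to univariable IVW; collinear non-zero columns are an error.
`mediation_decompose()` differences total and direct effects on the log-OR
scale; the indirect-effect standard error uses the independence
approximation √(se_c² + se_c′²) — conservative, because the two estimates
share instruments — and the proportion mediated carries a delta-method
standard error and is reported as missing when |c| is below tolerance. For
binary outcomes the decomposition is approximate (the odds ratio is
non-collapsible), so the adjusted-vs-unadjusted table is the primary
output, with proportions mediated as a labelled extension.

# Harmonization rules

Instruments are selected at strict p < 5×10⁻⁸ and clumped greedily
(accept lowest p, remove linked candidates at r² ≥ 0.001 within 10 000 kb;
ties broken lexicographically so the output is order-invariant). A variant
missing from the outcome set may be replaced by the best proxy with
r² > 0.8 that is present in both datasets; the proxy's own effects are used
as-is (no r²-attenuation correction) and harmonized as usual.

Allele matching proceeds by direct comparison, then strand
complementation; an effect/other swap negates the outcome beta and
complements its frequency. Palindromic variants (A/T, C/G) cannot be
resolved by labels: they are oriented by allele-frequency agreement and
dropped as `palindromic-ambiguous` when min(eaf, 1−eaf) > 0.42 in either
dataset. When a needed frequency is missing the variant is dropped — the
conservative choice, since frequency is the only orientation evidence for a
palindrome. Every instrument carries an action (`kept`, `sign-flipped`,
`proxied`, `dropped`) and a single drop reason, making the audit trail the
test surface for all rules.

# Multiplicity and power

The corrected threshold for the mediator family squares the phenotypic
correlation matrix element-wise, eigendecomposes it, counts the components
n needed to reach 99.5% of the trace (comparison is ≥ at the target), sets
T = n(n−1)/2 and uses α/√T. For the package's 15-phenotype reference
matrix this gives n = 13, T = 78, √T = 8.83 and a threshold of 0.006 at
3 dp; thresholds are reported rounded to 3 decimals with full precision
retained internally. The degenerate all-correlated case (n = 1, T = 0)
falls back to α with a warning. The primary exposure–outcome pair is tested
at α = 0.05, matching the design's per-objective error control.

Analytic power uses the noncentrality λ = |β|·√(n·R²·v), v = K(1−K) for a
binary outcome, with the two-sided form Φ(λ−z) + Φ(−λ−z) so that power
equals α exactly at β = 0. The Monte-Carlo oracle in the test suite
simulates the generative model and applies the fixed-effect IVW z-test —
the test the analytic formula models; the floored random-effects test is
deliberately not used there because its dispersion floor makes the null
conservative. The minimum detectable effect inverts power by bisection to
1e-6.

# The synthetic-data generator

`simulate_triple()` emulates the statistical structure of the study's data
sources rather than its genomes. Per candidate variant: frequency
p_j ~ U(0.05, 0.5); true exposure effect γ_j ~ N(0, σ_γ²) on the
standardized-trait, per-allele scale, so standard errors close over
frequency and sample size: se = 1/√(2p(1−p)·n) for continuous traits and
1/√(2p(1−p)·n·K(1−K)) for the binary outcome. Observed estimates are truth
plus independent normal noise on each side (the two-sample regime; sample
overlap is out of scope) and p-values are two-sided normal.

Default conditions are the package's reference scenario: J = 332 candidate
instruments, n_x = 1 131 881, n_m = 33 211, n_y = 63 926 with K = 0.344,
total effect log(0.70) carried by the direct path (b = 0), and
σ_γ = 0.011, chosen so the selected instruments explain ≈1.3% of exposure
variance — which makes the IVW standard error (≈0.07 on the log-OR scale)
and hence the confidence-interval width match what a study of this size
reports. Twenty-four outcome-primary variants (true exposure effect exactly
zero, outcome effects planted at |z| ~ U(6, 12)) emulate the
disease-primary loci that Steiger filtering exists to catch; because their
exposure associations are null they are rarely selected as instruments in a
faithful pipeline run, so Steiger stress tests pass them explicitly. Ten
percent of variants get palindromic allele codings with frequency drawn
U(0.30, 0.50), straddling the 0.42 rule.

Three design decisions deserve emphasis:

- **Directional pleiotropy is planted in the exposure-increasing
  orientation**: α_j = sign(γ_j)·(μ_α + σ_α·ε_j). With arbitrary allele
  labelling a constant α would average to zero against symmetric γ and
  could neither bias IVW nor be recovered as an Egger intercept; the
  sign-linked form is how directional pleiotropy is defined in the MR
  literature. `inside_violation` correlates the magnitude ε_j with
  standardized |γ_j|, allowing InSIDE-violating architectures (negative
  values concentrate pleiotropy in weak instruments).
- **Palindromic codings are assigned at generation**, identically across
  the three datasets, because the ambiguity the 0.42 rule addresses only
  arises when both datasets carry the same complementary allele pair.
  `inject_harmonization_noise()` perturbs one dataset with strand flips
  (labels complemented; effect unchanged), allele swaps (labels exchanged,
  beta negated, frequency complemented) and, optionally, palindromic
  recodes, logging every perturbation in a sidecar table so tests can
  verify exact reversal.
- **LD blocks append tag variants** (marginal effects scaled by r = √r²,
  one causal variant per block) rather than reclassifying candidates, so
  the truth bookkeeping — invalid count = round(prop_invalid·J) — stays
  exact. Block heads and singletons are spaced 20 Mb apart, beyond the
  clumping window; tags sit within kilobases of their head.

`simulate_mediator_panel()` extends a triple to K mediators over the same
variants, with exposure effects a_k, shared mediator-specific instruments,
and estimation noise correlated across mediators according to the
phenotypic correlation matrix — emulating phenotypes measured in a single
imaging cohort. Panel mediators carry no effect onto the simulated outcome,
so the panel represents the null-mediator study arm.

What passing tests on this generator do **not** show about real data: the
generator has no genome-realistic LD, no population stratification, no
winner's curse beyond what downstream selection on noisy estimates induces
naturally, no sample overlap, and exact log-linear effects for the binary
outcome (so mediation decomposition is exact in simulation where it is only
approximate in reality).

# Numerical choices and problem sizes

Grid, replicate and bootstrap defaults (contamination-mixture grid 10 001;
weighted-median bootstrap 5000; MR-PRESSO 5000 simulations, 1000 distortion
resamples) are conventional, overridable, and always seeded; identical
configuration and seed reproduce results bit for bit, and the study
bundle's manifest records the configuration hash and seeds needed to re-run
a study identically. Ties in instrument selection and clumping break
lexicographically on variant id. Degenerate inputs have defined behaviour:
single-variant IVW reduces to the ratio estimate; identical ratio estimates
give Q = 0 and the fixed-effect standard error; the contamination mixture
collapses to a point with ratio-based uncertainty when all ratio estimates
coincide; estimators below their minimum variant counts return
method-not-applicable results rather than errors, and a pair that fails
entirely is recorded in the study bundle while the rest of the study
continues.

The test suite validates the pipeline at desk scale: parameter recovery
uses 200 replicates of a 100-instrument scenario; the robustness scenario
plants 40% invalid instruments (μ_α = σ_α = 0.02, pleiotropy concentrated
in weak instruments via inside_violation = −0.9) over 40 replicates; Egger
recovery uses 50 replicates of a fully pleiotropic (constant 0.03)
scenario; MR-PRESSO outlier detection uses 100 seeds with a planted
10-standard-error outlier; family-wise error calibration draws 100
repetitions of 15 correlated null mediators; the power oracle uses 2000
Monte-Carlo replicates per grid cell as antithetic pairs, which keeps the
Monte-Carlo error well inside the comparison tolerance at that replicate
count. These sizes were chosen so each check has clear resolution for the
property it measures.

# Known limitations

Only one mediator is adjusted for at a time (the multi-mediator joint model
is out of scope, as is MVMR-Egger); proxies substitute the variant
wholesale rather than imputing the target's association; binary-trait
Steiger r² uses the effective-sample-size approximation; the mediation
decomposition on the odds-ratio scale is approximate under
non-collapsibility; and the generator's LD and pleiotropy architectures are
illustrative, not calibrated to any particular GWAS.
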