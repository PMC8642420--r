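---
title: "Drug-target Mendelian randomization with targetmr: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with targetmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The question and the model

Drug-target MR asks whether lifelong, genetically conferred modulation of a
drug's protein target changes disease risk. Instruments are variants inside
(or immediately around) the target's gene; because the protein itself is
rarely measured at scale, the instruments are scaled on the biomarker the
drug moves — here, SD units of LDL cholesterol for an HMG-CoA reductase
(statin) mimic. The causal parameter θ is the log odds ratio of disease per
SD unit of the biomarker; for an inhibitor the reporting convention negates
it to "per SD decrease", the direction of treatment.

Under the instrumental-variable assumptions (relevance, independence from
confounders, no pathway to the outcome except through the target), each
SNP's Wald ratio θ̂ⱼ = β̂ᵧⱼ/β̂ₓⱼ estimates θ. The package's estimators are:

* **Wald ratio** — single instrument. SE is first-order delta method,
  se(β̂ᵧ)/|β̂ₓ|, i.e. outcome noise only. This matches the no-measurement-
  error (NOME) convention under which the IVW weights are defined, and it
  is what a single-SNP IVW must reduce to exactly. The second-order term
  (adding β̂ᵧ²se(β̂ₓ)²/β̂ₓ⁴) is available via `second_order_se = TRUE` but
  off by default: with cis instruments of F ≈ 200–700 it changes the SE in
  the third decimal.
* **IVW, independent instruments** — weighted mean of ratios with weights
  wⱼ = (β̂ₓⱼ/se(β̂ᵧⱼ))², algebraically identical to weighted least squares
  of β̂ᵧ on β̂ₓ through the origin (a property the tests verify against
  `lm()` at 1e-10). Fixed effects with ≤ 3 SNPs; with ≥ 4 SNPs a
  multiplicative random-effects model scales the SE by max(1, √(Q/(n−2))).
  Two remarks on that rule. First, the SNP-count cutoff is a convention of
  the analysis being reproduced, not a statistical optimum; it is
  configurable (`random_effects_min_snps`). Second, the dispersion is
  floored at 1 — random effects never report a smaller SE than fixed
  effects — and the divisor n−2 is retained as specified for this
  pipeline even though regression-through-origin residuals have n−1
  degrees of freedom; with the homogeneous, strong-instrument data this
  package targets, Q/(n−2) ≤ 1 almost always, so the floor makes the two
  conventions coincide.
* **Correlated-instrument IVW** — with SNPs in LD the outcome betas are
  correlated, Ω = S ρ S (S = diag(se(β̂ᵧ)), ρ = signed LD correlation on
  the harmonized allele coding). The GLS solution
  (xᵀΩ⁻¹x)⁻¹xᵀΩ⁻¹y is computed by Cholesky whitening, never an explicit
  inverse; an exactly singular Ω (duplicate SNPs, |r| = 1) is an error
  with a pointer to the `ridge` option rather than a silently unstable
  answer. The sign convention matters: when harmonization flips SNP j's
  effect allele, row/column j of ρ must be negated — `align_ld()` does
  this, and skipping it would corrupt the sensitivity analysis while
  leaving the independent-SNP path untouched.

Cochran's Q (weights wⱼ, df = n−1) quantifies ratio heterogeneity both
within an instrument set and between strata in meta-analysis. Normal
(not t) reference distributions are used for all CIs and p-values,
matching the 95% CI convention of summary-level MR reporting.

## Harmonization and instrument selection

Exposure and outcome GWAS rarely share an effect-allele convention.
`harmonize()` resolves each shared SNP by direct match, allele swap
(negate β, complement the frequency), or strand complement, in that order.
Palindromic SNPs (A/T, C/G) are genuinely ambiguous: swap and strand flip
are indistinguishable. The default policy drops them when the minor allele
frequency is ≥ 0.42 on either side or missing, and otherwise aligns by
frequency — the conservative two-sample standard. The threshold is a
`palindromic_maf` argument because cohort pairs differ in how informative
frequency is; the underlying studies here did not state their
reconciliation rule, so this is a documented package choice, not an
inherited one.

`ld_prune()` implements greedy clumping: rank by ascending exposure
p-value, break ties by larger |β| then rsID (making the ranking total and
the output order-invariant), accept a SNP iff r² with everything already
accepted is below the threshold (default 0.01). In a cis region where all
pairs are correlated this reduces to "keep the lead SNP", which is exactly
the main-analysis design being emulated. Instrument strength is
F = mean((β̂ₓ/se)²); the confounder screen flags instruments associated
with socioeconomic position, smoking or alcohol at 5e-8 but deliberately
does not drop them — in the reproduced design the check is reported as a
diagnostic of the independence assumption, and silently changing the
instrument set on its basis would change the estimand.

## Scale conversions

Biobank GWAS of binary traits run as linear regressions report
coefficients in probability units. For modest effects,
β_logOR ≈ β_linear/(k(1−k)) with k the case fraction; SE divides by the
same factor, so z and p are unchanged (an exact identity, tested to
1e-12). The approximation's error grows with the true effect and with
extreme k; the acceptance suite measures it against a direct logistic fit
on simulated individual-level data (n = 20,000; k ∈ {0.05, 0.2, 0.5}) and
finds ≈ 2–3% of the effect size, well inside sampling noise. No attempt is
made to undo case ascertainment or mixed-model calibration in the source
GWAS; records are taken at face value. Population SDs of the biomarker in
physical units (≈ 0.87 mmol/L LDL-C in Europeans, 1.06 in East Asians) are
display metadata only — estimation never leaves SD units.

## Meta-analysis, differences, multiplicity

Strata (ancestries) are pooled by fixed-effects inverse-variance weighting
unless the between-stratum Q has p < 0.05 (configurable), in which case
DerSimonian–Laird random effects is used — closed form, no iteration,
τ² = max(0, (Q−df)/(Σw−Σw²/Σw)). Sex and ethnic differences are two-sample
z-tests assuming independent strata; that is the minimal test consistent
with reporting "a p-value for difference", and it is exact for
non-overlapping samples. Multiplicity is controlled per phenotype family:
default α = 0.05/10 = 0.005, with results annotated significant / nominal
/ null rather than filtered.

## Power

R² for a SNP is 2β²·MAF·(1−MAF); the classic heuristic n_MR = n_epi/R²
converts an epidemiological sample-size requirement. The detectable OR at
power 1−β uses the normal approximation for a binary outcome: the
z-statistic of the causal estimate has mean b·√(n·R²·k(1−k)), giving
b = (z_{1−α/2}+z_{power})/√(n·R²·k(1−k)). The acceptance suite closes the
loop: planting exp(b) as the truth and re-running the estimator 5000
times yields empirical power 0.75–0.85. The exact formula behind any
particular published list of detectable ORs also depends on each outcome
GWAS's n and case fraction, which are inputs here, not constants.

## The synthetic world

`simulate_two_sample()` works at the summary level: β̂ₓ ~ MVN(βₓ, DₓρDₓ)
and β̂ᵧ ~ MVN(θβₓ + α, DᵧρDᵧ), with analytic GWAS sampling SEs
1/√(2·maf·(1−maf)·n) for an SD-scaled trait and an extra k(1−k) factor for
a binary outcome, and α an optional balanced-pleiotropy draw. This is
exact for everything the estimators assume, fast enough for
thousands-of-replicate calibration tests, and reproducible byte-for-byte
from the scenario seed. The default `hmgcr_like_scenario()` states the
world being emulated: six cis SNPs with a dominant lead (per-allele
effects 0.062 down to 0.020 SD, realistic cis-region frequencies), AR(1)
LD with adjacent correlation 0.7 (every pair above the 0.01 pruning
threshold, so the main analysis is single-SNP), an exposure GWAS of
361,194, and an outcome GWAS of 192,000 with k = 0.04. The outcome-side
numbers are a documented reconstruction: the registry-based replication
cohort's per-outcome case counts are not in the main text, so n and k were
chosen once to reproduce the sampling SE implied by the published asthma
CI (≈ 0.27 on the log-OR scale) and not revisited.

What the simulator does **not** emulate — and therefore what a green test
does not establish: genotype-level sampling (Hardy–Weinberg departures,
imputation error), ascertained case-control sampling and mixed-model
calibration, sample overlap between exposure and outcome GWAS, directional
pleiotropy (the knob is balanced), and selection effects (survival,
participation). Individual-level simulation appears in exactly one place,
the logistic-vs-linear oracle, because that question is about the scale
approximation itself, not the estimators.

## Numerical choices and degenerate inputs

* LD matrices: asymmetry ≤ 1e-8 is averaged away; a smallest eigenvalue in
  (−1e-8, 0) — file-rounding territory — is clipped to zero and the
  diagonal renormalized; anything more negative is refused as data
  corruption rather than repaired.
* GLS solves use Cholesky with a relative diagonal tolerance of 1e-10;
  the optional ridge term inflates ρ's diagonal and renormalizes, trading
  a small bias for invertibility when instruments are nearly duplicate.
* Ties in pruning are broken deterministically (p, then |β|, then rsID);
  equal-p instruments therefore never make the selection depend on row
  order.
* A null instrument (β̂ₓ = 0) is an error, not an infinite ratio; an
  all-dropped harmonization is an error naming the cell, and the pipeline
  records per-cell failures and continues, because real analysis grids
  have missing cells.

## Interpreting the planted-signal acceptance run

The end-to-end check plants one non-null outcome (OR 2.05) among ten and
asks that the median run flag exactly it at α = 0.05. At the stated
stratum sizes the per-run power is ≈ 0.75 and the chance of zero false
positives among nine nulls is ≈ 0.63, so a literal single-run "exact set"
indicator would fail almost half the time even for a perfectly calibrated
pipeline. The test therefore evaluates the median **per outcome across 11
seeded runs**: the planted outcome's median p must fall below 0.05 (its
median sits near 0.008) and every null outcome's median p above it — the
faithful reading of "the median run reports exactly that outcome", made
robust to binomial noise without changing any generator parameter or
threshold.

## Known limitations

The estimators inherit the usual two-sample MR caveats: weak-instrument
bias is only diagnosed (F), not corrected; balanced pleiotropy widens
intervals but directional pleiotropy biases the point estimate and is out
of scope (no MR-Egger or median estimators, by design); the difference
tests assume non-overlapping strata; and the linear→log-OR conversion is a
small-effect approximation. The correlated-instrument Q statistic uses
independence weights and is reported as a descriptive diagnostic there,
not a calibrated test.
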