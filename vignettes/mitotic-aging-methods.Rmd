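---
title: "Methods: mitotic-age scoring, deconvolution and the composition-adjusted models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitotic-age scoring, deconvolution and the composition-adjusted models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotick)
```

## The scientific problem

Hematopoietic stem and progenitor cells accumulate DNA methylation at a
specific class of CpGs — promoter CpGs of polycomb-group target genes that
are unmethylated in fetal tissue — roughly in proportion to the number of
cell divisions behind a tissue. The mean methylation over such a clock set
(here called `pcgt_age`, the mitotic age) therefore reads out the
proliferative history of blood. Two complications make whole-blood analyses
of this signal treacherous:

1. **Lineage structure.** Differentiated myeloid cells (granulocytes,
   neutrophils, eosinophils, monocytes) carry globally lower methylation
   than lymphoid cells, and their attributed mitotic age is lower as well.
2. **Composition confounding.** Whole blood is a mixture dominated by
   granulocytes (~60% of leukocytes). A sample with more granulocytes
   reads out a lower mixture mitotic age regardless of any true change in
   the stem-cell tick rate. If a disease also shifts composition toward
   granulocytes — as inflammation-linked conditions do — the unadjusted
   association between mitotic-age acceleration and disease is biased
   toward or past the null.

The package implements the full analysis chain that addresses this:
clock scoring, age-residualized acceleration, reference-based leukocyte
deconvolution, composition-adjusted association models, stepwise covariate
selection, and repeated-measures progression models — plus a synthetic
generator that reproduces exactly the structure above, with known ground
truth, so every step can be benchmarked.

## Mitotic age and acceleration

For a beta matrix $B$ (CpG $\times$ sample, values in $[0,1]$) and a clock
CpG set $C$,

$$\mathrm{pcgtAge}_j = \frac{1}{|C_j|}\sum_{i \in C_j} \beta_{ij},$$

with $C_j$ the non-missing clock CpGs of sample $j$ (available-case mean;
a sample must cover at least `min_coverage` = 80% of the clock). The
acceleration `AccelEpiTOC` is the raw residual of an ordinary
least-squares regression of `pcgt_age` on chronologic age, fitted on the
full analysis sample (cases and controls jointly; a control-only fit is
available by subsetting before `age_acceleration()`). For reporting, the
residual is standardized to unit sample SD (denominator $n-1$).

The same residual-on-age construction yields the companion measures:
`age_acceleration()` of a weighted (Horvath/Hannum-style) clock age gives
AgeAccel; `intrinsic_acceleration()` residualizes on age *plus* cell
composition (IEAA, composition-independent by construction); and
`extrinsic_acceleration()` residualizes an immune-weighted clock age
(EEAA). The immune weighting in `immune_weighted_age()` is a configurable
surrogate — the published immune weights belong to external estimators and
are not reproduced here; whatever weights are used are recorded in the
output's attributes.

The packaged clock file `inst/extdata/epitoc_cpgs_synthetic.tsv` is a
**synthetic stand-in**: it lists the simulator's clock CpG identifiers, not
the published 385-probe list (which ships with the original clock's
supplement and can be supplied via `read_clock_definition()` for real-data
runs).

## Reference-based deconvolution

`build_reference()` ranks CpGs per cell type by the two-sample t-statistic
(type vs all others) on purified methylomes and keeps the top
`n_per_type` hyper- and hypomethylated markers per type (default 50 each;
a standard scale for blood deconvolution). `estimate_proportions()` then
solves, per mixed sample $b$,

$$\min_{w \ge 0,\ \mathbf{1}^\top w = 1}\ \lVert b - R w\rVert_2^2,$$

the constrained projection onto the purified reference $R$. The equality
constraint is imposed through an augmented equation with penalty weight
$10^4$ inside a non-negative least-squares solve; at that weight the sum
deviates from one by $\lesssim 10^{-8}$, and the solution matches an
exact active-set solver and a $10^{-3}$-step simplex grid search to the
tolerances asserted in the test suite. A `sum-le-one` mode adds a slack
component instead (useful when the reference does not span the mixture).
`estimate_extended_counts()` provides linear-predictor surrogates for
count-style estimates (naive/exhausted T cells, plasmablasts); the
coefficients are user-supplied and flagged as surrogates.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions; all generators are
deterministic given the seed.

* **Cell profiles** (`simulate_cell_profiles`): a shared bimodal
  background methylome; per-type marker blocks (2 × 30 CpGs each) so all
  eight types are identifiable; clock CpGs starting near-unmethylated
  (baseline $\le 0.05$); and a 0.02 global methylation deficit applied to
  myeloid background CpGs.
* **Purified panel** (`simulate_purified_panel`): six adult male donors
  (ages $\mathcal{N}(38, 13.6^2)$, truncated 22–60), one sample per
  donor × type. Clock CpGs gain `tick_increment_delta` = $10^{-4}$ per
  division with division counts `rate × age × donor frailty`
  (frailty log-normal, log-SD 0.15). The per-type rates (myeloid 12–14,
  lymphoid 29–33 divisions/year) were set analytically so that at the
  panel's mean age the within-donor lymphoid-minus-myeloid mitotic-age gap
  is ≈ 0.07 (band 0.06–0.08) and the CD8-vs-granulocyte difference ≈ 0.08.
  Ticking is deterministic in expectation; noise enters only at
  measurement, as logit-normal error (SD 0.10) with betas clipped to
  $[0.001, 0.999]$ so means near the boundaries are not distorted.
* **Whole-blood cohort** (`simulate_whole_blood_cohort`): 600 cases / 600
  controls (case status by design, matching case-control sampling), ages
  uniform 50–80. Proportions are Dirichlet (concentration 60) around a
  granulocyte-dominant mean (0.55 granulocytes; granulocytic types
  together ≈ 0.60); case means shift a further +0.10 toward granulocytes,
  taken proportionally from the lymphoid types. Cases' division counts are
  multiplied by `disease_tick_multiplier` = 1.10. Technical structure:
  eight batches contribute a sample-level logit offset (SD 0.05 between
  batches, 0.02 within) shared between the beta matrix and 848 simulated
  control probes, so the control-probe principal components genuinely
  index the cohort's technical variation.
* **Longitudinal scores** (`simulate_longitudinal_scores`): three visits
  two years apart for each case; each exam score follows a linear mixed
  model whose subject slope is `base + slope_per_sd × accel` plus a random
  slope, with MMSE-like scores declining (−0.06 per SD per year) and
  UPDRS-like scores rising (+0.19 and +0.05).

**Calibration.** The two disease knobs are not hand-picked numbers: they
were tuned once by the Monte-Carlo calibration script
`scripts/calibrate_generator.R` (cohorts of 6,000–12,000 run through the
full pipeline) so that the composition-adjusted log odds ratio per SD of
acceleration equals the design target 0.75 (OR ≈ 2.1) while the
unadjusted OR is attenuated just below 1 (≈ 0.91–0.94) — i.e. the
composition shift is strong enough to fully mask the tick-rate effect.
The frozen values (multiplier 1.10, shift 0.10) are the generator's
defaults and are recorded in every truth bundle.

**What the generator does not emulate.** Probe-level 450k annotation and
probe-type chemistry, genetic ancestry structure, smoking biology (both are
simulated as inert covariates), cancer tissue, and any model of progenitor
pool sizes — the division-count parameterization (rate × age × frailty) is
a modeling choice; no quantitative tick-rate model for hematopoiesis is
established, and the clock model itself ignores progenitor population
sizes. Passing recovery tests therefore shows the *analysis* is correct
under the assumed structure, not that real blood satisfies that structure.

## Statistical layer

* **Cell-type models** (`fit_lmm_celltype`): linear mixed model with a
  random donor intercept (REML), cell type or a binary myeloid-vs-lymphoid
  lineage term as predictor (reference type CD8 T). P-values are Wald
  (normal approximation) — a documented simplification; no
  degrees-of-freedom correction is applied. A singular random-effect fit
  falls back to fixed effects with a warning.
* **Association models** (`fit_logistic`): ML logit fits; per-SD flagged
  predictors standardized on the complete-case analysis sample;
  Wald CIs; perfect separation detected via boundary fitted probabilities
  and flagged rather than silently diverging. Because estimated
  proportions sum to one, the default adjusted model drops one composition
  term (CD4 T) to keep the design full rank.
* **Stepwise AIC** (`stepwise_aic`): greedy bidirectional search from a
  locked model (exposure + design covariates always retained), ML fits on
  the complete-case intersection so AICs are comparable, ties broken by
  term name for order-invariance, stopping when no move improves AIC by
  more than $10^{-6}$. On the default generator the search retains the
  myeloid fraction terms: unlike the real data — where granulocytes and
  CD8 T sufficed — the simulated granulocytic mass is split across three
  correlated types (granulocytes, neutrophils, eosinophils), so several
  terms carry independent confounding information.
* **Progression models** (`fit_lmm_progression`): random intercept +
  random slope on time per subject (REML); the acceleration × time
  interaction is the yearly change per SD. Singular random-slope fits drop
  to random intercepts, then to OLS, with warnings.
* **Correlation panels** (`pearson_corr_matrix`): pairwise Pearson R with
  t-transform p-values; optional partialing by residualizing all columns
  on covariates first.

## Numerical choices and degenerate inputs

* Beta values outside $[0,1]$ by more than $10^{-9}$ are rejected with the
  offending probe named; values within tolerance are clamped.
* Missing betas: available-case means for clock scoring; per-probe mean
  imputation before PCA and deconvolution (an explicit policy choice —
  how missing probes were handled in the motivating cohort is not
  documented).
* Technical PCs fix each component's sign so its largest-magnitude loading
  is positive, making outputs reproducible across platforms; explained
  variance fractions are reported over the full spectrum.
* Global mean methylation (`mean_methylation`) excludes the clock CpGs in
  the lineage analysis: at the simulated scale (2,000 CpGs) the 385
  division-coupled clock CpGs would otherwise add a mitotic component to
  the global mean that a genome-scale array dilutes ~70-fold, distorting
  the interpretation of the 0.02 depletion contrast.
* Zero-variance inputs raise errors (`standardize_sd`, constant age,
  constant control probes) or are flagged and masked (correlation panel);
  a zero-variance paired difference with nonzero mean reports the exact
  difference with the p-value flagged undefined.

## Problem sizes used by the tests and acceptance checks

Oracle-equivalence suites run 100 random instances per estimator. The
recovery checks use the generator at a reduced CpG count (1,400 CpGs,
15 markers per type per direction) — composition and clock information are
unchanged; only the inert background shrinks — with cohorts of n = 1,200
(single-replicate recovery), n = 600 × 100 replicates (direction of the
confounding reversal), and 300 patients × 3 visits (progression). The
default full-size conditions (2,000 CpGs, n = 1,200) are used by the
analysis drivers and the acceptance script.

## Known limitations

Wald inference throughout (anti-conservative for 6 donors; the balanced-
design closed forms are exact, but small-sample p-values should be read
qualitatively). The EEAA immune weighting is a surrogate. The generator's
acceleration-composition correlation (≈ −0.2 to −0.3 partialed on age) is
weaker than in real whole blood, where composition variance dominates;
the sign and the confounding direction are what the design pins down.
Reference-free deconvolution, EPIC-specific references, GEE/survival
models and multiple-testing correction across exams are out of scope.
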