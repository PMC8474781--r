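# mitotick

Epigenetic mitotic-age analysis for hematopoietic DNA methylation.

Blood accumulates DNA methylation at polycomb-group-target promoter CpGs in
proportion to its cell-division history; the mean beta over such a clock set
(*pcgtAge*) is a mitotic-age readout, and its residual on chronologic age
(*AccelEpiTOC*) measures mitotic-age **acceleration**. In whole blood this
signal is heavily confounded by leukocyte composition: granulocytes — the
dominant cell type — carry a much lower mitotic age than lymphocytes, so any
condition that shifts composition toward granulocytes masks a genuinely
faster stem-cell tick rate. `mitotick` implements the full analysis chain
for this problem, aimed at epigenetic-epidemiology analysts working with
450k-style beta matrices:

* **clocks** — `pcgt_age()` (unweighted clock-set mean), weighted clock
  ages with monotone calibration, and the acceleration family:
  `age_acceleration()` (AccelEpiTOC / AgeAccel), `intrinsic_acceleration()`
  (IEAA), `extrinsic_acceleration()` (EEAA), with per-SD standardization;
* **deconvolution** — Houseman-style reference-based composition:
  `build_reference()` from purified methylomes and constrained projection
  `estimate_proportions()` (non-negative weights, sum-to-one), plus
  linear-predictor surrogates for count-style estimates;
* **inference** — within-donor cell-type mixed models, paired tests,
  composition-adjusted logistic association with per-SD effects, greedy
  bidirectional `stepwise_aic()`, repeated-measures progression models with
  acceleration x time interactions, partial correlation panels, and
  stratified re-runs;
* **io** — delimited and GEO series-matrix beta readers with validation,
  sample-sheet alignment, and technical PCs from array control probes;
* **synthetic data** — a generator for purified-cell panels, confounded
  whole-blood case-control cohorts and longitudinal exam scores, with full
  ground truth, calibrated so the composition-adjusted odds ratio per SD is
  ~2.1 while the unadjusted estimate sits just below 1.

The model in one line: observed whole-blood methylation is a
proportion-weighted mixture of cell-type methylomes,
`beta_j = sum_k w_jk * profile_k`, with clock CpGs ticking as
`beta = clip(b0 + delta * divisions)`; the analysis recovers `w` by
constrained projection and the tick-rate effect by composition-adjusted
regression.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic conditions (seed 1). `Rscript analysis/02_purified_lineage.R`
scores a purified panel of 6 donors x 8 sorted cell types and prints:

```
myeloid-vs-lymphoid pcgtAge: beta = -0.077 (SE 0.0055, p = 1.1e-44)
CD8T - granulocyte paired difference: 0.089 (95% CI 0.045, 0.134)
myeloid global methylation deficit: beta = -0.0202 (SE 0.00013)
every donor's lymphoid mean exceeds its myeloid mean: TRUE
```

i.e. within donor, mitotic age is ~0.08 lower in myeloid than lymphoid
cells, and myeloid methylomes are globally depleted by ~0.02 — the lineage
structure that makes composition a confounder. `Rscript
analysis/04_association.R` then runs the whole-blood case-control analysis
(n = 1,200; deconvolution, technical PCs, AccelEpiTOC per SD):

```
adjusted OR per SD:   2.08 (95% CI 1.73, 2.50; p = 7.1e-15)
unadjusted OR per SD: 0.91 (95% CI 0.80, 1.02)
```

The adjusted model recovers the injected two-fold odds ratio per SD of
acceleration; without composition adjustment the association is fully
masked (OR below 1) because cases carry more low-mitotic-age granulocytes.
`analysis/05_progression.R` fits the exam-score mixed models among cases
(600 patients x 3 visits):

```
MMSE           yearly change per SD of acceleration: -0.069 (SE 0.014, p = 2e-06)
UPDRS3         yearly change per SD of acceleration: +0.157 (SE 0.045, p = 0.00042)
UPDRS3_tremor  yearly change per SD of acceleration: +0.037 (SE 0.012, p = 0.0015)
```

Higher baseline acceleration predicts faster cognitive decline (MMSE down)
and faster motor-symptom accrual (UPDRS-III up). `run_pipeline()` composes
all stages programmatically and writes the tables plus a reproducibility
manifest.

Real data drop in the same way: `read_beta_matrix()` accepts plain TSV/CSV
or GEO series-matrix files, `read_clock_definition()` loads a published
clock list (the packaged clock file is a synthetic stand-in matching the
simulator), and purified reference panels feed `build_reference()`.

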