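# Monte-Carlo calibration of the whole-blood generator's disease knobs.
# Targets (fixed before any acceptance test was written):
#   adjusted log-OR per SD of AccelEpiTOC = 0.75
#   unadjusted OR attenuated below 1 (~0.93)
library(mitotick)
run_one <- function(mult, shift, n = 6000, seed = 11) {
  cfg <- sim_config(n_cases = n/2, n_controls = n/2,
                    disease_tick_multiplier = mult,
                    case_granulocyte_shift = shift, seed = seed)
  co <- simulate_whole_blood_cohort(cfg)
  pan <- simulate_purified_panel(cfg)
  ref <- build_reference(pan$beta, pan$sheet, lineage = cfg$lineage)
  pr <- estimate_proportions(co$beta, ref)
  clk <- clock_definition("clk", co$truth$clock_cpgs)
  acc <- accel_table(co$beta, co$sheet, clk)
  pcs <- technical_pcs(co$controls, 2)
  d <- co$sheet
  d$accel_epitoc_sd <- acc$accel_epitoc_sd
  d <- cbind(d, as.matrix(pr[, ref$cell_types]),
             PC1 = pcs$scores[,1], PC2 = pcs$scores[,2])
  comp <- setdiff(ref$cell_types, "CD4T")
  covars <- c("age_years","sex","smoking","ancestry_label","PC1","PC2")
  adj <- fit_logistic(d, "status", c("accel_epitoc_sd", covars, comp), per_sd = comp)
  un  <- fit_logistic(d, "status", c("accel_epitoc_sd", covars))
  c(adj = adj$estimate[adj$term=="accel_epitoc_sd"],
    adj_se = adj$std_error[adj$term=="accel_epitoc_sd"],
    unadj = un$estimate[un$term=="accel_epitoc_sd"])
}
for (mult in c(1.10, 1.15, 1.20)) for (shift in c(0.06, 0.10)) {
  r <- run_one(mult, shift)
  cat(sprintf("mult %.3f shift %.2f -> adj logOR %.3f (se %.3f)  unadj logOR %.3f (OR %.2f)\n",
              mult, shift, r["adj"], r["adj_se"], r["unadj"], exp(r["unadj"])))
}
# refinement
for (mult in c(1.10, 1.105, 1.11)) {
  r1 <- run_one(mult, 0.10, n = 12000, seed = 21)
  r2 <- run_one(mult, 0.10, n = 12000, seed = 22)
  cat(sprintf("mult %.3f shift 0.10 -> adj %.3f / %.3f  unadj OR %.2f / %.2f\n",
              mult, r1["adj"], r2["adj"], exp(r1["unadj"]), exp(r2["unadj"])))
}
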