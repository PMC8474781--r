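#!/usr/bin/env Rscript
# Stage 6: correlation panel.
#
# Pearson correlations between mitotic-age acceleration and the estimated
# cell proportions (the composition-confounding structure), raw and
# partialed on age.  The granulocyte column is expected negative: samples
# dominated by low-mitotic-age granulocytes read out a lower whole-blood
# pcgtAge.

library(mitotick)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
panel <- simulate_purified_panel(cfg)
cohort <- simulate_whole_blood_cohort(cfg)
ref <- build_reference(panel$beta, panel$sheet, lineage = cfg$lineage)
props <- estimate_proportions(cohort$beta, ref)
clock <- clock_definition("mitotic_clock", cohort$truth$clock_cpgs)
acc <- accel_table(cohort$beta, cohort$sheet, clock)

cols <- data.frame(
  accel_epitoc_sd = acc$accel_epitoc_sd,
  pcgt_age = acc$pcgt_age,
  props[match(acc$sample_id, props$sample_id), ref$cell_types],
  check.names = FALSE)
cm <- pearson_corr_matrix(cols,
                          partial_on = data.frame(
                            age = cohort$sheet$age_years[
                              match(acc$sample_id, cohort$sheet$sample_id)]))
write.table(data.frame(variable = rownames(cm$r), round(cm$r, 4),
                       check.names = FALSE),
            "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("age-partialed correlations with AccelEpiTOC:\n")
for (ty in ref$cell_types)
  cat(sprintf("  %-14s R = %+0.2f\n", ty, cm$r["accel_epitoc_sd", ty]))
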