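#' Run the end-to-end mitotic-aging pipeline
#'
#' Orchestrates the full analysis in dependency order on a simulated study:
#' simulate a purified-cell panel and a whole-blood case-control cohort,
#' score the mitotic clock and acceleration, build the cell reference and
#' estimate composition, compute technical PCs from control probes, fit the
#' composition-adjusted and unadjusted disease association models, fit the
#' symptom-progression mixed models, and emit the correlation panel.  Every
#' stage writes a tidy TSV under `out_dir`, and a manifest records the
#' resolved configuration hash, input digests, seed, package version and
#' per-stage timings.  Identical config + seed yields byte-identical tables.
#'
#' @param config A [sim_config()], a list of `sim_config` argument
#'   overrides, or a path to a YAML file of such overrides.
#' @param out_dir Output directory (created if needed).
#' @param dry_run Validate the configuration and planned stages without
#'   computing.
#' @param write_beta Also write the (large) simulated beta matrices.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, dry_run = FALSE,
                         write_beta = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (dry_run) {
    message("config valid; stages: simulate, clocks, deconvolve, ",
            "technical_pcs, associate, progress, corr, report")
    return(invisible(list(config = config, dry_run = TRUE)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  timings <- c()
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  log_line("simulate: purified panel + whole-blood cohort, seed ", config$seed)
  panel <- stage("simulate_panel", simulate_purified_panel(config))
  cohort <- stage("simulate_cohort", simulate_whole_blood_cohort(config))
  long <- stage("simulate_scores",
                simulate_longitudinal_scores(config, cohort$truth))
  log_line("simulate: panel ", ncol(panel$beta), " samples; cohort ",
           ncol(cohort$beta), " samples; ", nrow(long$visits), " visit rows")

  clock <- clock_definition("mitotic_clock", panel$truth$clock_cpgs)
  log_line("deconvolve: building reference from the purified panel")
  ref <- stage("build_reference",
               build_reference(panel$beta, panel$sheet,
                               lineage = config$lineage))
  props <- stage("estimate_proportions",
                 estimate_proportions(cohort$beta, ref))
  prop_mat <- as.matrix(props[, ref$cell_types])
  rownames(prop_mat) <- props$sample_id

  log_line("technical_pcs: ", nrow(cohort$controls), " control probes")
  pcs <- stage("technical_pcs", technical_pcs(cohort$controls, 2L))

  log_line("clocks: pcgtAge + acceleration on ", ncol(cohort$beta), " samples")
  acc <- stage("accel_table", accel_table(cohort$beta, cohort$sheet, clock))

  d <- cohort$sheet
  d <- cbind(d, prop_mat[d$sample_id, , drop = FALSE],
             PC1 = pcs$scores[d$sample_id, 1L],
             PC2 = pcs$scores[d$sample_id, 2L])
  d$accel_epitoc_sd <- acc$accel_epitoc_sd[match(d$sample_id, acc$sample_id)]

  comp_terms <- setdiff(ref$cell_types, "CD4T")  # drop one: proportions sum to 1
  covars <- c("age_years", "sex", "smoking", "ancestry_label", "PC1", "PC2")
  log_line("associate: adjusted and unadjusted logistic models")
  adj <- stage("associate_adjusted",
               fit_logistic(d, "status",
                            c("accel_epitoc_sd", covars, comp_terms),
                            per_sd = comp_terms))
  unadj <- stage("associate_unadjusted",
                 fit_logistic(d, "status", c("accel_epitoc_sd", covars)))

  log_line("progress: exam-score mixed models on ", config$n_cases, " cases")
  visits <- long$visits
  base_cols <- c("subject_id", "age_years", "sex", "smoking", "ancestry_label",
                 "wave", "education", "pd_duration_years", "accel_epitoc_sd")
  visits <- merge(visits, d[d$status == 1L, base_cols], by = "subject_id")
  prog <- list()
  for (ex in names(config$slope_per_sd)) {
    prog[[ex]] <- stage(paste0("progress_", ex),
      fit_lmm_progression(visits, ex, "accel_epitoc_sd",
                          covariates = c("age_years", "sex",
                                         "pd_duration_years")))
  }

  log_line("corr: acceleration x composition correlation panel")
  corr_cols <- data.frame(accel_epitoc_sd = d$accel_epitoc_sd,
                          d[, ref$cell_types])
  corr <- stage("corr", pearson_corr_matrix(corr_cols))

  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(acc, "accel_table.tsv")
  wt(props, "cell_composition.tsv")
  wt(adj, "association_adjusted.tsv")
  wt(unadj, "association_unadjusted.tsv")
  wt(do.call(rbind, lapply(names(prog), function(ex)
    cbind(exam = ex, prog[[ex]]))), "progression.tsv")
  utils::write.table(data.frame(variable = rownames(corr$r), corr$r,
                                check.names = FALSE),
                     file.path(out_dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wt(data.frame(sample_id = pcs$sample_ids, pcs$scores), "technical_pcs.tsv")
  if (write_beta) {
    write_beta_matrix(cohort$beta, file.path(out_dir, "beta_cohort.tsv"))
    write_beta_matrix(panel$beta, file.path(out_dir, "beta_panel.tsv"))
  }

  cfg_file <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.function(x)) NULL else x), cfg_file)
  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mitotick")),
    stage_timings_s = as.list(timings),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log_line("done: ", length(outputs), " tables written to ", out_dir)
  invisible(list(config = config, panel = panel, cohort = cohort,
                 longitudinal = long, reference = ref, proportions = props,
                 technical_pcs = pcs, accel = acc,
                 association = list(adjusted = adj, unadjusted = unadj),
                 progression = prog, correlations = corr,
                 manifest = manifest))
}
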