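#' Define a DNA methylation clock
#'
#' A clock is a named CpG set with optional per-CpG weights, an intercept and
#' a monotone calibration transform.  The mitotic (epiTOC-style) clock is the
#' unweighted mean over its CpG set (`weights = NULL`); linear clocks
#' (Horvath/Hannum-style) supply weights and, optionally, a piecewise
#' log-linear age calibration.
#'
#' @param name Clock name.
#' @param cpg_ids Unique CpG identifiers.
#' @param weights `NULL` for a uniform-mean clock, else one coefficient per CpG.
#' @param intercept Linear-predictor intercept.
#' @param calibration A list: `list(type = "identity")` or
#'   `list(type = "anti_log_linear", adult_age = 20)`, the strictly monotone
#'   inverse transform `x < 0 : (1+a)exp(x)-1 ; x >= 0 : (1+a)x + a`.
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(name, cpg_ids, weights = NULL, intercept = 0,
                             calibration = list(type = "identity")) {
  cpg_ids <- as.character(cpg_ids)
  if (anyDuplicated(cpg_ids)) stop("clock CpG identifiers must be unique")
  if (!is.null(weights)) {
    if (length(weights) != length(cpg_ids))
      stop("weights length must equal the number of clock CpGs")
    weights <- stats::setNames(as.numeric(weights), cpg_ids)
  }
  if (!calibration$type %in% c("identity", "anti_log_linear"))
    stop("unknown calibration type: ", calibration$type)
  structure(list(name = name, cpg_ids = cpg_ids, weights = weights,
                 intercept = intercept, calibration = calibration),
            class = "clock_definition")
}

.apply_calibration <- function(x, calibration) {
  switch(calibration$type,
         identity = x,
         anti_log_linear = {
           a <- calibration$adult_age %||% 20
           ifelse(x < 0, (1 + a) * exp(x) - 1, (1 + a) * x + a)
         })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write clock-definition files
#'
#' Delimited text with columns `cpg_id` and `weight` (all-blank weights mean
#' a uniform-mean clock), preceded by optional header lines `#name=`,
#' `#intercept=`, `#calibration=` (`identity` or `anti_log_linear:<adult_age>`).
#'
#' @param path File path.
#' @return A [clock_definition()].
#' @export
read_clock_definition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key, default) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(m) == 0L) default else sub(paste0("^#", key, "="), "", m[1L])
  }
  name <- get_hdr("name", tools::file_path_sans_ext(basename(path)))
  intercept <- as.numeric(get_hdr("intercept", "0"))
  cal_str <- get_hdr("calibration", "identity")
  calibration <- if (grepl("^anti_log_linear", cal_str)) {
    a <- sub("^anti_log_linear:?", "", cal_str)
    list(type = "anti_log_linear", adult_age = if (nzchar(a)) as.numeric(a) else 20)
  } else list(type = "identity")
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  w <- if ("weight" %in% colnames(df) && any(!is.na(df$weight)))
    as.numeric(df$weight) else NULL
  clock_definition(name, df$cpg_id, weights = w, intercept = intercept,
                   calibration = calibration)
}

#' @rdname read_clock_definition
#' @param clock A [clock_definition()].
#' @export
write_clock_definition <- function(clock, path) {
  cal <- clock$calibration
  cal_str <- if (cal$type == "anti_log_linear")
    paste0("anti_log_linear:", cal$adult_age %||% 20) else "identity"
  hdr <- c(paste0("#name=", clock$name),
           paste0("#intercept=", format(clock$intercept, digits = 17)),
           paste0("#calibration=", cal_str))
  df <- data.frame(cpg_id = clock$cpg_ids,
                   weight = if (is.null(clock$weights)) NA_real_
                            else unname(clock$weights))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Mitotic age (pcgtAge): mean methylation over the clock CpG set
#'
#' For each sample, the unweighted mean of the non-missing clock-CpG betas.
#' The clock must cover at least `min_coverage` of its CpG set in the matrix.
#'
#' @param beta Beta matrix.
#' @param clock A uniform-mean [clock_definition()].
#' @param min_coverage Minimum fraction of clock CpGs that must be present.
#' @return A data.frame with `sample_id`, `pcgt_age`, and per-sample
#'   `n_cpgs_used`.
#' @export
pcgt_age <- function(beta, clock, min_coverage = 0.8) {
  present <- intersect(clock$cpg_ids, rownames(beta))
  cov <- length(present) / length(clock$cpg_ids)
  if (cov < min_coverage)
    stop(sprintf("clock coverage %.3f below %.3f: only %d of %d clock CpGs present",
                 cov, min_coverage, length(present), length(clock$cpg_ids)))
  sub <- beta[present, , drop = FALSE]
  used <- colSums(!is.na(sub))
  if (any(used == 0L)) stop("sample(s) with no non-missing clock CpGs")
  data.frame(sample_id = colnames(beta),
             pcgt_age = colMeans(sub, na.rm = TRUE),
             n_cpgs_used = used, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Linear-clock DNA methylation age
#'
#' `age = calibration(intercept + sum_j w_j beta_j)` per sample.  Clock CpGs
#' missing from the matrix raise an error; missing values within present
#' CpGs are imputed with the probe's cross-sample mean.
#'
#' @param beta Beta matrix.
#' @param clock A weighted [clock_definition()].
#' @return Named numeric vector of DNAm ages (years) per sample.
#' @export
linear_clock_age <- function(beta, clock) {
  if (is.null(clock$weights))
    stop("clock '", clock$name, "' has no weights; use pcgt_age for mean clocks")
  missing_cpgs <- setdiff(clock$cpg_ids, rownames(beta))
  if (length(missing_cpgs) > 0L)
    stop("clock CpGs absent from beta matrix: ",
         paste(utils::head(missing_cpgs, 5L), collapse = ", "))
  sub <- beta[clock$cpg_ids, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    miss <- is.na(sub[i, ])
    if (any(miss)) sub[i, miss] <- mean(sub[i, ], na.rm = TRUE)
  }
  lp <- drop(crossprod(sub, clock$weights[clock$cpg_ids])) + clock$intercept
  stats::setNames(.apply_calibration(lp, clock$calibration), colnames(beta))
}

#' Age-residualized acceleration
#'
#' Ordinary least-squares regression of a per-sample estimate (e.g. pcgtAge
#' or a DNAm age) on chronologic age; the raw residuals are the acceleration
#' (AccelEpiTOC when the estimate is pcgtAge).
#'
#' @param estimate Per-sample values.
#' @param age_years Chronologic ages, same length/order.
#' @return A list with `residuals`, `slope`, `intercept`, `fitted`.
#' @export
age_acceleration <- function(estimate, age_years) {
  if (length(estimate) != length(age_years)) stop("length mismatch")
  if (length(estimate) < 3L) stop("need at least 3 samples")
  if (stats::var(age_years) <= 0) stop("age is constant; design is singular")
  fit <- stats::lm(estimate ~ age_years)
  list(residuals = unname(stats::resid(fit)),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       fitted = unname(stats::fitted(fit)))
}

#' Intrinsic epigenetic age acceleration (IEAA)
#'
#' Residual of a DNAm age on chronologic age plus blood-cell composition
#' columns; by construction independent of the supplied composition.
#'
#' @param dnam_age Per-sample DNAm age.
#' @param age_years Chronologic age.
#' @param cell_composition Data.frame or matrix of per-sample cell columns.
#' @return Numeric residual vector.
#' @export
intrinsic_acceleration <- function(dnam_age, age_years, cell_composition) {
  cc <- as.matrix(cell_composition)
  keep <- apply(cc, 2L, function(x) stats::var(x) > 0)
  X <- cbind(age_years, cc[, keep, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    aliased <- colnames(cbind(`(Intercept)` = 1, X))[-qrX$pivot[seq_len(qrX$rank)]]
    stop("collinear design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(dnam_age ~ X)
  unname(stats::resid(fit))
}

#' Extrinsic epigenetic age acceleration (EEAA)
#'
#' Residual on chronologic age of an immune-weighted DNAm age.  The
#' immune-weighted age is a configured linear combination of a Hannum-style
#' clock age and immune cell abundances (see [immune_weighted_age()]); the
#' weights used are recorded in the result's attributes.
#'
#' @param immune_weighted_age Per-sample immune-weighted DNAm age.
#' @param age_years Chronologic age.
#' @return Numeric residual vector; attribute `weights` carries provenance
#'   when the input has one.
#' @export
extrinsic_acceleration <- function(immune_weighted_age, age_years) {
  res <- age_acceleration(immune_weighted_age, age_years)$residuals
  attr(res, "weights") <- attr(immune_weighted_age, "weights")
  res
}

#' Immune-weighted DNAm age
#'
#' `hannum_age + sum_c w_c * abundance_c`, the input to EEAA.  The default
#' weights are a configurable surrogate (the published immune weighting is
#' external to this package); they are attached to the output for
#' provenance.
#'
#' @param hannum_age Per-sample Hannum-style clock age.
#' @param cell_abundances Data.frame/matrix of immune-cell columns.
#' @param weights Named weights for a subset of the abundance columns.
#' @return Numeric vector with attribute `weights`.
#' @export
immune_weighted_age <- function(hannum_age, cell_abundances,
                                weights = c(CD8T = 10, plasmablast = 5,
                                            CD8n = -10)) {
  cc <- as.data.frame(cell_abundances)
  miss <- setdiff(names(weights), colnames(cc))
  if (length(miss) > 0L)
    stop("immune weighting needs missing cell column(s): ",
         paste(miss, collapse = ", "))
  out <- hannum_age
  for (nm in names(weights)) out <- out + weights[[nm]] * cc[[nm]]
  attr(out, "weights") <- weights
  out
}

#' Standardize to zero mean and unit sample SD
#'
#' @param values Numeric vector with positive sample SD (n-1 denominator).
#' @return Standardized vector.
#' @export
standardize_sd <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0) stop("cannot standardize: zero or undefined SD")
  (values - mean(values)) / s
}

#' Assemble the per-sample acceleration table
#'
#' Computes pcgtAge, AccelEpiTOC (raw and per-SD) and, when the inputs are
#' supplied, Horvath-style AgeAccel, IEAA and EEAA with per-SD twins.
#'
#' @param beta Beta matrix.
#' @param sheet Aligned sample sheet with `age_years`.
#' @param clock Uniform-mean mitotic clock definition.
#' @param cell_composition Optional per-sample composition (for IEAA).
#' @param dnam_age Optional per-sample linear-clock age (for AgeAccel/IEAA).
#' @param immune_age Optional immune-weighted age (for EEAA).
#' @param min_coverage Passed to [pcgt_age()].
#' @return Data.frame keyed by `sample_id`.
#' @export
accel_table <- function(beta, sheet, clock, cell_composition = NULL,
                        dnam_age = NULL, immune_age = NULL,
                        min_coverage = 0.8) {
  al <- align_samples(beta, sheet)
  pa <- pcgt_age(al$beta, clock, min_coverage = min_coverage)
  age <- as.numeric(al$sheet$age_years)
  acc <- age_acceleration(pa$pcgt_age, age)
  out <- data.frame(sample_id = pa$sample_id,
                    pcgt_age = pa$pcgt_age,
                    n_clock_cpgs_used = pa$n_cpgs_used,
                    accel_epitoc_raw = acc$residuals,
                    accel_epitoc_sd = standardize_sd(acc$residuals),
                    stringsAsFactors = FALSE)
  if (!is.null(dnam_age)) {
    da <- dnam_age[out$sample_id]
    out$dnam_age <- da
    out$age_accel_raw <- age_acceleration(da, age)$residuals
    out$age_accel_sd <- standardize_sd(out$age_accel_raw)
    if (!is.null(cell_composition)) {
      cc <- cell_composition[out$sample_id, , drop = FALSE]
      out$ieaa_raw <- intrinsic_acceleration(da, age, cc)
      out$ieaa_sd <- standardize_sd(out$ieaa_raw)
    }
  }
  if (!is.null(immune_age)) {
    ia <- immune_age[out$sample_id]
    out$eeaa_raw <- as.numeric(extrinsic_acceleration(ia, age))
    out$eeaa_sd <- standardize_sd(out$eeaa_raw)
  }
  out
}

#' Mean methylation per sample over background probes
#'
#' Global-methylation summary used for the lineage depletion contrast.  By
#' default the clock CpGs are excluded: they carry a division-coupled gain
#' by design, and at the simulated probe counts they would otherwise
#' contribute a mitotic component to the global mean that a genome-scale
#' array dilutes to negligibility.
#'
#' @param beta Beta matrix.
#' @param exclude CpG identifiers to drop (default none).
#' @return Named numeric vector of per-sample means.
#' @export
mean_methylation <- function(beta, exclude = NULL) {
  rows <- setdiff(rownames(beta), exclude)
  if (length(rows) == 0L) stop("no probes left after exclusion")
  colMeans(beta[rows, , drop = FALSE], na.rm = TRUE)
}
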