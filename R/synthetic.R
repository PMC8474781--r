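#' Simulation configuration for synthetic hematopoietic methylomes
#'
#' Builds the configuration object consumed by all generators.  Defaults
#' encode the study conditions the analysis layer assumes: a purified-cell
#' panel of six adult male donors across eight sorted cell types (four
#' myeloid, four lymphoid), division-coupled methylation gain at a 385-CpG
#' clock set that starts near-unmethylated, a genome-wide myeloid methylation
#' deficit of 0.02, granulocyte-dominant whole-blood mixtures (mean
#' granulocyte fraction 0.55, total granulocytic mass ~0.6), and a
#' case-control cohort in which cases carry both a faster mitotic tick rate
#' and a granulocyte-shifted composition, so that the composition confounds
#' the acceleration-disease association negatively.
#'
#' The disease tick multiplier and the case granulocyte shift are calibrated
#' by Monte-Carlo simulation (see the packaged calibration notes in the
#' methods vignette) so that the composition-adjusted log odds ratio per SD
#' of mitotic-age acceleration equals `target_log_or_per_sd` while the
#' unadjusted odds ratio is attenuated below one.
#'
#' @param n_cpgs_total Total simulated CpGs (clock + background).
#' @param n_clock_cpgs Clock-set size (division-coupled CpGs).
#' @param n_marker_per_type Hyper- and hypomethylated marker CpGs per cell
#'   type (each type gets `2 * n_marker_per_type` discriminating CpGs).
#' @param cell_types Ordered cell-type labels.
#' @param lineage Named lineage tags (`"myeloid"`/`"lymphoid"`) per cell type.
#' @param lineage_tick_rates Named divisions-per-year attributed to each cell
#'   type's proliferative history.
#' @param tick_increment_delta Beta gain per division at clock CpGs.
#' @param myeloid_depletion_shift Global mean-beta deficit of myeloid
#'   profiles at background CpGs.
#' @param n_donors_purified,donor_age_mean,donor_age_sd Purified-panel donors.
#' @param n_cases,n_controls Whole-blood cohort arms.
#' @param age_range_years Cohort age range (uniform draw).
#' @param frailty_sd_log Log-SD of the subject-level multiplicative frailty
#'   on division counts.
#' @param disease_tick_multiplier Relative tick-rate increase in cases; may be
#'   a named vector `c(male=, female=)` for a sex-modified effect.
#' @param target_log_or_per_sd The adjusted log odds ratio per SD the
#'   multiplier is calibrated to (recorded as ground truth).
#' @param proportion_means Named Dirichlet mean composition (sums to 1).
#' @param proportion_concentration Dirichlet concentration (precision).
#' @param case_granulocyte_shift Added granulocyte mean fraction in cases,
#'   removed proportionally from the lymphoid types.
#' @param noise_sd_logit Logit-scale measurement noise SD.
#' @param technical_batches,batch_sd_logit,sample_offset_sd_logit Batch
#'   structure of the technical (sample-level) logit offset.
#' @param n_control_probes Number of simulated array control probes.
#' @param n_visits,visit_spacing_years Longitudinal exam design.
#' @param slope_per_sd Named exam-score slope change per SD of true
#'   acceleration (negative for MMSE-like, positive for UPDRS-like exams).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cpgs_total = 2000L,
                       n_clock_cpgs = 385L,
                       n_marker_per_type = 30L,
                       cell_types = c("granulocytes", "neutrophils", "eosinophils",
                                      "monocytes", "Bcells", "CD4T", "CD8T", "NK"),
                       lineage = c(granulocytes = "myeloid", neutrophils = "myeloid",
                                   eosinophils = "myeloid", monocytes = "myeloid",
                                   Bcells = "lymphoid", CD4T = "lymphoid",
                                   CD8T = "lymphoid", NK = "lymphoid"),
                       lineage_tick_rates = c(granulocytes = 12, neutrophils = 13,
                                              eosinophils = 13, monocytes = 14,
                                              Bcells = 29, CD4T = 31,
                                              CD8T = 33, NK = 31),
                       tick_increment_delta = 1e-4,
                       myeloid_depletion_shift = 0.02,
                       n_donors_purified = 6L,
                       donor_age_mean = 38, donor_age_sd = 13.6,
                       n_cases = 600L, n_controls = 600L,
                       age_range_years = c(50, 80),
                       frailty_sd_log = 0.15,
                       disease_tick_multiplier = 1.10,
                       target_log_or_per_sd = 0.75,
                       proportion_means = c(granulocytes = 0.55, neutrophils = 0.04,
                                            eosinophils = 0.01, monocytes = 0.08,
                                            Bcells = 0.06, CD4T = 0.15,
                                            CD8T = 0.07, NK = 0.04),
                       proportion_concentration = 60,
                       case_granulocyte_shift = 0.10,
                       noise_sd_logit = 0.10,
                       technical_batches = 8L,
                       batch_sd_logit = 0.05,
                       sample_offset_sd_logit = 0.02,
                       n_control_probes = 848L,
                       n_visits = 3L, visit_spacing_years = 2,
                       slope_per_sd = c(MMSE = -0.06, UPDRS3 = 0.19,
                                        UPDRS3_tremor = 0.05),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_clock_cpgs > cfg$n_cpgs_total)
    stop("n_clock_cpgs exceeds n_cpgs_total")
  if (any(cfg$lineage_tick_rates < 0) || cfg$tick_increment_delta < 0)
    stop("tick rates and increments must be non-negative")
  if (any(cfg$proportion_means < 0) || cfg$proportion_concentration <= 0)
    stop("Dirichlet parameters must be positive")
  if (abs(sum(cfg$proportion_means) - 1) > 1e-8)
    stop("proportion_means must sum to 1")
  if (!setequal(names(cfg$lineage), cfg$cell_types) ||
      !setequal(names(cfg$lineage_tick_rates), cfg$cell_types))
    stop("lineage and tick rates must be named by cell_types")
  nm <- cfg$n_cpgs_total - cfg$n_clock_cpgs
  if (2L * cfg$n_marker_per_type * length(cfg$cell_types) > nm)
    stop("not enough background CpGs for the requested marker blocks")
  class(cfg) <- "sim_config"
  cfg
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

.clip01 <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

#' Dirichlet sampler
#' @param n Number of draws.
#' @param alpha Positive concentration vector.
#' @return `n` x `length(alpha)` matrix of simplex points.
#' @export
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

# logit-normal measurement noise plus optional per-sample technical offset
.measure <- function(expected, sd_logit, sample_offset = 0) {
  z <- logit(.clip01(expected)) +
    rep(sample_offset, each = nrow(expected)) +
    stats::rnorm(length(expected), 0, sd_logit)
  m <- matrix(inv_logit(z), nrow = nrow(expected), dimnames = dimnames(expected))
  .clip01(m)
}

#' Simulate per-cell-type baseline methylomes
#'
#' Draws a shared bimodal background methylome, adds cell-type-specific
#' marker blocks (strongly hyper-/hypomethylated CpGs that make every type
#' identifiable by deconvolution), subtracts the myeloid depletion shift from
#' all background CpGs of myeloid profiles, and assigns clock CpGs a
#' near-unmethylated baseline (beta <= 0.05) shared across types.  Profiles
#' are expectation-level: no measurement noise and no division ticking.
#'
#' @param config A [sim_config()].
#' @return A list with `profiles` (CpG x cell-type matrix), `clock_cpgs`,
#'   `marker_cpgs` (named list per type), `lineage`, and the config.
#' @export
simulate_cell_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- length(config$cell_types)
  n_clk <- config$n_clock_cpgs
  n_bg <- config$n_cpgs_total - n_clk
  clock_ids <- sprintf("cgS%05d", seq_len(n_clk))
  bg_ids <- sprintf("cgB%05d", seq_len(n_bg))

  # shared bimodal background baseline
  comp <- sample.int(3L, n_bg, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  base <- numeric(n_bg)
  base[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 8)
  base[comp == 2L] <- stats::rbeta(sum(comp == 2L), 8, 2)
  base[comp == 3L] <- stats::rbeta(sum(comp == 3L), 2, 2)
  bg <- matrix(rep(base, K), nrow = n_bg,
               dimnames = list(bg_ids, config$cell_types))
  # small type-specific jitter so between-type variance is positive everywhere
  bg <- .clip01(bg + matrix(stats::rnorm(n_bg * K, 0, 0.01), nrow = n_bg))

  # marker blocks: 2*n_marker_per_type discriminating CpGs per type
  marker_cpgs <- vector("list", K); names(marker_cpgs) <- config$cell_types
  idx <- 0L
  for (k in seq_len(K)) {
    nh <- config$n_marker_per_type
    rows <- idx + seq_len(2L * nh); idx <- idx + 2L * nh
    hi <- rows[seq_len(nh)]; lo <- rows[nh + seq_len(nh)]
    bg[hi, ] <- .clip01(0.10 + abs(stats::rnorm(length(hi) * K, 0, 0.03)))
    bg[hi, k] <- .clip01(0.90 - abs(stats::rnorm(length(hi), 0, 0.03)))
    bg[lo, ] <- .clip01(0.90 - abs(stats::rnorm(length(lo) * K, 0, 0.03)))
    bg[lo, k] <- .clip01(0.10 + abs(stats::rnorm(length(lo), 0, 0.03)))
    marker_cpgs[[k]] <- bg_ids[rows]
  }

  # myeloid global depletion at background CpGs
  myeloid <- config$cell_types[config$lineage[config$cell_types] == "myeloid"]
  bg[, myeloid] <- .clip01(bg[, myeloid] - config$myeloid_depletion_shift)

  # clock baselines: near-unmethylated, shared across types
  b0 <- stats::runif(n_clk, 0.005, 0.045)
  clk <- matrix(rep(b0, K), nrow = n_clk,
                dimnames = list(clock_ids, config$cell_types))

  profiles <- rbind(clk, bg)
  list(profiles = profiles, clock_cpgs = clock_ids, clock_baseline = b0,
       marker_cpgs = marker_cpgs,
       lineage = config$lineage[config$cell_types], config = config)
}

# division counts: rate * age * frailty (* disease multiplier)
.divisions <- function(config, ages, frailty, multiplier = 1) {
  D <- outer(ages * frailty * multiplier, config$lineage_tick_rates[config$cell_types])
  colnames(D) <- config$cell_types
  D
}

# expected clock beta for one division-count vector D (length K): CpG x type
.ticked_clock <- function(b0, delta, D) {
  m <- outer(b0, delta * D, `+`)
  pmin(m, 1)                    # biological ceiling; floor impossible (gains only)
}

#' Simulate a purified-cell methylation panel
#'
#' One sample per (donor, cell type).  Clock CpGs gain
#' `tick_increment_delta` per division, with per-type division counts
#' `rate x age x donor frailty`; lymphoid rates exceed myeloid so the
#' within-donor mitotic-age gap is ~0.06-0.08 at the panel's mean age.
#' Logit-normal measurement noise is applied to every value.
#'
#' @param config A [sim_config()].
#' @return A list with `beta` (BetaMatrix), `sheet` (SampleSheet) and
#'   `truth` (ground-truth bundle).
#' @export
simulate_purified_panel <- function(config) {
  prof <- simulate_cell_profiles(config)
  set.seed(config$seed + 1L)
  nd <- config$n_donors_purified
  K <- length(config$cell_types)
  ages <- pmin(pmax(stats::rnorm(nd, config$donor_age_mean, config$donor_age_sd), 22), 60)
  frailty <- exp(stats::rnorm(nd, 0, config$frailty_sd_log))

  beta <- matrix(NA_real_, nrow = nrow(prof$profiles), ncol = nd * K)
  rownames(beta) <- rownames(prof$profiles)
  ids <- character(nd * K); divisions <- matrix(NA_real_, nd, K,
    dimnames = list(paste0("donor", seq_len(nd)), config$cell_types))
  for (i in seq_len(nd)) {
    D <- .divisions(config, ages[i], frailty[i])[1L, ]
    divisions[i, ] <- D
    expected <- prof$profiles
    expected[prof$clock_cpgs, ] <-
      .ticked_clock(prof$clock_baseline, config$tick_increment_delta, D)
    cols <- (i - 1L) * K + seq_len(K)
    ids[cols] <- paste0("donor", i, "_", config$cell_types)
    beta[, cols] <- .measure(expected, config$noise_sd_logit)
  }
  colnames(beta) <- ids
  sheet <- data.frame(
    sample_id = ids,
    subject_id = rep(paste0("donor", seq_len(nd)), each = K),
    age_years = rep(ages, each = K),
    sex = "male",
    cell_type_label = rep(config$cell_types, nd),
    lineage = rep(unname(prof$lineage), nd),
    stringsAsFactors = FALSE)
  truth <- list(division_counts = divisions, donor_ages = ages,
                donor_frailty = frailty, clock_cpgs = prof$clock_cpgs,
                profiles = prof$profiles, config = config, seed = config$seed)
  list(beta = beta, sheet = sheet, truth = truth)
}

#' Simulate a whole-blood case-control cohort
#'
#' Mixes the cell-type profiles with subject-level Dirichlet proportions
#' (granulocyte-dominant; cases shifted further toward granulocytes), ticks
#' the clock CpGs with subject-level division counts (cases multiplied by the
#' disease tick multiplier), applies batch-structured technical offsets plus
#' logit-normal noise, and simulates array control probes carrying the same
#' technical structure.  The granulocyte shift in cases makes composition a
#' negative confounder of the acceleration-disease association: the
#' unadjusted estimate is attenuated below the composition-adjusted one.
#'
#' @param config A [sim_config()].
#' @return A list with `beta`, `sheet`, `controls` (control-probe matrix) and
#'   `truth` containing true proportions, division counts, the injected
#'   disease effect, and the true standardized acceleration per subject.
#' @export
simulate_whole_blood_cohort <- function(config) {
  prof <- simulate_cell_profiles(config)
  set.seed(config$seed + 2L)
  n <- config$n_cases + config$n_controls
  if (n == 0L) stop("n_cases + n_controls must be positive")
  K <- length(config$cell_types)
  ids <- sprintf("wb%05d", seq_len(n))
  status <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))
  ages <- stats::runif(n, config$age_range_years[1L], config$age_range_years[2L])
  sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "male", "female")
  frailty <- exp(stats::rnorm(n, 0, config$frailty_sd_log))
  mult <- rep(1, n)
  dm <- config$disease_tick_multiplier
  if (length(dm) == 1L) mult[status == 1L] <- dm
  else mult[status == 1L] <- unname(dm[sex[status == 1L]])

  # composition: cases shifted toward granulocytes, out of the lymphoid types
  mu <- config$proportion_means[config$cell_types]
  lymph <- config$cell_types[config$lineage[config$cell_types] == "lymphoid"]
  mu_case <- mu
  mu_case["granulocytes"] <- mu["granulocytes"] + config$case_granulocyte_shift
  mu_case[lymph] <- mu[lymph] * (sum(mu[lymph]) - config$case_granulocyte_shift) /
    sum(mu[lymph])
  W <- matrix(NA_real_, n, K, dimnames = list(ids, config$cell_types))
  W[status == 0L, ] <- rdirichlet(sum(status == 0L), config$proportion_concentration * mu)
  W[status == 1L, ] <- rdirichlet(sum(status == 1L), config$proportion_concentration * mu_case)

  # expected mixture: background constant across subjects, clock subject-level
  bg_rows <- setdiff(rownames(prof$profiles), prof$clock_cpgs)
  expected <- matrix(NA_real_, nrow = nrow(prof$profiles), ncol = n,
                     dimnames = list(rownames(prof$profiles), ids))
  expected[bg_rows, ] <- prof$profiles[bg_rows, ] %*% t(W)
  D <- .divisions(config, ages, frailty, mult)     # n x K division counts
  clk_mix <- matrix(0, length(prof$clock_cpgs), n)
  for (k in seq_len(K)) {
    ticked <- pmin(outer(prof$clock_baseline,
                         config$tick_increment_delta * D[, k], `+`), 1)
    clk_mix <- clk_mix + ticked * rep(W[, k], each = nrow(ticked))
  }
  expected[prof$clock_cpgs, ] <- clk_mix

  batch <- sample.int(config$technical_batches, n, replace = TRUE)
  batch_eff <- stats::rnorm(config$technical_batches, 0, config$batch_sd_logit)
  offset <- batch_eff[batch] + stats::rnorm(n, 0, config$sample_offset_sd_logit)
  beta <- .measure(expected, config$noise_sd_logit, sample_offset = offset)

  # control probes: no biology, technical offset amplified + probe noise
  ncp <- config$n_control_probes
  cp_base <- stats::runif(ncp, 0.2, 0.8)
  cp_sens <- stats::runif(ncp, 0.5, 1.5)
  controls <- inv_logit(outer(logit(cp_base), rep(1, n)) +
                          outer(cp_sens, offset * 4) +
                          matrix(stats::rnorm(ncp * n, 0, 0.05), ncp, n))
  dimnames(controls) <- list(sprintf("ctrl%04d", seq_len(ncp)), ids)

  sheet <- data.frame(
    sample_id = ids, subject_id = ids,
    age_years = ages, sex = sex, status = status,
    ancestry_label = sample(c("European", "Hispanic"), n, TRUE, c(0.7, 0.3)),
    smoking = sample(c("never", "former", "current"), n, TRUE, c(0.5, 0.35, 0.15)),
    wave = sample(c("wave1", "wave2"), n, TRUE),
    education = sample(c("lt12", "hs", "college"), n, TRUE, c(0.3, 0.4, 0.3)),
    pd_duration_years = ifelse(status == 1L, stats::runif(n, 1, 10), NA_real_),
    batch = batch, stringsAsFactors = FALSE)

  # noise-free mitotic age and its composition+age-adjusted true acceleration
  pcgt_true <- colMeans(expected[prof$clock_cpgs, ])
  fit <- stats::lm(pcgt_true ~ ages + W[, -match("CD4T", colnames(W))])
  true_accel_sd <- standardize_sd(stats::resid(fit))

  truth <- list(true_proportions = W, true_division_counts = D,
                true_disease_effect = list(
                  tick_multiplier = config$disease_tick_multiplier,
                  target_log_or_per_sd = config$target_log_or_per_sd),
                true_accel_sd = stats::setNames(true_accel_sd, ids),
                pcgt_true = stats::setNames(pcgt_true, ids),
                status = stats::setNames(status, ids),
                batch_effects = batch_eff, sample_offsets = offset,
                clock_cpgs = prof$clock_cpgs, profiles = prof$profiles,
                config = config, seed = config$seed)
  list(beta = beta, sheet = sheet, controls = controls, truth = truth)
}

#' Simulate longitudinal exam-score trajectories
#'
#' For every case subject in the cohort truth bundle, generates `n_visits`
#' visit records whose exam-score slopes depend linearly on the subject's
#' true standardized acceleration:
#' `score_it = b0 + u0_i + (b_t + slope_per_sd * accel_i + u1_i) * t + e_it`,
#' with Gaussian random intercepts/slopes and residuals.  MMSE-like scores
#' use a negative `slope_per_sd`, UPDRS-like positive.
#'
#' @param config A [sim_config()].
#' @param truth Truth bundle from [simulate_whole_blood_cohort()].
#' @param exam_params Optional per-exam overrides of the default trajectory
#'   parameters (named lists with `intercept`, `time_slope`, `re_int_sd`,
#'   `re_slope_sd`, `resid_sd`); setting the SDs to zero gives the
#'   deterministic limit where scores are exactly linear in time.
#' @return A list with `visits` (one row per subject-visit, exam scores in
#'   columns) and `true_slopes` (subject x exam matrix of realized slopes).
#' @export
simulate_longitudinal_scores <- function(config, truth, exam_params = NULL) {
  if (is.null(truth$true_accel_sd) || is.null(truth$status))
    stop("truth bundle lacks per-subject acceleration/status")
  if (config$n_visits < 2L) stop("n_visits must be >= 2")
  set.seed(config$seed + 3L)
  subj <- names(truth$status)[truth$status == 1L]
  accel <- truth$true_accel_sd[subj]
  if (anyNA(accel)) stop("missing true acceleration for some case subjects")
  npat <- length(subj)
  tt <- (seq_len(config$n_visits) - 1L) * config$visit_spacing_years

  exams <- list(
    MMSE = list(intercept = 28, time_slope = -0.15, re_int_sd = 1.5,
                re_slope_sd = 0.05, resid_sd = 1.0),
    UPDRS3 = list(intercept = 20, time_slope = 1.0, re_int_sd = 6,
                  re_slope_sd = 0.3, resid_sd = 3.0),
    UPDRS3_tremor = list(intercept = 4, time_slope = 0.15, re_int_sd = 1.5,
                         re_slope_sd = 0.05, resid_sd = 0.8))
  exams <- exams[names(config$slope_per_sd)]
  for (ex in names(exam_params %||% list()))
    exams[[ex]] <- utils::modifyList(exams[[ex]], exam_params[[ex]])

  visits <- data.frame(
    subject_id = rep(subj, each = config$n_visits),
    visit_time_years = rep(tt, npat), stringsAsFactors = FALSE)
  true_slopes <- matrix(NA_real_, npat, length(exams),
                        dimnames = list(subj, names(exams)))
  for (ex in names(exams)) {
    p <- exams[[ex]]
    u0 <- stats::rnorm(npat, 0, p$re_int_sd)
    u1 <- stats::rnorm(npat, 0, p$re_slope_sd)
    slope <- p$time_slope + config$slope_per_sd[[ex]] * accel + u1
    true_slopes[, ex] <- slope
    mu <- rep(p$intercept + u0, each = config$n_visits) +
      rep(slope, each = config$n_visits) * visits$visit_time_years
    visits[[ex]] <- mu + stats::rnorm(nrow(visits), 0, p$resid_sd)
  }
  list(visits = visits, true_slopes = true_slopes)
}
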