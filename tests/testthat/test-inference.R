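test_that("cell-type mixed model reduces to group-mean contrasts on balanced data", {
  # balanced complete design with subject offsets: fixed effects must equal
  # group mean differences exactly
  set.seed(41)
  types <- c("CD8T", "CD4T", "granulocytes", "monocytes")
  subj <- paste0("d", 1:6)
  d <- expand.grid(subject_id = subj, cell_type_label = types,
                   stringsAsFactors = FALSE)
  type_eff <- c(CD8T = 0.12, CD4T = 0.10, granulocytes = 0.04, monocytes = 0.05)
  subj_eff <- setNames(rnorm(6, 0, 0.02), subj)
  d$y <- type_eff[d$cell_type_label] + subj_eff[d$subject_id] +
    rnorm(nrow(d), 0, 0.005)
  fr <- fit_lmm_celltype(d$y, d, contrast = "celltype", reference = "CD8T")
  gm <- tapply(d$y, d$cell_type_label, mean)
  for (ty in setdiff(types, "CD8T")) {
    expect_equal(fr$estimate[fr$term == ty], unname(gm[ty] - gm["CD8T"]),
                 tolerance = 1e-8)
  }
  expect_equal(fr$n_subjects[1], 6L)

  # all cell types identical, zero noise: contrasts are zero (singular
  # random effect falls back to fixed effects with a warning)
  d0 <- d; d0$y <- 0.1
  fr0 <- suppressWarnings(fit_lmm_celltype(d0$y, d0, contrast = "celltype"))
  expect_true(all(abs(fr0$estimate[fr0$term != "(Intercept)"]) < 1e-10))
})

test_that("lineage contrast reports myeloid relative to lymphoid", {
  d <- expand.grid(subject_id = paste0("d", 1:5),
                   cell_type_label = c("CD8T", "granulocytes"),
                   stringsAsFactors = FALSE)
  d$lineage <- ifelse(d$cell_type_label == "CD8T", "lymphoid", "myeloid")
  set.seed(42)
  d$y <- ifelse(d$lineage == "myeloid", 0.05, 0.12) + rnorm(nrow(d), 0, 0.004)
  fr <- suppressWarnings(fit_lmm_celltype(d$y, d, contrast = "lineage"))
  est <- fr$estimate[fr$term == "myeloid"]
  expect_lt(est, 0)
  expect_equal(est, mean(d$y[d$lineage == "myeloid"]) -
                 mean(d$y[d$lineage == "lymphoid"]), tolerance = 1e-6)
})

test_that("paired differences match the closed-form t interval", {
  a <- c(0.10, 0.20); b <- c(0.04, 0.10)   # differences 0.06, 0.10
  pd <- paired_difference(a, b)
  d <- a - b
  se <- sd(d) / sqrt(2)
  expect_equal(pd$mean_difference, 0.08)
  expect_equal(pd$ci_low, 0.08 - qt(0.975, 1) * se, tolerance = 1e-10)
  expect_equal(pd$ci_high, 0.08 + qt(0.975, 1) * se, tolerance = 1e-10)
  expect_equal(pd$t, 0.08 / se, tolerance = 1e-10)

  # identity and antisymmetry
  x <- runif(8)
  pid <- paired_difference(x, x)
  expect_equal(pid$mean_difference, 0)
  expect_equal(pid$t, 0)
  y <- runif(8)
  p1 <- paired_difference(x, y); p2 <- paired_difference(y, x)
  expect_equal(p1$mean_difference, -p2$mean_difference)
  expect_equal(p1$p_value, p2$p_value)

  # zero-variance nonzero difference: exact difference, p flagged undefined
  pz <- paired_difference(c(1, 2, 3), c(0, 1, 2))
  expect_equal(pz$mean_difference, 1)
  expect_true(is.na(pz$p_value) && pz$degenerate)
})

test_that("logistic fit matches 2x2 closed forms and detects separation", {
  d <- data.frame(y = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)),
                  x = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)))
  fr <- fit_logistic(d, "y", "x")
  expect_equal(fr$odds_ratio[fr$term == "x"], 4.0, tolerance = 1e-6)
  expect_equal(fr$std_error[fr$term == "x"],
               sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20), tolerance = 1e-6)

  # exactly balanced predictor: OR = 1
  db <- data.frame(y = rep(c(1, 0), each = 20), x = rep(c(0, 1), 20))
  frb <- fit_logistic(db, "y", "x")
  expect_equal(frb$odds_ratio[frb$term == "x"], 1, tolerance = 1e-8)

  # per-SD scaling invariance: positive rescaling leaves the per-SD OR unchanged
  set.seed(43)
  n <- 300
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * z))
  dz <- data.frame(y = y, x = z)
  dz2 <- data.frame(y = y, x = 17.3 * z)
  f1 <- fit_logistic(dz, "y", "x", per_sd = "x")
  f2 <- fit_logistic(dz2, "y", "x", per_sd = "x")
  expect_equal(f1$estimate[f1$term == "x"], f2$estimate[f2$term == "x"],
               tolerance = 1e-8)

  # perfect separation flagged, not silently diverged
  ds <- data.frame(y = rep(c(0, 1), each = 10), x = c(rnorm(10, -5), rnorm(10, 5)))
  expect_warning(fs <- fit_logistic(ds, "y", "x"), "separation")
  expect_true(attr(fs, "separation"))
  expect_error(fit_logistic(data.frame(y = rep(1, 10), x = rnorm(10)), "y", "x"),
               "both classes")
})

test_that("stepwise AIC follows the greedy path and honors locked terms", {
  set.seed(44)
  n <- 400
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n), x5 = rnorm(n), age = runif(n, 40, 80))
  lp <- 0.9 * d$x1 - 0.8 * d$x2 + 0.01 * (d$age - 60)
  d$y <- rbinom(n, 1, plogis(lp))

  # empty candidate set returns the locked model
  s0 <- stepwise_aic(d, "y", locked = "age", candidates = character(0))
  expect_identical(s0$selected_terms, "age")

  s <- stepwise_aic(d, "y", locked = "age",
                    candidates = c("x1", "x2", "x3", "x4", "x5"))
  expect_true(all(c("x1", "x2") %in% s$selected_candidates))
  expect_true("age" %in% s$selected_terms)
  # trace strictly decreasing
  expect_true(all(diff(s$trace$aic) < 0))

  # invariant to candidate input order
  s_rev <- stepwise_aic(d, "y", locked = "age",
                        candidates = rev(c("x1", "x2", "x3", "x4", "x5")))
  expect_identical(s$selected_candidates, s_rev$selected_candidates)
  expect_equal(s$aic, s_rev$aic)

  # greedy path reaches the all-subsets optimum here (verified exhaustively);
  # in general the greedy AIC can only be >= the global minimum
  cands <- c("x1", "x2", "x3", "x4", "x5")
  subsets <- unlist(lapply(0:5, function(k)
    combn(cands, k, simplify = FALSE)), recursive = FALSE)
  aics <- vapply(subsets, function(ss) {
    f <- as.formula(paste("y ~", paste(c("age", ss), collapse = " + ")))
    AIC(glm(f, data = d, family = binomial()))
  }, numeric(1))
  expect_gte(s$aic, min(aics) - 1e-8)
  expect_lt(s$aic - min(aics), 1e-6)   # greedy finds the optimum on this design
})

test_that("progression mixed model recovers deterministic slopes exactly", {
  cfg <- lean_config(seed = 45, n_cases = 40L, n_controls = 40L)
  co <- simulate_whole_blood_cohort(cfg)
  zero <- list(re_int_sd = 0, re_slope_sd = 0, resid_sd = 0)
  long <- simulate_longitudinal_scores(cfg, co$truth,
    exam_params = list(MMSE = zero, UPDRS3 = zero, UPDRS3_tremor = zero))
  v <- long$visits
  v$accel <- co$truth$true_accel_sd[v$subject_id]
  fr <- suppressWarnings(
    fit_lmm_progression(v, "MMSE", "accel", per_sd_accel = FALSE))
  it <- attr(fr, "interaction_term")
  expect_equal(fr$estimate[fr$term == it], cfg$slope_per_sd[["MMSE"]],
               tolerance = 1e-6)

  # null interaction when slopes do not depend on acceleration
  cfg0 <- lean_config(seed = 46, n_cases = 60L, n_controls = 10L,
                      slope_per_sd = c(MMSE = 0))
  co0 <- simulate_whole_blood_cohort(cfg0)
  long0 <- simulate_longitudinal_scores(cfg0, co0$truth)
  v0 <- long0$visits
  v0$accel <- co0$truth$true_accel_sd[v0$subject_id]
  fr0 <- suppressWarnings(fit_lmm_progression(v0, "MMSE", "accel"))
  it0 <- attr(fr0, "interaction_term")
  expect_lt(abs(fr0$z_value[fr0$term == it0]), 3)

  one_visit <- v[!duplicated(v$subject_id), ]
  expect_error(fit_lmm_progression(one_visit, "MMSE", "accel"), "single visit")
})

test_that("correlation panel matches the covariance-formula oracle", {
  set.seed(47)
  x <- rnorm(40)
  cols <- data.frame(x = x, y = 2 * x + 1)
  cm <- pearson_corr_matrix(cols)
  expect_equal(cm$r["x", "y"], 1, tolerance = 1e-12)

  big <- as.data.frame(matrix(rnorm(200 * 8), 200, 8))
  cm8 <- pearson_corr_matrix(big)
  for (i in 1:8) for (j in 1:8) {
    if (i == j) next
    expect_equal(cm8$r[i, j], oracle_pearson(big[[i]], big[[j]]),
                 tolerance = 1e-12)
  }
  # null: independent permutation
  xn <- rnorm(1000)
  cmn <- pearson_corr_matrix(data.frame(a = xn, b = sample(xn)))
  expect_lt(abs(cmn$r["a", "b"]), 0.1)

  # zero-variance column flagged and masked
  cz <- pearson_corr_matrix(data.frame(a = xn[1:10], b = rep(1, 10)))
  expect_identical(cz$degenerate, "b")
  expect_true(is.na(cz$r["a", "b"]))

  # partialing on a shared covariate removes induced correlation
  z <- rnorm(500)
  dd <- data.frame(u = z + rnorm(500, 0, 0.3), v = z + rnorm(500, 0, 0.3))
  raw <- pearson_corr_matrix(dd)
  part <- pearson_corr_matrix(dd, partial_on = data.frame(z = z))
  expect_gt(raw$r["u", "v"], 0.8)
  expect_lt(abs(part$r["u", "v"]), 0.15)
})

test_that("stratified runs partition the sample and reproduce per-stratum fits", {
  set.seed(48)
  d <- data.frame(y = rbinom(60, 1, 0.5), x = rnorm(60),
                  sex = rep(c("male", "female"), each = 30))
  # two identical strata give identical estimates
  d2 <- d; d2$x[31:60] <- d$x[1:30]; d2$y[31:60] <- d$y[1:30]
  out <- stratify(d2, "sex", function(s) fit_logistic(s, "y", "x"))
  expect_equal(out$male$estimate, out$female$estimate, tolerance = 1e-10)
  # partition: strata disjoint, union = all rows
  sizes <- vapply(split(d, d$sex), nrow, integer(1))
  expect_equal(sum(sizes), nrow(d))
  expect_warning(stratify(d[1:12, ], "sex", nrow, min_n = 20), "skipped")
  expect_error(stratify(d, "nope", nrow), "not found")
})

test_that("sex-modified disease effects are recovered in stratified order", {
  cfg <- lean_config(seed = 49, n_cases = 400L, n_controls = 400L,
                     disease_tick_multiplier = c(male = 1.16, female = 1.05))
  co <- simulate_whole_blood_cohort(cfg)
  clk <- clock_definition("clk", co$truth$clock_cpgs)
  at <- accel_table(co$beta, co$sheet, clk)
  d <- co$sheet
  d$accel <- at$accel_epitoc_sd[match(d$sample_id, at$sample_id)]
  W <- co$truth$true_proportions
  d <- cbind(d, W[d$sample_id, c("granulocytes", "CD8T")])
  ors <- stratify(d, "sex", function(s)
    fit_logistic(s, "status", c("accel", "age_years", "granulocytes", "CD8T")))
  get_or <- function(fr) fr$odds_ratio[fr$term == "accel"]
  expect_gt(get_or(ors$male), get_or(ors$female))
})
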