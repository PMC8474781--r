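test_that("pcgt_age is the unweighted clock-CpG mean", {
  m <- rand_beta(10, 4)
  clk <- clock_definition("toy", rownames(m)[1:4])
  m[1:4, 1] <- 0; m[1:4, 2] <- 1; m[1:4, 3] <- c(0.2, 0.4, 0.2, 0.4)
  pa <- pcgt_age(m, clk)
  expect_equal(pa$pcgt_age[1:3], c(0, 1, 0.3))

  set.seed(3)
  m <- rand_beta(385, 10)
  clk <- clock_definition("full", rownames(m))
  expect_equal(pcgt_age(m, clk)$pcgt_age, oracle_col_mean(m),
               tolerance = 1e-12)

  # invariance to row and sample order
  perm_r <- sample(nrow(m)); perm_c <- sample(ncol(m))
  pa1 <- pcgt_age(m, clk)
  pa2 <- pcgt_age(m[perm_r, perm_c], clk)
  expect_equal(pa2$pcgt_age[match(pa1$sample_id, pa2$sample_id)],
               pa1$pcgt_age)

  # monotonicity: raising any clock CpG never decreases pcgt_age
  m2 <- m; m2[5, 3] <- min(1, m2[5, 3] + 0.2)
  expect_gte(pcgt_age(m2, clk)$pcgt_age[3], pa1$pcgt_age[3])
})

test_that("pcgt_age enforces clock coverage and handles missingness", {
  m <- rand_beta(10, 3)
  clk <- clock_definition("toy", c(rownames(m)[1:5], paste0("absent", 1:5)))
  expect_error(pcgt_age(m, clk, min_coverage = 0.8), "5 of 10")
  pa <- pcgt_age(m, clk, min_coverage = 0.5)
  expect_equal(pa$n_cpgs_used, rep(5L, 3))
  m[1, 1] <- NA
  pa2 <- pcgt_age(m, clk, min_coverage = 0.5)
  expect_equal(pa2$pcgt_age[1], mean(m[2:5, 1]))
  expect_equal(pa2$n_cpgs_used[1], 4L)
})

test_that("linear clock ages match the dot-product oracle and calibrate", {
  m <- rand_beta(60, 8)
  cz <- clock_definition("const", rownames(m)[1:10], weights = rep(0, 10),
                         intercept = 7.5)
  expect_equal(unname(linear_clock_age(m, cz)), rep(7.5, 8))
  c1 <- clock_definition("ident", rownames(m)[3], weights = 1)
  expect_equal(unname(linear_clock_age(m, c1)), unname(m[3, ]))

  set.seed(5)
  w <- rnorm(50)
  ck <- clock_definition("rand", rownames(m)[1:50], weights = w, intercept = 2)
  oracle <- sapply(seq_len(ncol(m)), function(j) 2 + sum(w * m[1:50, j]))
  expect_equal(unname(linear_clock_age(m, ck)), oracle, tolerance = 1e-10)

  cal <- clock_definition("cal", rownames(m)[1:50], weights = w, intercept = -1,
                          calibration = list(type = "anti_log_linear",
                                             adult_age = 20))
  lp <- oracle - 3
  expect_equal(unname(linear_clock_age(m, cal)),
               ifelse(lp < 0, 21 * exp(lp) - 1, 21 * lp + 20),
               tolerance = 1e-10)
  expect_error(linear_clock_age(m, clock_definition("nm", rownames(m)[1:3])),
               "no weights")
})

test_that("clock definition files round-trip", {
  ck <- clock_definition("demo", sprintf("cg%03d", 1:20), weights = rnorm(20),
                         intercept = 0.694,
                         calibration = list(type = "anti_log_linear",
                                            adult_age = 20))
  f <- tempfile(fileext = ".tsv")
  write_clock_definition(ck, f)
  ck2 <- read_clock_definition(f)
  expect_equal(ck2$name, "demo")
  expect_equal(unname(ck2$weights), unname(ck$weights), tolerance = 1e-12)
  expect_equal(ck2$intercept, 0.694)
  expect_equal(ck2$calibration$adult_age, 20)
  # uniform-mean clock: blank weights
  cu <- clock_definition("mean_clock", sprintf("cg%03d", 1:5))
  write_clock_definition(cu, f)
  expect_null(read_clock_definition(f)$weights)
})

test_that("age acceleration equals OLS residuals on age", {
  age <- c(40, 50, 60, 70, 80)
  est <- 0.1 + 0.002 * age
  acc <- age_acceleration(est, age)
  expect_equal(acc$residuals, rep(0, 5), tolerance = 1e-12)
  expect_equal(acc$slope, 0.002)

  est <- c(0.10, 0.13, 0.12, 0.16, 0.18)
  acc <- age_acceleration(est, age)
  expect_equal(acc$residuals, oracle_ols_resid(est, age), tolerance = 1e-12)
  expect_lt(abs(sum(acc$residuals)), 1e-8)
  expect_lt(abs(sum(acc$residuals * age)), 1e-8)

  # residuals invariant to shifting the age origin
  acc_shift <- age_acceleration(est, age - 1900)
  expect_equal(acc_shift$residuals, acc$residuals, tolerance = 1e-10)
  expect_error(age_acceleration(est, rep(50, 5)), "constant")
  expect_error(age_acceleration(est[1:2], age[1:2]), "at least 3")
})

test_that("IEAA is independent of the adjusted composition", {
  set.seed(9)
  n <- 1000
  age <- runif(n, 40, 80)
  gran <- rbeta(n, 6, 4)
  dnam_age <- age + 3 * gran + rnorm(n, 0, 2)
  cc <- data.frame(granulocytes = gran, CD8T = rbeta(n, 2, 8))
  ieaa <- intrinsic_acceleration(dnam_age, age, cc)
  expect_lt(abs(cor(ieaa, gran)), 0.05)
  # orthogonal to every regressor
  expect_lt(abs(sum(ieaa * age)), 1e-6)
  expect_lt(abs(sum(ieaa * gran)), 1e-6)
  # zero-variance cell columns reduce to plain age acceleration
  cc0 <- data.frame(a = rep(0.3, n), b = rep(0.1, n))
  expect_equal(intrinsic_acceleration(dnam_age, age, cc0),
               age_acceleration(dnam_age, age)$residuals, tolerance = 1e-10)
  expect_error(intrinsic_acceleration(dnam_age, age,
                                      data.frame(x = age, y = 2 * age)),
               "collinear|aliased")
})

test_that("EEAA reduces to age acceleration with zero immune weights and recovers injected correlation", {
  set.seed(10)
  n <- 800
  age <- runif(n, 40, 80)
  hannum <- age + rnorm(n, 0, 3)
  cells <- data.frame(CD8T = rbeta(n, 2, 8), plasmablast = rbeta(n, 1, 20),
                      CD8n = rbeta(n, 2, 10))
  iw0 <- immune_weighted_age(hannum, cells,
                             weights = c(CD8T = 0, plasmablast = 0, CD8n = 0))
  expect_equal(as.numeric(extrinsic_acceleration(iw0, age)),
               age_acceleration(hannum, age)$residuals, tolerance = 1e-12)
  iw <- immune_weighted_age(hannum, cells)
  ee <- extrinsic_acceleration(iw, age)
  expect_lt(abs(mean(ee)), 1e-8)
  expect_identical(attr(ee, "weights"), attr(iw, "weights"))
  expect_error(immune_weighted_age(hannum, cells[, 1:2]), "CD8n")

  # injected corr 0.3 between the immune-age residual and a mitotic acceleration
  z <- rnorm(n)
  accel_truth <- 0.3 * standardize_sd(age_acceleration(hannum, age)$residuals) +
    sqrt(1 - 0.3^2) * z
  r <- cor(extrinsic_acceleration(hannum, age), accel_truth)
  expect_lt(abs(r - 0.3), 0.1)
})

test_that("standardize_sd centers and scales with the n-1 SD", {
  expect_equal(standardize_sd(c(-1, 1)), c(-1, 1) / sqrt(2))
  set.seed(2)
  x <- rnorm(50, 5, 3)
  z <- standardize_sd(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # affine invariance
  for (b in c(2.5, -0.7)) {
    expect_equal(standardize_sd(3 + b * x), sign(b) * z, tolerance = 1e-12)
  }
  expect_error(standardize_sd(rep(1, 5)), "zero")
})

test_that("accel_table assembles per-sample measures with zero-mean residuals and unit-SD twins", {
  cfg <- lean_config(seed = 4)
  co <- simulate_whole_blood_cohort(cfg)
  clk <- clock_definition("clk", co$truth$clock_cpgs)
  at <- accel_table(co$beta, co$sheet, clk)
  expect_equal(nrow(at), ncol(co$beta))
  expect_true(all(at$pcgt_age >= 0 & at$pcgt_age <= 1))
  expect_lt(abs(mean(at$accel_epitoc_raw)), 1e-8)
  expect_equal(sd(at$accel_epitoc_sd), 1, tolerance = 1e-8)
})
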