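#' @importFrom stats as.formula coef pnorm qnorm vcov logLik AIC resid setNames
NULL

# tidy one fixed-effect table into the FitResult layout
.fit_result <- function(term, estimate, se, n_obs, n_subjects = NA_integer_,
                        loglik = NA_real_, aic = NA_real_, family = "gaussian") {
  z <- estimate / se
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(term = term, estimate = estimate, std_error = se,
                    ci_low = estimate - qnorm(0.975) * se,
                    ci_high = estimate + qnorm(0.975) * se,
                    z_value = z, p_value = p,
                    n_obs = n_obs, n_subjects = n_subjects,
                    log_likelihood = loglik, aic = aic,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (family == "binomial") {
    out$odds_ratio <- exp(out$estimate)
    out$or_ci_low <- exp(out$ci_low)
    out$or_ci_high <- exp(out$ci_high)
  }
  out
}

.tidy_lmer <- function(fit, n_subjects) {
  s <- summary(fit)$coefficients
  .fit_result(rownames(s), s[, "Estimate"], s[, "Std. Error"],
              n_obs = stats::nobs(fit), n_subjects = n_subjects,
              loglik = as.numeric(logLik(fit)), aic = AIC(fit))
}

.tidy_lm_like <- function(fit, family = "gaussian", n_subjects = NA_integer_) {
  s <- summary(fit)$coefficients
  .fit_result(rownames(s), s[, 1L], s[, 2L], n_obs = stats::nobs(fit),
              n_subjects = n_subjects, loglik = as.numeric(logLik(fit)),
              aic = AIC(fit), family = family)
}

#' Within-subject cell-type model of a repeated per-sample measure
#'
#' Linear mixed model for purified-cell panels: the measure (e.g. pcgtAge or
#' mean methylation) as outcome, cell type (or a binary myeloid-vs-lymphoid
#' lineage term) as predictor, and a random intercept per subject.  REML
#' estimates with Wald (normal-approximation) p-values.  If the random
#' effect variance is estimated singular the model falls back to a
#' fixed-effects fit with a warning.
#'
#' @param values Per-sample measure, aligned to `sheet` rows.
#' @param sheet Sample sheet with `subject_id`, `cell_type_label` and (for
#'   the lineage contrast) `lineage`.
#' @param contrast `"celltype"` (each type against `reference`) or
#'   `"lineage"` (myeloid relative to lymphoid).
#' @param reference Reference cell type for the celltype contrast.
#' @return FitResult data.frame (one row per fixed-effect term).
#' @export
fit_lmm_celltype <- function(values, sheet, contrast = c("celltype", "lineage"),
                             reference = "CD8T") {
  contrast <- match.arg(contrast)
  d <- data.frame(y = as.numeric(values),
                  subject = factor(sheet$subject_id),
                  stringsAsFactors = FALSE)
  if (nlevels(d$subject) < 2L) stop("need at least 2 subjects")
  if (contrast == "celltype") {
    d$x <- stats::relevel(factor(sheet$cell_type_label), ref = reference)
  } else {
    d$x <- factor(sheet$lineage, levels = c("lymphoid", "myeloid"))
  }
  if (nlevels(d$x) < 2L) stop("need at least 2 cell types / lineages")
  fit <- tryCatch(
    suppressMessages(lme4::lmer(y ~ x + (1 | subject), data = d, REML = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    out <- .tidy_lmer(fit, n_subjects = nlevels(d$subject))
  } else {
    warning("singular random-effect variance; falling back to fixed-effects fit")
    out <- .tidy_lm_like(stats::lm(y ~ x, data = d),
                         n_subjects = nlevels(d$subject))
  }
  out$term <- sub("^x", "", out$term)
  out
}

#' Paired difference (classical paired t)
#'
#' @param values_a,values_b Per-subject paired values.
#' @param conf_level Confidence level.
#' @return A list with `mean_difference`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p_value`, `n_pairs`, and `degenerate` (TRUE when the differences have
#'   zero variance with nonzero mean, in which case p is undefined).
#' @export
paired_difference <- function(values_a, values_b, conf_level = 0.95) {
  ok <- stats::complete.cases(values_a, values_b)
  d <- values_a[ok] - values_b[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0) {
    return(list(mean_difference = mean(d), ci_low = mean(d), ci_high = mean(d),
                t = if (mean(d) == 0) 0 else NA_real_, df = n - 1L,
                p_value = NA_real_, n_pairs = n, degenerate = mean(d) != 0))
  }
  tt <- stats::t.test(values_a[ok], values_b[ok], paired = TRUE,
                      conf.level = conf_level)
  list(mean_difference = unname(tt$estimate), ci_low = tt$conf.int[1L],
       ci_high = tt$conf.int[2L], t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, n_pairs = n,
       degenerate = FALSE)
}

# standardize the flagged columns of a model frame (sample SD, n-1)
.per_sd_scale <- function(d, per_sd) {
  for (v in per_sd) d[[v]] <- standardize_sd(as.numeric(d[[v]]))
  d
}

#' Logistic association model
#'
#' Maximum-likelihood logit fit of a binary outcome on the supplied terms;
#' predictors flagged `per_sd` are standardized (zero mean, unit sample SD)
#' on the complete-case analysis sample before fitting.  Wald CIs and odds
#' ratios are reported per term.  Perfect separation is detected (monotone
#' likelihood / boundary fit) and flagged via attribute `separation` and a
#' warning rather than silently returning a diverged fit.
#'
#' @param data Data.frame holding outcome and predictors.
#' @param outcome Name of the binary (0/1) outcome column.
#' @param terms Character vector of predictor terms (may include `a:b`).
#' @param per_sd Subset of `terms` to standardize per SD.
#' @return FitResult data.frame; attribute `fit` holds the glm object.
#' @export
fit_logistic <- function(data, outcome, terms, per_sd = character(0)) {
  vars <- unique(c(outcome, unlist(strsplit(terms, ":", fixed = TRUE))))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y)) != 2L) stop("outcome must have both classes present")
  d <- .per_sd_scale(d, intersect(per_sd, colnames(d)))
  f <- as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, d)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  separation <- sep_warn &&
    any(stats::fitted(fit) > 1 - 1e-6 | stats::fitted(fit) < 1e-6)
  if (separation)
    warning("possible perfect separation: fitted probabilities at the boundary ",
            "(monotone likelihood); estimates and SEs are unreliable")
  out <- .tidy_lm_like(fit, family = "binomial")
  attr(out, "fit") <- fit
  attr(out, "separation") <- separation
  out
}

#' Bidirectional stepwise model selection by AIC
#'
#' Greedy bidirectional search from the locked model: at each step the
#' single add/drop move with the largest AIC decrease is applied (ties
#' broken by term name order), stopping when no move improves AIC by more
#' than `1e-6`.  Locked terms are always retained.  All fits (ML) use the
#' complete-case intersection over the locked and candidate variables, so
#' AICs are comparable.
#'
#' @param data Data.frame.
#' @param outcome Outcome column name.
#' @param locked Terms always in the model (exposure + design covariates).
#' @param candidates Terms eligible to enter/leave.
#' @param family `"binomial"` or `"gaussian"`.
#' @return A list with `selected_terms`, `formula`, `fit`, and `trace`
#'   (data.frame of accepted moves with the AIC after each).
#' @export
stepwise_aic <- function(data, outcome, locked, candidates,
                         family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  all_vars <- unique(c(outcome,
                       unlist(strsplit(c(locked, candidates), ":", fixed = TRUE))))
  d <- data[stats::complete.cases(data[, all_vars, drop = FALSE]),
            all_vars, drop = FALSE]
  fit_terms <- function(terms) {
    rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
    f <- as.formula(paste(outcome, "~", rhs))
    if (family == "binomial") stats::glm(f, data = d, family = stats::binomial())
    else stats::glm(f, data = d, family = stats::gaussian())
  }
  in_model <- character(0)
  cur_fit <- fit_terms(locked)
  cur_aic <- AIC(cur_fit)
  trace <- data.frame(step = 0L, move = "start", term = NA_character_,
                      aic = cur_aic, stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    adds <- sort(setdiff(candidates, in_model))
    drops <- sort(in_model)
    moves <- data.frame(
      move = c(rep("add", length(adds)), rep("drop", length(drops))),
      term = c(adds, drops), stringsAsFactors = FALSE)
    if (nrow(moves) == 0L) break
    moves$aic <- vapply(seq_len(nrow(moves)), function(i) {
      trial <- if (moves$move[i] == "add") c(in_model, moves$term[i])
               else setdiff(in_model, moves$term[i])
      AIC(fit_terms(c(locked, trial)))
    }, numeric(1))
    moves <- moves[order(moves$aic, moves$term), , drop = FALSE]
    if (moves$aic[1L] >= cur_aic - 1e-6) break
    step_i <- step_i + 1L
    if (moves$move[1L] == "add") in_model <- c(in_model, moves$term[1L])
    else in_model <- setdiff(in_model, moves$term[1L])
    cur_aic <- moves$aic[1L]
    trace <- rbind(trace, data.frame(step = step_i, move = moves$move[1L],
                                     term = moves$term[1L], aic = cur_aic,
                                     stringsAsFactors = FALSE))
  }
  selected <- c(locked, sort(in_model))
  fit <- fit_terms(selected)
  list(selected_terms = selected, selected_candidates = sort(in_model),
       formula = stats::formula(fit), fit = fit, trace = trace,
       aic = AIC(fit))
}

#' Symptom-progression mixed model with an acceleration-by-time interaction
#'
#' Linear mixed model of repeated exam scores with fixed effects for the
#' acceleration measure (standardized per SD over subjects), time since
#' baseline, their interaction, and any configured baseline covariates, and
#' random intercept plus random slope on time per subject.  The interaction
#' estimate is the yearly change in the exam score per SD of acceleration.
#' A singular random-slope variance triggers a fall back to random intercept
#' only, then to ordinary least squares, with warnings.
#'
#' @param visits Visit-level data.frame with `subject_id` and a time column.
#' @param outcome Exam-score column name.
#' @param accel Acceleration column name (constant within subject).
#' @param time Time column name (years since baseline).
#' @param covariates Additional fixed-effect terms (baseline covariates).
#' @param per_sd_accel Standardize the acceleration per SD over subjects.
#' @param random `"intercept_slope"` (default) or `"intercept"`.
#' @return FitResult data.frame; attribute `fit` carries the model object.
#' @export
fit_lmm_progression <- function(visits, outcome, accel,
                                time = "visit_time_years",
                                covariates = character(0),
                                per_sd_accel = TRUE,
                                random = c("intercept_slope", "intercept")) {
  random <- match.arg(random)
  vars <- unique(c(outcome, accel, time, "subject_id",
                   unlist(strsplit(covariates, ":", fixed = TRUE))))
  d <- visits[stats::complete.cases(visits[, vars, drop = FALSE]), vars,
              drop = FALSE]
  nv <- table(d$subject_id)
  if (max(nv) < 2L) stop("every subject has a single visit; no within-subject time")
  if (sum(nv >= 2L) < 2L) stop("need repeated visits on at least 2 subjects")
  if (per_sd_accel) {
    subj_vals <- tapply(d[[accel]], d$subject_id, function(x) x[1L])
    mu <- mean(subj_vals); s <- stats::sd(subj_vals)
    if (!is.finite(s) || s <= 0) stop("acceleration has zero SD over subjects")
    d[[accel]] <- (d[[accel]] - mu) / s
  }
  fx <- paste(c(paste0(accel, " * ", time), covariates), collapse = " + ")
  re <- if (random == "intercept_slope")
    paste0("(1 + ", time, " | subject_id)") else "(1 | subject_id)"
  f <- as.formula(paste(outcome, "~", fx, "+", re))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4))))),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    out <- .tidy_lmer(fit, n_subjects = length(unique(d$subject_id)))
  } else if (random == "intercept_slope") {
    warning("singular random-slope fit; refitting with random intercept only")
    return(fit_lmm_progression(d, outcome, accel, time, covariates,
                               per_sd_accel = FALSE, random = "intercept"))
  } else {
    warning("singular random-intercept fit; falling back to OLS")
    ols <- stats::lm(as.formula(paste(outcome, "~", fx)), data = d)
    fit <- ols
    out <- .tidy_lm_like(ols, n_subjects = length(unique(d$subject_id)))
  }
  attr(out, "fit") <- fit
  attr(out, "interaction_term") <- grep(":", out$term, value = TRUE)[1L]
  out
}

#' Pearson correlation panel, optionally partialed on covariates
#'
#' Pairwise Pearson correlations over the supplied columns.  With
#' `partial_on`, every column is first residualized on the covariates
#' (ordinary least squares on the complete cases), so the panel shows
#' partial correlations given those covariates.  P-values come from the t
#' transform `t = r sqrt((n-2)/(1-r^2))`.  Zero-variance columns are flagged
#' and their rows/columns set to missing.
#'
#' @param columns Data.frame of named per-sample numeric columns.
#' @param partial_on Optional data.frame of covariate columns (same rows).
#' @return A list with matrices `r`, `p_value`, `n`, and `degenerate`
#'   (names of zero-variance columns).
#' @export
pearson_corr_matrix <- function(columns, partial_on = NULL) {
  x <- as.data.frame(columns)
  if (!is.null(partial_on)) {
    cc <- stats::complete.cases(cbind(x, partial_on))
    x <- x[cc, , drop = FALSE]
    Z <- stats::model.matrix(~ ., data = as.data.frame(partial_on)[cc, , drop = FALSE])
    x[] <- lapply(x, function(col) stats::resid(stats::lm.fit(Z, col)))
  }
  degenerate <- names(x)[vapply(x, function(col)
    stats::var(col, na.rm = TRUE) == 0, logical(1))]
  m <- ncol(x)
  r <- p <- nmat <- matrix(NA_real_, m, m, dimnames = list(names(x), names(x)))
  for (i in seq_len(m)) for (j in seq_len(i)) {
    if (names(x)[i] %in% degenerate || names(x)[j] %in% degenerate) next
    ok <- stats::complete.cases(x[[i]], x[[j]])
    n <- sum(ok)
    if (n < 3L) next
    rij <- stats::cor(x[[i]][ok], x[[j]][ok])
    r[i, j] <- r[j, i] <- rij
    nmat[i, j] <- nmat[j, i] <- n
    if (i == j) { p[i, j] <- NA_real_; next }
    tstat <- rij * sqrt((n - 2) / max(1 - rij^2, 1e-300))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = nmat, degenerate = degenerate)
}

#' Run a fit separately within strata
#'
#' @param data Data.frame.
#' @param by Stratification column (e.g. `sex` or `status`).
#' @param fit_fun Function taking the stratum data.frame.
#' @param min_n Minimum stratum size; smaller strata are skipped with a
#'   warning.
#' @return Named list of fit results, one per retained stratum.
#' @export
stratify <- function(data, by, fit_fun, min_n = 10L) {
  if (!by %in% colnames(data)) stop("stratification column not found: ", by)
  strata <- split(data, data[[by]])
  out <- list()
  for (nm in names(strata)) {
    if (nrow(strata[[nm]]) < min_n) {
      warning("stratum '", nm, "' below minimum n (", nrow(strata[[nm]]),
              " < ", min_n, "); skipped")
      next
    }
    out[[nm]] <- fit_fun(strata[[nm]])
  }
  out
}
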