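#' Build a cell-type reference from purified methylomes
#'
#' For each cell type, CpGs are ranked by the two-sample t-statistic of that
#' type's purified samples against all others; the top `n_per_type`
#' hypermethylated and top `n_per_type` hypomethylated CpGs per type are
#' pooled, and the reference stores each type's mean methylome over the
#' pooled set.
#'
#' @param purified Beta matrix of purified-cell samples.
#' @param sheet Sample sheet with `cell_type_label` (and matching
#'   `sample_id`s).
#' @param n_per_type Markers per direction per cell type.
#' @param lineage Optional named lineage tags carried into the reference.
#' @return A list of class `cell_reference` with `cell_types`, `cpg_ids`,
#'   `mean_betas` (CpG x type) and `lineage`.
#' @export
build_reference <- function(purified, sheet, n_per_type = 50L, lineage = NULL) {
  al <- align_samples(purified, sheet)
  labels <- as.character(al$sheet$cell_type_label)
  types <- unique(labels)
  if (length(types) < 2L) stop("need at least 2 cell types")
  counts <- table(labels)
  if (any(counts < 2L))
    stop("cell type(s) with fewer than 2 purified samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  b <- al$beta
  selected <- character(0)
  for (ty in types) {
    in_ty <- labels == ty
    t_stat <- .row_t_stat(b[, in_ty, drop = FALSE], b[, !in_ty, drop = FALSE])
    ord <- order(t_stat, decreasing = TRUE)
    hyper <- rownames(b)[ord[seq_len(min(n_per_type, length(ord)))]]
    hypo <- rownames(b)[rev(ord)[seq_len(min(n_per_type, length(ord)))]]
    selected <- union(selected, c(hyper, hypo))
  }
  mean_betas <- vapply(types, function(ty)
    rowMeans(b[selected, labels == ty, drop = FALSE]), numeric(length(selected)))
  rownames(mean_betas) <- selected
  structure(list(cell_types = types, cpg_ids = selected,
                 mean_betas = mean_betas, lineage = lineage,
                 n_per_type = n_per_type),
            class = "cell_reference")
}

# Welch-style per-row two-sample t statistics (in-group vs out-group)
.row_t_stat <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- apply(a, 1L, stats::var, na.rm = TRUE)
  vb <- apply(b, 1L, stats::var, na.rm = TRUE)
  se <- sqrt(va / na + vb / nb)
  se[se < 1e-12] <- 1e-12
  (ma - mb) / se
}

#' Estimate leukocyte proportions by constrained projection
#'
#' Houseman-style reference-based deconvolution: per sample, finds the
#' non-negative weight vector minimizing `||b - R w||^2` over the shared
#' CpGs, subject to the weights summing to one (default) or at most one.
#' The sum constraint is enforced through an augmented equation with a large
#' penalty weight (1e4), solved by non-negative least squares; in
#' `sum-le-one` mode a slack component absorbs the remainder.
#'
#' @param beta Beta matrix of mixed (whole-blood) samples.
#' @param ref A [build_reference()] result.
#' @param mode `"sum-to-one"` (default) or `"sum-le-one"`.
#' @param penalty Augmented-row weight for the sum constraint.
#' @return A data.frame with `sample_id`, one proportion column per cell
#'   type, and `fit_residual_norm` (residual over the shared CpGs).
#' @export
estimate_proportions <- function(beta, ref, mode = c("sum-to-one", "sum-le-one"),
                                 penalty = 1e4) {
  mode <- match.arg(mode)
  shared <- intersect(ref$cpg_ids, rownames(beta))
  K <- length(ref$cell_types)
  if (length(shared) < 10L * K)
    stop(sprintf("only %d reference CpGs shared with the beta matrix; need >= %d",
                 length(shared), 10L * K))
  R <- ref$mean_betas[shared, , drop = FALSE]
  if (qr(R)$rank < K)
    stop("reference is rank-deficient at the shared CpGs; cell types not identifiable")
  slack <- mode == "sum-le-one"
  A <- if (slack) cbind(R, 0) else R
  A <- rbind(A, penalty)
  n <- ncol(beta)
  W <- matrix(NA_real_, n, K, dimnames = list(colnames(beta), ref$cell_types))
  rn <- numeric(n)
  for (j in seq_len(n)) {
    bj <- beta[shared, j]
    if (anyNA(bj)) bj[is.na(bj)] <- mean(bj, na.rm = TRUE)
    sol <- pracma::lsqnonneg(A, c(bj, penalty))
    w <- sol$x[seq_len(K)]
    W[j, ] <- w
    rn[j] <- sqrt(sum((bj - drop(R %*% w))^2))
  }
  data.frame(sample_id = colnames(beta), W, fit_residual_norm = rn,
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write a cell-type reference file
#'
#' Delimited text: `cpg_id` plus one mean-methylation column per cell type.
#'
#' @param path File path.
#' @param lineage Optional named lineage tags.
#' @return A `cell_reference`.
#' @export
read_cell_reference <- function(path, lineage = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(list(cell_types = colnames(m), cpg_ids = rownames(m),
                 mean_betas = m, lineage = lineage, n_per_type = NA_integer_),
            class = "cell_reference")
}

#' @rdname read_cell_reference
#' @param ref A `cell_reference`.
#' @export
write_cell_reference <- function(ref, path) {
  df <- data.frame(cpg_id = ref$cpg_ids, ref$mean_betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Linear-predictor surrogate for count-style cell estimates
#'
#' Computes `intercept + sum_j w_j beta_j` per sample for each target
#' population in a predictor table (naive/exhausted T-cell and plasmablast
#' style estimates).  These are surrogates: the coefficients are
#' user-supplied, not the published count estimators.
#'
#' @param beta Beta matrix.
#' @param predictors Either a path to a delimited predictor file (columns
#'   `cpg_id` then one column per population, with an `(Intercept)` row) or
#'   a list of `list(intercept=, weights=named vector)` per population.
#' @param max_missing Maximum tolerated fraction of absent predictor CpGs.
#' @return Data.frame of per-sample surrogate counts, one column per
#'   population, with attribute `surrogate = TRUE`.
#' @export
estimate_extended_counts <- function(beta, predictors, max_missing = 0.2) {
  if (is.character(predictors)) {
    df <- utils::read.delim(predictors, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ridx <- df[[1L]] == "(Intercept)"
    pops <- colnames(df)[-1L]
    predictors <- lapply(pops, function(p)
      list(intercept = if (any(ridx)) df[[p]][ridx][1L] else 0,
           weights = stats::setNames(df[[p]][!ridx], df[[1L]][!ridx])))
    names(predictors) <- pops
  }
  out <- data.frame(sample_id = colnames(beta), stringsAsFactors = FALSE)
  for (pop in names(predictors)) {
    pr <- predictors[[pop]]
    w <- pr$weights[!is.na(pr$weights)]
    present <- intersect(names(w), rownames(beta))
    if (length(present) < (1 - max_missing) * length(w))
      stop(sprintf("predictor '%s': %d of %d CpGs missing (> %.0f%% allowed)",
                   pop, length(w) - length(present), length(w),
                   100 * max_missing))
    sub <- beta[present, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      miss <- is.na(sub[i, ])
      if (any(miss)) sub[i, miss] <- mean(sub[i, ], na.rm = TRUE)
    }
    out[[pop]] <- drop(crossprod(sub, w[present])) + (pr$intercept %||% 0)
  }
  attr(out, "surrogate") <- TRUE
  out
}
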