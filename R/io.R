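#' Read a CpG-by-sample beta-value matrix
#'
#' Reads a delimited text file (TSV or CSV, autodetected from the extension)
#' whose first column holds CpG probe identifiers and whose header row holds
#' sample identifiers, and returns a validated numeric matrix of methylation
#' beta fractions.  A GEO series-matrix dialect is also supported: only the
#' block between `!series_matrix_table_begin` and `!series_matrix_table_end`
#' is parsed; all metadata lines are ignored.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"` (default; series-matrix if the file contains
#'   a `!series_matrix_table_begin` marker), `"plain"` or `"geo"`.
#' @param na_tokens Character vector of cell values mapped to missing.
#' @return A numeric matrix with CpG identifiers as rownames and sample
#'   identifiers as colnames; all non-missing values lie in \[0, 1\].
#' @export
read_beta_matrix <- function(path, dialect = c("auto", "plain", "geo"),
                             na_tokens = c("NA", "NaN", "NULL", "null", "")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    head_lines <- readLines(path, n = 200L, warn = FALSE)
    dialect <- if (any(grepl("^!series_matrix_table_begin", head_lines)))
      "geo" else "plain"
  }
  if (dialect == "geo") {
    lines <- readLines(path, warn = FALSE)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("malformed series-matrix file: table block not found in ", path)
    txt <- lines[(beg + 1L):(end - 1L)]
    df <- utils::read.delim(text = txt, check.names = FALSE,
                            colClasses = "character", quote = "\"")
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                            colClasses = "character", quote = "\"")
  }
  .df_to_beta_matrix(df, na_tokens, where = path)
}

.df_to_beta_matrix <- function(df, na_tokens, where = "input") {
  if (ncol(df) < 2L) stop("beta matrix needs a probe column plus samples: ", where)
  cpg_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(cpg_ids))
    stop("duplicate probe identifiers in ", where, ": ",
         paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in ", where, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals %in% na_tokens] <- NA_character_
  suppressWarnings(num <- array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at probe %s, sample %s in %s",
                 vals[bad[1L, 1L], bad[1L, 2L]], cpg_ids[bad[1L, 1L]],
                 sample_ids[bad[1L, 2L]], where))
  dimnames(num) <- list(cpg_ids, sample_ids)
  validate_beta_matrix(num, where = where)
}

#' Validate a beta matrix
#'
#' Checks unique dimnames and that every non-missing value lies in
#' \[0, 1\] within tolerance `tol`; values inside the tolerance band are
#' clamped onto the boundary.
#'
#' @param beta Numeric matrix, CpGs in rows, samples in columns.
#' @param tol Numeric tolerance for boundary violations.
#' @param where Label used in error messages.
#' @return The validated (possibly clamped) matrix.
#' @export
validate_beta_matrix <- function(beta, tol = 1e-9, where = "beta matrix") {
  if (!is.matrix(beta) || !is.numeric(beta)) stop(where, " must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop(where, " must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta))) stop("duplicate probe identifiers in ", where)
  if (anyDuplicated(colnames(beta))) stop("duplicate sample identifiers in ", where)
  out <- which(!is.na(beta) & (beta < -tol | beta > 1 + tol), arr.ind = TRUE)
  if (nrow(out) > 0L)
    stop(sprintf("beta value %g out of [0,1] at probe %s, sample %s in %s",
                 beta[out[1L, 1L], out[1L, 2L]], rownames(beta)[out[1L, 1L]],
                 colnames(beta)[out[1L, 2L]], where))
  beta[!is.na(beta) & beta < 0] <- 0
  beta[!is.na(beta) & beta > 1] <- 1
  beta
}

#' Write a beta matrix as delimited text
#'
#' @param beta Validated beta matrix.
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  beta <- validate_beta_matrix(beta)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(cpg_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' One row per (sample, visit).  Column types are left as read; model code
#' coerces what it needs.
#'
#' @param path Path to a TSV/CSV sample sheet with a `sample_id` column.
#' @return A data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("sample sheet lacks a sample_id column: ", path)
  df
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(sheet, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a beta matrix with a sample sheet
#'
#' Restricts both objects to their common samples, in a single shared order
#' (the beta matrix's column order restricted to the intersection).  Dropped
#' samples are reported with a warning.
#'
#' @param beta Beta matrix (samples in columns).
#' @param sheet Sample sheet with a `sample_id` column.
#' @return A list with elements `beta` and `sheet`.
#' @export
align_samples <- function(beta, sheet) {
  ids_b <- colnames(beta)
  ids_s <- as.character(sheet$sample_id)
  common <- ids_b[ids_b %in% ids_s]
  if (length(common) == 0L) stop("no samples shared between beta matrix and sample sheet")
  dropped <- c(setdiff(ids_b, common), setdiff(ids_s, common))
  if (length(dropped) > 0L)
    warning("dropping ", length(dropped), " unmatched sample(s): ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  list(beta = beta[, common, drop = FALSE],
       sheet = sheet[match(common, ids_s), , drop = FALSE])
}

#' Technical-variation principal components from control probes
#'
#' Computes the leading principal components of the sample-by-probe matrix of
#' control-probe methylation levels, after per-probe mean imputation of
#' missing values and column mean-centering.  Scores are deterministic up to
#' sign; the sign of each component is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param controls Control-probe matrix (probes in rows, samples in columns).
#' @param n_components Number of components to retain.
#' @return A list with `scores` (samples x components), `sample_ids`, and
#'   `explained_variance_fractions` (fractions of total variance, over the
#'   full spectrum, for the retained components).
#' @export
technical_pcs <- function(controls, n_components = 2L) {
  x <- t(controls)                       # samples x probes
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(#probes, #samples)")
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) stop("control-probe matrix is constant; no variance to decompose")
  pc <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {               # sign convention: top loading positive
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  ev <- pc$sdev^2
  colnames(sc) <- paste0("PC", seq_len(k))
  list(scores = sc, sample_ids = rownames(x),
       explained_variance_fractions = (ev / sum(ev))[seq_len(k)])
}
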