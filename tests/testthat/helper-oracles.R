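# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and pracma): brute-force loops, normal equations,
# an independently written active-set NNLS, and simplex grid search.

# random CpG x sample beta matrix with dimnames
rand_beta <- function(n_cpg, n_s) {
  m <- matrix(runif(n_cpg * n_s), n_cpg, n_s,
              dimnames = list(sprintf("cg%04d", seq_len(n_cpg)),
                              sprintf("s%03d", seq_len(n_s))))
  m
}

# per-column mean by explicit loop-and-divide
oracle_col_mean <- function(m) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    s <- 0; n <- 0
    for (i in seq_len(nrow(m))) {
      v <- m[i, j]
      if (!is.na(v)) { s <- s + v; n <- n + 1 }
    }
    out[j] <- s / n
  }
  out
}

# OLS residuals by the normal equations, no lm()
oracle_ols_resid <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  drop(y - X1 %*% beta)
}

# Lawson-Hanson active-set NNLS, written independently of pracma
oracle_nnls <- function(A, b, tol = 1e-12, max_iter = 10 * ncol(A)^2 + 100) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(t(A) %*% (b - A %*% x))
  iter <- 0
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      z[P] <- drop(solve(t(A[, P, drop = FALSE]) %*% A[, P, drop = FALSE],
                         t(A[, P, drop = FALSE]) %*% b))
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P[x[P] < tol]] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(t(A) %*% (b - A %*% x))
  }
  x
}

# exhaustive grid search over the 2-simplex (two free weights)
oracle_grid_2mix <- function(R, b, step = 1e-3) {
  w1 <- seq(0, 1, by = step)
  best <- c(NA, NA); best_obj <- Inf
  for (w in w1) {
    obj <- sum((b - R %*% c(w, 1 - w))^2)
    if (obj < best_obj) { best_obj <- obj; best <- c(w, 1 - w) }
  }
  best
}

# Pearson correlation from the raw covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  num / den
}

# lean simulation config for fast tests
lean_config <- function(seed = 1L, ...) {
  sim_config(n_cpgs_total = 1400L, n_marker_per_type = 15L, seed = seed, ...)
}

# write a small beta matrix file and return the path
write_tmp_beta <- function(m, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  write_beta_matrix(m, f)
  f
}
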