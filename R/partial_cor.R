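#' Spearman and partial Spearman correlation
#'
#' The pipeline's comparison statistic throughout. `spearman_corr()` is the
#' plain rank correlation with average-rank tie handling (ties are routine:
#' model RDM vectors are binary). `partial_spearman()` rank-transforms all
#' vectors, residualizes `x` and `y` on the covariate ranks plus an
#' intercept by least squares, and returns the Pearson correlation of the
#' residuals; with no covariates it reduces exactly to `spearman_corr()`.
#'
#' @param x,y Numeric vectors of equal length (>= 3), typically
#'   upper-triangle RDM vectors in the shared pair order.
#' @param covariates List of numeric vectors of the same length (possibly
#'   empty) whose rank-explained variance is removed from both `x` and `y`.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_corr <- function(x, y) {
  check_cor_input(x, y)
  stats::cor(rank_avg(x), rank_avg(y))
}

#' @rdname spearman_corr
#' @export
partial_spearman <- function(x, y, covariates = list()) {
  check_cor_input(x, y)
  if (length(covariates) == 0) return(spearman_corr(x, y))
  Q <- covariate_basis(covariates, n = length(x))
  rx <- residualize(rank_avg(x), Q)
  ry <- residualize(rank_avg(y), Q)
  tol <- 1e-12 * length(x)
  if (sum(rx^2) <= tol || sum(ry^2) <= tol) {
    stop("degenerate partial correlation: residual variance is numerically zero",
         call. = FALSE)
  }
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

rank_avg <- function(x) rank(x, ties.method = "average")

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in correlation input", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  invisible(NULL)
}

# Orthonormal basis for span{1, rank(covariate_1), ...}. Residualizing
# against this basis is least-squares residualization on covariate ranks
# plus intercept.
covariate_basis <- function(covariates, n) {
  Z <- cbind(rep(1, n))
  for (cv in covariates) {
    if (length(cv) != n) stop("covariate length mismatch", call. = FALSE)
    Z <- cbind(Z, rank_avg(cv))
  }
  qr_z <- qr(Z)
  qr.Q(qr_z)[, seq_len(qr_z$rank), drop = FALSE]
}

# Residual of y (vector or column matrix) after projection on orthonormal Q.
residualize <- function(y, Q) {
  y - Q %*% crossprod(Q, y)
}

# Column-wise partial Spearman of a pre-ranked matrix against a pre-ranked
# vector, sharing one covariate basis. Internal fast path for time courses:
# `ranked_mat` is pairs x times with each column already rank-transformed,
# `ranked_x` the ranked model vector, `Q` from covariate_basis() (or NULL
# for plain Spearman). Columns whose residual variance collapses give NA.
partial_cor_cols <- function(ranked_mat, ranked_x, Q = NULL) {
  if (!is.null(Q)) {
    ranked_mat <- residualize(ranked_mat, Q)
    ranked_x <- drop(residualize(ranked_x, Q))
  } else {
    ranked_mat <- sweep(ranked_mat, 2, colMeans(ranked_mat))
    ranked_x <- ranked_x - mean(ranked_x)
  }
  ss_y <- colSums(ranked_mat^2)
  ss_x <- sum(ranked_x^2)
  tol <- 1e-12 * nrow(ranked_mat)
  out <- drop(crossprod(ranked_mat, ranked_x)) / sqrt(ss_y * ss_x)
  out[ss_y <= tol] <- NA_real_
  if (ss_x <= tol) out[] <- NA_real_
  unname(out)
}

# Column-wise average ranks. Tie-free columns (the generic case for
# continuous data) take a sort-index shortcut; ties fall back to rank().
rank_columns <- function(m) {
  n <- nrow(m)
  vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (anyDuplicated(v)) {
      rank_avg(v)
    } else {
      r <- numeric(n)
      r[order(v)] <- seq_len(n)
      r
    }
  }, numeric(n))
}
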