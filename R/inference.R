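#' Sign-flip cluster-based permutation test on subject time courses
#'
#' Nonparametric group test for time courses whose group mean is zero under
#' the null (correlation values, or differences of correlations). Each
#' permutation multiplies every subject's whole time course by a random
#' sign and recomputes the group mean. The cluster-forming threshold at
#' each time point is the 95th percentile of that time point's permutation
#' distribution of |mean|; observed clusters are maximal runs of
#' supra-threshold time points, scored by their length (number of
#' contiguous significant time points) against the permutation distribution
#' of maximal cluster lengths, with an add-one estimator.
#'
#' @param values Subjects x times numeric matrix (>= 2 subjects), or the
#'   output of [timecourse_matrix()].
#' @param times Time stamps in ms (taken from `attr(values, "times")` if
#'   present).
#' @param n_perm Number of sign permutations (default 1024). If `n_perm`
#'   exceeds `2^nsubjects`, all sign assignments are enumerated exactly
#'   instead (with a warning).
#' @param alpha Cluster significance level (default 0.05).
#' @param seed Integer seed for the random sign draws.
#' @param threshold_percentile Cluster-forming percentile (default 95).
#' @return An object of class `cluster_result`: list with `clusters` (data
#'   frame `start_ms`, `end_ms`, `size`, `p`, `significant`), the per-time
#'   `threshold`, the observed `statistic` (group mean), `times`, `n_perm`,
#'   `alpha`.
#' @export
sign_flip_cluster_test <- function(values, times = NULL, n_perm = 1024,
                                   alpha = 0.05, seed = 1,
                                   threshold_percentile = 95) {
  values <- as.matrix(values)
  if (is.null(times)) times <- attr(values, "times")
  if (is.null(times)) times <- seq_len(ncol(values))
  nsub <- nrow(values)
  if (nsub < 2) stop("need at least 2 subjects", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite values in time courses", call. = FALSE)
  stopifnot(n_perm >= 100, length(times) == ncol(values))

  exhaustive <- nsub <= 30 && n_perm > 2^nsub
  if (exhaustive) {
    warning("n_perm = ", n_perm, " exceeds 2^", nsub,
            " sign assignments; enumerating exhaustively", call. = FALSE)
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), nsub)))
    signs <- grid
    n_perm <- nrow(signs)
  } else {
    set.seed(as.integer(seed))
    signs <- matrix(sample(c(-1, 1), n_perm * nsub, replace = TRUE),
                    n_perm, nsub)
  }

  perm_means <- (signs %*% values) / nsub               # n_perm x times
  threshold <- apply(abs(perm_means), 2, stats::quantile,
                     probs = threshold_percentile / 100, names = FALSE)
  observed <- colMeans(values)
  supra <- abs(observed) > threshold

  obs_clusters <- run_clusters(supra)
  # null distribution of the maximal cluster length under the same
  # per-time thresholds
  null_max <- apply(abs(perm_means) > rep(threshold, each = n_perm), 1,
                    max_run_length)
  ps <- vapply(obs_clusters$size, function(sz) {
    (1 + sum(null_max >= sz)) / (n_perm + 1)
  }, numeric(1))

  clusters <- data.frame(
    start_ms = times[obs_clusters$start],
    end_ms = times[obs_clusters$end],
    size = obs_clusters$size,
    p = ps,
    significant = ps < alpha
  )
  structure(list(clusters = clusters, threshold = threshold,
                 statistic = observed, times = times, supra = supra,
                 n_perm = n_perm, alpha = alpha,
                 threshold_percentile = threshold_percentile),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", nrow(x$clusters), "cluster(s),",
      sum(x$clusters$significant), "significant at alpha =", x$alpha,
      "(", x$n_perm, "permutations )\n")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

# maximal runs of TRUE in a logical vector
run_clusters <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  list(start = starts[keep], end = ends[keep], size = r$lengths[keep])
}

max_run_length <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

#' Inter-subject noise ceiling for RDM series
#'
#' Bounds on the RDM correlation any model could attain given inter-subject
#' variability. At each time point, the upper bound is the mean over
#' subjects of the Spearman correlation between each subject's RDM vector
#' and the all-subject mean vector; the lower bound uses the leave-one-out
#' mean instead. Time points where a subject's RDM vector is constant give
#' a missing value (recorded, not dropped).
#'
#' @param subject_series List of >= 3 [rdm_series] sharing stimulus set and
#'   time axis.
#' @return Data frame with columns `time_ms`, `lower`, `upper`.
#' @export
noise_ceiling <- function(subject_series) {
  stopifnot(length(subject_series) >= 3)
  ss <- subject_series[[1]]$stimulus_set
  times <- subject_series[[1]]$times
  for (s in subject_series) {
    if (!identical(s$stimulus_set$id, ss$id) || !identical(s$times, times)) {
      stop("all subjects must share stimulus set and time axis", call. = FALSE)
    }
  }
  nsub <- length(subject_series)
  nt <- length(times)
  upper <- lower <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    V <- vapply(subject_series, function(s) s$vectors[, t],
                numeric(nrow(subject_series[[1]]$vectors)))
    vsum <- rowSums(V)
    up <- lo <- rep(NA_real_, nsub)
    for (s in seq_len(nsub)) {
      v <- V[, s]
      if (stats::var(v) == 0) next  # degenerate subject/time: stays NA
      gm <- vsum / nsub
      loo <- (vsum - v) / (nsub - 1)
      if (stats::var(gm) > 0) up[s] <- stats::cor(v, gm, method = "spearman")
      if (stats::var(loo) > 0) lo[s] <- stats::cor(v, loo, method = "spearman")
    }
    upper[t] <- mean(up)
    lower[t] <- mean(lo)
  }
  data.frame(time_ms = times, lower = lower, upper = upper)
}
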