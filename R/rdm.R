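#' Representational dissimilarity matrices
#'
#' An `rdm` is a square, symmetric, zero-diagonal matrix of pairwise
#' dissimilarities over a [stimulus_set]. It is the pipeline's universal
#' currency: data RDMs, layer RDMs and idealized model RDMs all share this
#' container and the same fixed stimulus order.
#'
#' @param d Square numeric matrix of dissimilarities.
#' @param stimulus_set The [stimulus_set] indexing the rows/columns.
#' @param validate Check invariants (symmetry to 1e-9, zero diagonal,
#'   finiteness)? Default `TRUE`.
#' @return An object of class `rdm`: the matrix with the stimulus set
#'   attached as an attribute.
#' @export
rdm <- function(d, stimulus_set, validate = TRUE) {
  assert_stimulus_set(stimulus_set)
  d <- as.matrix(d)
  n <- n_stimuli(stimulus_set)
  if (!is.numeric(d) || nrow(d) != n || ncol(d) != n) {
    stop("dissimilarity matrix is ", nrow(d), "x", ncol(d),
         " but the stimulus set has ", n, " stimuli", call. = FALSE)
  }
  dimnames(d) <- list(stimulus_set$id, stimulus_set$id)
  out <- structure(d, stimulus_set = stimulus_set, class = c("rdm", "matrix", "array"))
  if (validate) validate_rdm(out)
  out
}

#' @rdname rdm
#' @param x Object to test or validate.
#' @export
is_rdm <- function(x) inherits(x, "rdm")

#' @rdname rdm
#' @export
validate_rdm <- function(x) {
  if (!is_rdm(x)) stop("not an `rdm` object", call. = FALSE)
  if (!all(is.finite(x))) stop("RDM contains non-finite entries", call. = FALSE)
  if (max(abs(x - t(x))) > 1e-9) {
    stop("RDM is asymmetric beyond tolerance 1e-9 (max |d - t(d)| = ",
         format(max(abs(x - t(x)))), ")", call. = FALSE)
  }
  if (any(diag(x) != 0)) stop("RDM diagonal must be exactly 0", call. = FALSE)
  invisible(x)
}

rdm_stimulus_set <- function(x) attr(x, "stimulus_set")

#' Compute an RDM from a feature matrix
#'
#' Pairwise correlation distances between the row patterns of a
#' stimuli-by-features matrix: `1 - Pearson r` (the convention for network
#' activations) or `1 - Spearman r` (the convention for sensor patterns).
#'
#' @param features A [feature_matrix], or a plain numeric matrix with one
#'   row per stimulus (then `stimulus_set` must be given).
#' @param metric `"one_minus_pearson"` or `"one_minus_spearman"`.
#' @param stimulus_set Required when `features` is a bare matrix.
#' @return An [rdm]. Entries lie in `[0, 2]`.
#' @details A row with zero variance has no defined correlation with any
#'   other row; such rows raise an error naming the stimulus rather than
#'   being dropped, since a silent drop would desynchronize stimulus order.
#' @export
compute_rdm <- function(features,
                        metric = c("one_minus_pearson", "one_minus_spearman"),
                        stimulus_set = NULL) {
  metric <- match.arg(metric)
  if (inherits(features, "feature_matrix")) {
    stimulus_set <- attr(features, "stimulus_set")
    values <- unclass(features)
  } else {
    if (is.null(stimulus_set)) {
      stop("`stimulus_set` is required when `features` is a bare matrix",
           call. = FALSE)
    }
    values <- as.matrix(features)
  }
  assert_stimulus_set(stimulus_set)
  if (nrow(values) != n_stimuli(stimulus_set)) {
    stop("feature matrix has ", nrow(values), " rows but the stimulus set has ",
         n_stimuli(stimulus_set), " stimuli", call. = FALSE)
  }
  if (nrow(values) < 3) stop("need at least 3 stimuli", call. = FALSE)
  if (ncol(values) < 2) stop("need at least 2 features", call. = FALSE)
  if (!all(is.finite(values))) stop("feature matrix has non-finite entries", call. = FALSE)
  rv <- apply(values, 1, stats::var)
  if (any(rv == 0)) {
    stop("zero-variance feature row(s) for stimulus: ",
         paste(stimulus_set$id[rv == 0], collapse = ", "), call. = FALSE)
  }
  if (metric == "one_minus_spearman") {
    values <- t(apply(values, 1, rank_avg))
  }
  d <- 1 - stats::cor(t(values))
  d <- (d + t(d)) / 2   # symmetrize away rounding noise
  # snap float dust to the exact endpoints so identical (or exactly
  # anticorrelated) patterns stay tied under rank transforms
  d[abs(d) < 1e-12] <- 0
  d[abs(d - 2) < 1e-12] <- 2
  diag(d) <- 0
  rdm(d, stimulus_set)
}

#' Upper-triangle vectorization of an RDM
#'
#' Returns the `n(n-1)/2` off-diagonal dissimilarities in fixed row-major
#' pair order: (1,2), (1,3), ..., (1,n), (2,3), ... This single ordering is
#' shared by every correlation computed downstream.
#'
#' @param x An [rdm] (or plain symmetric matrix).
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
vectorize_upper <- function(x) {
  m <- unclass(x)
  t(m)[lower.tri(m)]
}

#' @rdname vectorize_upper
#' @param v Vector as produced by [vectorize_upper()].
#' @param stimulus_set Stimulus set of the reconstructed RDM.
#' @export
reconstruct_rdm <- function(v, stimulus_set) {
  n <- n_stimuli(stimulus_set)
  if (length(v) != n * (n - 1) / 2) {
    stop("vector length ", length(v), " does not match n(n-1)/2 = ",
         n * (n - 1) / 2, call. = FALSE)
  }
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v      # fills column-major = row-major pairs of t(m)
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  rdm(m, stimulus_set)
}

# index pairs (i, j), i < j, in the vectorization order above
upper_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Category-averaged 3x3 RDM
#'
#' Averages the parent RDM within each block of category pairs. Diagonal
#' (within-category) cells are the mean over off-diagonal entries of that
#' block only; the RDM's zero diagonal never enters any mean.
#'
#' @param x An [rdm] whose stimulus set has at least 2 stimuli per category.
#' @return A 3x3 symmetric matrix (class `category_rdm`) with dimnames the
#'   category labels.
#' @export
category_average_rdm <- function(x) {
  validate_rdm(x)
  ss <- rdm_stimulus_set(x)
  cats <- stimulus_categories()
  counts <- table(factor(ss$label, levels = cats))
  if (any(counts < 2)) {
    stop("within-category mean undefined: category with <2 stimuli: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  d3 <- matrix(NA_real_, 3, 3, dimnames = list(cats, cats))
  m <- unclass(x)
  for (a in seq_along(cats)) {
    for (b in seq_along(cats)) {
      ia <- which(ss$label == cats[a])
      ib <- which(ss$label == cats[b])
      block <- m[ia, ib, drop = FALSE]
      if (a == b) {
        d3[a, b] <- mean(block[row(block) != col(block)])
      } else {
        d3[a, b] <- mean(block)
      }
    }
  }
  structure(d3, class = c("category_rdm", "matrix", "array"))
}

#' Classical (Torgerson) MDS embedding of an RDM
#'
#' Deterministic classical scaling on double-centered squared
#' dissimilarities, for visualizing RDM geometry. Coordinates are centered
#' at the origin and defined up to orthogonal rotation/reflection.
#'
#' @param x An [rdm].
#' @param k Embedding dimension, `1 <= k < n`.
#' @return A stimuli-by-`k` coordinate matrix with stimulus ids as rownames.
#' @export
classical_mds_embed <- function(x, k = 2) {
  validate_rdm(x)
  n <- nrow(x)
  stopifnot(k >= 1, k < n)
  coords <- stats::cmdscale(unclass(x), k = k)
  if (ncol(coords) < k) {  # rank-deficient geometry: pad with zero axes
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  rownames(coords) <- rdm_stimulus_set(x)$id
  coords
}
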