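# Independent oracles and small fixtures shared across tests. Each oracle
# deliberately avoids the code path it checks.

# random symmetric zero-diagonal RDM over a balanced stimulus set
random_rdm <- function(n_per_category, seed = 1, scale = 1) {
  set.seed(seed)
  ss <- balanced_stimulus_set(n_per_category)
  n <- nrow(ss)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, scale)
  m <- m + t(m)
  rdm(m, ss)
}

# first-order partial correlation via the recursive closed form on rank
# correlations (the textbook identity, not residualization)
oracle_partial_one <- function(x, y, z) {
  rxy <- cor(rank(x), rank(y))
  rxz <- cor(rank(x), rank(z))
  ryz <- cor(rank(y), rank(z))
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# partial Spearman via lm() residuals on ranks -- independent of the
# package's QR-projection implementation
oracle_partial_lm <- function(x, y, covariates) {
  Z <- do.call(cbind, lapply(covariates, rank))
  rx <- resid(lm(rank(x) ~ Z))
  ry <- resid(lm(rank(y) ~ Z))
  cor(rx, ry)
}

oracle_commonality <- function(neural, system, target, other) {
  oracle_partial_lm(neural, system, list(other))^2 -
    oracle_partial_lm(neural, system, list(target, other))^2
}

# category block means by explicit index enumeration
oracle_category_means <- function(m, labels) {
  cats <- c("face", "pareidolia", "object")
  out <- matrix(NA_real_, 3, 3, dimnames = list(cats, cats))
  for (a in cats) for (b in cats) {
    acc <- c()
    for (i in which(labels == a)) for (j in which(labels == b)) {
      if (i != j) acc <- c(acc, m[i, j])
    }
    out[a, b] <- mean(acc)
  }
  out
}

# exhaustive sign-flip cluster p-values for tiny subject counts
oracle_sign_flip_exhaustive <- function(values, threshold_percentile = 95) {
  nsub <- nrow(values)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), nsub)))
  perm_means <- (signs %*% values) / nsub
  thresh <- apply(abs(perm_means), 2, quantile,
                  probs = threshold_percentile / 100, names = FALSE)
  observed <- colMeans(values)
  supra <- abs(observed) > thresh
  r <- rle(supra)
  sizes <- r$lengths[r$values]
  null_max <- apply(abs(perm_means) > rep(thresh, each = nrow(signs)), 1,
                    function(m) { rr <- rle(m); if (any(rr$values)) max(rr$lengths[rr$values]) else 0L })
  vapply(sizes, function(sz) (1 + sum(null_max >= sz)) / (nrow(signs) + 1),
         numeric(1))
}
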