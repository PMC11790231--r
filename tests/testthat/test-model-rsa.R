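test_that("idealized model RDMs have the hypothesized block structure", {
  ss <- balanced_stimulus_set(32)
  mf <- build_ideal_rdm(ss, "pareidolia_faces")
  mo <- build_ideal_rdm(ss, "pareidolia_objects")
  lab <- ss$label
  for (d in list(mf, mo)) {
    expect_true(all(unclass(d) %in% c(0, 1)))
    expect_identical(dim(unclass(d)), c(96L, 96L))
    # within-category 0, face-object 1 in both hypotheses
    for (cat in stimulus_categories()) {
      blk <- unclass(d)[lab == cat, lab == cat]
      expect_true(all(blk == 0))
    }
    expect_true(all(unclass(d)[lab == "face", lab == "object"] == 1))
  }
  expect_true(all(unclass(mf)[lab == "face", lab == "pareidolia"] == 0))
  expect_true(all(unclass(mf)[lab == "pareidolia", lab == "object"] == 1))
  expect_true(all(unclass(mo)[lab == "face", lab == "pareidolia"] == 1))
  expect_true(all(unclass(mo)[lab == "pareidolia", lab == "object"] == 0))
  # the two hypotheses differ exactly on the pareidolia cross blocks
  diff <- unclass(mf) != unclass(mo)
  in_cross <- outer(lab, lab, function(a, b)
    (a == "pareidolia") != (b == "pareidolia"))
  expect_true(all(diff == in_cross))
  expect_error(build_ideal_rdm(stimulus_set(c("a", "b", "c"),
                                            c("face", "face", "object"))),
               "missing category")
})

test_that("model RDMs are invariant to stimulus order up to the permutation", {
  ss <- balanced_stimulus_set(3)
  set.seed(4)
  perm <- sample(nrow(ss))
  ssp <- stimulus_set(ss$id[perm], ss$label[perm])
  m1 <- build_ideal_rdm(ss, "pareidolia_faces")
  m2 <- build_ideal_rdm(ssp, "pareidolia_faces")
  expect_equal(unclass(m1)[perm, perm], unclass(m2), ignore_attr = TRUE)
})

test_that("Spearman between the two 32/32/32 model vectors equals the block-count phi", {
  ss <- balanced_stimulus_set(32)
  vf <- vectorize_upper(build_ideal_rdm(ss, "pareidolia_faces"))
  vo <- vectorize_upper(build_ideal_rdm(ss, "pareidolia_objects"))
  # brute-force phi from enumerated block counts
  n11 <- sum(vf == 1 & vo == 1); n00 <- sum(vf == 0 & vo == 0)
  n10 <- sum(vf == 1 & vo == 0); n01 <- sum(vf == 0 & vo == 1)
  expect_identical(c(n11, n10, n01, n00), c(1024L, 1024L, 1024L, 1488L))
  cnt <- as.numeric(c(n11, n10, n01, n00))
  phi <- (cnt[1] * cnt[4] - cnt[2] * cnt[3]) /
    sqrt((cnt[1] + cnt[2]) * (cnt[3] + cnt[4]) * (cnt[1] + cnt[3]) * (cnt[2] + cnt[4]))
  expect_equal(spearman_corr(vf, vo), phi, tolerance = 1e-12)
})

test_that("spearman_corr matches a rank-then-Pearson oracle and rank invariances", {
  set.seed(11)
  for (k in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    expect_equal(spearman_corr(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  x <- rnorm(40)
  expect_equal(spearman_corr(x, exp(3 * x)), 1)        # monotone transform
  expect_equal(spearman_corr(x, -x), -1)               # reverse ranks
  expect_error(spearman_corr(x, rep(1, 40)), "constant")
})

test_that("partial_spearman reduces to spearman_corr without covariates", {
  set.seed(21)
  for (k in 1:100) {
    x <- rnorm(30); y <- rnorm(30)
    expect_identical(partial_spearman(x, y, list()), spearman_corr(x, y))
  }
})

test_that("partial_spearman matches the recursive closed form for one covariate", {
  set.seed(31)
  for (k in 1:200) {
    x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
    expect_equal(partial_spearman(x, y, list(z)), oracle_partial_one(x, y, z),
                 tolerance = 1e-10)
  }
})

test_that("partial_spearman removes covariate-driven association", {
  set.seed(41)
  n <- 4560
  z <- rnorm(n)
  y <- rank(z) + rnorm(n, sd = 200)
  x <- rnorm(n)
  expect_lt(abs(partial_spearman(x, y, list(z))), 0.1)
})

test_that("degenerate partials error rather than returning a number", {
  z <- seq_len(30)
  x <- as.numeric(z)      # x is an exact monotone function of covariate z
  y <- rnorm(30)
  expect_error(partial_spearman(x, y, list(z)), "degenerate")
})

test_that("time-wise model RSA recovers self-similar series and rejects noise", {
  ss <- balanced_stimulus_set(8)
  mf <- build_ideal_rdm(ss, "pareidolia_faces")
  mo <- build_ideal_rdm(ss, "pareidolia_objects")
  times <- seq(0, 50, by = 5)
  set.seed(5)
  base <- vectorize_upper(mf)
  # tie-preserving scaling: data is an exact monotone image of the model
  vecs_exact <- sapply(seq_along(times), function(t) base * (1 + 0.1 * t))
  tc_exact <- model_rsa_timecourse(rdm_series(vecs_exact, times, ss, "exact"),
                                   mf, list(mo))
  expect_true(all(tc_exact$rho > 0.999))
  # tiny additive jitter breaks the model's ties, which caps the rank
  # correlation below 1; self-similarity must still dominate
  vecs <- sapply(times, function(t) pmax(base + rnorm(length(base), sd = 0.01), 0))
  tc <- model_rsa_timecourse(rdm_series(vecs, times, ss, "selfsim"), mf, list(mo))
  expect_true(all(tc$rho > 0.8))
  expect_identical(tc$time_ms, times)
  # pure noise at the full pair count: mean |rho| small
  ss96 <- balanced_stimulus_set(32)
  m96 <- build_ideal_rdm(ss96, "pareidolia_faces")
  o96 <- build_ideal_rdm(ss96, "pareidolia_objects")
  set.seed(6)
  noise_vecs <- matrix(runif(4560 * 20), 4560, 20)
  sn <- rdm_series(noise_vecs, seq(0, 95, by = 5), ss96, "noise")
  tcn <- model_rsa_timecourse(sn, m96, list(o96))
  expect_lt(mean(abs(tcn$rho)), 0.05)
})

test_that("plural and singular time-course paths agree", {
  sim <- simulate_subject_rdm_series(
    generator_config(n_subjects = 2, n_per_category = 8,
                     times = seq(0, 300, 25), seed = 7))
  mf <- sim$ground_truth$model_face
  mo <- sim$ground_truth$model_object
  both <- model_rsa_timecourses(sim$series, list(mf, mo))
  single <- model_rsa_timecourse(sim$series, mf, list(mo))
  expect_equal(both$rho[both$model == "pareidolia_faces"], single$rho)
})
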