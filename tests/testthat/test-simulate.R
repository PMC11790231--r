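test_that("generator defaults encode the study conditions", {
  cfg <- generator_config()
  expect_identical(cfg$n_subjects, 22)
  expect_identical(cfg$n_per_category, 32)
  expect_identical(cfg$times, seq(-100, 1000, by = 5))
  expect_length(cfg$times, 221)
  expect_identical(cfg$peak_face_ms, 165)
  expect_identical(cfg$peak_object_ms, 255)
})

test_that("simulated series satisfy RDM invariants for every seed", {
  for (seed in 1:5) {
    sim <- simulate_subject_rdm_series(
      generator_config(n_subjects = 2, n_per_category = 6,
                       times = seq(0, 100, 25), seed = seed))
    for (s in sim$series) {
      expect_true(all(is.finite(s$vectors)))
      expect_true(all(s$vectors >= 0))
      d <- rdm_at(s, 50)
      expect_equal(unclass(d), t(unclass(d)))
      expect_identical(unname(diag(unclass(d))), rep(0, 18))
    }
  }
})

test_that("regeneration from the same config is bit-identical", {
  cfg <- generator_config(n_subjects = 3, n_per_category = 6,
                          times = seq(0, 200, 20), seed = 99)
  s1 <- simulate_subject_rdm_series(cfg)
  s2 <- simulate_subject_rdm_series(cfg)
  expect_identical(s1$series[[3]]$vectors, s2$series[[3]]$vectors)
  lf1 <- simulate_layer_features(layer_schedule_config(n_layers = 3, seed = 5,
                                                       n_features = 32))
  lf2 <- simulate_layer_features(layer_schedule_config(n_layers = 3, seed = 5,
                                                       n_features = 32))
  expect_identical(unclass(lf1$layers[[2]]), unclass(lf2$layers[[2]]))
  fx1 <- make_saliency_fixture(height = 30, width = 30, window = 6, stride = 3, seed = 2)
  fx2 <- make_saliency_fixture(height = 30, width = 30, window = 6, stride = 3, seed = 2)
  expect_identical(fx1$image, fx2$image)
})

test_that("noiseless single-bump series is maximally model-correlated at the peak", {
  cfg <- generator_config(n_subjects = 1, n_per_category = 8, noise_sd = 0,
                          amp_object = 0, times = seq(-100, 500, 5), seed = 1)
  sim <- simulate_subject_rdm_series(cfg)
  tc <- model_rsa_timecourse(sim$series[[1]], sim$ground_truth$model_face,
                             list(sim$ground_truth$model_object))
  # rank correlation is amplitude-blind: without noise every time point is
  # an exact monotone image of the model, so rho(t) sits at its maximum
  # (1) everywhere, including the planted peak
  expect_equal(tc$rho[tc$time_ms == 165], max(tc$rho))
  expect_equal(tc$rho[tc$time_ms == 165], 1, tolerance = 1e-12)
  expect_identical(cfg$times[which.max(sim$ground_truth$w_face)], 165)
  # with noise, amplitude matters again and the peak is recovered uniquely
  cfgn <- generator_config(n_subjects = 4, n_per_category = 8, noise_sd = 0.3,
                           amp_object = 0, times = seq(-100, 500, 5), seed = 2)
  simn <- simulate_subject_rdm_series(cfgn)
  tcn <- summarize_timecourse(
    model_rsa_timecourse(simn$series, simn$ground_truth$model_face,
                         list(simn$ground_truth$model_object)))
  expect_lt(abs(tcn$time_ms[which.max(tcn$mean)] - 165), 20)
})

test_that("noisy upper-triangle entries average to the ground-truth mixture", {
  cfg <- generator_config(n_subjects = 220, n_per_category = 4,
                          times = c(165, 255), noise_sd = 0.5, seed = 12)
  sim <- simulate_subject_rdm_series(cfg)
  stack <- sapply(sim$series, function(s) s$vectors[, 1])
  expect_equal(rowMeans(stack), sim$ground_truth$noiseless[, 1],
               tolerance = 0.02)
})

test_that("rho at the planted peak decreases strictly with noise", {
  rho_at_peak <- sapply(c(0.2, 0.6, 1.2), function(ns) {
    cfg <- generator_config(n_subjects = 4, n_per_category = 8, noise_sd = ns,
                            baseline = 4, times = seq(100, 300, 10), seed = 33)
    sim <- simulate_subject_rdm_series(cfg)
    tc <- model_rsa_timecourse(sim$series, sim$ground_truth$model_face,
                               list(sim$ground_truth$model_object))
    mean(tc$rho[tc$time_ms == 160])
  })
  expect_true(all(diff(rho_at_peak) < 0))
})

test_that("configs with heavy zero-clipping are rejected", {
  expect_error(simulate_subject_rdm_series(
    generator_config(n_subjects = 1, n_per_category = 6, baseline = 0.2,
                     noise_sd = 0.5, times = c(0, 5))),
    "clip")
})

test_that("layer generator realizes the scheduled geometry", {
  ss <- balanced_stimulus_set(8)
  # zero scatter, zero noise: RDM is an exact monotone image of the mixture
  cfg0 <- layer_schedule_config(n_layers = 2, w_face = c(0.9, 0.1),
                                w_object = c(0.1, 0.9), n_features = 64,
                                scatter = 0, seed = 9)
  sim0 <- simulate_layer_features(cfg0, ss)
  for (l in 1:2) {
    d <- compute_rdm(sim0$layers[[l]])
    mix <- sim0$ground_truth$mixture_3x3[[l]]
    lab <- ss$label
    mixv <- mix[cbind(lab[rsadyn:::upper_pairs(24)[, 1]],
                      lab[rsadyn:::upper_pairs(24)[, 2]])]
    expect_equal(cor(vectorize_upper(d), mixv, method = "spearman"), 1)
  }
  # object-loaded late layers favor the object model
  cfg <- layer_schedule_config(n_layers = 4, w_face = c(0.9, 0.6, 0.3, 0.05),
                               w_object = c(0.05, 0.3, 0.6, 0.9),
                               n_features = 128, scatter = 0.05, seed = 10)
  sim <- simulate_layer_features(cfg, ss)
  mf <- build_ideal_rdm(ss, "pareidolia_faces")
  mo <- build_ideal_rdm(ss, "pareidolia_objects")
  d_late <- compute_rdm(sim$layers[[4]])
  rho_o <- partial_spearman(vectorize_upper(mo), vectorize_upper(d_late),
                            list(vectorize_upper(mf)))
  rho_f <- partial_spearman(vectorize_upper(mf), vectorize_upper(d_late),
                            list(vectorize_upper(mo)))
  expect_gt(rho_o, rho_f)
  expect_error(layer_schedule_config(n_features = 2), "n_features")
})
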