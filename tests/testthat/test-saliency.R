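test_that("constant scorer gives an all-zero attribution map", {
  img <- matrix(runif(30 * 30), 30, 30)
  scorer <- function(x) c(face = 1, object = 2)
  attr_map <- occlusion_attribution(img, scorer, "face", window = 10, stride = 5)
  expect_true(all(unclass(attr_map) == 0))
})

test_that("whole-image window reduces to a single occlusion delta", {
  set.seed(1)
  img <- matrix(runif(20 * 20), 20, 20)
  w <- matrix(rnorm(20 * 20), 20, 20)
  scorer <- function(x) c(face = sum(w * x), object = 0)
  base <- 0.5
  attr_map <- occlusion_attribution(img, scorer, "face", window = 20,
                                    stride = 20, baseline = base)
  expected <- sum(w * img) - sum(w * base)
  expect_equal(unique(as.vector(unclass(attr_map))), expected, tolerance = 1e-12)
})

test_that("linear scorer with non-overlapping tiles matches the analytic tile contribution", {
  set.seed(2)
  img <- matrix(runif(24 * 24), 24, 24)
  w <- matrix(rnorm(24 * 24), 24, 24)
  scorer <- function(x) c(face = sum(w * x), object = -sum(w * x))
  attr_map <- occlusion_attribution(img, scorer, "face", window = 8, stride = 8,
                                    baseline = 0)
  for (r0 in c(1, 9, 17)) for (c0 in c(1, 9, 17)) {
    tile <- sum(w[r0:(r0 + 7), c0:(c0 + 7)] * img[r0:(r0 + 7), c0:(c0 + 7)])
    expect_equal(unclass(attr_map)[r0:(r0 + 7), c0:(c0 + 7)],
                 matrix(tile, 8, 8), tolerance = 1e-12)
  }
})

test_that("attribution is linear in the scorer", {
  set.seed(3)
  img <- matrix(runif(18 * 18), 18, 18)
  w1 <- matrix(rnorm(18 * 18), 18, 18)
  w2 <- matrix(rnorm(18 * 18), 18, 18)
  s1 <- function(x) c(face = sum(w1 * x))
  s2 <- function(x) c(face = sum(w2 * x))
  s12 <- function(x) c(face = 2 * sum(w1 * x) - 3 * sum(w2 * x))
  args <- list(class_label = "face", window = 6, stride = 4, baseline = 0.2)
  a1 <- do.call(occlusion_attribution, c(list(img, s1), args))
  a2 <- do.call(occlusion_attribution, c(list(img, s2), args))
  a12 <- do.call(occlusion_attribution, c(list(img, s12), args))
  expect_equal(unclass(a12), 2 * unclass(a1) - 3 * unclass(a2), tolerance = 1e-10)
})

test_that("edge clamping leaves no pixel uncovered", {
  img <- matrix(runif(25 * 31), 25, 31)   # extents not multiples of stride
  scorer <- function(x) c(face = sum(x))
  attr_map <- occlusion_attribution(img, scorer, "face", window = 7, stride = 5)
  expect_true(all(attr(attr_map, "coverage")))
})

test_that("non-finite scorer output names the window position", {
  img <- matrix(runif(12 * 12), 12, 12)
  s_orig <- sum(img)
  scorer <- function(x) c(face = if (sum(x) < s_orig - 0.5) NaN else 1)
  expect_error(
    occlusion_attribution(img, scorer, "face", window = 4, stride = 4,
                          baseline = 0),
    "window at")
})

test_that("mask ratios count strictly positive pixels and respect invariances", {
  m <- matrix(c(1, -1, 0, 2, 0, -3, 4, 5, 0), 3, 3)
  mask_all <- matrix(TRUE, 3, 3)
  expect_equal(mask_positive_ratio(m, mask_all), 4 / 9)
  expect_equal(mask_positive_ratio(matrix(1, 3, 3), mask_all), 1)
  expect_equal(mask_positive_ratio(matrix(c(0, -1), 3, 4)[, 1:3], mask_all), 0)
  # invariant to strictly positive rescaling
  expect_equal(mask_positive_ratio(0.01 * m, mask_all),
               mask_positive_ratio(100 * m, mask_all))
  expect_error(mask_positive_ratio(m, matrix(FALSE, 3, 3)), "empty")
  # planted 40% positives
  m2 <- matrix(-1, 10, 10); m2[1:40] <- 1
  expect_equal(mask_positive_ratio(m2, matrix(TRUE, 10, 10)), 0.4)
})

test_that("ratio aggregation computes group means and SEMs", {
  df <- data.frame(stimulus = c("a", "b"), mask = "Eyes", class = "face",
                   ratio = c(0.5, 0.7))
  agg <- aggregate_ratios(df)
  expect_equal(agg$mean, 0.6)
  expect_equal(agg$sem, sd(c(0.5, 0.7)) / sqrt(2))
  expect_equal(agg$sem, 0.1, tolerance = 1e-12)
  # identical ratios give SEM 0; single stimulus flags NA
  df2 <- rbind(df, data.frame(stimulus = c("a", "b"), mask = "Mouth",
                              class = "face", ratio = c(0.3, 0.3)),
               data.frame(stimulus = "a", mask = "Face", class = "object",
                          ratio = 0.2))
  agg2 <- aggregate_ratios(df2)
  expect_equal(agg2$sem[agg2$mask == "Mouth"], 0)
  expect_true(is.na(agg2$sem[agg2$mask == "Face"]))
  expect_identical(agg2$n[agg2$mask == "Face"], 1L)
})

test_that("saliency fixtures plant eye-concentrated face evidence", {
  fx <- make_saliency_fixture(height = 60, width = 60, window = 10, stride = 5,
                              seed = 4)
  expect_false(any(fx$masks$Eyes & fx$masks$Mouth))
  expect_false(any(fx$masks$Face & fx$masks$OutsideFace))
  af <- occlusion_attribution(fx$image, fx$scorer, "face", window = 10,
                              stride = 5, baseline = 0)
  ao <- occlusion_attribution(fx$image, fx$scorer, "object", window = 10,
                              stride = 5, baseline = 0)
  exp_r <- fx$expected_ratios
  for (i in seq_len(nrow(exp_r))) {
    amap <- if (exp_r$class[i] == "face") af else ao
    expect_equal(mask_positive_ratio(amap, fx$masks[[exp_r$mask[i]]]),
                 exp_r$ratio[i],
                 info = paste(exp_r$mask[i], exp_r$class[i]))
  }
  expect_equal(mask_positive_ratio(af, fx$masks$Eyes), 1)
  expect_lt(mask_positive_ratio(ao, fx$masks$Eyes), 1)
  # Face ratio is the pixel-count-weighted mean over a partition of Face
  rest <- fx$masks$Face & !fx$masks$Eyes & !fx$masks$Mouth
  parts <- list(fx$masks$Eyes, fx$masks$Mouth, rest)
  weighted <- sum(vapply(parts, function(p) {
    mask_positive_ratio(af, p) * sum(p)
  }, numeric(1))) / sum(fx$masks$Face)
  expect_equal(mask_positive_ratio(af, fx$masks$Face), weighted, tolerance = 1e-12)
})

test_that("symmetric scorer makes face and object ratios identical", {
  fx <- make_saliency_fixture(height = 40, width = 40, window = 8, stride = 4,
                              seed = 5)
  w <- matrix(1, 40, 40)
  scorer <- function(img) c(face = sum(w * img), object = sum(w * img))
  af <- occlusion_attribution(fx$image, scorer, "face", window = 8, stride = 4,
                              baseline = 0)
  ao <- occlusion_attribution(fx$image, scorer, "object", window = 8, stride = 4,
                              baseline = 0)
  for (mk in names(fx$masks)) {
    expect_identical(mask_positive_ratio(af, fx$masks[[mk]]),
                     mask_positive_ratio(ao, fx$masks[[mk]]))
  }
})
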