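#' Generator configuration for synthetic subject RDM series
#'
#' Defaults emulate the study conditions the pipeline targets: 22 subjects,
#' a balanced 32/32/32 stimulus set, RDMs from -100 to 1000 ms in 5 ms
#' steps (221 time points), and two-stage category dynamics -- a
#' face-likeness component peaking at 165 ms and an object-likeness
#' component peaking at 255 ms. Ground-truth dissimilarity at time t is
#'
#' \deqn{D(t) = baseline + w_F(t) M_F + w_O(t) M_O}
#'
#' with Gaussian weight bumps `w_F`, `w_O` of the configured amplitudes and
#' width (plus an optional sustained late plateau on the object weight),
#' and `M_F`, `M_O` the two idealized model RDMs. Subjects receive
#' independent additive Gaussian noise on upper-triangle entries.
#'
#' @param n_subjects Number of subjects (default 22).
#' @param n_per_category Stimuli per category (default 32).
#' @param times Time grid in ms (default `seq(-100, 1000, by = 5)`).
#' @param peak_face_ms,peak_object_ms Peak latencies of the two weight
#'   bumps (defaults 165 and 255 ms).
#' @param amp_face,amp_object Bump amplitudes (unitless dissimilarity,
#'   defaults 1).
#' @param width_ms Gaussian width (sd) of both bumps (default 50 ms).
#' @param baseline Constant dissimilarity floor (default 1.5), keeping
#'   noise-induced clipping at zero rare.
#' @param object_plateau Amplitude of an optional sustained late object
#'   component (smooth ramp centered 200 ms; default 0, so the recoverable
#'   ground truth is exactly the two peak latencies).
#' @param noise_sd Subject noise sd on dissimilarities (default 0.5).
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 22, n_per_category = 32,
                             times = seq(-100, 1000, by = 5),
                             peak_face_ms = 165, peak_object_ms = 255,
                             amp_face = 1, amp_object = 1,
                             width_ms = 50, baseline = 1.5,
                             object_plateau = 0, noise_sd = 0.5, seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_per_category = n_per_category,
              times = as.numeric(times), peak_face_ms = peak_face_ms,
              peak_object_ms = peak_object_ms, amp_face = amp_face,
              amp_object = amp_object, width_ms = width_ms,
              baseline = baseline, object_plateau = object_plateau,
              noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(n_subjects >= 1, n_per_category >= 2,
            all(diff(cfg$times) > 0), width_ms > 0,
            amp_face >= 0, amp_object >= 0, noise_sd >= 0)
  class(cfg) <- "generator_config"
  cfg
}

weight_curves <- function(cfg) {
  t <- cfg$times
  w_face <- cfg$amp_face * exp(-(t - cfg$peak_face_ms)^2 / (2 * cfg$width_ms^2))
  w_object <- cfg$amp_object * exp(-(t - cfg$peak_object_ms)^2 / (2 * cfg$width_ms^2)) +
    cfg$object_plateau * stats::plogis((t - 200) / 30)
  list(w_face = w_face, w_object = w_object)
}

#' Simulate subject RDM time series
#'
#' @param cfg A [generator_config()].
#' @return List with `series` (one [rdm_series] per subject),
#'   `ground_truth` (times, the two weight curves, the two model RDMs, the
#'   noiseless pair-by-time dissimilarity matrix) and the `config` echoed
#'   for provenance. Regeneration from the same config is bit-identical.
#' @details If the expected fraction of entries clipped at zero (from the
#'   Gaussian noise model and the ground-truth dissimilarities) exceeds 1%,
#'   the configuration is rejected with an error: heavier clipping would
#'   distort the dissimilarity semantics the downstream analyses assume.
#' @export
simulate_subject_rdm_series <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  ss <- balanced_stimulus_set(cfg$n_per_category)
  m_face <- build_ideal_rdm(ss, "pareidolia_faces")
  m_object <- build_ideal_rdm(ss, "pareidolia_objects")
  vf <- vectorize_upper(m_face)
  vo <- vectorize_upper(m_object)
  w <- weight_curves(cfg)
  # noiseless ground truth, pairs x times
  gt <- cfg$baseline + outer(vf, w$w_face) + outer(vo, w$w_object)
  if (any(gt < 0)) {
    stop("configuration yields negative ground-truth dissimilarities", call. = FALSE)
  }
  if (cfg$noise_sd > 0) {
    expected_clip <- mean(stats::pnorm(-gt / cfg$noise_sd))
    if (expected_clip > 0.01) {
      stop("configuration would clip ", sprintf("%.1f%%", 100 * expected_clip),
           " of dissimilarities at zero (tolerance 1%); raise `baseline` or ",
           "lower `noise_sd`", call. = FALSE)
    }
  }
  set.seed(cfg$seed)
  series <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    noise <- if (cfg$noise_sd > 0) {
      matrix(stats::rnorm(length(gt), sd = cfg$noise_sd), nrow(gt), ncol(gt))
    } else 0
    vecs <- pmax(gt + noise, 0)
    series[[s]] <- rdm_series(vecs, cfg$times, ss,
                              subject_id = sprintf("sub%02d", s))
  }
  list(series = series,
       ground_truth = list(times = cfg$times, w_face = w$w_face,
                           w_object = w$w_object, model_face = m_face,
                           model_object = m_object, noiseless = gt),
       config = cfg)
}

#' Layer-schedule configuration for synthetic feature matrices
#'
#' Defaults emulate a 15-layer feed-forward hierarchy in which
#' face-likeness structure dominates early layers and object-likeness
#' structure grows across depth: the face mixing weight falls linearly from
#' 0.8 to 0.2 and the object weight rises from 0.2 to 0.8.
#'
#' @param n_layers Number of layers (default 15).
#' @param w_face,w_object Mixing weight per layer for each hypothesis RDM
#'   (length `n_layers`; defaults as above).
#' @param n_features Features per layer (default 512).
#' @param scatter Within-category scatter sd relative to the category base
#'   pattern (default 0.1).
#' @param noise_sd Additional per-entry feature noise sd (default 0).
#' @param seed Integer seed.
#' @return A list of class `layer_schedule_config`.
#' @export
layer_schedule_config <- function(n_layers = 15,
                                  w_face = seq(0.8, 0.2, length.out = n_layers),
                                  w_object = seq(0.2, 0.8, length.out = n_layers),
                                  n_features = 512, scatter = 0.1,
                                  noise_sd = 0, seed = 1) {
  stopifnot(n_layers >= 1, length(w_face) == n_layers,
            length(w_object) == n_layers, all(is.finite(c(w_face, w_object))),
            n_features >= 3, scatter >= 0, noise_sd >= 0)
  structure(list(n_layers = n_layers, w_face = w_face, w_object = w_object,
                 n_features = n_features, scatter = scatter,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "layer_schedule_config")
}

#' Simulate layer-wise feature matrices with scheduled geometry mixing
#'
#' Each layer's stimuli are built from three category base patterns whose
#' pairwise Pearson correlations are `1 - scale * (w_F M3_F + w_O M3_O)`,
#' where `M3_F`, `M3_O` are the 3x3 category versions of the two hypothesis
#' RDMs. The base patterns are exact: an orthonormal zero-mean basis mixed
#' by the Cholesky factor of the target correlation matrix, so at zero
#' scatter and zero noise the sample correlation RDM is an exact affine
#' image of the scheduled model mixture. Within-category scatter and
#' feature noise then degrade it gracefully.
#'
#' @param cfg A [layer_schedule_config()].
#' @param stimulus_set Stimulus set (default the balanced 32/32/32 set).
#' @param scale Dissimilarity scale mapping mixture weights to correlation
#'   distance (default 0.45; the 3x3 target correlation matrix must stay
#'   positive definite).
#' @return List with `layers` (one [feature_matrix] per layer) and
#'   `ground_truth` (the schedule and per-layer target mixture RDMs).
#' @export
simulate_layer_features <- function(cfg = layer_schedule_config(),
                                    stimulus_set = balanced_stimulus_set(),
                                    scale = 0.45) {
  stopifnot(inherits(cfg, "layer_schedule_config"))
  assert_stimulus_set(stimulus_set)
  cats <- stimulus_categories()
  cat_idx <- match(stimulus_set$label, cats)
  n <- n_stimuli(stimulus_set)
  m3 <- function(hypothesis) {
    cell <- matrix(1, 3, 3, dimnames = list(cats, cats))
    diag(cell) <- 0
    if (hypothesis == "pareidolia_faces") {
      cell["face", "pareidolia"] <- cell["pareidolia", "face"] <- 0
    } else {
      cell["object", "pareidolia"] <- cell["pareidolia", "object"] <- 0
    }
    cell
  }
  m3f <- m3("pareidolia_faces"); m3o <- m3("pareidolia_objects")
  set.seed(cfg$seed)
  # orthonormal zero-mean basis rows (constant direction removed)
  qr_b <- qr(cbind(1, matrix(stats::rnorm(cfg$n_features * 3), cfg$n_features, 3)))
  U <- t(qr.Q(qr_b)[, 2:4]) * sqrt(cfg$n_features)  # rows ~ unit-variance
  layers <- vector("list", cfg$n_layers)
  mixtures <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    mix3 <- cfg$w_face[l] * m3f + cfg$w_object[l] * m3o
    total <- cfg$w_face[l] + cfg$w_object[l]
    sc <- if (total > 0) scale / max(mix3) else 0
    C3 <- 1 - sc * mix3
    ev <- eigen(C3, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) {
      stop("target category correlation matrix not positive definite at layer ",
           l, "; reduce `scale`", call. = FALSE)
    }
    B <- t(chol(C3)) %*% U          # 3 x n_features, exact correlations C3
    X <- B[cat_idx, , drop = FALSE]
    if (cfg$scatter > 0) {
      X <- X + cfg$scatter * matrix(stats::rnorm(n * cfg$n_features),
                                    n, cfg$n_features)
    }
    if (cfg$noise_sd > 0) {
      X <- X + cfg$noise_sd * matrix(stats::rnorm(n * cfg$n_features),
                                     n, cfg$n_features)
    }
    layers[[l]] <- feature_matrix(X, stimulus_set,
                                  layer_label = sprintf("layer%02d", l))
    mixtures[[l]] <- mix3
  }
  list(layers = layers,
       ground_truth = list(w_face = cfg$w_face, w_object = cfg$w_object,
                           mixture_3x3 = mixtures, scale = scale,
                           config = cfg))
}

#' Synthetic saliency fixture: image, region masks, analytic scorer
#'
#' Builds a strictly positive random image, rectangular region masks
#' (Eyes and Mouth inside Face; OutsideFace the complement of Face), and a
#' linear two-class scorer with known ground truth: the face-class weights
#' live only in the Eyes region (optionally also the Mouth), the
#' object-class weights only outside the face. Expected positive-pixel
#' ratios under occlusion attribution are computed in closed form from the
#' window-coverage geometry and returned.
#'
#' @param height,width Image geometry in pixels (defaults 120 x 120).
#' @param face Face rectangle `c(row1, row2, col1, col2)` (default centered,
#'   half the image).
#' @param eyes,mouth Rectangles inside `face` (defaults upper/lower bands).
#' @param include_mouth Give the face class weight in the Mouth region too?
#'   Default `FALSE` (all face weight in Eyes).
#' @param window,stride Occlusion geometry used for the closed-form
#'   expected ratios (defaults 12 and 6).
#' @param seed Integer seed for the image pixels.
#' @return List with `image`, `masks` (named list of logical matrices:
#'   Face, Eyes, Mouth, OutsideFace), `scorer`, the weight matrices, and
#'   `expected_ratios` (data frame `mask`, `class`, `ratio`).
#' @export
make_saliency_fixture <- function(height = 120, width = 120,
                                  face = NULL, eyes = NULL, mouth = NULL,
                                  include_mouth = FALSE,
                                  window = 12, stride = 6, seed = 1) {
  if (is.null(face)) face <- round(c(height * 0.25, height * 0.75,
                                     width * 0.25, width * 0.75))
  fh <- face[2] - face[1]; fw <- face[4] - face[3]
  if (is.null(eyes)) eyes <- round(c(face[1] + 0.20 * fh, face[1] + 0.35 * fh,
                                     face[3] + 0.15 * fw, face[4] - 0.15 * fw))
  if (is.null(mouth)) mouth <- round(c(face[1] + 0.65 * fh, face[1] + 0.80 * fh,
                                       face[3] + 0.25 * fw, face[4] - 0.25 * fw))
  rect_mask <- function(r) {
    m <- matrix(FALSE, height, width)
    m[r[1]:r[2], r[3]:r[4]] <- TRUE
    m
  }
  face_m <- rect_mask(face); eyes_m <- rect_mask(eyes); mouth_m <- rect_mask(mouth)
  if (any(eyes_m & mouth_m)) stop("Eyes and Mouth regions overlap", call. = FALSE)
  if (any(eyes_m & !face_m) || any(mouth_m & !face_m)) {
    stop("Eyes and Mouth must lie inside the Face region", call. = FALSE)
  }
  outside_m <- !face_m
  masks <- list(Face = face_m, Eyes = eyes_m, Mouth = mouth_m,
                OutsideFace = outside_m)

  set.seed(as.integer(seed))
  image <- matrix(stats::runif(height * width, min = 0.1, max = 1), height, width)

  w_face <- matrix(0, height, width)
  w_face[eyes_m] <- 1
  if (include_mouth) w_face[mouth_m] <- 1
  w_object <- matrix(0, height, width)
  w_object[outside_m] <- 1
  scorer <- function(img) {
    c(face = sum(w_face * img), object = sum(w_object * img))
  }

  expected <- expected_occlusion_ratios(masks, list(face = w_face, object = w_object),
                                        height, width, window, stride)
  list(image = image, masks = masks, scorer = scorer,
       weights = list(face = w_face, object = w_object),
       window = window, stride = stride,
       expected_ratios = expected)
}

# Closed-form expected positive-pixel ratios for a linear scorer with
# nonnegative weights on a strictly positive image and baseline 0: a pixel
# gets positive attribution iff some occlusion window covering it overlaps
# the scorer's support. Pure window-coverage geometry, independent of the
# occlusion scoring code path.
expected_occlusion_ratios <- function(masks, weights, H, W, window, stride) {
  starts <- function(extent) {
    s <- seq(1, extent - window + 1, by = stride)
    if (s[length(s)] != extent - window + 1) s <- c(s, extent - window + 1)
    s
  }
  rs <- starts(H); cs <- starts(W)
  rows <- list()
  for (cl in names(weights)) {
    support <- weights[[cl]] > 0
    reach <- matrix(FALSE, H, W)
    for (r in rs) for (cc in cs) {
      win_r <- r:(r + window - 1); win_c <- cc:(cc + window - 1)
      if (any(support[win_r, win_c])) reach[win_r, win_c] <- TRUE
    }
    for (mk in names(masks)) {
      rows[[length(rows) + 1]] <- data.frame(
        mask = mk, class = cl,
        ratio = sum(reach & masks[[mk]]) / sum(masks[[mk]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
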