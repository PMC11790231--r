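#' Occlusion-based class attribution
#'
#' Slides an occluding window over the image, replacing each window with a
#' baseline intensity, and records how much the classifier's score for the
#' requested class drops: `delta(p) = score(original) - score(occluded at
#' p)`. Each pixel's attribution is the mean of `delta` over all windows
#' covering it, so positive values mark features that support the class
#' (occluding them lowers the score). Window positions step by `stride`;
#' the final position along each axis is clamped to the image border so no
#' pixel is left uncovered.
#'
#' @param image Numeric H x W matrix (grayscale) or H x W x 3 array, values
#'   in `[0, 1]`.
#' @param scorer Function mapping an image (same shape) to a named numeric
#'   vector of class scores, with names including `class_label`.
#' @param class_label Class whose attribution is wanted, e.g. `"face"` or
#'   `"object"`.
#' @param window Occluder side length in pixels (default 40).
#' @param stride Step between window positions in pixels (default 20).
#' @param baseline Occluder intensity; default the image's global mean.
#' @return An object of class `attribution_map`: the H x W matrix of signed
#'   attributions with `class_label`, `window`, `stride` and `baseline`
#'   attributes.
#' @export
occlusion_attribution <- function(image, scorer, class_label,
                                  window = 40, stride = 20, baseline = NULL) {
  dims <- dim(image)
  H <- dims[1]; W <- dims[2]
  if (!all(is.finite(image))) stop("image contains non-finite pixels", call. = FALSE)
  stopifnot(window >= 1, stride >= 1)
  if (window > min(H, W)) {
    stop("window (", window, ") exceeds image size ", H, "x", W, call. = FALSE)
  }
  if (is.null(baseline)) baseline <- mean(image)
  s0 <- score_class(scorer, image, class_label, "original image")

  starts <- function(extent) {
    s <- seq(1, extent - window + 1, by = stride)
    if (s[length(s)] != extent - window + 1) s <- c(s, extent - window + 1)
    s
  }
  rs <- starts(H); cs <- starts(W)
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (r in rs) {
    for (cc in cs) {
      occ <- image
      if (length(dims) == 3) {
        occ[r:(r + window - 1), cc:(cc + window - 1), ] <- baseline
      } else {
        occ[r:(r + window - 1), cc:(cc + window - 1)] <- baseline
      }
      delta <- s0 - score_class(scorer, occ, class_label,
                                paste0("window at (", r, ",", cc, ")"))
      acc[r:(r + window - 1), cc:(cc + window - 1)] <-
        acc[r:(r + window - 1), cc:(cc + window - 1)] + delta
      cnt[r:(r + window - 1), cc:(cc + window - 1)] <-
        cnt[r:(r + window - 1), cc:(cc + window - 1)] + 1
    }
  }
  values <- matrix(0, H, W)
  covered <- cnt > 0
  values[covered] <- acc[covered] / cnt[covered]
  structure(values, class_label = class_label, window = window,
            stride = stride, baseline = baseline, coverage = covered,
            class = c("attribution_map", "matrix", "array"))
}

score_class <- function(scorer, image, class_label, where) {
  sc <- scorer(image)
  val <- if (!is.null(names(sc))) sc[[class_label]] else sc[[1]]
  if (!is.finite(val)) {
    stop("scorer returned non-finite score for ", where, call. = FALSE)
  }
  val
}

#' Positive-attribution pixel ratio within a region mask
#'
#' Fraction of pixels inside the mask whose class attribution is strictly
#' above zero. Zeros do not count as positive.
#'
#' @param attr An [occlusion_attribution()] map (or plain numeric matrix).
#' @param mask Logical/0-1 matrix of the same geometry; must be nonempty.
#' @return Ratio in `[0, 1]`.
#' @export
mask_positive_ratio <- function(attr, mask) {
  mask <- mask > 0
  if (!identical(dim(unclass(attr))[1:2], dim(mask)[1:2])) {
    stop("attribution map and mask geometries differ", call. = FALSE)
  }
  npix <- sum(mask)
  if (npix == 0) stop("empty region mask", call. = FALSE)
  sum(unclass(attr)[mask] > 0) / npix
}

#' Aggregate mask ratios across stimuli
#'
#' Group means and SEMs of positive-pixel ratios per (mask, class), across
#' stimuli, reported side by side for the two classes. With a single
#' stimulus in a group the mean is reported and the SEM is `NA`.
#'
#' @param ratios Data frame with columns `stimulus`, `mask`, `class`,
#'   `ratio`.
#' @return Data frame with columns `mask`, `class`, `mean`, `sem`, `n`.
#' @export
aggregate_ratios <- function(ratios) {
  stopifnot(all(c("stimulus", "mask", "class", "ratio") %in% names(ratios)))
  if (any(ratios$ratio < 0 | ratios$ratio > 1)) {
    stop("ratios must lie in [0, 1]", call. = FALSE)
  }
  key <- interaction(ratios$mask, ratios$class, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(ratios)), key), function(idx) {
    v <- ratios$ratio[idx]
    data.frame(mask = ratios$mask[idx[1]], class = ratios$class[idx[1]],
               mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mask, out$class), , drop = FALSE]
}
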