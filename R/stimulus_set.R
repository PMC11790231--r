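#' Stimulus sets
#'
#' A stimulus set fixes the identity, category label and -- crucially -- the
#' order of the stimuli. Every RDM, feature matrix and model RDM built from
#' the same set shares that order, so upper-triangle vectors from different
#' sources are directly comparable.
#'
#' @param ids Character vector of unique stimulus identifiers.
#' @param labels Character vector of per-stimulus categories, each one of
#'   `"face"`, `"pareidolia"` or `"object"`.
#' @return An object of class `stimulus_set`: a data frame with columns
#'   `id` and `label`, row order fixed.
#' @examples
#' ss <- stimulus_set(c("f1", "p1", "o1"), c("face", "pareidolia", "object"))
#' @export
stimulus_set <- function(ids, labels) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (length(ids) != length(labels)) {
    stop("`ids` and `labels` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("stimulus ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(labels), stimulus_categories())
  if (length(bad)) {
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(stimulus_categories(), collapse = ", "),
         call. = FALSE)
  }
  structure(
    data.frame(id = ids, label = labels, stringsAsFactors = FALSE),
    class = c("stimulus_set", "data.frame")
  )
}

#' @rdname stimulus_set
#' @export
stimulus_categories <- function() c("face", "pareidolia", "object")

#' Balanced default stimulus set
#'
#' Convenience constructor for the canonical balanced design: `n_per_category`
#' faces, pareidolia images and matched objects, in that block order.
#'
#' @param n_per_category Stimuli per category (default 32, giving 96 in all).
#' @return A [stimulus_set].
#' @export
balanced_stimulus_set <- function(n_per_category = 32) {
  stopifnot(n_per_category >= 1)
  cats <- stimulus_categories()
  stimulus_set(
    ids = paste0(rep(substr(cats, 1, 1), each = n_per_category),
                 sprintf("%03d", seq_len(n_per_category))),
    labels = rep(cats, each = n_per_category)
  )
}

n_stimuli <- function(ss) nrow(ss)

assert_stimulus_set <- function(ss) {
  if (!inherits(ss, "stimulus_set")) {
    stop("expected a `stimulus_set` object", call. = FALSE)
  }
  invisible(ss)
}
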