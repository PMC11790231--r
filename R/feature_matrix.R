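#' Feature matrices
#'
#' A stimuli-by-features activation (or response-pattern) matrix bound to a
#' [stimulus_set], with one row per stimulus in stimulus-set order. The
#' source is arbitrary -- network layer activations, sensor patterns, or the
#' synthetic generator [simulate_layer_features()].
#'
#' @param values Numeric matrix, stimuli x features.
#' @param stimulus_set The [stimulus_set] indexing the rows.
#' @param layer_label Free-text label (e.g. `"conv3_1"`, `"layer15"`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, stimulus_set, layer_label = "") {
  assert_stimulus_set(stimulus_set)
  values <- as.matrix(values)
  if (nrow(values) != n_stimuli(stimulus_set)) {
    stop("feature matrix has ", nrow(values), " rows but the stimulus set has ",
         n_stimuli(stimulus_set), " stimuli", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  rownames(values) <- stimulus_set$id
  structure(values,
            stimulus_set = stimulus_set,
            layer_label = layer_label,
            class = c("feature_matrix", "matrix", "array"))
}

#' @rdname feature_matrix
#' @param x Object to test.
#' @export
is_feature_matrix <- function(x) inherits(x, "feature_matrix")
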