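#' Idealized hypothesis model RDMs
#'
#' Binary RDMs encoding the two competing hypotheses about where pareidolia
#' stimuli sit in representational space. Low dissimilarity is coded 0, high
#' dissimilarity 1:
#'
#' * `"pareidolia_faces"` -- pareidolia faces are represented like real
#'   faces: face-pareidolia pairs are 0, pareidolia-object pairs are 1.
#' * `"pareidolia_objects"` -- pareidolia faces are represented like their
#'   matched objects: pareidolia-object pairs are 0, face-pareidolia 1.
#'
#' In both models within-category pairs are 0 and face-object pairs are 1;
#' the two models differ exactly on the face-pareidolia and
#' pareidolia-object blocks.
#'
#' @param stimulus_set A [stimulus_set] containing all three categories.
#' @param hypothesis `"pareidolia_faces"` or `"pareidolia_objects"`.
#' @return An [rdm] with binary entries; the hypothesis label is attached
#'   as attribute `"hypothesis"` and the object also has class `model_rdm`.
#' @export
build_ideal_rdm <- function(stimulus_set,
                            hypothesis = c("pareidolia_faces", "pareidolia_objects")) {
  hypothesis <- match.arg(hypothesis)
  assert_stimulus_set(stimulus_set)
  missing_cat <- setdiff(stimulus_categories(), unique(stimulus_set$label))
  if (length(missing_cat)) {
    stop("stimulus set is missing category: ",
         paste(missing_cat, collapse = ", "), call. = FALSE)
  }
  lab <- stimulus_set$label
  # 3x3 cell template over (face, pareidolia, object)
  cell <- matrix(1, 3, 3, dimnames = list(stimulus_categories(), stimulus_categories()))
  diag(cell) <- 0
  if (hypothesis == "pareidolia_faces") {
    cell["face", "pareidolia"] <- cell["pareidolia", "face"] <- 0
  } else {
    cell["object", "pareidolia"] <- cell["pareidolia", "object"] <- 0
  }
  d <- cell[lab, lab]
  diag(d) <- 0
  out <- rdm(d, stimulus_set)
  attr(out, "hypothesis") <- hypothesis
  class(out) <- c("model_rdm", class(out))
  out
}

model_hypothesis <- function(x) attr(x, "hypothesis")

#' @rdname build_ideal_rdm
#' @param hypothesis The hypothesis whose competitor is wanted.
#' @export
other_hypothesis <- function(hypothesis) {
  switch(match.arg(hypothesis, c("pareidolia_faces", "pareidolia_objects")),
         pareidolia_faces = "pareidolia_objects",
         pareidolia_objects = "pareidolia_faces")
}
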