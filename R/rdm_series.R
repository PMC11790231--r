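#' Time-resolved RDM series
#'
#' One subject's RDM at each time point, stored compactly as a
#' pairs-by-times matrix of upper-triangle vectors (fixed pair order, see
#' [vectorize_upper()]) plus the shared time axis in milliseconds.
#'
#' @param vectors Numeric matrix `n(n-1)/2 x length(times)`; column `t` is
#'   the vectorized RDM at `times[t]`. Alternatively a list of [rdm]s.
#' @param times Strictly increasing numeric vector of time stamps (ms).
#' @param stimulus_set Shared [stimulus_set].
#' @param subject_id Free-text subject identifier.
#' @return An object of class `rdm_series`.
#' @export
rdm_series <- function(vectors, times, stimulus_set, subject_id = "") {
  assert_stimulus_set(stimulus_set)
  if (is.list(vectors)) {
    vectors <- vapply(vectors, vectorize_upper,
                      numeric(n_pairs(stimulus_set)))
  }
  vectors <- as.matrix(vectors)
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (ncol(vectors) != length(times)) {
    stop("series has ", ncol(vectors), " columns but ", length(times),
         " time stamps", call. = FALSE)
  }
  if (nrow(vectors) != n_pairs(stimulus_set)) {
    stop("series rows (", nrow(vectors), ") do not match n(n-1)/2 = ",
         n_pairs(stimulus_set), call. = FALSE)
  }
  if (!all(is.finite(vectors))) stop("non-finite dissimilarities in series", call. = FALSE)
  structure(list(vectors = vectors, times = times,
                 stimulus_set = stimulus_set, subject_id = subject_id),
            class = "rdm_series")
}

n_pairs <- function(ss) {
  n <- n_stimuli(ss)
  n * (n - 1) / 2
}

#' @rdname rdm_series
#' @param x An `rdm_series`.
#' @param time Time stamp (ms) of the wanted RDM; must match one of
#'   `x$times` exactly.
#' @export
rdm_at <- function(x, time) {
  stopifnot(inherits(x, "rdm_series"))
  idx <- match(time, x$times)
  if (is.na(idx)) stop("time ", time, " ms not in series", call. = FALSE)
  reconstruct_rdm(x$vectors[, idx], x$stimulus_set)
}

#' @export
print.rdm_series <- function(x, ...) {
  cat("<rdm_series> subject:", x$subject_id,
      "|", n_stimuli(x$stimulus_set), "stimuli |",
      length(x$times), "time points (",
      min(x$times), "..", max(x$times), "ms )\n")
  invisible(x)
}

#' Time-wise partial RSA between a model RDM and an RDM series
#'
#' For every time point, the partial Spearman correlation between the model
#' RDM's upper-triangle vector and the subject's data RDM vector at that
#' time, controlling for the covariate model RDMs (typically the competing
#' hypothesis). Time points where the partial correlation is degenerate are
#' recorded as `NA`, never dropped, so the time axis stays intact.
#'
#' @param series An [rdm_series] or a list of them (one per subject).
#' @param model A model [rdm] (see [build_ideal_rdm()]).
#' @param covariates List of covariate model [rdm]s (may be empty).
#' @return A data frame with columns `subject`, `time_ms`, `model`, `rho`,
#'   one row per subject x time.
#' @export
model_rsa_timecourse <- function(series, model, covariates = list()) {
  if (inherits(series, "rdm_series")) series <- list(series)
  validate_rdm(model)
  model_lab <- model_hypothesis(model)
  if (is.null(model_lab)) model_lab <- "model"
  ss <- rdm_stimulus_set(model)
  for (s in series) {
    if (!identical(s$stimulus_set$id, ss$id)) {
      stop("series and model must share one stimulus set", call. = FALSE)
    }
  }
  rx <- rank_avg(vectorize_upper(model))
  Q <- if (length(covariates)) {
    covariate_basis(lapply(covariates, vectorize_upper), n = length(rx))
  }
  out <- lapply(series, function(s) {
    ranked <- rank_columns(s$vectors)
    rho <- partial_cor_cols(ranked, rx, Q)
    data.frame(subject = if (nzchar(s$subject_id)) s$subject_id else "s1",
               time_ms = s$times, model = model_lab, rho = rho,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Both hypotheses' partial RSA time courses in one pass
#'
#' Convenience wrapper running [model_rsa_timecourse()] for each model in
#' `models` with the remaining models as covariates, sharing the (costly)
#' rank transform of the data across models.
#'
#' @inheritParams model_rsa_timecourse
#' @param models List of model [rdm]s (each is correlated controlling for
#'   all the others).
#' @return Row-bound data frame as from [model_rsa_timecourse()].
#' @export
model_rsa_timecourses <- function(series, models) {
  if (inherits(series, "rdm_series")) series <- list(series)
  stopifnot(length(models) >= 1)
  mvecs <- lapply(models, vectorize_upper)
  labs <- vapply(seq_along(models), function(m) {
    model_hypothesis(models[[m]]) %||% paste0("model", m)
  }, character(1))
  rx <- lapply(mvecs, rank_avg)
  Q <- lapply(seq_along(models), function(m) {
    if (length(models) > 1) covariate_basis(mvecs[-m], n = length(mvecs[[1]]))
  })
  out <- lapply(series, function(s) {
    ranked <- rank_columns(s$vectors)
    per_model <- lapply(seq_along(models), function(m) {
      data.frame(subject = if (nzchar(s$subject_id)) s$subject_id else "s1",
                 time_ms = s$times, model = labs[m],
                 rho = partial_cor_cols(ranked, rx[[m]], Q[[m]]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_model)
  })
  do.call(rbind, out)
}

#' Reshape an RSA time course to a subjects-by-times matrix
#'
#' Helper bridging tidy time-course tables (from [model_rsa_timecourse()]
#' or [commonality_timecourse()]) to the group-inference functions, which
#' take a subjects x times value matrix.
#'
#' @param tc Data frame with columns `subject`, `time_ms` and one value
#'   column.
#' @param value Name of the value column (default the third column).
#' @return Numeric matrix, subjects x times, with an attribute `times`.
#' @export
timecourse_matrix <- function(tc, value = NULL) {
  if (is.null(value)) value <- setdiff(names(tc), c("subject", "time_ms", "model", "target_model", "system"))[1]
  subs <- unique(tc$subject)
  times <- sort(unique(tc$time_ms))
  m <- matrix(NA_real_, length(subs), length(times),
              dimnames = list(subs, times))
  m[cbind(match(tc$subject, subs), match(tc$time_ms, times))] <- tc[[value]]
  attr(m, "times") <- times
  m
}
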