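#' Commonality index
#'
#' Variance uniquely shared among a neural RDM vector, a model-system RDM
#' vector (e.g. a network's penultimate layer) and one hypothesis RDM,
#' while controlling the competing hypothesis:
#'
#' \deqn{c = r^2(neural, system | other) - r^2(neural, system | target, other)}
#'
#' where `r` is the partial Spearman correlation. A positive `c` means the
#' target hypothesis uniquely accounts for part of the neural-system
#' alignment; negative values (suppression) are reported as-is, never
#' clipped.
#'
#' @param neural_vec,system_vec,target_model_vec,other_model_vec Equal-length
#'   numeric vectors in the shared upper-triangle pair order.
#' @return The commonality index (finite scalar, |c| <= 1), or `NA` if a
#'   partial correlation is degenerate.
#' @export
commonality_index <- function(neural_vec, system_vec,
                              target_model_vec, other_model_vec) {
  r_other <- tryCatch(
    partial_spearman(neural_vec, system_vec, list(other_model_vec)),
    error = function(e) NA_real_)
  r_both <- tryCatch(
    partial_spearman(neural_vec, system_vec,
                     list(target_model_vec, other_model_vec)),
    error = function(e) NA_real_)
  r_other^2 - r_both^2
}

#' Commonality time course
#'
#' Applies [commonality_index()] at every time point of each subject's RDM
#' series, for each hypothesis as target (controlling the other). The
#' model-system RDM is fixed across time (e.g. a penultimate-layer RDM).
#'
#' @param series An [rdm_series] or list of them (one per subject).
#' @param system_rdm The model-system [rdm], or a list of layer RDMs, in
#'   which case the last (penultimate-layer convention) is used.
#' @param models List of the two hypothesis model [rdm]s.
#' @param system_label Label recorded in the output (default `"system"`).
#' @return Data frame with columns `subject`, `time_ms`, `target_model`,
#'   `system`, `c`, one row per subject x time x target model.
#' @seealso [summarize_timecourse()] for group means and SEMs;
#'   [sign_flip_cluster_test()] on `timecourse_matrix()` of one target's
#'   rows for significance.
#' @export
commonality_timecourse <- function(series, system_rdm, models,
                                   system_label = "system") {
  if (inherits(series, "rdm_series")) series <- list(series)
  if (is.list(system_rdm) && !is_rdm(system_rdm)) {
    system_rdm <- system_rdm[[length(system_rdm)]]
  }
  validate_rdm(system_rdm)
  stopifnot(length(models) == 2)
  ss <- rdm_stimulus_set(system_rdm)
  for (s in series) {
    if (!identical(s$stimulus_set$id, ss$id)) {
      stop("series and system RDM must share one stimulus set", call. = FALSE)
    }
  }
  sys_ranked <- rank_avg(vectorize_upper(system_rdm))
  mvecs <- lapply(models, vectorize_upper)
  labs <- vapply(seq_along(models), function(m) {
    model_hypothesis(models[[m]]) %||% paste0("model", m)
  }, character(1))
  # one covariate basis per conditioning set, shared across subjects/times
  Q_other <- lapply(seq_along(models), function(m) {
    covariate_basis(mvecs[-m], n = length(sys_ranked))
  })
  Q_both <- covariate_basis(mvecs, n = length(sys_ranked))
  out <- lapply(series, function(s) {
    ranked <- rank_columns(s$vectors)
    per_model <- lapply(seq_along(models), function(m) {
      r_other <- partial_cor_cols(ranked, sys_ranked, Q_other[[m]])
      r_both <- partial_cor_cols(ranked, sys_ranked, Q_both)
      data.frame(subject = if (nzchar(s$subject_id)) s$subject_id else "s1",
                 time_ms = s$times, target_model = labs[m],
                 system = system_label, c = r_other^2 - r_both^2,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_model)
  })
  do.call(rbind, out)
}

#' Group summary of a subject-level time course table
#'
#' Group mean and SEM across subjects at each time point, per grouping
#' level (model or target model). With a single subject the mean is the
#' subject's value and the SEM is `NA` (flagged by `n = 1`).
#'
#' @param tc Data frame from [model_rsa_timecourse()] or
#'   [commonality_timecourse()].
#' @param value Value column name; default auto-detected (`rho` or `c`).
#' @return Data frame with `time_ms`, grouping column(s), `mean`, `sem`, `n`.
#' @export
summarize_timecourse <- function(tc, value = NULL) {
  if (is.null(value)) value <- intersect(c("rho", "c"), names(tc))[1]
  group_cols <- intersect(c("model", "target_model", "system"), names(tc))
  key <- interaction(c(list(tc$time_ms), tc[group_cols]), drop = TRUE)
  split_rows <- split(seq_len(nrow(tc)), key)
  rows <- lapply(split_rows, function(idx) {
    v <- tc[[value]][idx]
    v_ok <- v[is.finite(v)]
    out <- tc[idx[1], c("time_ms", group_cols), drop = FALSE]
    out$mean <- mean(v_ok)
    out$sem <- if (length(v_ok) > 1) stats::sd(v_ok) / sqrt(length(v_ok)) else NA_real_
    out$n <- length(v_ok)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$time_ms), , drop = FALSE]
}
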