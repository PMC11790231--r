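#' Read and write RDM containers
#'
#' An RDM container is a directory holding a plain-text stimulus manifest
#' (`manifest.csv`, columns `id,label`, one row per stimulus in order) and
#' the dissimilarities as delimited text: `rdm.csv` (full n x n matrix)
#' for a single RDM, or `vectors.csv` (upper-triangle pairs x times) plus
#' `times.csv` for a series. Loading validates symmetry (to 1e-9), the
#' zero diagonal, and that manifest and matrix sizes agree.
#'
#' @param x An [rdm] or [rdm_series].
#' @param path Container directory (created if needed).
#' @return `write_rdm_container()` returns `path` invisibly;
#'   `read_rdm_container()` returns the [rdm] or [rdm_series].
#' @export
write_rdm_container <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (is_rdm(x)) {
    ss <- rdm_stimulus_set(x)
    utils::write.csv(ss, file.path(path, "manifest.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(x)), file.path(path, "rdm.csv"),
                     row.names = FALSE)
  } else if (inherits(x, "rdm_series")) {
    utils::write.csv(x$stimulus_set, file.path(path, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(time_ms = x$times), file.path(path, "times.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(x$vectors), file.path(path, "vectors.csv"),
                     row.names = FALSE)
    writeLines(x$subject_id, file.path(path, "subject.txt"))
  } else {
    stop("expected an `rdm` or `rdm_series`", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_rdm_container
#' @export
read_rdm_container <- function(path) {
  man_file <- file.path(path, "manifest.csv")
  if (!file.exists(man_file)) stop("no manifest.csv in ", path, call. = FALSE)
  man <- utils::read.csv(man_file, stringsAsFactors = FALSE)
  ss <- stimulus_set(man$id, man$label)
  if (file.exists(file.path(path, "vectors.csv"))) {
    times <- utils::read.csv(file.path(path, "times.csv"))$time_ms
    vecs <- as.matrix(utils::read.csv(file.path(path, "vectors.csv")))
    if (nrow(vecs) != n_pairs(ss)) {
      stop("container mismatch: manifest has ", n_stimuli(ss),
           " stimuli (", n_pairs(ss), " pairs) but vectors.csv has ",
           nrow(vecs), " rows", call. = FALSE)
    }
    subj_file <- file.path(path, "subject.txt")
    subj <- if (file.exists(subj_file)) readLines(subj_file, n = 1) else ""
    rdm_series(unname(vecs), times, ss, subject_id = subj)
  } else {
    d <- as.matrix(utils::read.csv(file.path(path, "rdm.csv")))
    if (nrow(d) != n_stimuli(ss) || ncol(d) != n_stimuli(ss)) {
      stop("container mismatch: manifest has ", n_stimuli(ss),
           " stimuli but rdm.csv is ", nrow(d), "x", ncol(d), call. = FALSE)
    }
    rdm(unname(d), ss)
  }
}

#' Read and write feature matrices as CSV
#'
#' Stimuli x features, first column `id`; labels come from a companion
#' manifest written alongside.
#'
#' @param x A [feature_matrix].
#' @param path CSV file path; a `<path>.manifest.csv` sidecar holds labels.
#' @export
write_feature_csv <- function(x, path) {
  stopifnot(is_feature_matrix(x))
  ss <- attr(x, "stimulus_set")
  df <- data.frame(id = ss$id, unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(ss, paste0(path, ".manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param layer_label Label for the loaded matrix.
#' @export
read_feature_csv <- function(path, layer_label = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  man <- utils::read.csv(paste0(path, ".manifest.csv"), stringsAsFactors = FALSE)
  ss <- stimulus_set(man$id, man$label)
  if (!identical(as.character(df$id), ss$id)) {
    stop("feature CSV ids do not match the manifest", call. = FALSE)
  }
  feature_matrix(as.matrix(df[, -1, drop = FALSE]), ss, layer_label = layer_label)
}

#' Read and write binary region masks as PNG
#'
#' Masks are strictly binary: pixels are 0 or 255 (0 or 1 after reading).
#'
#' @param mask Logical or 0/1 matrix.
#' @param path PNG file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- unique(as.vector(img))
  if (!all(vals %in% c(0, 1))) {
    stop("mask PNG is not strictly binary (0/255)", call. = FALSE)
  }
  img > 0
}

#' Run manifest
#'
#' Every pipeline run records what produced its outputs: stage names,
#' package version, the configuration snapshot, seeds, paths and a
#' timestamp. Deterministic stages regenerate bit-identically from a
#' manifest.
#'
#' @param stages Character vector of stage names executed.
#' @param config List of configuration values (seeds included).
#' @param paths Named list/character of input and output paths.
#' @param file Where to write the manifest (JSON).
#' @export
write_run_manifest <- function(stages, config, paths, file) {
  manifest <- list(
    package = "rsadyn",
    version = as.character(utils::packageVersion("rsadyn")),
    stages = stages,
    config = config,
    paths = paths,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}

#' Demo pipeline: generator to RSA to cluster test to commonality
#'
#' Runs the core analysis chain on synthetic defaults (scaled by the
#' arguments): simulate subject RDM series, compute both partial RSA time
#' courses, test them with the sign-flip cluster test, and compute the
#' commonality time courses against a synthetic model-system RDM. All
#' stochastic stages are seeded from `seed`; results are written as tidy
#' CSV tables plus a run manifest.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param cfg A [generator_config()]; defaults to a scaled-down version of
#'   the study conditions so the demo runs in seconds.
#' @param n_perm Sign permutations for the cluster test (default 1024).
#' @return Invisibly, a list with the result tables and the manifest path.
#' @export
run_demo_pipeline <- function(out_dir, seed = 1,
                              cfg = generator_config(n_subjects = 8,
                                                     n_per_category = 12,
                                                     seed = seed),
                              n_perm = 1024) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_subject_rdm_series(cfg)
  mf <- sim$ground_truth$model_face
  mo <- sim$ground_truth$model_object
  tc_f <- model_rsa_timecourse(sim$series, mf, list(mo))
  tc_o <- model_rsa_timecourse(sim$series, mo, list(mf))
  cl_f <- sign_flip_cluster_test(timecourse_matrix(tc_f), n_perm = n_perm,
                                 seed = seed + 1)
  cl_o <- sign_flip_cluster_test(timecourse_matrix(tc_o), n_perm = n_perm,
                                 seed = seed + 2)
  # synthetic model-system RDM: equal mixture of both hypotheses + jitter
  ssys <- balanced_stimulus_set(cfg$n_per_category)
  set.seed(seed + 3)
  sys_vec <- 0.5 * vectorize_upper(mf) + 0.5 * vectorize_upper(mo) +
    stats::rnorm(n_pairs(ssys), sd = 0.1)
  sys_rdm <- reconstruct_rdm(pmax(sys_vec, 0), ssys)
  ct <- commonality_timecourse(sim$series, sys_rdm, list(mf, mo),
                               system_label = "mixture_system")
  rsa_tab <- rbind(tc_f, tc_o)
  cl_tab <- rbind(cbind(model = "pareidolia_faces", cl_f$clusters),
                  cbind(model = "pareidolia_objects", cl_o$clusters))
  utils::write.csv(rsa_tab, file.path(out_dir, "rsa_timecourse.csv"),
                   row.names = FALSE)
  utils::write.csv(cl_tab, file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(ct, file.path(out_dir, "commonality.csv"), row.names = FALSE)
  manifest <- write_run_manifest(
    stages = c("simulate", "rsa", "cluster-test", "commonality"),
    config = c(unclass(cfg), list(n_perm = n_perm, master_seed = seed)),
    paths = list(out_dir = out_dir),
    file = file.path(out_dir, "manifest.json"))
  invisible(list(rsa = rsa_tab, clusters = cl_tab, commonality = ct,
                 manifest = manifest))
}
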