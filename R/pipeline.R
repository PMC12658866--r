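#' Pipeline configuration
#'
#' Gathers every tunable of the end-to-end analysis in one validated
#' object. The separation regime (`3 * delta < epsilon < 4 * delta`) is
#' enforced at construction, so an inconsistent `epsilon`/`r` pair fails
#' here rather than mid-run.
#'
#' @param epsilon Representative-vector resolution (default 0.08).
#' @param r Separation ratio, `delta = r * epsilon` (default 0.3).
#' @param gamma Coarse view radius; default `3 * epsilon`.
#' @param retention_window Optional `c(t_r1_min, t_r1_max)` in seconds.
#' @param mz_min,mz_max Optional fixed bin range; default from the data.
#' @param n_views Number of randomized views `S` (default 1000).
#' @param n_bootstrap Bootstrap resamples per view `B` (default 1000).
#' @param q_range Candidate cluster numbers (default `2:15`).
#' @param ari_threshold Stability threshold (default 0.5).
#' @param min_phi Minimum recurrence of a reported group (default 50).
#' @param coverage Replicate-distance coverage for calibration (0.95).
#' @param epsilon_floor Calibration floor (1e-6).
#' @param seed Base seed; all randomness derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(epsilon = 0.08, r = 0.3, gamma = NULL,
                            retention_window = NULL, mz_min = NULL,
                            mz_max = NULL, n_views = 1000,
                            n_bootstrap = 1000, q_range = 2:15,
                            ari_threshold = 0.5, min_phi = 50,
                            coverage = 0.95, epsilon_floor = 1e-6,
                            seed = 1) {
  params <- separation_params(epsilon = epsilon, r = r, gamma = gamma)
  stopifnot(n_views >= 1, n_bootstrap >= 1, all(q_range >= 2),
            ari_threshold >= 0, ari_threshold <= 1, min_phi >= 1,
            coverage > 0, coverage <= 1)
  structure(
    list(params = params, retention_window = retention_window,
         mz_min = mz_min, mz_max = mz_max, n_views = as.integer(n_views),
         n_bootstrap = as.integer(n_bootstrap),
         q_range = as.integer(q_range), ari_threshold = ari_threshold,
         min_phi = min_phi, coverage = coverage,
         epsilon_floor = epsilon_floor, seed = as.integer(seed)),
    class = "pipeline_config")
}

config_field_names <- function() {
  c("epsilon", "r", "gamma", "retention_window", "mz_min", "mz_max",
    "n_views", "n_bootstrap", "q_range", "ari_threshold", "min_phi",
    "coverage", "epsilon_floor", "seed")
}

#' Load a pipeline configuration file
#'
#' JSON (or YAML, when the yaml package is available) with keys matching
#' the arguments of [pipeline_config()]; unknown keys are rejected.
#'
#' @param path Config file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package.", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), config_field_names())
  if (length(unknown) > 0) {
    stop("Unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full marker and group-discovery pipeline
#'
#' Executes, in order: vectorisation of every sample (binning on a shared
#' m/z grid, unit normalisation, optional retention-window exclusion),
#' per-sample representative-vector selection, cross-sample unique-marker
#' detection, pooling, the randomized-view ensemble, the bootstrap
#' stability scan, and representative-group extraction. When `out_dir` is
#' given, the standard tables, the per-view stability scores and a
#' machine-readable run manifest (parameters, seeds, per-stage counts,
#' file hashes) are written there; reruns with the same inputs and seed
#' are byte-identical.
#'
#' @param samples Long tibble with `sample_id`, `t_r1_s`, `t_r2_s`, `mz`,
#'   `intensity` covering all samples.
#' @param config A [pipeline_config()].
#' @param metadata Optional metadata tibble (joined into outputs).
#' @param out_dir Optional artifact directory.
#' @return A `pipeline_result`: list with `nms`, `rms`, `rums`, `pooled`,
#'   `scan`, `groups`, `summary`, `config`.
#' @export
run_pipeline <- function(samples, config = pipeline_config(),
                         metadata = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  params <- config$params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  bins <- stage("bin_range", {
    if (!is.null(config$mz_min) && !is.null(config$mz_max)) {
      bin_range(config$mz_min, config$mz_max)
    } else {
      global_bin_range(samples)
    }
  })
  nms <- stage("vectorize",
               vectorize_samples(samples, bins = bins,
                                 window = config$retention_window))
  rms <- stage("representative_vectors", {
    out <- lapply(nms, representative_vectors, params = params)
    names(out) <- names(nms)
    out
  })
  rums <- stage("relatively_unique", relatively_unique(rms, params = params))
  pooled <- stage("pool_rums", pool_rums(rums))
  views <- stage("views",
                 ball_mapper_views(pooled, gamma = params$gamma,
                                   n_views = config$n_views,
                                   seed = config$seed))
  scan <- stage("consistency_scan",
                consistency_scan(views, q_range = config$q_range,
                                 B = config$n_bootstrap,
                                 threshold = config$ari_threshold,
                                 seed = config$seed))
  groups <- stage("representative_groups",
                  extract_representative_groups(scan,
                                                min_phi = config$min_phi))
  summary_tb <- marker_summary(rms, rums, nms_list = nms)
  if (!is.null(metadata)) {
    summary_tb <- dplyr::left_join(summary_tb, metadata, by = "sample_id")
  }
  result <- structure(
    list(nms = nms, rms = rms, rums = rums, pooled = pooled, scan = scan,
         groups = groups, summary = summary_tb, config = config,
         bins = bins),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d samples, %d pooled markers, Q* = %d, %d groups\n",
    length(x$nms), nrow(x$pooled$vectors), x$scan$q_star, nrow(x$groups)))
  invisible(x)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)

  utils::write.csv(result$summary, fp("summary.csv"), row.names = FALSE)
  markers <- dplyr::bind_rows(lapply(result$rums, function(ru) {
    tibble::tibble(sample_id = ru$sample_id,
                   row = ru$indices,
                   retention_index = ru$retention_index,
                   nearest_foreign = ru$nearest_foreign)
  }))
  utils::write.csv(markers, fp("rums.csv"), row.names = FALSE)
  utils::write.csv(tidy(result$scan), fp("consistency.csv"),
                   row.names = FALSE)
  utils::write.csv(result$scan$P, fp("pq.csv"), row.names = FALSE)
  groups_flat <- dplyr::mutate(
    tibble::as_tibble(result$groups),
    members = vapply(.data$members, paste, "", collapse = ";"))
  utils::write.csv(groups_flat, fp("groups.csv"), row.names = FALSE)

  files <- c("summary.csv", "rums.csv", "consistency.csv", "pq.csv",
             "groups.csv")
  manifest <- list(
    package = "spectramapper",
    version = as.character(utils::packageVersion("spectramapper")),
    parameters = list(
      epsilon = result$config$params$epsilon, r = result$config$params$r,
      delta = result$config$params$delta,
      gamma = result$config$params$gamma,
      n_views = result$config$n_views,
      n_bootstrap = result$config$n_bootstrap,
      q_range = result$config$q_range,
      ari_threshold = result$config$ari_threshold,
      min_phi = result$config$min_phi, seed = result$config$seed),
    bin_range = list(m = result$bins$m, M = result$bins$M,
                     d = result$bins$d),
    counts = list(
      n_spectra = stats::setNames(
        lapply(result$nms, function(m) nrow(m$values)), names(result$nms)),
      n_dropped = stats::setNames(
        lapply(result$nms, function(m) m$n_dropped), names(result$nms)),
      n_rms = stats::setNames(
        lapply(result$rms, function(s) length(s$indices)),
        names(result$rms)),
      n_rums = stats::setNames(
        lapply(result$rums, function(s) length(s$indices)),
        names(result$rums)),
      n_pooled = nrow(result$pooled$vectors),
      q_star = result$scan$q_star,
      n_stable_views = length(result$scan$s_star),
      n_groups = nrow(result$groups)),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
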