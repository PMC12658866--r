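#' Configuration for the synthetic GC x GC-MS generator
#'
#' The generator emulates the statistical regime the marker pipeline is
#' built for: every sample shares a majority of background spectra, owns a
#' few genuinely sample-specific spectral templates, and belongs to a
#' planted group whose members carry near-identical (but per-sample
#' distinct) group templates. Templates are sparse nonnegative vectors on
#' disjoint m/z supports, so after unit normalisation any two templates
#' from different roles sit at distance `sqrt(2)`, while the per-sample
#' variants of one group template sit at the controlled distance
#' `variant_distance` — close enough to share a coarse-view node, far
#' enough (`> 3 * delta`) to each qualify as a unique marker.
#'
#' @param K Number of samples.
#' @param n_spectra Spectra per sample.
#' @param bins [bin_range()] of the m/z grid (default 29..600).
#' @param n_shared Number of background templates common to all samples.
#' @param n_unique_per_sample Planted sample-specific templates per sample.
#' @param planted_groups Partition of `1:K` as a list of integer vectors;
#'   `NULL` splits the samples into three contiguous groups. Use `list()`
#'   for no planted group structure.
#' @param n_group_templates Group templates per planted group.
#' @param noise_sd Additive truncated-Gaussian intensity noise (counts),
#'   applied per bin before scaling.
#' @param scale_range Interval for the per-spectrum multiplicative
#'   intensity factor.
#' @param seed Seed making the dataset fully reproducible.
#' @param rep_unique,rep_group Spectra allotted to each unique / group
#'   template; the rest of `n_spectra` is background.
#' @param support_size Bins per template support.
#' @param variant_distance Post-normalisation distance between two samples'
#'   variants of one group template (default 0.15).
#' @param template_intensity Base counts scale of a template (default 100).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(K = 8, n_spectra = 400, bins = bin_range(29, 600),
                         n_shared = 8, n_unique_per_sample = 2,
                         planted_groups = NULL, n_group_templates = 3,
                         noise_sd = 0.2, scale_range = c(0.5, 2), seed = 1,
                         rep_unique = 20, rep_group = 20, support_size = 3,
                         variant_distance = 0.15,
                         template_intensity = 100) {
  stopifnot(K >= 1, n_spectra >= 1, inherits(bins, "bin_range"),
            n_shared >= 0, n_unique_per_sample >= 0, n_group_templates >= 0,
            noise_sd >= 0, length(scale_range) == 2, all(scale_range > 0),
            scale_range[1] <= scale_range[2], support_size >= 1,
            variant_distance > 0, variant_distance < sqrt(2),
            template_intensity > 0)
  if (is.null(planted_groups)) {
    planted_groups <- unname(split(seq_len(K),
                                   cut(seq_len(K), breaks = min(3, K),
                                       labels = FALSE)))
  }
  if (length(planted_groups) > 0) {
    flat <- sort(unlist(planted_groups))
    if (!identical(as.integer(flat), seq_len(K))) {
      stop("`planted_groups` must partition 1:K.", call. = FALSE)
    }
  }
  structure(
    list(K = K, n_spectra = n_spectra, bins = bins, n_shared = n_shared,
         n_unique_per_sample = n_unique_per_sample,
         planted_groups = planted_groups,
         n_group_templates = n_group_templates, noise_sd = noise_sd,
         scale_range = scale_range, seed = seed, rep_unique = rep_unique,
         rep_group = rep_group, support_size = support_size,
         variant_distance = variant_distance,
         template_intensity = template_intensity),
    class = "synth_config")
}

#' Generate a synthetic GC x GC-MS dataset with known ground truth
#'
#' Draws the template catalogue (shared background, per-sample unique, and
#' per-group templates with per-sample variants), assigns every spectrum of
#' every sample to a template, and emits noisy scaled realisations on a
#' regular synthetic retention grid. Peak m/z values are jittered inside
#' their unit bin, as a high-resolution instrument would report them.
#' Everything is reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List with `samples` (long tibble `sample_id`, `t_r1_s`,
#'   `t_r2_s`, `mz`, `intensity`), `metadata` (tibble `sample_id`,
#'   `country`, `winery`, `category`, `vintage`; `country` encodes the
#'   planted group), and `truth` (a `ground_truth`: `templates` unit-vector
#'   matrix, `template_info` tibble with roles, `assignments` tibble, and
#'   `planted_partition` as sample-id sets).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  d <- cf$bins$d
  n_groups <- length(cf$planted_groups)
  group_sizes <- vapply(cf$planted_groups, length, 1L)
  sample_ids <- sprintf("S%02d", seq_len(cf$K))
  group_of <- integer(cf$K)
  for (g in seq_len(n_groups)) group_of[cf$planted_groups[[g]]] <- g

  n_templates <- cf$n_shared + cf$K * cf$n_unique_per_sample +
    n_groups * cf$n_group_templates
  bins_needed <- n_templates * cf$support_size + sum(group_sizes)
  if (bins_needed > d) {
    stop(sprintf(
      paste0("Template separation unachievable: %d templates need %d ",
             "disjoint support bins but the bin range has only %d."),
      n_templates, bins_needed, d), call. = FALSE)
  }

  with_seed_local(cf$seed, {
    # --- template catalogue on disjoint supports ------------------------
    pool <- sample.int(d)  # randomised bin placement, still disjoint
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    unit_template <- function(support) {
      v <- numeric(d)
      v[support] <- stats::runif(length(support), 0.5, 1)
      v / sqrt(sum(v^2))
    }
    info <- list()
    vecs <- list()
    add_template <- function(id, role, sample_id, group, vec) {
      info[[length(info) + 1L]] <<- tibble::tibble(
        template_id = id, role = role, sample_id = sample_id, group = group)
      vecs[[length(vecs) + 1L]] <<- vec
    }
    for (j in seq_len(cf$n_shared)) {
      add_template(paste0("shared_", j), "shared", NA_character_, NA_integer_,
                   unit_template(take(cf$support_size)))
    }
    for (k in seq_len(cf$K)) {
      for (j in seq_len(cf$n_unique_per_sample)) {
        add_template(paste0("unique_", sample_ids[k], "_", j), "unique",
                     sample_ids[k], NA_integer_,
                     unit_template(take(cf$support_size)))
      }
    }
    # group templates: one base per (group, template), rotated toward a
    # sample-specific axis so variants are `variant_distance` apart
    sin_theta <- cf$variant_distance / sqrt(2)
    cos_theta <- sqrt(1 - sin_theta^2)
    for (g in seq_len(n_groups)) {
      ax <- take(group_sizes[g])  # one variant axis bin per member sample
      for (j in seq_len(cf$n_group_templates)) {
        base <- unit_template(take(cf$support_size))
        for (ki in seq_along(cf$planted_groups[[g]])) {
          k <- cf$planted_groups[[g]][ki]
          v <- cos_theta * base
          v[ax[ki]] <- v[ax[ki]] + sin_theta
          add_template(paste0("group", g, "_", j, "_", sample_ids[k]),
                       "variant", sample_ids[k], g, v)
        }
      }
    }
    template_info <- dplyr::bind_rows(info)
    templates <- do.call(rbind, vecs)
    rownames(templates) <- template_info$template_id

    # --- per-sample spectrum allocation ---------------------------------
    alloc_sample <- function(k) {
      sid <- sample_ids[k]
      own <- template_info$template_id[
        !is.na(template_info$sample_id) & template_info$sample_id == sid]
      is_unique <- grepl("^unique_", own)
      marker_counts <- ifelse(is_unique, cf$rep_unique, cf$rep_group)
      shared_ids <- template_info$template_id[template_info$role == "shared"]
      n_marker <- sum(marker_counts)
      if (length(shared_ids) > 0) {
        n_bg <- cf$n_spectra - n_marker
        if (n_bg < length(shared_ids)) {
          stop("n_spectra too small for the requested template allocation.",
               call. = FALSE)
        }
        bg <- rep(shared_ids, length.out = n_bg)
        ids <- c(rep(own, marker_counts), bg)
      } else {
        if (cf$n_spectra < length(own)) {
          stop("n_spectra smaller than the per-sample template roster.",
               call. = FALSE)
        }
        ids <- rep(own, length.out = max(cf$n_spectra, n_marker))
        ids <- ids[seq_len(cf$n_spectra)]
      }
      sample(ids)  # spread templates over the retention grid
    }

    # --- emission on a regular retention grid ---------------------------
    n2 <- 16L  # second-dimension points per modulation
    rows <- vector("list", cf$K)
    assignments <- vector("list", cf$K)
    for (k in seq_len(cf$K)) {
      ids <- alloc_sample(k)
      n <- length(ids)
      i <- seq_len(n)
      t1 <- 8 * (1 + (i - 1) %/% n2)
      t2 <- 0.25 + 0.5 * ((i - 1) %% n2)
      tmpl <- templates[ids, , drop = FALSE] * cf$template_intensity
      noise <- matrix(stats::rnorm(n * d, sd = cf$noise_sd), nrow = n)
      raw <- pmax(tmpl + noise, 0)
      scale <- stats::runif(n, cf$scale_range[1], cf$scale_range[2])
      raw <- raw * scale
      nz <- which(raw > 0, arr.ind = TRUE)
      mz_jit <- stats::runif(nrow(nz), -0.3, 0.3)
      rows[[k]] <- tibble::tibble(
        sample_id = sample_ids[k],
        t_r1_s = t1[nz[, 1]],
        t_r2_s = t2[nz[, 1]],
        mz = cf$bins$m + (nz[, 2] - 1) + mz_jit,
        intensity = raw[nz])
      assignments[[k]] <- tibble::tibble(
        sample_id = sample_ids[k], t_r1_s = t1, t_r2_s = t2,
        template_id = ids)
    }
    samples <- dplyr::arrange(dplyr::bind_rows(rows),
                              .data$sample_id, .data$t_r1_s, .data$t_r2_s,
                              .data$mz)
    metadata <- tibble::tibble(
      sample_id = sample_ids,
      country = if (n_groups > 0) paste0("G", group_of) else "G0",
      winery = paste0("W", seq_len(cf$K)),
      category = "synthetic",
      vintage = 2000L + seq_len(cf$K))
    truth <- structure(
      list(templates = templates, template_info = template_info,
           assignments = dplyr::bind_rows(assignments),
           planted_partition = lapply(cf$planted_groups,
                                      function(g) sample_ids[g]),
           config = cf),
      class = "ground_truth")
    list(samples = samples, metadata = metadata, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d templates (%d shared, %d unique, %d group variants), %d planted groups\n",
    nrow(x$templates), sum(x$template_info$role == "shared"),
    sum(x$template_info$role == "unique"),
    sum(x$template_info$role == "variant"),
    length(x$planted_partition)))
  invisible(x)
}

#' Score recovery of planted structure
#'
#' Compares pipeline output against the generator's ground truth. For
#' marker sets (`rums_set` list): a planted sample-specific template
#' (unique or group variant) counts as recovered when some detected marker
#' of the right sample lies within `epsilon` of it; recall is the fraction
#' of planted templates recovered and precision the fraction of detected
#' markers lying within `epsilon` of a planted template of their sample
#' (`NA` when nothing was detected). For representative groups
#' (`rep_groups`): the fraction of planted groups whose exact member set
#' occurs among the reported groups.
#'
#' @param predicted Named list of `rums_set` objects, or a `rep_groups`
#'   tibble.
#' @param truth A `ground_truth` from [generate_dataset()].
#' @param epsilon Matching radius for marker recovery (default 0.08).
#' @return A tibble of metrics (`metric`, `value`).
#' @export
evaluate_recovery <- function(predicted, truth, epsilon = 0.08) {
  stopifnot(inherits(truth, "ground_truth"))
  if (inherits(predicted, "rep_groups")) {
    planted <- lapply(truth$planted_partition, function(g) unname(sort(g)))
    found <- lapply(predicted$members, function(g) unname(sort(g)))
    hit <- vapply(planted, function(g)
      any(vapply(found, identical, TRUE, g)), TRUE)
    return(tibble::tibble(
      metric = c("group_recall", "n_planted_groups", "n_reported_groups"),
      value = c(mean(hit), length(planted), nrow(predicted))))
  }
  stopifnot(all(vapply(predicted, inherits, TRUE, "rums_set")))
  ids <- vapply(predicted, function(x) x$sample_id, "")
  roster <- unique(stats::na.omit(truth$template_info$sample_id))
  if (!all(ids %in% roster)) {
    stop("Predictions refer to samples absent from this ground truth.",
         call. = FALSE)
  }
  planted <- truth$template_info$role %in% c("unique", "variant")
  pl_info <- truth$template_info[planted, ]
  pl_vec <- truth$templates[planted, , drop = FALSE]
  recovered <- logical(nrow(pl_info))
  n_pred <- 0L
  n_matched <- 0L
  for (k in seq_along(predicted)) {
    sid <- ids[k]
    vr <- predicted[[k]]$vectors
    n_pred <- n_pred + nrow(vr)
    sel <- which(pl_info$sample_id == sid)
    if (length(sel) == 0 || nrow(vr) == 0) next
    d2 <- cross_dist2(vr, pl_vec[sel, , drop = FALSE])
    recovered[sel] <- recovered[sel] | (apply(d2, 2, min) < epsilon^2)
    n_matched <- n_matched + sum(apply(d2, 1, min) < epsilon^2)
  }
  tibble::tibble(
    metric = c("rums_recall", "rums_precision", "n_planted", "n_predicted"),
    value = c(if (nrow(pl_info)) mean(recovered) else NA_real_,
              if (n_pred > 0) n_matched / n_pred else NA_real_,
              nrow(pl_info), n_pred))
}
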