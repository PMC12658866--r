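#' Separation parameters for marker detection
#'
#' The marker pipeline is governed by one resolution and one ratio: the
#' Ball Mapper radius `epsilon` used to pick representative vectors, and
#' `r` setting the minimum separation `delta = r * epsilon`. A vector is a
#' relatively unique marker when it lies more than `3 * delta` from every
#' other sample's representative vectors, which keeps its within-`delta`
#' neighbourhood at least `delta` clear of those representatives. The
#' coarse visualisation radius is `gamma = 3 * epsilon`. The regime
#' `3 * delta < epsilon < 4 * delta` ties local support (neighbours within
#' `delta`) to cross-sample separation (beyond `3 * delta`); parameter sets
#' outside it are rejected.
#'
#' @param epsilon Representative-vector resolution; default 0.08.
#' @param r Separation ratio; default 0.3 (so `delta = 0.024`,
#'   `3 * delta = 0.072`, `gamma = 0.24`).
#' @param gamma Optional override of the coarse view radius.
#' @return A `separation_params` list: `epsilon`, `r`, `delta`, `gamma`.
#' @examples
#' separation_params()          # the default calibrated regime
#' try(separation_params(0.08, 0.5))  # rejected: 3*delta = 0.12 > epsilon
#' @export
separation_params <- function(epsilon = 0.08, r = 0.3, gamma = NULL) {
  stopifnot(is.numeric(epsilon), epsilon > 0, is.numeric(r), r > 0)
  delta <- r * epsilon
  if (!(3 * delta < epsilon && epsilon < 4 * delta)) {
    stop(sprintf(
      paste0("Invalid separation regime: need 3*delta < epsilon < 4*delta, ",
             "got delta = %g so (%g, %g) must bracket epsilon = %g."),
      delta, 3 * delta, 4 * delta, epsilon), call. = FALSE)
  }
  if (is.null(gamma)) gamma <- 3 * epsilon
  stopifnot(gamma > 0)
  structure(list(epsilon = epsilon, r = r, delta = delta, gamma = gamma),
            class = "separation_params")
}

#' @export
print.separation_params <- function(x, ...) {
  cat(sprintf(
    "<separation_params> epsilon %.4g, r %.3g, delta %.4g (3*delta %.4g), gamma %.4g\n",
    x$epsilon, x$r, x$delta, 3 * x$delta, x$gamma))
  invisible(x)
}

#' Representative spectral vectors of one sample
#'
#' Runs the greedy epsilon-net over a sample's unit-normalised feature
#' matrix; the landmarks are the sample's representative vectors. They
#' cover every spectrum of the sample within `epsilon` while being pairwise
#' more than `epsilon` apart — a compact sketch of the sample that makes
#' cross-sample comparison tractable.
#'
#' @param nms An `nms_matrix` from [nms_vectors()].
#' @param params [separation_params()].
#' @param ordering Optional visiting order over rows.
#' @return An `rms_set`: list with `sample_id`, `indices` (matrix row
#'   numbers of the landmarks, discovery order), `retention_index` (their
#'   0-based retention indices), `vectors` (the landmark rows), `cover`.
#' @export
representative_vectors <- function(nms, params = separation_params(),
                                   ordering = NULL) {
  stopifnot(inherits(nms, "nms_matrix"), inherits(params, "separation_params"))
  cover <- greedy_epsilon_net(nms$values, params$epsilon, ordering)
  structure(
    list(sample_id = nms$sample_id,
         indices = cover$landmarks,
         retention_index = nms$retention$retention_index[cover$landmarks],
         vectors = nms$values[cover$landmarks, , drop = FALSE],
         cover = cover),
    class = "rms_set")
}

#' @export
print.rms_set <- function(x, ...) {
  cat(sprintf("<rms_set> sample %s: %d representative vectors\n",
              x$sample_id, length(x$indices)))
  invisible(x)
}

# squared Euclidean cross-distance matrix between row sets
cross_dist2 <- function(a, b) {
  sa <- rowSums(a^2)
  sb <- rowSums(b^2)
  pmax(outer(sa, sb, "+") - 2 * tcrossprod(a, b), 0)
}

#' Relatively unique spectral vectors
#'
#' A representative vector of sample `k` is *relatively unique* when its
#' distance to every representative vector of every other sample exceeds
#' `3 * delta` (strictly). "Relatively" because uniqueness is judged
#' against the other samples of this dataset, not against chemistry at
#' large. With a single sample the condition is vacuous and every
#' representative vector qualifies. Comparison runs against the other
#' samples' representative sets (not their full spectra), which is what
#' makes the screen tractable; `exhaustive = TRUE` additionally audits
#' against the full normalised matrices.
#'
#' @param rms_sets Named list of `rms_set`, one per sample.
#' @param params [separation_params()].
#' @param exhaustive Compare against full `nms` matrices instead of
#'   representative sets (small data only); needs `nms_list`.
#' @param nms_list Named list of `nms_matrix`, required when
#'   `exhaustive = TRUE`.
#' @return Named list of `rums_set` objects (`sample_id`, `indices`,
#'   `retention_index`, `vectors`, `nearest_foreign`: distance to the
#'   closest other-sample representative vector).
#' @export
relatively_unique <- function(rms_sets, params = separation_params(),
                              exhaustive = FALSE, nms_list = NULL) {
  stopifnot(length(rms_sets) >= 1,
            all(vapply(rms_sets, inherits, TRUE, "rms_set")))
  ids <- vapply(rms_sets, function(x) x$sample_id, "")
  out <- vector("list", length(rms_sets))
  names(out) <- ids
  thr2 <- (3 * params$delta)^2
  for (k in seq_along(rms_sets)) {
    vk <- rms_sets[[k]]$vectors
    others <- if (exhaustive) {
      if (is.null(nms_list)) {
        stop("`exhaustive = TRUE` requires `nms_list`.", call. = FALSE)
      }
      lapply(nms_list[ids[-k]], function(m) m$values)
    } else {
      lapply(rms_sets[-k], function(s) s$vectors)
    }
    if (length(others) == 0) {
      keep <- rep(TRUE, nrow(vk))
      nearest <- rep(Inf, nrow(vk))
    } else {
      min2 <- rep(Inf, nrow(vk))
      for (o in others) {
        d2 <- cross_dist2(vk, o)
        min2 <- pmin(min2, apply(d2, 1, min))
      }
      keep <- min2 > thr2
      nearest <- sqrt(min2)
    }
    out[[k]] <- structure(
      list(sample_id = ids[k],
           indices = rms_sets[[k]]$indices[keep],
           retention_index = rms_sets[[k]]$retention_index[keep],
           vectors = vk[keep, , drop = FALSE],
           nearest_foreign = nearest[keep]),
      class = "rums_set")
  }
  out
}

#' @export
print.rums_set <- function(x, ...) {
  cat(sprintf("<rums_set> sample %s: %d relatively unique vectors\n",
              x$sample_id, length(x$indices)))
  invisible(x)
}

#' Marker count summary table
#'
#' One row per sample with the sizes of the spectral, representative and
#' unique-marker sets — the standard per-sample reduction report.
#'
#' @param rms_sets Named list of `rms_set`.
#' @param rums_sets Named list of `rums_set` (matching names).
#' @param nms_list Optional named list of `nms_matrix` to add `n_spectra`.
#' @return Tibble with `sample_id`, optionally `n_spectra`, `n_rms`,
#'   `n_rums`.
#' @export
marker_summary <- function(rms_sets, rums_sets, nms_list = NULL) {
  tb <- tibble::tibble(
    sample_id = vapply(rms_sets, function(x) x$sample_id, ""),
    n_rms = vapply(rms_sets, function(x) length(x$indices), 1L),
    n_rums = vapply(rums_sets[names(rms_sets)],
                    function(x) length(x$indices), 1L))
  if (!is.null(nms_list)) {
    tb <- dplyr::mutate(
      tb,
      n_spectra = vapply(nms_list[tb$sample_id],
                         function(m) nrow(m$values), 1L),
      .after = "sample_id")
  }
  tb
}

#' Audit the locality of unique markers
#'
#' A marker should not only be separated from other samples itself: its
#' own within-`delta` neighbourhood should stay more than `delta` away
#' from every spectrum of every other sample. With coverage radius
#' `epsilon` larger than `delta` this is not a theorem, so it is checked
#' empirically: for every marker, every same-sample neighbour strictly
#' within `delta`, and every other-sample spectrum, the neighbour's
#' distance to that spectrum must exceed `delta`.
#'
#' @param rums_sets Named list of `rums_set`.
#' @param nms_list Named list of `nms_matrix` the markers came from.
#' @param params [separation_params()].
#' @return A `locality_report`: list with `violations` (tibble `sample_id`,
#'   `rums_row`, `neighbor_row`, `other_sample`, `other_row`, `distance`)
#'   and `summary` (tibble `sample_id`, `n_rums`, `n_neighbors`,
#'   `n_violations`).
#' @export
verify_locality <- function(rums_sets, nms_list,
                            params = separation_params()) {
  delta <- params$delta
  viol <- list()
  summ <- list()
  for (id in names(rums_sets)) {
    ru <- rums_sets[[id]]
    own <- nms_list[[id]]$values
    nb_rows <- integer(0)
    if (length(ru$indices) > 0) {
      d2 <- cross_dist2(ru$vectors, own)
      nb_rows <- which(apply(d2, 2, min) < delta^2)
    }
    n_v <- 0L
    if (length(nb_rows) > 0) {
      nb <- own[nb_rows, , drop = FALSE]
      for (other in setdiff(names(nms_list), id)) {
        od2 <- cross_dist2(nb, nms_list[[other]]$values)
        bad <- which(od2 <= delta^2, arr.ind = TRUE)
        if (nrow(bad) > 0) {
          n_v <- n_v + nrow(bad)
          # attribute each violating neighbour to the marker(s) it supports
          for (r in seq_len(nrow(bad))) {
            nb_row <- nb_rows[bad[r, 1]]
            which_ru <- which(d2[, nb_row] < delta^2)
            viol[[length(viol) + 1L]] <- tibble::tibble(
              sample_id = id,
              rums_row = ru$indices[which_ru],
              neighbor_row = nb_row,
              other_sample = other,
              other_row = bad[r, 2],
              distance = sqrt(od2[bad[r, 1], bad[r, 2]]))
          }
        }
      }
    }
    summ[[length(summ) + 1L]] <- tibble::tibble(
      sample_id = id, n_rums = length(ru$indices),
      n_neighbors = length(nb_rows), n_violations = n_v)
  }
  structure(
    list(violations = if (length(viol)) dplyr::bind_rows(viol) else
      tibble::tibble(sample_id = character(0), rums_row = integer(0),
                     neighbor_row = integer(0), other_sample = character(0),
                     other_row = integer(0), distance = numeric(0)),
         summary = dplyr::bind_rows(summ)),
    class = "locality_report")
}

#' @export
print.locality_report <- function(x, ...) {
  cat(sprintf("<locality_report> %d violation(s) across %d sample(s)\n",
              nrow(x$violations), nrow(x$summary)))
  invisible(x)
}
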