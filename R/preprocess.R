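#' Integer m/z bin range
#'
#' A bin range fixes the common coordinate system for discretised mass
#' spectra: unit-width bins centred on consecutive integers, bin `n`
#' covering the half-open interval `[n - 1/2, n + 1/2)`. All spectra of a
#' dataset are discretised onto the same range so that their vectors live in
#' one `d`-dimensional space, `d = M - m + 1`.
#'
#' @param m Integer lower bin (inclusive).
#' @param M Integer upper bin (inclusive); `m <= M`.
#' @return An object of class `bin_range` with elements `m`, `M` and `d`.
#' @examples
#' bin_range(29, 600)
#' @export
bin_range <- function(m, M) {
  stopifnot(is.numeric(m), is.numeric(M), length(m) == 1, length(M) == 1)
  m <- as.integer(m)
  M <- as.integer(M)
  if (m > M) stop("`m` must not exceed `M`.", call. = FALSE)
  structure(list(m = m, M = M, d = M - m + 1L), class = "bin_range")
}

#' @export
print.bin_range <- function(x, ...) {
  cat(sprintf("<bin_range> m/z %d..%d (d = %d bins)\n", x$m, x$M, x$d))
  invisible(x)
}

# bin containing m/z value x under the [n - 1/2, n + 1/2) convention
mz_bin <- function(mz) as.integer(floor(mz + 0.5))

#' Dataset-global bin range
#'
#' Scans one or more samples' peak tables and returns the smallest integer
#' bin range whose half-open unit bins cover every observed m/z value, so
#' that all samples share a common discretisation grid.
#'
#' @param samples A data frame in long point format with at least an `mz`
#'   column (typically also `sample_id`, `t_r1_s`, `t_r2_s`, `intensity`).
#' @return A [bin_range()].
#' @examples
#' pts <- tibble::tibble(mz = c(45.7, 60.2), intensity = c(1, 1))
#' global_bin_range(pts)  # bins 46..60
#' @export
global_bin_range <- function(samples) {
  stopifnot(is.data.frame(samples), "mz" %in% names(samples))
  mz <- samples$mz[is.finite(samples$mz)]
  if (length(mz) == 0) {
    stop("No spectra with peaks found: cannot determine a bin range.",
         call. = FALSE)
  }
  if (any(mz <= 0)) stop("m/z values must be strictly positive.", call. = FALSE)
  bin_range(mz_bin(min(mz)), mz_bin(max(mz)))
}

#' Discretise one mass spectrum onto integer bins
#'
#' Bins a raw high-resolution spectrum onto the integer m/z grid by taking,
#' in each unit bin `[n - 1/2, n + 1/2)`, the maximum intensity of the peaks
#' falling in it; bins with no peak are zero. Taking the per-bin maximum
#' keeps the most prominent feature of each bin and discards the rest.
#'
#' @param spectrum A data frame with columns `mz` and `intensity` (may have
#'   zero rows), or a list with those elements.
#' @param bins A [bin_range()] covering the dataset-global m/z range. A peak
#'   outside `[m - 1/2, M + 1/2)` is an error: the global range contract is
#'   violated.
#' @return A numeric vector of length `bins$d`, indexed by bins `m..M`.
#' @examples
#' sp <- tibble::tibble(mz = c(29.3, 29.6, 30.9), intensity = c(5, 7, 2))
#' discretize_spectrum(sp, bin_range(29, 31))  # 5 7 2
#' @export
discretize_spectrum <- function(spectrum, bins) {
  stopifnot(inherits(bins, "bin_range"))
  mz <- spectrum$mz
  intensity <- spectrum$intensity
  v <- numeric(bins$d)
  if (length(mz) == 0) return(v)
  if (any(intensity < 0)) stop("Negative peak intensity.", call. = FALSE)
  b <- mz_bin(mz)
  if (any(b < bins$m | b > bins$M)) {
    bad <- which(b < bins$m | b > bins$M)[1]
    stop(sprintf(
      "Peak at m/z %.4f falls outside the global bin range [%g, %g).",
      mz[bad], bins$m - 0.5, bins$M + 0.5), call. = FALSE)
  }
  idx <- b - bins$m + 1L
  agg <- tapply(intensity, idx, max)
  v[as.integer(names(agg))] <- as.numeric(agg)
  v
}

#' Project a discrete spectrum onto the unit sphere
#'
#' Divides a nonnegative discrete mass-spectral vector by its Euclidean
#' norm. The result depends only on the direction of the spectrum, not on
#' the total signal: multiplying every intensity by any `c > 0` gives the
#' same normalised vector, which is what makes downstream distances
#' intensity-invariant.
#'
#' @param v Numeric vector with at least one positive entry.
#' @return Unit-norm numeric vector of the same length.
#' @export
normalize_spectrum <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("empty spectrum: cannot normalise an all-zero vector.",
                     call. = FALSE)
  v / nrm
}

#' Restrict a sample run to a first-dimension retention window
#'
#' Keeps exactly the rows whose first retention time lies in the closed
#' window `[t_r1_min, t_r1_max]` (seconds). The beginning and end of a
#' GC x GC acquisition usually lie outside the region of interest and are
#' excluded before vectorisation; row order is preserved.
#'
#' @param run A data frame with a `t_r1_s` column.
#' @param window Numeric length-2 vector `c(t_r1_min, t_r1_max)`.
#' @return The filtered data frame; a warning (not an error) if empty.
#' @export
exclude_retention_window <- function(run, window) {
  stopifnot(is.data.frame(run), "t_r1_s" %in% names(run),
            is.numeric(window), length(window) == 2)
  if (window[1] > window[2]) {
    stop("Retention window must satisfy t_r1_min <= t_r1_max.", call. = FALSE)
  }
  out <- dplyr::filter(run, .data$t_r1_s >= window[1],
                       .data$t_r1_s <= window[2])
  if (nrow(out) == 0) {
    warning("Retention window excludes every spectrum.", call. = FALSE)
  }
  out
}

#' Normalised spectral feature matrix of one sample
#'
#' Turns one sample's long point table into its feature matrix: each
#' distinct retention coordinate `(t_r1_s, t_r2_s)`, taken in lexicographic
#' order, becomes one row holding the unit-normalised discretised spectrum.
#' Spectra that discretise to the all-zero vector cannot be normalised and
#' are dropped with their count recorded.
#'
#' @param run Long-format data frame for a single sample with columns
#'   `t_r1_s`, `t_r2_s`, `mz`, `intensity` (a `sample_id` column, if
#'   present, must be constant).
#' @param bins A [bin_range()]; typically [global_bin_range()] over all
#'   samples so matrices are comparable.
#' @param window Optional retention window passed to
#'   [exclude_retention_window()].
#' @param sample_id Sample code; defaults to the run's `sample_id` column.
#' @return An `nms_matrix`: list with `values` (rows unit-norm, one per
#'   retained retention index), `retention` (tibble of 0-based
#'   `retention_index`, `t_r1_s`, `t_r2_s`), `sample_id`, `bins`,
#'   `n_dropped`.
#' @export
nms_vectors <- function(run, bins, window = NULL, sample_id = NULL) {
  stopifnot(is.data.frame(run),
            all(c("t_r1_s", "t_r2_s", "mz", "intensity") %in% names(run)))
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(run)) {
      ids <- unique(run$sample_id)
      if (length(ids) != 1) {
        stop("`run` holds several sample_ids; pass one sample at a time.",
             call. = FALSE)
      }
      as.character(ids)
    } else "sample"
  }
  if (!is.null(window)) run <- exclude_retention_window(run, window)
  if (any(run$intensity < 0)) {
    stop("Negative intensities in sample ", sample_id, ".", call. = FALSE)
  }
  if (nrow(run) == 0) {
    stop("Sample ", sample_id, " has no spectra after window exclusion.",
         call. = FALSE)
  }
  b <- mz_bin(run$mz)
  if (any(b < bins$m | b > bins$M)) {
    stop("Sample ", sample_id,
         " has peaks outside the global bin range.", call. = FALSE)
  }

  key <- order_retention(run$t_r1_s, run$t_r2_s)
  coords <- dplyr::distinct(
    tibble::tibble(t_r1_s = run$t_r1_s, t_r2_s = run$t_r2_s)[key, ])
  spec_of <- match(
    paste(run$t_r1_s, run$t_r2_s),
    paste(coords$t_r1_s, coords$t_r2_s))

  mat <- matrix(0, nrow = nrow(coords), ncol = bins$d)
  # per-(spectrum, bin) maximum: keep the largest intensity of each cell
  ord <- order(spec_of, b, -run$intensity)
  keep <- !duplicated(cbind(spec_of, b)[ord, , drop = FALSE])
  sel <- ord[keep]
  mat[cbind(spec_of[sel], b[sel] - bins$m + 1L)] <- run$intensity[sel]

  nrm <- sqrt(rowSums(mat^2))
  zero <- nrm == 0
  mat <- mat[!zero, , drop = FALSE] / nrm[!zero]
  coords <- coords[!zero, , drop = FALSE]
  if (nrow(mat) == 0) {
    stop("Sample ", sample_id, " has only empty spectra.", call. = FALSE)
  }
  structure(
    list(values = mat,
         retention = tibble::tibble(retention_index = seq_len(nrow(mat)) - 1L,
                                    t_r1_s = coords$t_r1_s,
                                    t_r2_s = coords$t_r2_s),
         sample_id = sample_id,
         bins = bins,
         n_dropped = sum(zero)),
    class = "nms_matrix")
}

order_retention <- function(t1, t2) order(t1, t2)

#' @export
print.nms_matrix <- function(x, ...) {
  cat(sprintf(
    "<nms_matrix> sample %s: %d unit spectra x %d bins (m/z %d..%d), %d empty dropped\n",
    x$sample_id, nrow(x$values), x$bins$d, x$bins$m, x$bins$M, x$n_dropped))
  invisible(x)
}

#' @export
as_tibble.nms_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = x$sample_id),
    x$retention,
    tibble::as_tibble(x$values, .name_repair = function(n)
      paste0("mz", seq(x$bins$m, x$bins$M))))
}

#' Vectorise every sample of a dataset
#'
#' Convenience wrapper: splits a multi-sample long table by `sample_id`,
#' applies a shared [global_bin_range()] (unless given) and an optional
#' retention window, and returns one [nms_vectors()] matrix per sample.
#'
#' @param samples Long-format data frame with `sample_id`, `t_r1_s`,
#'   `t_r2_s`, `mz`, `intensity`.
#' @param bins Optional shared [bin_range()].
#' @param window Optional retention window.
#' @return Named list of `nms_matrix` objects, in order of first appearance.
#' @export
vectorize_samples <- function(samples, bins = NULL, window = NULL) {
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
  if (is.null(bins)) bins <- global_bin_range(samples)
  ids <- unique(samples$sample_id)
  out <- lapply(ids, function(id) {
    nms_vectors(samples[samples$sample_id == id, , drop = FALSE],
                bins = bins, window = window, sample_id = as.character(id))
  })
  names(out) <- as.character(ids)
  out
}

#' Calibrate the Ball Mapper resolution from replicate runs
#'
#' Replicate measurements of the same material bound the reproducibility of
#' the instrument: distances between matched spectra of replicates reflect
#' technical variation only. The resolution is set to the empirical
#' `coverage` quantile (lower, type-1 order statistic) of the Euclidean
#' distances between retention-matched normalised spectra across all
#' replicate pairs, so that the chosen radius absorbs that fraction of
#' technical variation and distances beyond it can be read as chemical.
#'
#' @param replicates List of two or more `nms_matrix` objects of the same
#'   material on the same bin range.
#' @param coverage Fraction of replicate distances the radius must cover;
#'   default 0.95.
#' @param epsilon_floor Lower bound returned when replicates are (near)
#'   identical; default `1e-6`.
#' @param match `"grid"` requires identical retention coordinates and pairs
#'   rows by them; `"nearest"` pairs each spectrum with the nearest
#'   retention coordinate of the other replicate within `tol_s` seconds of
#'   first retention time (used, with a message, when grids differ).
#' @param tol_s Nearest-match tolerance in seconds (half a modulation
#'   period, default 4).
#' @return The calibrated radius (a positive scalar).
#' @export
calibrate_resolution <- function(replicates, coverage = 0.95,
                                 epsilon_floor = 1e-6,
                                 match = c("grid", "nearest"), tol_s = 4) {
  match <- match.arg(match)
  stopifnot(is.list(replicates))
  if (length(replicates) < 2) {
    stop("At least two replicate runs are required.", call. = FALSE)
  }
  stopifnot(all(vapply(replicates, inherits, TRUE, "nms_matrix")),
            coverage > 0, coverage <= 1)
  b0 <- replicates[[1]]$bins
  same_bins <- vapply(replicates, function(r)
    r$bins$m == b0$m && r$bins$M == b0$M, TRUE)
  if (!all(same_bins)) stop("Replicates must share a bin range.", call. = FALSE)

  dists <- c()
  pairs <- utils::combn(length(replicates), 2)
  for (p in seq_len(ncol(pairs))) {
    a <- replicates[[pairs[1, p]]]
    b <- replicates[[pairs[2, p]]]
    ka <- paste(a$retention$t_r1_s, a$retention$t_r2_s)
    kb <- paste(b$retention$t_r1_s, b$retention$t_r2_s)
    ia <- which(ka %in% kb)
    if (match == "grid") {
      if (length(ia) == 0) {
        stop("Replicate retention grids do not overlap; ",
             "use match = \"nearest\".", call. = FALSE)
      }
      ib <- match(ka[ia], kb)
    } else {
      message("calibrate_resolution: nearest-coordinate matching within ",
              tol_s, " s.")
      ia <- seq_along(ka)
      ib <- vapply(ia, function(i) {
        dd <- abs(b$retention$t_r1_s - a$retention$t_r1_s[i]) +
          abs(b$retention$t_r2_s - a$retention$t_r2_s[i])
        j <- which.min(dd)
        if (abs(b$retention$t_r1_s[j] - a$retention$t_r1_s[i]) <= tol_s)
          j else NA_integer_
      }, 1L)
      ia <- ia[!is.na(ib)]
      ib <- ib[!is.na(ib)]
      if (length(ia) == 0) stop("No matchable spectra.", call. = FALSE)
    }
    dists <- c(dists,
               sqrt(rowSums((a$values[ia, , drop = FALSE] -
                               b$values[ib, , drop = FALSE])^2)))
  }
  eps <- as.numeric(stats::quantile(dists, probs = coverage, type = 1))
  max(eps, epsilon_floor)
}
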