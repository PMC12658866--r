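# Independent brute-force oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# bin-by-bin, peak-by-peak discretisation (half-open bins [n-1/2, n+1/2))
oracle_discretize <- function(mz, intensity, m, M) {
  out <- numeric(M - m + 1)
  for (bi in seq_along(out)) {
    n <- m + bi - 1
    vals <- intensity[mz >= n - 0.5 & mz < n + 0.5]
    if (length(vals) > 0) out[bi] <- max(vals)
  }
  out
}

# full pairwise check of epsilon-net coverage (open balls) and separation
oracle_check_net <- function(points, cover) {
  eps <- cover$epsilon
  lm <- cover$landmarks
  dmat <- as.matrix(stats::dist(points))
  covered <- apply(dmat[, lm, drop = FALSE] < eps, 1, any)
  separation <- if (length(lm) < 2) TRUE else {
    dl <- dmat[lm, lm]
    all(dl[upper.tri(dl)] >= eps)
  }
  membership_ok <- all(vapply(seq_along(lm), function(l) {
    setequal(cover$membership[[l]], which(dmat[, lm[l]] < eps))
  }, TRUE))
  list(coverage = all(covered), separation = separation,
       membership = membership_ok)
}

# ARI by explicit pair counting over all element pairs
oracle_ari_pairs <- function(p1, p2) {
  n <- length(p1)
  a <- b <- cc <- d <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- p1[i] == p1[j]
      s2 <- p2[i] == p2[j]
      if (s1 && s2) a <- a + 1
      else if (s1 && !s2) b <- b + 1
      else if (!s1 && s2) cc <- cc + 1
      else d <- d + 1
    }
  }
  tot <- a + b + cc + d
  expected <- (a + b) * (a + cc) / tot
  maximum <- ((a + b) + (a + cc)) / 2
  if (maximum == expected) return(1)
  (a - expected) / (maximum - expected)
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_max + 1)) {
      grow(c(labels, lab), max(next_max, lab))
    }
  }
  grow(integer(0), 0L)
  out
}

# unit vector on the (e1, e2) great circle at arc angle theta, embedded in d
unit_arc <- function(theta, d = 3) {
  v <- numeric(d)
  v[1] <- cos(theta)
  v[2] <- sin(theta)
  v
}

# wrap a plain matrix of unit rows as an nms_matrix
fake_nms <- function(mat, sample_id = "S") {
  structure(
    list(values = mat,
         retention = tibble::tibble(
           retention_index = seq_len(nrow(mat)) - 1L,
           t_r1_s = 8 * seq_len(nrow(mat)), t_r2_s = 1),
         sample_id = sample_id,
         bins = bin_range(1, ncol(mat)),
         n_dropped = 0L),
    class = "nms_matrix")
}

# wrap explicit vectors as a rums_set (for recovery-metric unit tests)
fake_rums <- function(mat, sample_id) {
  structure(
    list(sample_id = sample_id, indices = seq_len(nrow(mat)),
         retention_index = seq_len(nrow(mat)) - 1L, vectors = mat,
         nearest_foreign = rep(Inf, nrow(mat))),
    class = "rums_set")
}

# small planted-structure config used by several files (d = 120 grid)
small_synth <- function(seed = 1, K = 4, n_spectra = 200,
                        planted_groups = list(1:2, 3:4), ...) {
  synth_config(K = K, n_spectra = n_spectra, bins = bin_range(29, 148),
               planted_groups = planted_groups, seed = seed, ...)
}
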