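#' Pool unique markers across samples
#'
#' Concatenates every sample's relatively unique vectors into one point
#' cloud on the unit sphere, keeping each vector traceable to its source
#' sample. The pooled cloud is the input to the randomized-view group
#' discovery. Samples whose marker set is empty contribute no rows but are
#' retained in the sample roster (their frequency-matrix rows will be zero
#' and flagged).
#'
#' @param rums_sets Named list of `rums_set` objects.
#' @return A `pooled_rums`: list with `vectors` (J x d matrix), `sample_of`
#'   (length-J sample id per row), `sample_ids` (full roster), `counts`
#'   (named per-sample marker counts).
#' @export
pool_rums <- function(rums_sets) {
  stopifnot(length(rums_sets) >= 1,
            all(vapply(rums_sets, inherits, TRUE, "rums_set")))
  ids <- unname(vapply(rums_sets, function(x) x$sample_id, ""))
  counts <- unname(vapply(rums_sets, function(x) length(x$indices), 1L))
  names(counts) <- ids
  if (sum(counts) == 0) {
    stop("Every sample's unique-marker set is empty; nothing to pool.",
         call. = FALSE)
  }
  vectors <- do.call(rbind, lapply(rums_sets, function(x) x$vectors))
  sample_of <- rep(ids, counts)
  structure(list(vectors = vectors, sample_of = sample_of,
                 sample_ids = ids, counts = counts),
            class = "pooled_rums")
}

#' @export
print.pooled_rums <- function(x, ...) {
  cat(sprintf("<pooled_rums> %d vectors from %d samples (%d empty)\n",
              nrow(x$vectors), length(x$sample_ids), sum(x$counts == 0)))
  invisible(x)
}

#' One randomized Ball Mapper view with its frequency matrix
#'
#' Shuffles the pooled marker cloud with a seeded uniform permutation,
#' builds the greedy epsilon-net Ball Mapper at the coarse radius `gamma`,
#' and records how each sample's markers distribute over the resulting
#' nodes: entry `(k, l)` is the number of sample `k`'s markers inside node
#' `l`'s ball divided by the sample's total marker count, so rows lie in
#' `[0, 1]` (a marker sitting in two overlapping balls counts in both
#' columns). Because the greedy net is order-dependent, different seeds
#' give genuinely different views of the same cloud; the ensemble of views
#' is what the stability scan consumes.
#'
#' @param pooled A [pool_rums()] result.
#' @param gamma Coarse view radius (default `3 * 0.08`).
#' @param seed Seed of the permutation.
#' @param shuffle_id Optional integer tag carried into results.
#' @return A `mapper_view`: list with `shuffle_id`, `seed`, `graph`
#'   (`ball_mapper`), `freq` (K x L matrix, rownames sample ids),
#'   `empty_samples`.
#' @export
frequency_matrix <- function(pooled, gamma = 0.24, seed = 1,
                             shuffle_id = NULL) {
  stopifnot(inherits(pooled, "pooled_rums"), gamma > 0)
  J <- nrow(pooled$vectors)
  perm <- with_seed_local(seed, sample.int(J))
  graph <- ball_mapper(pooled$vectors, epsilon = gamma, ordering = perm)
  L <- nrow(graph$nodes)
  K <- length(pooled$sample_ids)
  freq <- matrix(0, nrow = K, ncol = L,
                 dimnames = list(pooled$sample_ids, NULL))
  for (l in seq_len(L)) {
    mem <- graph$cover$membership[[l]]
    tab <- table(pooled$sample_of[mem])
    freq[names(tab), l] <- as.numeric(tab)
  }
  freq <- freq / ifelse(pooled$counts == 0, 1, pooled$counts)[pooled$sample_ids]
  structure(list(shuffle_id = shuffle_id, seed = seed, graph = graph,
                 freq = freq,
                 empty_samples = pooled$sample_ids[pooled$counts == 0]),
            class = "mapper_view")
}

#' @export
print.mapper_view <- function(x, ...) {
  cat(sprintf("<mapper_view> %s%d samples x %d nodes (seed %s)\n",
              if (is.null(x$shuffle_id)) "" else
                paste0("shuffle ", x$shuffle_id, ": "),
              nrow(x$freq), ncol(x$freq), format(x$seed)))
  invisible(x)
}

#' Ensemble of randomized views
#'
#' @param pooled A [pool_rums()] result.
#' @param gamma Coarse view radius.
#' @param n_views Number of randomized views `S`.
#' @param seed Base seed; view `s` uses `seed + s`.
#' @return List of `mapper_view` objects.
#' @export
ball_mapper_views <- function(pooled, gamma = 0.24, n_views = 1000,
                              seed = 1) {
  lapply(seq_len(n_views), function(s) {
    frequency_matrix(pooled, gamma = gamma, seed = seed + s, shuffle_id = s)
  })
}

cosine_dissimilarity <- function(mat) {
  nrm <- sqrt(rowSums(mat^2))
  nrm[nrm == 0] <- 1
  sim <- tcrossprod(mat / nrm)
  sim[sim > 1] <- 1
  stats::as.dist(1 - sim)
}

# average-linkage tree over cosine dissimilarity of the rows
row_tree <- function(mat) stats::hclust(cosine_dissimilarity(mat),
                                        method = "average")

# cut the rows of `mat` into exactly Q clusters, giving each all-zero row
# its own cluster (cosine direction undefined there)
cut_rows <- function(mat, Q, warn = TRUE) {
  K <- nrow(mat)
  if (Q < 2 || Q > K) {
    stop("Q must satisfy 2 <= Q <= ", K, ".", call. = FALSE)
  }
  zero <- rowSums(mat^2) == 0
  labels <- integer(K)
  if (any(zero)) {
    if (warn) warning(sum(zero), " all-zero row(s) assigned to their own ",
                      "cluster.", call. = FALSE)
    qz <- sum(zero)
    if (Q - qz < 1 || (K - qz) < (Q - qz)) {
      stop("Too few non-zero rows for Q = ", Q, ".", call. = FALSE)
    }
    if (Q - qz == 1) {
      labels[!zero] <- 1L
    } else {
      labels[!zero] <- stats::cutree(row_tree(mat[!zero, , drop = FALSE]),
                                     k = Q - qz)
    }
    labels[zero] <- (Q - qz) + seq_len(qz)
  } else {
    labels <- stats::cutree(row_tree(mat), k = Q)
  }
  stats::setNames(labels, rownames(mat))
}

# cut the same row set at several Q at once (one tree when no zero rows)
cut_rows_multi <- function(mat, qs, warn = FALSE) {
  if (any(rowSums(mat^2) == 0)) {
    out <- vapply(qs, function(q) cut_rows(mat, q, warn = warn),
                  integer(nrow(mat)))
  } else {
    out <- stats::cutree(row_tree(mat), k = qs)
    if (is.null(dim(out))) out <- matrix(out, ncol = length(qs))
  }
  colnames(out) <- qs
  out
}

#' Cluster the samples of one view
#'
#' Agglomerative (average-linkage) clustering of the view's frequency-
#' matrix rows under cosine dissimilarity, cut to exactly `Q` clusters.
#' Samples with an all-zero row (no markers) have no cosine direction and
#' are placed in singleton clusters with a warning.
#'
#' @param view A `mapper_view` (or a bare numeric matrix of rows).
#' @param Q Number of clusters, `2 <= Q <= K`.
#' @return Named integer vector of cluster labels in `1..Q`.
#' @export
cluster_rows <- function(view, Q) {
  mat <- if (inherits(view, "mapper_view")) view$freq else as.matrix(view)
  cut_rows(mat, Q)
}

#' Bootstrap stability of one view's clustering
#'
#' Scores how reproducible the `Q`-cluster solution of a view is: the rows
#' of the frequency matrix are resampled with replacement `B` times, each
#' resample is re-clustered, and the Adjusted Rand Index between the
#' reference labels and the resample's labels — restricted to the distinct
#' samples present in the resample, one label per sample — is averaged
#' over replicates. Resamples with fewer than two distinct samples carry
#' no partition information and are skipped (counted in the attributes).
#'
#' @param view A `mapper_view` or numeric matrix.
#' @param Q Number of clusters.
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Seed of the resampling stream.
#' @return Mean ARI over the used replicates, with attribute `n_used`.
#' @export
bootstrap_ari <- function(view, Q, B = 1000, seed = 1) {
  if (B < 1) stop("B must be at least 1.", call. = FALSE)
  mat <- if (inherits(view, "mapper_view")) view$freq else as.matrix(view)
  K <- nrow(mat)
  ref <- cut_rows(mat, Q, warn = FALSE)
  aris <- with_seed_local(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(K, K, replace = TRUE)
      distinct <- !duplicated(idx)
      if (sum(distinct) < 2) return(NA_real_)
      boot <- cut_rows(mat[idx, , drop = FALSE], Q, warn = FALSE)
      adjusted_rand_index(ref[idx[distinct]], boot[distinct])
    }, 1.0)
  })
  used <- !is.na(aris)
  out <- mean(aris[used])
  attr(out, "n_used") <- sum(used)
  out
}

#' Select the consensus cluster number from a stability profile
#'
#' @param P Integer vector of per-`Q` stable-view counts.
#' @param q_range The `Q` values `P` refers to (same length, ascending).
#' @return The `Q` maximising `P`; ties resolved toward the smallest `Q`.
#' @examples
#' select_q_star(c(3, 9, 9, 4), 2:5)  # 3: first maximum wins
#' @export
select_q_star <- function(P, q_range) {
  stopifnot(length(P) == length(q_range), !is.unsorted(q_range))
  q_range[which.max(P)]
}

#' Stability scan over an ensemble of views
#'
#' For every view `s` and every candidate cluster number `Q`, computes the
#' bootstrap-stability score `ARI(s, Q)` (mean ARI over `B` row resamples,
#' see [bootstrap_ari()]; one set of resamples per view is shared across
#' all `Q`). The consistency score `P(Q)` counts the views whose score
#' reaches `threshold`; the consensus cluster number `Q*` maximises it
#' (smallest `Q` on ties), and the stable-view set keeps the views with
#' `ARI(s, Q*) >= threshold` together with their `Q*`-cluster partitions.
#'
#' @param views List of `mapper_view` objects.
#' @param q_range Candidate cluster numbers; values above `K` are dropped
#'   with a message. Default `2:15`.
#' @param B Bootstrap resamples per view.
#' @param threshold Stability threshold on the mean ARI; default 0.5.
#' @param seed Base seed; each view's resampling stream is seeded with
#'   `seed` plus the view's own permutation seed.
#' @return A `consistency_table`: `ari` (S x |Q| matrix), `q_range`,
#'   `P` (tibble `Q`, `P`), `q_star`, `threshold`, `B`, `s_star`
#'   (stable view indices), `ari_star`, `partitions` (K x S label matrix
#'   at `Q*`), `sample_ids`.
#' @export
consistency_scan <- function(views, q_range = 2:15, B = 1000,
                             threshold = 0.5, seed = 1) {
  stopifnot(length(views) >= 1,
            all(vapply(views, inherits, TRUE, "mapper_view")))
  K <- nrow(views[[1]]$freq)
  sample_ids <- rownames(views[[1]]$freq)
  qr <- q_range[q_range >= 2 & q_range <= K]
  if (length(qr) < length(q_range)) {
    message("consistency_scan: Q values outside 2..", K, " dropped.")
  }
  if (length(qr) == 0) stop("No admissible Q values.", call. = FALSE)
  S <- length(views)
  ari <- matrix(NA_real_, nrow = S, ncol = length(qr),
                dimnames = list(NULL, qr))
  ref_labels <- array(NA_integer_, dim = c(K, length(qr), S))

  for (s in seq_len(S)) {
    mat <- views[[s]]$freq
    ref_labels[, , s] <- cut_rows_multi(mat, qr)
    sums <- numeric(length(qr))
    used <- integer(length(qr))
    # resampling stream keyed to the view's own seed (falling back to its
    # position) so results do not depend on the order views are passed in
    boot_seed <- seed + (views[[s]]$seed %||% s)
    with_seed_local(boot_seed, {
      for (b in seq_len(B)) {
        idx <- sample.int(K, K, replace = TRUE)
        distinct <- !duplicated(idx)
        if (sum(distinct) < 2) next
        boot <- cut_rows_multi(mat[idx, , drop = FALSE], qr)
        for (qi in seq_along(qr)) {
          sums[qi] <- sums[qi] +
            adjusted_rand_index(ref_labels[idx[distinct], qi, s],
                                boot[distinct, qi])
          used[qi] <- used[qi] + 1L
        }
      }
    })
    ari[s, ] <- sums / pmax(used, 1)
  }

  P <- colSums(ari >= threshold)
  q_star <- select_q_star(P, qr)
  qi_star <- match(q_star, qr)
  ari_star <- ari[, qi_star]
  s_star <- which(ari_star >= threshold)
  partitions <- ref_labels[, qi_star, , drop = TRUE]
  if (is.null(dim(partitions))) partitions <- matrix(partitions, nrow = K)
  rownames(partitions) <- sample_ids
  structure(
    list(ari = ari, q_range = qr,
         P = tibble::tibble(Q = qr, P = as.integer(P)),
         q_star = q_star, threshold = threshold, B = B,
         s_star = s_star, ari_star = ari_star,
         partitions = partitions, sample_ids = sample_ids),
    class = "consistency_table")
}

#' @export
print.consistency_table <- function(x, ...) {
  cat(sprintf(
    "<consistency_table> %d views x Q in %d..%d (B = %d): Q* = %d, %d stable views\n",
    nrow(x$ari), min(x$q_range), max(x$q_range), x$B, x$q_star,
    length(x$s_star)))
  invisible(x)
}

#' Mine representative sample groups from the stable views
#'
#' Every stable view contributes its `Q*`-cluster partition; each cluster,
#' read as a set of sample ids, enters a multiset. A representative group
#' is a sample set recurring in that multiset: its occurrence frequency
#' `phi` is its multiplicity, and its reproducibility `A` is the mean
#' stability score of the views in which it occurs. Groups may overlap and
#' a sample may appear in several groups — overlapping relationships that
#' exclusive clustering cannot express are exactly what the multiset view
#' retains.
#'
#' @param scan A [consistency_scan()] result (or a list with `partitions`,
#'   `s_star`, `ari_star`, `sample_ids`).
#' @param min_phi Report only groups recurring at least this often;
#'   default 50.
#' @return A `rep_groups` tibble: `rank`, `members` (list column of sample
#'   ids), `size`, `phi`, `A`; sorted by `phi` desc, then `size` desc, then
#'   members lexicographically.
#' @export
extract_representative_groups <- function(scan, min_phi = 50) {
  if (length(scan$s_star) == 0) {
    stop("No stable views: cannot extract representative groups.",
         call. = FALSE)
  }
  keys <- character(0)
  members <- list()
  phi <- integer(0)
  a_sum <- numeric(0)
  for (s in scan$s_star) {
    labs <- scan$partitions[, s]
    for (q in unique(labs)) {
      grp <- unname(sort(scan$sample_ids[labs == q]))
      key <- paste(grp, collapse = "\r")
      j <- match(key, keys)
      if (is.na(j)) {
        keys <- c(keys, key)
        members[[length(members) + 1L]] <- grp
        phi <- c(phi, 1L)
        a_sum <- c(a_sum, scan$ari_star[s])
      } else {
        phi[j] <- phi[j] + 1L
        a_sum[j] <- a_sum[j] + scan$ari_star[s]
      }
    }
  }
  tb <- tibble::tibble(members = members,
                       size = vapply(members, length, 1L),
                       phi = phi, A = a_sum / phi)
  tb <- tb[tb$phi >= min_phi, , drop = FALSE]
  key_str <- vapply(tb$members, paste, "", collapse = ",")
  ord <- order(-tb$phi, -tb$size, key_str)
  tb <- tb[ord, , drop = FALSE]
  tb <- dplyr::mutate(tb, rank = dplyr::row_number(), .before = 1)
  class(tb) <- c("rep_groups", class(tb))
  tb
}
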