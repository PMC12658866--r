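pooled_from_matrix <- function(mat, sample_of, sample_ids = NULL) {
  ids <- sample_ids %||% unique(sample_of)
  counts <- vapply(ids, function(id) sum(sample_of == id), 1L)
  names(counts) <- ids
  structure(list(vectors = mat, sample_of = sample_of,
                 sample_ids = ids, counts = counts),
            class = "pooled_rums")
}

test_that("pooling conserves marker counts and traceability", {
  one <- fake_rums(diag(3), "A")
  p1 <- pool_rums(list(A = one))
  expect_equal(nrow(p1$vectors), 3)
  expect_equal(p1$counts[["A"]], 3)

  two <- fake_rums(rbind(c(0, 0, 1)), "B")
  p2 <- pool_rums(list(A = one, B = two))
  expect_equal(nrow(p2$vectors), 4)
  expect_equal(p2$sample_of, c("A", "A", "A", "B"))

  none <- fake_rums(matrix(0, 0, 3), "C")
  expect_error(pool_rums(list(C = none)), "empty")

  # an empty sample rides along in the roster
  p3 <- pool_rums(list(A = one, C = none))
  expect_equal(p3$sample_ids, c("A", "C"))
  expect_equal(p3$counts[["C"]], 0)
})

test_that("frequency matrices record per-sample node occupancy in [0, 1]", {
  # all of one sample's markers in one node
  mat <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1))
  pooled <- pooled_from_matrix(mat, c("A", "A", "A", "B"))
  v <- frequency_matrix(pooled, gamma = 0.1, seed = 3)
  expect_equal(dim(v$freq), c(2, 2))
  expect_equal(sort(v$freq["A", ]), c(0, 1))
  expect_equal(sort(v$freq["B", ]), c(0, 1))

  # 1-D toy: A at {0, 0.07}, B at {0.5}, radius 0.1
  toy <- pooled_from_matrix(matrix(c(0, 0.07, 0.5), ncol = 1),
                            c("A", "A", "B"))
  vt <- frequency_matrix(toy, gamma = 0.1, seed = 1)
  expect_equal(dim(vt$freq), c(2, 2))
  expect_equal(sort(vt$freq["A", ]), c(0, 1))
  expect_equal(sort(vt$freq["B", ]), c(0, 1))
  expect_true(all(vt$freq >= 0 & vt$freq <= 1))

  # overlapping balls: a point in two balls counts in both columns
  ov <- pooled_from_matrix(matrix(c(0, 0.07, 0.14), ncol = 1),
                           c("A", "A", "A"))
  vo <- frequency_matrix(ov, gamma = 0.08, seed = 2)
  expect_gt(sum(vo$freq["A", ]), 1 - 1e-12)

  # an empty sample yields a flagged all-zero row
  withempty <- pooled_from_matrix(mat, c("A", "A", "A", "B"),
                                  sample_ids = c("A", "B", "C"))
  ve <- frequency_matrix(withempty, gamma = 0.1, seed = 4)
  expect_equal(unname(ve$freq["C", ]), c(0, 0))
  expect_equal(ve$empty_samples, "C")

  # the view's cover satisfies the net conditions at the coarse radius
  chk <- oracle_check_net(mat, v$graph$cover)
  expect_true(chk$coverage && chk$separation)
})

test_that("row clustering recovers planted splits and guards its range", {
  rows <- rbind(a1 = c(1, 0, 0), a2 = c(1, 0, 0),
                b1 = c(0, 1, 0), b2 = c(0, 1, 0))
  labs <- cluster_rows(rows, 2)
  expect_equal(labs[["a1"]], labs[["a2"]])
  expect_equal(labs[["b1"]], labs[["b2"]])
  expect_true(labs[["a1"]] != labs[["b1"]])

  # exhaustive: no other bipartition separates these rows correctly
  singles <- cluster_rows(rows, 4)
  expect_equal(length(unique(singles)), 4)
  expect_error(cluster_rows(rows, 1), "Q must satisfy")
  expect_error(cluster_rows(rows, 5), "Q must satisfy")

  withzero <- rbind(rows, z = c(0, 0, 0))
  expect_warning(labz <- cluster_rows(withzero, 3), "all-zero")
  expect_equal(length(unique(labz)), 3)
  expect_true(!labz[["z"]] %in% labz[c("a1", "a2", "b1", "b2")])
})

test_that("bootstrap stability separates duplicated structure from noise", {
  # two exactly-duplicated groups of six rows: perfectly stable
  rows <- rbind(matrix(rep(c(1, 0), 6), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 1), 6), ncol = 2, byrow = TRUE))
  expect_equal(as.numeric(bootstrap_ari(rows, 2, B = 50, seed = 1)), 1)

  # i.i.d. noise rows: stability is well below perfect (it does not reach
  # zero — the reference and every resample cluster the same data, so the
  # score retains a positive baseline)
  set.seed(99)
  noise <- matrix(abs(rnorm(20 * 12)), 20, 12)
  val <- as.numeric(bootstrap_ari(noise, 4, B = 200, seed = 2))
  expect_lt(val, 0.6)
  expect_gt(val, -0.15)

  expect_error(bootstrap_ari(rows, 2, B = 0), "at least 1")
})

test_that("the consistency scan counts stable views and picks Q*", {
  expect_equal(select_q_star(c(34, 795, 871, 924, 971, 980, 981, 976, 986,
                               993, 991, 970, 928, 755), 2:15), 11)
  expect_equal(select_q_star(rep(7, 14), 2:15), 2)  # ties -> smallest Q
  # hand-built threshold crossings
  expect_equal(select_q_star(c(1, 5, 5, 2), 2:5), 3)

  mat <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 0, 0),
               c(0, 1, 0), c(0, 1, 0), c(0, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
  rownames(mat) <- paste0("S", 1:12)
  mk_view <- function(s) structure(
    list(shuffle_id = s, seed = 100 + s, graph = NULL, freq = mat,
         empty_samples = character(0)), class = "mapper_view")
  views <- lapply(1:5, mk_view)
  scan <- consistency_scan(views, q_range = 2:6, B = 30, seed = 5)
  expect_equal(dim(scan$ari), c(5, 5))
  expect_true(all(scan$ari >= -1 & scan$ari <= 1))
  expect_true(all(scan$P$P >= 0 & scan$P$P <= 5))
  # three exactly-duplicated groups: stability peaks at the planted Q = 3
  # (replicates dip below 1 only when a resample loses a whole group)
  expect_true(all(scan$ari[, "3"] > 0.95))
  expect_true(all(scan$ari[, "3"] >= apply(scan$ari, 1, max) - 1e-9))
  expect_equal(scan$q_star, 3)
  expect_equal(length(scan$s_star), 5)

  # P is invariant to the order the views are passed in
  scan_rev <- consistency_scan(rev(views), q_range = 2:6, B = 30, seed = 5)
  expect_equal(scan_rev$P, scan$P)
  expect_equal(sort(scan_rev$ari[, "3"]), sort(scan$ari[, "3"]))
})

test_that("representative groups are mined from the stable multiset", {
  # degenerate: every stable view yields the identical partition
  sample_ids <- paste0("S", 1:4)
  partitions <- matrix(rep(c(1, 1, 2, 2), 3), ncol = 3,
                       dimnames = list(sample_ids, NULL))
  scan <- list(partitions = partitions, s_star = 1:3,
               ari_star = c(0.9, 0.7, 0.8), sample_ids = sample_ids)
  gg <- extract_representative_groups(scan, min_phi = 1)
  expect_equal(nrow(gg), 2)
  expect_equal(gg$phi, c(3, 3))
  expect_equal(gg$A, c(0.8, 0.8))

  # five hand-written partitions over six samples vs direct enumeration
  ids6 <- paste0("S", 1:6)
  plist <- list(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 3, 3),
                c(1, 1, 1, 2, 2, 2), c(1, 2, 2, 3, 3, 3),
                c(1, 1, 1, 2, 2, 2))
  parts <- do.call(cbind, plist)
  rownames(parts) <- ids6
  ari_star <- c(0.6, 0.7, 0.8, 0.9, 1.0)
  scan6 <- list(partitions = parts, s_star = 1:5, ari_star = ari_star,
                sample_ids = ids6)
  got <- extract_representative_groups(scan6, min_phi = 1)
  # enumerate by hand: collect every cluster of every partition
  expected <- list()
  for (s in 1:5) {
    for (q in unique(plist[[s]])) {
      key <- paste(ids6[plist[[s]] == q], collapse = ",")
      cur <- expected[[key]] %||% list(phi = 0L, a = numeric(0))
      expected[[key]] <- list(phi = cur$phi + 1L, a = c(cur$a, ari_star[s]))
    }
  }
  expect_equal(nrow(got), length(expected))
  for (i in seq_len(nrow(got))) {
    key <- paste(got$members[[i]], collapse = ",")
    expect_equal(got$phi[i], expected[[key]]$phi)
    expect_equal(got$A[i], mean(expected[[key]]$a))
  }
  # sorted by recurrence, then size
  expect_true(all(diff(got$phi) <= 0))

  # invariant to permuting the multiset
  perm <- c(3, 1, 5, 2, 4)
  scan_p <- list(partitions = parts[, perm], s_star = 1:5,
                 ari_star = ari_star[perm], sample_ids = ids6)
  got_p <- extract_representative_groups(scan_p, min_phi = 1)
  expect_equal(got_p, got)

  # min_phi filters
  top <- extract_representative_groups(scan6, min_phi = 3)
  expect_true(all(top$phi >= 3))
  expect_error(extract_representative_groups(
    list(partitions = parts, s_star = integer(0), ari_star = ari_star,
         sample_ids = ids6)), "No stable views")
})
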