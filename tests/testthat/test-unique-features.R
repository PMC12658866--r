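test_that("separation parameters enforce the admissible regime", {
  p <- separation_params(0.08, 0.3)
  expect_equal(p$delta, 0.024)
  expect_equal(3 * p$delta, 0.072)
  expect_equal(p$gamma, 0.24)
  expect_error(separation_params(0.08, 0.5), "3\\*delta")
  expect_error(separation_params(0.08, 0.2), "3\\*delta")
})

test_that("representative vectors are the sample's epsilon-net landmarks", {
  same <- fake_nms(matrix(rep(c(1, 0, 0), 10), 10, 3, byrow = TRUE), "A")
  rms <- representative_vectors(same)
  expect_equal(length(rms$indices), 1)

  # two motifs far apart, noisy copies within epsilon/2 of each
  set.seed(2)
  motif1 <- unit_arc(0)
  motif2 <- unit_arc(pi / 2)
  jitter_on_sphere <- function(v, ang) {
    u <- c(-v[2], v[1], 0)
    w <- cos(ang) * v + sin(ang) * u
    w / sqrt(sum(w^2))
  }
  rows <- rbind(
    t(vapply(runif(15, -0.02, 0.02), jitter_on_sphere, numeric(3), v = motif1)),
    t(vapply(runif(15, -0.02, 0.02), jitter_on_sphere, numeric(3), v = motif2)))
  rms2 <- representative_vectors(fake_nms(rows, "B"))
  expect_equal(length(rms2$indices), 2)
  chk <- oracle_check_net(rows, rms2$cover)
  expect_true(chk$coverage && chk$separation)
})

test_that("relative uniqueness applies the strict 3-delta rule", {
  params <- separation_params()
  # a single sample: the cross-sample condition is vacuous
  a <- representative_vectors(fake_nms(diag(3), "A"), params)
  solo <- relatively_unique(list(A = a), params)
  expect_equal(length(solo$A$indices), length(a$indices))

  # identical representative sets kill each other
  b <- representative_vectors(fake_nms(diag(3), "B"), params)
  both <- relatively_unique(list(A = a, B = b), params)
  expect_equal(length(both$A$indices), 0)
  expect_equal(length(both$B$indices), 0)

  # orthogonal unit vectors are mutually unique (distance sqrt(2) > 0.072)
  a1 <- representative_vectors(fake_nms(rbind(c(1, 0)), "A"), params)
  b1 <- representative_vectors(fake_nms(rbind(c(0, 1)), "B"), params)
  ru <- relatively_unique(list(A = a1, B = b1), params)
  expect_equal(length(ru$A$indices), 1)
  expect_equal(length(ru$B$indices), 1)
  expect_equal(ru$A$nearest_foreign, sqrt(2))

  # a tie at exactly 3*delta is excluded (strict inequality); the pair
  # (1, 0) vs (1, 3*delta) has squared distance (3*delta)^2 exactly
  at <- representative_vectors(fake_nms(rbind(c(1, 0)), "A"), params)
  bt <- representative_vectors(fake_nms(rbind(c(1, 3 * params$delta)), "B"),
                               params)
  tie <- relatively_unique(list(A = at, B = bt), params)
  expect_equal(length(tie$A$indices), 0)
})

test_that("markers form the subset chain and grow when samples leave", {
  ds <- generate_dataset(small_synth(seed = 21))
  nms <- vectorize_samples(ds$samples)
  params <- separation_params()
  rms <- lapply(nms, representative_vectors, params = params)
  rums <- relatively_unique(rms, params)
  for (id in names(nms)) {
    expect_true(all(rums[[id]]$indices %in% rms[[id]]$indices))
    expect_lte(length(rums[[id]]$indices), length(rms[[id]]$indices))
    expect_lte(length(rms[[id]]$indices), nrow(nms[[id]]$values))
    # post-hoc brute-force check of the separation rule
    for (other in setdiff(names(nms), id)) {
      if (length(rums[[id]]$indices) == 0) next
      d2 <- spectramapper:::cross_dist2(rums[[id]]$vectors,
                                        rms[[other]]$vectors)
      expect_true(all(sqrt(d2) > 3 * params$delta))
    }
  }
  # dropping one sample never shrinks another's marker set
  keep <- setdiff(names(rms), "S02")
  fewer <- relatively_unique(rms[keep], params)
  for (id in keep) {
    expect_true(all(rums[[id]]$indices %in% fewer[[id]]$indices))
  }
})

test_that("end-to-end marker sets are invariant to intensity scaling", {
  ds <- generate_dataset(small_synth(seed = 31, K = 3, n_spectra = 150,
                                     planted_groups = list(1:3)))
  params <- separation_params()
  run_markers <- function(samples) {
    nms <- vectorize_samples(samples, bins = bin_range(29, 148))
    rms <- lapply(nms, representative_vectors, params = params)
    relatively_unique(rms, params)
  }
  base <- run_markers(ds$samples)
  scaled <- dplyr::mutate(
    ds$samples,
    intensity = intensity * ifelse(sample_id == "S02", 25, 1))
  again <- run_markers(scaled)
  for (id in names(base)) {
    expect_equal(base[[id]]$indices, again[[id]]$indices)
  }
})

test_that("the locality audit reports exactly the planted violations", {
  params <- separation_params()
  # compliant: two samples, orthogonal templates, no neighbours across
  a <- fake_nms(rbind(unit_arc(0), unit_arc(0.01)), "A")
  bvec <- c(0, 0, 1)
  b <- fake_nms(rbind(bvec), "B")
  rms <- list(A = representative_vectors(a, params),
              B = representative_vectors(b, params))
  rums <- relatively_unique(rms, params)
  rep0 <- verify_locality(rums, list(A = a, B = b), params)
  expect_equal(nrow(rep0$violations), 0)

  # adversarial: marker F at 0, neighbour at arc 0.02 (< delta); the other
  # sample holds a point at arc 0.035 (0.015 from the neighbour) that its
  # own representative (arc 0.085, > 3*delta from F) covers and hides
  a2 <- fake_nms(rbind(unit_arc(0), unit_arc(0.02)), "A")
  b2 <- fake_nms(rbind(unit_arc(0.085), unit_arc(0.035)), "B")
  rms2 <- list(A = representative_vectors(a2, params),
               B = representative_vectors(b2, params))
  expect_equal(rms2$B$indices, 1)  # 0.035 is covered by 0.085
  rums2 <- relatively_unique(rms2, params)
  expect_equal(rums2$A$indices, 1)  # F survives the 3-delta screen
  rep1 <- verify_locality(rums2, list(A = a2, B = b2), params)
  expect_equal(nrow(rep1$violations), 1)
  expect_equal(rep1$violations$sample_id, "A")
  expect_equal(rep1$violations$other_sample, "B")
  expect_equal(rep1$violations$distance, 2 * sin((0.035 - 0.02) / 2),
               tolerance = 1e-9)

  # no neighbour strictly within delta: vacuously clean
  a3 <- fake_nms(rbind(unit_arc(0)), "A")
  b3 <- fake_nms(rbind(bvec), "B")
  rms3 <- list(A = representative_vectors(a3, params),
               B = representative_vectors(b3, params))
  rums3 <- relatively_unique(rms3, params)
  rep2 <- verify_locality(rums3, list(A = a3, B = b3), params)
  expect_equal(nrow(rep2$violations), 0)
})

test_that("marker summary mirrors the per-sample reduction", {
  ds <- generate_dataset(small_synth(seed = 41, K = 3, n_spectra = 150,
                                     planted_groups = list()))
  nms <- vectorize_samples(ds$samples)
  rms <- lapply(nms, representative_vectors)
  rums <- relatively_unique(rms)
  tb <- marker_summary(rms, rums, nms)
  expect_equal(names(tb), c("sample_id", "n_spectra", "n_rms", "n_rums"))
  expect_true(all(tb$n_rums <= tb$n_rms & tb$n_rms <= tb$n_spectra))
  expect_equal(tb$n_rums,
               vapply(rums[tb$sample_id], function(x) length(x$indices), 1L))
})
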