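test_that("discretisation follows the half-open max-bin rule", {
  bins <- bin_range(29, 31)
  empty <- tibble::tibble(mz = numeric(0), intensity = numeric(0))
  expect_equal(discretize_spectrum(empty, bins), c(0, 0, 0))

  sp <- tibble::tibble(mz = c(29.3, 29.6, 30.9), intensity = c(5, 7, 2))
  expect_equal(discretize_spectrum(sp, bins), c(5, 7, 2))

  two <- tibble::tibble(mz = c(30.1, 30.4), intensity = c(4, 9))
  expect_equal(discretize_spectrum(two, bin_range(30, 30)), 9)

  # a peak at exactly n + 1/2 belongs to the next bin
  edge <- tibble::tibble(mz = c(29.5), intensity = 3)
  expect_equal(discretize_spectrum(edge, bins), c(0, 3, 0))

  out <- tibble::tibble(mz = 32.0, intensity = 1)
  expect_error(discretize_spectrum(out, bins), "outside the global bin range")
})

test_that("discretisation agrees with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    m <- sample(20:60, 1)
    M <- m + sample(0:29, 1)
    n_peaks <- sample(0:50, 1)
    mz <- runif(n_peaks, m - 0.5, M + 0.5 - 1e-9)
    intensity <- runif(n_peaks, 0, 100)
    got <- discretize_spectrum(tibble::tibble(mz = mz, intensity = intensity),
                               bin_range(m, M))
    expect_equal(got, oracle_discretize(mz, intensity, m, M))
  }
})

test_that("global bin range covers the observed m/z domain and is monotone", {
  acq <- tibble::tibble(mz = c(29.0, 600.4), intensity = c(1, 1))
  br <- global_bin_range(acq)
  expect_equal(c(br$m, br$M), c(29, 600))

  single <- global_bin_range(tibble::tibble(mz = 100.2, intensity = 1))
  expect_equal(c(single$m, single$M, single$d), c(100, 100, 1))

  span <- global_bin_range(tibble::tibble(mz = c(45.7, 60.2),
                                          intensity = c(1, 1)))
  expect_equal(c(span$m, span$M, span$d), c(46, 60, 15))

  expect_error(global_bin_range(tibble::tibble(mz = numeric(0),
                                               intensity = numeric(0))),
               "No spectra")

  # adding a sample never shrinks the range
  set.seed(7)
  base <- tibble::tibble(mz = runif(20, 50, 80), intensity = 1)
  br0 <- global_bin_range(base)
  for (i in 1:10) {
    extra <- tibble::tibble(mz = runif(10, 30, 120), intensity = 1)
    br1 <- global_bin_range(dplyr::bind_rows(base, extra))
    expect_lte(br1$m, br0$m)
    expect_gte(br1$M, br0$M)
  }
})

test_that("unit-sphere projection is scale invariant and rejects zero", {
  expect_equal(normalize_spectrum(c(3, 4, 0)), c(0.6, 0.8, 0))
  v <- c(0.3, 0, 5, 2)
  expect_equal(normalize_spectrum(17.3 * v), normalize_spectrum(v))
  expect_error(normalize_spectrum(c(0, 0, 0)), "empty spectrum")
})

test_that("retention-window exclusion keeps the closed interval in order", {
  run <- tibble::tibble(t_r1_s = c(600, 3000, 5400), t_r2_s = 1,
                        mz = 50, intensity = 1)
  expect_identical(exclude_retention_window(run, c(0, 1e6)), run)
  kept <- exclude_retention_window(run, c(1200, 4800))
  expect_equal(kept$t_r1_s, 3000)
  expect_warning(exclude_retention_window(run, c(0, 0)), "excludes every")
  expect_error(exclude_retention_window(run, c(10, 5)), "t_r1_min")
})

test_that("feature matrices have unit rows in lexicographic retention order", {
  ds <- generate_dataset(small_synth(seed = 5, K = 2, n_spectra = 80,
                                     planted_groups = list()))
  nms <- vectorize_samples(ds$samples)
  for (m in nms) {
    expect_equal(sqrt(rowSums(m$values^2)), rep(1, nrow(m$values)),
                 tolerance = 1e-9)
    ord <- order(m$retention$t_r1_s, m$retention$t_r2_s)
    expect_equal(ord, seq_len(nrow(m$values)))
  }
})

test_that("all-zero spectra are dropped and counted", {
  run <- tibble::tibble(
    t_r1_s = c(8, 8, 16), t_r2_s = c(1, 2, 1),
    mz = c(50.1, 60.2, 55.0), intensity = c(5, 0, 3))
  m <- nms_vectors(run, bin_range(50, 61), sample_id = "A")
  expect_equal(nrow(m$values), 2)
  expect_equal(m$n_dropped, 1)
})

test_that("scaling a sample's intensities leaves its feature matrix unchanged", {
  ds <- generate_dataset(small_synth(seed = 9, K = 2, n_spectra = 80,
                                     planted_groups = list()))
  one <- ds$samples[ds$samples$sample_id == "S01", ]
  a <- nms_vectors(one, bin_range(29, 148))
  scaled <- dplyr::mutate(one, intensity = intensity * 4)
  b <- nms_vectors(scaled, bin_range(29, 148))
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_equal(a$retention, b$retention)
})

test_that("resolution calibration is the coverage order statistic", {
  # 100 matched replicate pairs with distances 0.001 .. 0.100
  d <- 3
  thetas <- vapply((1:100) / 1000, function(ch) 2 * asin(ch / 2), 1.0)
  a <- fake_nms(t(vapply(rep(0, 100), unit_arc, numeric(d), d = d)), "r1")
  b <- fake_nms(t(vapply(thetas, unit_arc, numeric(d), d = d)), "r2")
  expect_equal(calibrate_resolution(list(a, b), coverage = 0.95), 0.095,
               tolerance = 1e-9)

  # identical replicates degenerate to the configured floor
  expect_equal(calibrate_resolution(list(a, a), epsilon_floor = 1e-4), 1e-4)

  # monotone nondecreasing in coverage
  covs <- c(0.5, 0.8, 0.9, 0.95, 1)
  eps <- vapply(covs, function(cv)
    calibrate_resolution(list(a, b), coverage = cv), 1.0)
  expect_true(all(diff(eps) >= 0))

  expect_error(calibrate_resolution(list(a)), "two replicate")
  c_bad <- fake_nms(diag(4), "r3")
  expect_error(calibrate_resolution(list(a, c_bad)), "bin range")
})
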