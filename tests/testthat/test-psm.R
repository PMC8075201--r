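# eigenspectrum analysis and dimensionality indicators

test_that("the spectrum matches a brute-force correlation eigendecomposition", {
  set.seed(51)
  for (dims in list(c(8, 5), c(20, 10), c(12, 7))) {
    m <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
    sp <- pca_eigenspectrum(m)
    ev <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sp$eigenvalues, ev[seq_along(sp$eigenvalues)],
                 tolerance = 1e-8)
    expect_equal(sum(sp$explained), 1, tolerance = 1e-9)
    expect_true(all(diff(sp$eigenvalues) <= 1e-10))
  }
})

test_that("a rank-one matrix concentrates all variance on one component", {
  set.seed(52)
  base <- stats::rnorm(10)
  m <- outer(base, c(1, -2, 0.5, 3))
  sp <- pca_eigenspectrum(m)
  expect_equal(sp$explained[1], 1, tolerance = 1e-9)
})

test_that("orthogonal standardized columns give a flat spectrum", {
  m <- unclass(stats::poly(1:9, degree = 4))
  sp <- pca_eigenspectrum(m)
  expect_equal(sp$eigenvalues, rep(1, 4), tolerance = 1e-8)
  expect_equal(sp$explained, rep(0.25, 4), tolerance = 1e-8)
})

test_that("zero-variance columns are dropped with a warning", {
  set.seed(53)
  m <- cbind(matrix(stats::rnorm(30), 10, 3), 0.7)
  expect_warning(sp <- pca_eigenspectrum(m), "zero-variance")
  expect_equal(sp$n_components, 3L)
  expect_equal(sp$n_dropped, 1L)
  expect_equal(sum(sp$explained), 1, tolerance = 1e-9)
  expect_error(pca_eigenspectrum(matrix(1, 5, 3)), "degenerate")
})

test_that("indicators sum fixed component ranges of explained variance", {
  sp <- fake_spectrum(c(0.6, 0.2, 0.1, 0.05, 0.03, 0.01, 0.01))
  di <- dimensionality_indicators(sp)
  expect_equal(di$wght_pd, 0.8)
  expect_equal(di$wght_sd, 0.19)

  rank2 <- fake_spectrum(c(0.7, 0.3))          # padded beyond rank
  di2 <- dimensionality_indicators(rank2)
  expect_equal(di2$wght_pd, 1)
  expect_equal(di2$wght_sd, 0)

  flat <- fake_spectrum(rep(1 / 240, 240))
  di3 <- dimensionality_indicators(flat)
  expect_equal(di3$wght_pd, 2 / 240)
  expect_equal(di3$wght_sd, 4 / 240)
})

test_that("indicators are invariant to micro-stage column reordering", {
  set.seed(54)
  m <- matrix(stats::rnorm(200), 20, 10)
  di <- dimensionality_indicators(pca_eigenspectrum(m))
  perm <- sample.int(10)
  di_p <- dimensionality_indicators(pca_eigenspectrum(m[, perm]))
  expect_equal(di_p$wght_pd, di$wght_pd, tolerance = 1e-10)
  expect_equal(di_p$wght_sd, di$wght_sd, tolerance = 1e-10)
})

test_that("the Kaiser-like cutoff is the lower median of eigenvalue counts", {
  sp2 <- fake_spectrum(c(2, 1.5, 0.5) / 4)     # eigenvalues 2, 1.5, 0.5
  expect_equal(kaiser_median_cutoff(list(sp2, sp2, sp2)), 2L)

  mk <- function(k, p = 12) {                  # spectrum with k eigenvalues > 1
    ev <- c(rep(2, k), rep(0.5, p - k))
    fake_spectrum(ev / sum(ev), n_vars = p)
  }
  expect_equal(kaiser_median_cutoff(list(mk(1), mk(6), mk(6))), 6L)
  expect_equal(kaiser_median_cutoff(list(mk(2), mk(3), mk(4), mk(5))), 3L)
})

test_that("the quantile profile matches a sort-and-interpolate oracle", {
  sp <- fake_spectrum(c(0.5, 0.2, 0.3))
  expect_equal(quantile_profile(list(sp, sp, sp), 0.05), 0.7)

  mk <- function(w) fake_spectrum(c(w / 2, w / 2, 1 - w))
  expect_equal(quantile_profile(lapply(c(0.5, 0.9, 0.7), mk), 0.5), 0.7)

  set.seed(55)
  ws <- stats::runif(100, 0.3, 0.95)
  spectra <- lapply(ws, mk)
  for (q in c(0.05, 0.31, 0.8)) {
    s <- sort(ws)
    h <- (length(s) - 1) * q + 1
    oracle <- s[floor(h)] + (h - floor(h)) * (s[min(100, floor(h) + 1)] - s[floor(h)])
    expect_equal(quantile_profile(spectra, q), oracle, tolerance = 1e-12)
  }
})
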