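test_that("masked FFT correlation equals the nested-loop direct sum", {
  set.seed(101)
  for (k in 1:10) {
    fx <- random_masked_pair(16)
    fft_map <- correlate_2d(fx$A, fx$B, fx$mask, 5)
    ref <- correlate_2d_direct(fx$A, fx$B, fx$mask, 5)
    expect_true(all(fft_map$n_pairs == ref$n_pairs))
    expect_lt(max(abs(fft_map$values - ref$values), na.rm = TRUE), 1e-10)
  }
})

test_that("hand-evaluated zero-lag value and constant-image limit", {
  # [[4,0],[0,0]] autocorrelation at (0,0): <I^2>/<I>^2 - 1 = 4/1 - 1 = 3
  img <- matrix(c(4, 0, 0, 0), 2, 2)
  g <- correlate_2d_direct(img, img, nuclear_mask(matrix(TRUE, 2, 2)), 0)
  expect_equal(g$values[1, 1], 3)
  # constant image: no fluctuations, G = 0 at every lag
  cimg <- matrix(5, 16, 16)
  g0 <- correlate_2d(cimg, cimg, nuclear_mask(matrix(TRUE, 16, 16)), 4)
  expect_equal(max(abs(g0$values)), 0, tolerance = 1e-12)
})

test_that("correlate_2d validates its inputs", {
  m <- nuclear_mask(matrix(TRUE, 16, 16))
  z <- matrix(0, 16, 16)
  expect_error(correlate_2d(z, z, m, 4), class = "iccscoloc_degenerate_error")
  expect_error(correlate_2d(matrix(1, 16, 16), matrix(1, 16, 16), m, 8),
               class = "iccscoloc_validation_error") # lag >= dim/2
  expect_error(correlate_2d(matrix(1, 16, 16), matrix(1, 8, 8), m, 2),
               class = "iccscoloc_validation_error")
})

test_that("autocorrelation maps are point symmetric", {
  set.seed(102)
  for (k in 1:5) {
    fx <- random_masked_pair(20)
    g <- correlate_2d(fx$A, fx$A, fx$mask, 6)
    flipped <- g$values[rev(seq_len(nrow(g$values))), rev(seq_len(ncol(g$values)))]
    expect_identical(g$values, flipped)
  }
})

test_that("radial averaging bins by euclidean lag radius", {
  # single defined lag at (0,0)
  v <- matrix(NA_real_, 3, 3); v[2, 2] <- 3
  np <- matrix(0, 3, 3); np[2, 2] <- 400
  r <- radial_average(fake_map(v, np), min_pairs = 1)
  expect_equal(r$radii_px, 0)
  expect_equal(r$g, 3)
  # four unit lags with values 1,1,3,3 -> mean 2, counts 4
  v2 <- matrix(NA_real_, 3, 3)
  v2[1, 2] <- 1; v2[3, 2] <- 1; v2[2, 1] <- 3; v2[2, 3] <- 3
  r2 <- radial_average(fake_map(v2), min_pairs = 1)
  expect_equal(r2$radii_px, 1)
  expect_equal(r2$g, 2)
  expect_equal(r2$counts, 4L)
  expect_error(radial_average(fake_map(v2), bin_width_px = 0),
               class = "iccscoloc_validation_error")
})

test_that("radial mean of a rotationally symmetric map tracks the profile", {
  L <- 6
  lags <- -L:L
  v <- outer(lags, lags, function(dy, dx) exp(-(dx^2 + dy^2) / 9))
  r <- radial_average(fake_map(v), bin_width_px = 1, min_pairs = 1)
  keep <- r$radii_px <= L # corner bins undersample the annulus
  expect_equal(r$g[keep], exp(-r$radii_px[keep]^2 / 9), tolerance = 0.02)
  # the r = 0 bin is exactly the zero-lag value
  expect_equal(r$g[r$radii_px == 0], v[L + 1, L + 1])
})

test_that("gaussian fit recovers analytic parameters", {
  r <- 1:12
  fit <- fit_gaussian(fake_radial(r, 0.5 * exp(-r^2 / 16) + 0.1),
                      exclude_zero_lag = TRUE, fit_range_px = 12)
  expect_true(fit$converged)
  expect_equal(fit$g0, 0.5, tolerance = 1e-6)
  expect_equal(fit$w_px, 4, tolerance = 1e-6)
  expect_equal(fit$g_inf, 0.1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("gaussian fit handles flat profiles and refuses tiny inputs", {
  fit <- fit_gaussian(fake_radial(0:10, rep(0, 11)), FALSE, 10)
  expect_true(fit$converged)
  expect_lt(abs(fit$g0), 1e-8)
  expect_lt(abs(fit$g_inf), 1e-8)
  expect_error(fit_gaussian(fake_radial(1:3, c(1, 0.5, 0.2)), FALSE, 10),
               class = "iccscoloc_validation_error")
})

test_that("fitted width is stable under noise (Monte Carlo)", {
  r <- 1:12
  clean <- 0.5 * exp(-r^2 / 16) + 0.1
  set.seed(103)
  ws <- vapply(1:100, function(i) {
    fit_gaussian(fake_radial(r, clean + stats::rnorm(12, 0, 0.01)), TRUE, 12)$w_px
  }, numeric(1))
  expect_lt(abs(stats::median(ws) - 4) / 4, 0.05)
})

test_that("coloc_fraction implements the amplitude-ratio formula", {
  expect_equal(coloc_fraction(fake_fit(0.5), fake_fit(0.5), fake_fit(0.5))$f, 1)
  expect_equal(coloc_fraction(fake_fit(0.4), fake_fit(0.3), fake_fit(0))$f, 0)
  res <- coloc_fraction(fake_fit(0.4), fake_fit(0.2), fake_fit(0.1))
  expect_equal(res$f_raw, (0.1 / 0.2 + 0.1 / 0.4) / 2) # = 0.375
  expect_equal(res$f, 0.375)
  expect_length(res$qc_flags, 0)
})

test_that("coloc_fraction flags degenerate amplitude configurations", {
  # above-1 raw fractions are clamped and flagged
  over <- coloc_fraction(fake_fit(0.2), fake_fit(0.2), fake_fit(0.3))
  expect_equal(over$f_raw, 1.5)
  expect_equal(over$f, 1)
  expect_true("clamped" %in% over$qc_flags)
  # negative cross amplitude: f = 0 with anti-correlation flag
  anti <- coloc_fraction(fake_fit(0.4), fake_fit(0.4), fake_fit(-0.1))
  expect_equal(anti$f, 0)
  expect_true("anticorrelated" %in% anti$qc_flags)
  # non-positive autocorrelation: undefined fraction, flag, no error
  bad <- coloc_fraction(fake_fit(0), fake_fit(0.4), fake_fit(0.1))
  expect_true(is.na(bad$f))
  expect_true("nonpositive_autocorrelation" %in% bad$qc_flags)
  # large offsets are flagged
  off <- coloc_fraction(fake_fit(0.4, g_inf = 0.1), fake_fit(0.4), fake_fit(0.2))
  expect_true(any(grepl("large_offset", off$qc_flags)))
  # non-converged fits are a caller error
  expect_error(coloc_fraction(fake_fit(0.4, converged = FALSE), fake_fit(0.4),
                              fake_fit(0.1)),
               class = "iccscoloc_validation_error")
})

test_that("the whole estimator is invariant to intensity rescaling", {
  sim <- simulate_two_channel(foci_sim_params(f_true = 0.5, seed = 7))
  mask <- nuclear_mask(sim$truth$nucleus_mask_true)
  base <- run_iccs(sim$image, 1, 2, mask)
  scaled_img <- multichannel_image(list(sim$image$channels[[1]] * 3.7,
                                        sim$image$channels[[2]] * 0.21))
  scaled <- run_iccs(scaled_img, 1, 2, mask)
  expect_lt(abs(scaled$fit11$g0 - base$fit11$g0), 1e-9)
  expect_lt(abs(scaled$fit12$g0 - base$fit12$g0), 1e-9)
  expect_lt(abs(scaled$f - base$f), 1e-9)
})

test_that("autocorrelation amplitude falls as foci density rises", {
  # the inverse-number amplitude law holds for fluctuations about the
  # particle signal itself, so the background is off here
  g0_at <- function(n) {
    sim <- simulate_two_channel(foci_sim_params(
      n_foci_a = n, n_foci_b = n, f_true = 0, noise = "none",
      background = 0, amplitude_cv = 1e-6, seed = 31))
    run_iccs(sim$image, 1, 2,
             nuclear_mask(sim$truth$nucleus_mask_true))$fit11$g0
  }
  g0s <- vapply(c(20, 50, 100), g0_at, numeric(1))
  expect_true(all(diff(g0s) < 0))
})

test_that("iccs_results_table flattens results", {
  sim <- simulate_two_channel(foci_sim_params(f_true = 1, seed = 13))
  res <- run_iccs(sim$image, 1, 2, nuclear_mask(sim$truth$nucleus_mask_true))
  tab <- iccs_results_table(list(res, res), cell_ids = c("c1", "c2"))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("g0_11", "g0_22", "g0_12", "f_raw", "f") %in% names(tab)))
  expect_equal(tab$f[1], res$f)
})
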