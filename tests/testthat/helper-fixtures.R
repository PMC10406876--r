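# shared fixtures; everything is generated in code, no binary files

# a gaussian_fit with prescribed parameters (for arithmetic tests of
# coloc_fraction that do not need an actual fit)
fake_fit <- function(g0, w = 4, g_inf = 0, converged = TRUE) {
  structure(list(g0 = g0, w_px = w, g_inf = g_inf, converged = converged,
                 rss = 0, n_points = 10L),
            class = "gaussian_fit")
}

# a correlation_map built from an explicit lag grid
fake_map <- function(values, n_pairs = NULL, auto = TRUE) {
  L <- (nrow(values) - 1) / 2
  if (is.null(n_pairs)) n_pairs <- matrix(1000, nrow(values), ncol(values))
  structure(list(values = values, n_pairs = n_pairs, lags = -L:L, auto = auto),
            class = "correlation_map")
}

# random test image pair + random mask guaranteed non-degenerate
random_masked_pair <- function(n = 16, p_mask = 0.7) {
  A <- matrix(stats::runif(n * n, 1, 10), n)
  B <- matrix(stats::runif(n * n, 1, 10), n)
  m <- matrix(stats::runif(n * n) < p_mask, n)
  m[n %/% 2, n %/% 2] <- TRUE
  list(A = A, B = B, mask = nuclear_mask(m))
}

# simulate one nucleus and return the estimated colocalized fraction
estimate_f <- function(f_true, seed, n_foci = 50, config = iccs_config(), ...) {
  sim <- simulate_two_channel(foci_sim_params(
    f_true = f_true, n_foci_a = n_foci, n_foci_b = n_foci, seed = seed, ...))
  run_iccs(sim$image, 1, 2, nuclear_mask(sim$truth$nucleus_mask_true), config)$f
}

# a radial_correlation from explicit samples
fake_radial <- function(r, g, counts = rep(100L, length(r))) {
  structure(list(radii_px = r, g = g, counts = counts),
            class = "radial_correlation")
}
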