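#' Settings for an ICCS run
#'
#' @param max_lag_px Largest lag, in pixels, at which the 2D correlation
#'   functions are evaluated (default 32; ~1.3 um at 40 nm pixels,
#'   several PSF widths).
#' @param bin_width_px Radial bin width for the angular mean (default 1).
#' @param fit_range_px Largest radius entering the Gaussian fit
#'   (default 20 px, ~0.8 um).
#' @param exclude_zero_lag Drop the zero-lag bin before fitting
#'   (default TRUE: uncorrelated shot noise contributes a delta spike at
#'   zero lag only, which would bias the amplitude).
#' @param min_pairs Lags supported by fewer mask pixel pairs are dropped
#'   before radial averaging (default 100; estimates from a handful of
#'   pairs near the mask boundary are unstable).
#' @export
iccs_config <- function(max_lag_px = 32, bin_width_px = 1, fit_range_px = 20,
                        exclude_zero_lag = TRUE, min_pairs = 100) {
  if (max_lag_px < 1) abort_validation("max_lag_px must be >= 1")
  if (bin_width_px <= 0) abort_validation("bin_width_px must be positive")
  if (fit_range_px <= 0) abort_validation("fit_range_px must be positive")
  list(max_lag_px = as.integer(max_lag_px), bin_width_px = bin_width_px,
       fit_range_px = fit_range_px, exclude_zero_lag = isTRUE(exclude_zero_lag),
       min_pairs = as.integer(min_pairs))
}

# Linear cross-correlation sum C(dy, dx) = sum_x X(x) Y(x + d) for
# d in [-L, L]^2, via zero-padded FFTs. Returns a (2L+1) x (2L+1)
# matrix with lag (0, 0) at the centre.
xcorr_fft <- function(X, Y, L) {
  d <- dim(X)
  P1 <- stats::nextn(d[1] + L, c(2, 3, 5))
  P2 <- stats::nextn(d[2] + L, c(2, 3, 5))
  Xp <- matrix(0, P1, P2); Xp[seq_len(d[1]), seq_len(d[2])] <- X
  Yp <- matrix(0, P1, P2); Yp[seq_len(d[1]), seq_len(d[2])] <- Y
  C <- Re(stats::fft(Conj(stats::fft(Xp)) * stats::fft(Yp), inverse = TRUE)) / (P1 * P2)
  idx <- function(lags, P) ifelse(lags >= 0, lags + 1L, P + lags + 1L)
  C[idx(-L:L, P1), idx(-L:L, P2)]
}

#' Masked 2D intensity-fluctuation correlation
#'
#' Computes the normalized spatial correlation
#' `G(dy, dx) = <I_i(x) I_j(x + d)> / (<I_i> <I_j>) - 1`, where every
#' average runs over the pixel pairs whose two endpoints both lie inside
#' the nuclear mask. The means in the denominator are therefore lag
#' dependent (each lag sees its own pair population), which removes the
#' bias an irregular mask would otherwise imprint on the correlation.
#' Implemented with FFTs of the mask-zeroed images; the contract is the
#' masked direct sum, and an autocorrelation (`img_i` identical to
#' `img_j`) is symmetrized so that point symmetry holds exactly.
#'
#' @param img_i,img_j Numeric matrices of identical dimensions.
#' @param mask A [nuclear_mask()] with matching dimensions.
#' @param max_lag_px Largest lag (must be below half the image size).
#' @return An object of class `correlation_map` with fields `values`
#'   ((2L+1)^2 matrix, NA where undefined), `n_pairs`, `lags`
#'   (vector -L..L), and `pair` (attribute set by [run_iccs()]).
#' @export
correlate_2d <- function(img_i, img_j, mask, max_lag_px = 32) {
  if (!inherits(mask, "nuclear_mask")) abort_validation("mask must be a nuclear_mask")
  if (!identical(dim(img_i), dim(img_j)))
    abort_validation("images must share dimensions")
  if (!identical(dim(img_i), dim(mask$mask)))
    abort_validation("mask dimensions must match the images")
  L <- as.integer(max_lag_px)
  if (L < 1 || L >= min(dim(img_i)) / 2)
    abort_validation("max_lag_px must be >= 1 and < min(image dims)/2")
  M <- mask$mask * 1
  if (mean(img_i[mask$mask]) <= 0 || mean(img_j[mask$mask]) <= 0)
    abort_degenerate("zero mean intensity inside the mask")
  auto <- identical(img_i, img_j)

  A <- img_i * M; B <- img_j * M
  P <- round(xcorr_fft(M, M, L))          # pair count per lag
  N <- xcorr_fft(A, B, L)                 # sum of products
  Si <- xcorr_fft(A, M, L)                # sum of I_i over pairs
  Sj <- xcorr_fft(M, B, L)                # sum of I_j over pairs
  G <- (N * P) / (Si * Sj) - 1
  G[P < 1] <- NA_real_
  if (auto) {
    G <- (G + G[rev(seq_len(nrow(G))), rev(seq_len(ncol(G)))]) / 2
  }
  structure(list(values = G, n_pairs = P, lags = -L:L, auto = auto),
            class = "correlation_map")
}

#' Brute-force masked correlation (reference implementation)
#'
#' Direct nested-loop evaluation of the masked correlation sum, kept as
#' an independent oracle for the FFT path. Quadratic cost; use on small
#' images only.
#'
#' @inheritParams correlate_2d
#' @export
correlate_2d_direct <- function(img_i, img_j, mask, max_lag_px) {
  M <- mask$mask
  d <- dim(img_i)
  L <- as.integer(max_lag_px)
  lags <- -L:L
  G <- matrix(NA_real_, 2 * L + 1, 2 * L + 1)
  P <- matrix(0L, 2 * L + 1, 2 * L + 1)
  for (a in seq_along(lags)) {
    dy <- lags[a]
    for (b in seq_along(lags)) {
      dx <- lags[b]
      s_ij <- 0; s_i <- 0; s_j <- 0; n <- 0L
      for (y in seq_len(d[1])) {
        y2 <- y + dy
        if (y2 < 1 || y2 > d[1]) next
        for (x in seq_len(d[2])) {
          x2 <- x + dx
          if (x2 < 1 || x2 > d[2]) next
          if (M[y, x] && M[y2, x2]) {
            s_ij <- s_ij + img_i[y, x] * img_j[y2, x2]
            s_i <- s_i + img_i[y, x]
            s_j <- s_j + img_j[y2, x2]
            n <- n + 1L
          }
        }
      }
      P[a, b] <- n
      if (n > 0) G[a, b] <- (s_ij / n) / ((s_i / n) * (s_j / n)) - 1
    }
  }
  structure(list(values = G, n_pairs = P, lags = lags,
                 auto = identical(img_i, img_j)),
            class = "correlation_map")
}

#' Angular mean of a 2D correlation map
#'
#' Each defined lag contributes its G value to the radial bin containing
#' `r = sqrt(dy^2 + dx^2)`; bins are centred at multiples of
#' `bin_width_px` and the bin value is the unweighted mean of the
#' contributing lags. The reported radius of a bin is the mean radius of
#' its contributing lags. Empty bins are omitted.
#'
#' @param map2d A `correlation_map`.
#' @param bin_width_px Radial bin width (> 0).
#' @param min_pairs Lags with fewer supporting pixel pairs are dropped
#'   first (see [iccs_config()]).
#' @return An object of class `radial_correlation` with fields
#'   `radii_px`, `g`, `counts`.
#' @export
radial_average <- function(map2d, bin_width_px = 1, min_pairs = 100) {
  if (!inherits(map2d, "correlation_map")) abort_validation("map2d must be a correlation_map")
  if (bin_width_px <= 0) abort_validation("bin_width_px must be positive")
  lagr <- sqrt(outer(map2d$lags^2, map2d$lags^2, "+"))
  ok <- !is.na(map2d$values) & map2d$n_pairs >= min_pairs
  if (!any(ok)) abort_validation("no defined lags after the pair-count filter")
  bin <- as.integer(floor(lagr[ok] / bin_width_px + 0.5))
  g <- tapply(map2d$values[ok], bin, mean)
  counts <- as.integer(table(bin))
  # report the mean radius of the contributing lags, not the nominal bin
  # centre: on the square lag grid an annulus samples radii unevenly and
  # the fit should see the radius the bin actually averages over
  radii <- as.numeric(tapply(lagr[ok], bin, mean))
  ord <- order(radii)
  structure(list(radii_px = radii[ord], g = as.numeric(g)[ord],
                 counts = counts[ord]),
            class = "radial_correlation")
}

#' Fit the radial correlation with a Gaussian model
#'
#' Nonlinear least squares of `g(r) = G0 * exp(-r^2 / w^2) + Ginf` over
#' bins with `r <= fit_range_px`. `w` is bounded below by the larger of
#' 0.5 px and the smallest fitted radius: a width narrower than the
#' innermost sample cannot be distinguished from a delta spike, and
#' letting the optimizer go there turns the amplitude into an unbounded
#' extrapolation of a single noisy bin. Initial values: amplitude from
#' the innermost fitted bin, width 3 px, offset from the outer 25% of
#' fitted radii. A failed optimization returns `converged = FALSE`
#' rather than throwing.
#'
#' @param radial A `radial_correlation`.
#' @param exclude_zero_lag Drop the r = 0 bin before fitting.
#' @param fit_range_px Largest radius used.
#' @return An object of class `gaussian_fit` with fields `g0`, `w_px`,
#'   `g_inf`, `converged`, `rss`, `n_points`.
#' @export
fit_gaussian <- function(radial, exclude_zero_lag = TRUE, fit_range_px = 20) {
  if (!inherits(radial, "radial_correlation"))
    abort_validation("radial must be a radial_correlation")
  keep <- radial$radii_px <= fit_range_px
  if (exclude_zero_lag) keep <- keep & radial$radii_px > 0
  r <- radial$radii_px[keep]
  g <- radial$g[keep]
  if (length(r) < 4)
    abort_validation(sprintf("need >= 4 bins inside fit range, have %d", length(r)))

  fitres <- function(g0, w, ginf, converged) {
    resid <- g - (g0 * exp(-r^2 / w^2) + ginf)
    structure(list(g0 = g0, w_px = w, g_inf = ginf, converged = converged,
                   rss = sum(resid^2), n_points = length(r)),
              class = "gaussian_fit")
  }
  if (stats::var(g) == 0) {
    # flat profile: exact fit with zero amplitude at the initial width
    return(fitres(0, 3, g[1], TRUE))
  }
  n_tail <- max(1L, ceiling(length(r) * 0.25))
  w_lo <- max(0.5, min(r))
  start <- list(g0 = g[1] - mean(utils::tail(g, n_tail)),
                w = min(max(3, w_lo * 1.5), fit_range_px),
                ginf = mean(utils::tail(g, n_tail)))
  lower <- c(-Inf, w_lo + 1e-9, -Inf)
  upper <- c(Inf, fit_range_px, Inf)
  fit <- tryCatch(
    stats::nls(g ~ g0 * exp(-r^2 / w^2) + ginf, start = start,
               lower = lower, upper = upper, algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    return(fitres(unname(p["g0"]), unname(p["w"]), unname(p["ginf"]), TRUE))
  }
  # fall back to box-constrained quasi-Newton on the residual sum of squares
  obj <- function(p) sum((g - (p[1] * exp(-r^2 / p[2]^2) + p[3]))^2)
  opt <- tryCatch(
    stats::optim(unlist(start), obj, method = "L-BFGS-B",
                 lower = lower, upper = upper),
    error = function(e) NULL)
  if (is.null(opt)) return(fitres(start$g0, start$w, start$ginf, FALSE))
  fitres(opt$par[1], opt$par[2], opt$par[3], opt$convergence == 0)
}

#' Colocalized fraction from fitted correlation amplitudes
#'
#' `f_raw = (G12(0)/G22(0) + G12(0)/G11(0)) / 2`, the mean of the
#' cross- to auto-correlation amplitude ratios; with equal particle
#' numbers in the two channels this is the fraction of particles present
#' in both. `f` is `f_raw` clamped to [0, 1]. Quality-control flags
#' record clamping, anti-correlation (negative cross amplitude, reported
#' as f = 0), non-positive autocorrelation amplitudes (f undefined), and
#' offsets exceeding 10% of the amplitude.
#'
#' @param fit11,fit22,fit12 `gaussian_fit` objects for the two
#'   autocorrelations and the cross-correlation.
#' @return An object of class `iccs_result` with fields `fit11`,
#'   `fit22`, `fit12`, `f_raw`, `f`, `qc_flags`.
#' @export
coloc_fraction <- function(fit11, fit22, fit12) {
  for (f in list(fit11, fit22, fit12)) {
    if (!inherits(f, "gaussian_fit")) abort_validation("inputs must be gaussian_fit objects")
    if (!isTRUE(f$converged)) abort_validation("all three fits must have converged")
  }
  flags <- character(0)
  for (nm in c("fit11", "fit22", "fit12")) {
    ft <- get(nm)
    if (abs(ft$g_inf) > 0.1 * abs(ft$g0)) flags <- c(flags, paste0("large_offset_", nm))
  }
  if (fit11$g0 <= 0 || fit22$g0 <= 0) {
    flags <- c(flags, "nonpositive_autocorrelation")
    return(structure(list(fit11 = fit11, fit22 = fit22, fit12 = fit12,
                          f_raw = NA_real_, f = NA_real_, qc_flags = flags),
                     class = "iccs_result"))
  }
  f_raw <- (fit12$g0 / fit22$g0 + fit12$g0 / fit11$g0) / 2
  if (fit12$g0 < 0) flags <- c(flags, "anticorrelated")
  f <- min(1, max(0, f_raw))
  if (f != f_raw && fit12$g0 >= 0) flags <- c(flags, "clamped")
  structure(list(fit11 = fit11, fit22 = fit22, fit12 = fit12,
                 f_raw = f_raw, f = f, qc_flags = flags),
            class = "iccs_result")
}

#' @export
print.iccs_result <- function(x, ...) {
  cat(sprintf("<iccs_result> f = %s (raw %s)\n",
              format(x$f, digits = 4), format(x$f_raw, digits = 4)))
  cat(sprintf("  g0: 11 = %.4g, 22 = %.4g, 12 = %.4g\n",
              x$fit11$g0, x$fit22$g0, x$fit12$g0))
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Full ICCS analysis of one nucleus
#'
#' Runs the two autocorrelations and the cross-correlation over the
#' masked pixels, radially averages each map, fits the Gaussian model,
#' and forms the colocalized fraction. Deterministic given inputs and
#' configuration.
#'
#' @param image A [multichannel_image()].
#' @param ch_a,ch_b Channel indices (1-based).
#' @param mask A [nuclear_mask()].
#' @param config An [iccs_config()] list.
#' @param keep_profiles Attach the three radial profiles to the result
#'   (`$profiles`) for plotting/serialization.
#' @return An `iccs_result`.
#' @export
run_iccs <- function(image, ch_a, ch_b, mask, config = iccs_config(),
                     keep_profiles = FALSE) {
  if (!inherits(image, "multichannel_image"))
    abort_validation("image must be a multichannel_image")
  nch <- length(image$channels)
  if (ch_a < 1 || ch_a > nch || ch_b < 1 || ch_b > nch)
    abort_validation("channel index out of range")
  A <- image$channels[[ch_a]]
  B <- image$channels[[ch_b]]
  maps <- list(
    m11 = correlate_2d(A, A, mask, config$max_lag_px),
    m22 = correlate_2d(B, B, mask, config$max_lag_px),
    m12 = correlate_2d(A, B, mask, config$max_lag_px))
  profiles <- lapply(maps, radial_average, bin_width_px = config$bin_width_px,
                     min_pairs = config$min_pairs)
  fits <- lapply(profiles, fit_gaussian,
                 exclude_zero_lag = config$exclude_zero_lag,
                 fit_range_px = config$fit_range_px)
  res <- coloc_fraction(fits$m11, fits$m22, fits$m12)
  if (keep_profiles) res$profiles <- profiles
  res
}

#' Flatten ICCS results to a one-row-per-cell data frame
#'
#' @param results List of `iccs_result` objects.
#' @param cell_ids Optional identifiers (default sequence).
#' @param pair_label Label describing the channel pair.
#' @export
iccs_results_table <- function(results, cell_ids = seq_along(results),
                               pair_label = "ch1-ch2") {
  if (length(cell_ids) != length(results))
    abort_validation("cell_ids length must match results")
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    data.frame(cell_id = cell_ids[k], pair = pair_label,
               g0_11 = r$fit11$g0, g0_22 = r$fit22$g0, g0_12 = r$fit12$g0,
               w_11 = r$fit11$w_px, w_22 = r$fit22$w_px, w_12 = r$fit12$w_px,
               g_inf_11 = r$fit11$g_inf, g_inf_22 = r$fit22$g_inf,
               g_inf_12 = r$fit12$g_inf,
               f_raw = r$f_raw, f = r$f,
               qc_flags = paste(r$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
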