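#' Parameters for the two-channel nuclear foci simulator
#'
#' The generator emulates a confocal two-colour image of a single
#' nucleus: diffraction-limited foci rendered as isotropic Gaussians of
#' width `psf_sigma_px`, log-normal focus amplitudes (immunofluorescence
#' spot brightness is right-skewed), a uniform background, and Poisson
#' (shot) and/or Gaussian (read) noise. A fraction `f_true` of the foci
#' is planted at identical coordinates in both channels; the remainder
#' are placed independently, uniformly inside an elliptical nucleus.
#'
#' Defaults describe a realistic closed-pinhole acquisition at 40 nm
#' pixels: a 256 x 256 field holding an 8 x 6.4 um elliptical nucleus,
#' 50 foci per channel, PSF sigma 2 px (~80 nm, i.e. a ~190 nm FWHM),
#' mean focus amplitude 100 counts with CV 0.3, background 10 counts,
#' shot noise.
#'
#' @param image_size_px Integer pair (height, width).
#' @param nucleus List with `center` (y, x) and `semi_axes` (a_y, a_x)
#'   in pixels; must fit inside the image.
#' @param n_foci_a,n_foci_b Foci per channel.
#' @param f_true Planted colocalized fraction in [0, 1].
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param amplitude_mean,amplitude_cv Log-normal amplitude moments.
#' @param background Constant background level (counts).
#' @param noise One of "poisson", "gaussian", "both", "none".
#' @param gaussian_sd Read-noise SD when Gaussian noise is on.
#' @param jitter_nm SD of a Gaussian displacement applied to the B-copy
#'   of each colocalized focus (0 = identical coordinates, the
#'   idealization of colocalized).
#' @param include_dna_channel Append a third channel mimicking a DNA
#'   counterstain (uniform nuclear fill), for segmentation tests.
#' @param seed Integer RNG seed; the simulation is bit-reproducible
#'   given the seed.
#' @export
foci_sim_params <- function(image_size_px = c(256, 256),
                            nucleus = list(center = c(128.5, 128.5),
                                           semi_axes = c(100, 80)),
                            n_foci_a = 50, n_foci_b = 50,
                            f_true = 0.5, psf_sigma_px = 2,
                            amplitude_mean = 100, amplitude_cv = 0.3,
                            background = 10, noise = "poisson",
                            gaussian_sd = 2, jitter_nm = 0,
                            pixel_size_nm = 40,
                            include_dna_channel = FALSE, seed = 1) {
  p <- list(image_size_px = as.integer(image_size_px), nucleus = nucleus,
            n_foci_a = as.integer(n_foci_a), n_foci_b = as.integer(n_foci_b),
            f_true = f_true, psf_sigma_px = psf_sigma_px,
            amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
            background = background, noise = noise, gaussian_sd = gaussian_sd,
            jitter_nm = jitter_nm, pixel_size_nm = pixel_size_nm,
            include_dna_channel = isTRUE(include_dna_channel),
            seed = as.integer(seed))
  if (p$f_true < 0 || p$f_true > 1) abort_validation("f_true must be in [0, 1]")
  if (p$n_foci_a < 1 || p$n_foci_b < 1) abort_validation("need at least one focus per channel")
  if (p$psf_sigma_px <= 0) abort_validation("psf_sigma_px must be positive")
  if (!p$noise %in% c("poisson", "gaussian", "both", "none"))
    abort_validation("noise must be poisson, gaussian, both or none")
  ctr <- nucleus$center; ax <- nucleus$semi_axes
  if (ctr[1] - ax[1] < 1 || ctr[1] + ax[1] > p$image_size_px[1] ||
      ctr[2] - ax[2] < 1 || ctr[2] + ax[2] > p$image_size_px[2])
    abort_validation("nucleus ellipse must fit inside the image")
  p
}

# draw n points uniformly inside the nucleus ellipse
sample_in_ellipse <- function(n, nucleus) {
  u <- sqrt(stats::runif(n))
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(y = nucleus$center[1] + nucleus$semi_axes[1] * u * sin(theta),
        x = nucleus$center[2] + nucleus$semi_axes[2] * u * cos(theta))
}

# add Gaussian foci to an image in place; coords n x 2 (y, x)
render_foci <- function(img, coords, amplitudes, sigma) {
  r <- ceiling(4 * sigma)
  d <- dim(img)
  for (k in seq_len(nrow(coords))) {
    y0 <- coords[k, 1]; x0 <- coords[k, 2]
    ys <- max(1, floor(y0) - r):min(d[1], ceiling(y0) + r)
    xs <- max(1, floor(x0) - r):min(d[2], ceiling(x0) + r)
    img[ys, xs] <- img[ys, xs] + amplitudes[k] *
      exp(-(ys - y0)^2 / (2 * sigma^2)) %o% exp(-(xs - x0)^2 / (2 * sigma^2))
  }
  img
}

rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

apply_noise <- function(img, noise, gaussian_sd) {
  out <- switch(noise,
    none = img,
    poisson = matrix(stats::rpois(length(img), img), nrow(img)),
    gaussian = img + matrix(stats::rnorm(length(img), 0, gaussian_sd), nrow(img)),
    both = matrix(stats::rpois(length(img), img), nrow(img)) +
      matrix(stats::rnorm(length(img), 0, gaussian_sd), nrow(img)))
  pmax(out, 0)
}

ellipse_mask <- function(image_size_px, nucleus) {
  ys <- seq_len(image_size_px[1]); xs <- seq_len(image_size_px[2])
  outer(((ys - nucleus$center[1]) / nucleus$semi_axes[1])^2,
        ((xs - nucleus$center[2]) / nucleus$semi_axes[2])^2, "+") <= 1
}

#' Simulate a two-channel nuclear foci image with known colocalization
#'
#' `round(f_true * min(n_a, n_b))` foci are shared between the channels
#' (identical coordinates unless `jitter_nm > 0`); the remaining foci of
#' each channel are placed independently. Amplitudes are drawn
#' independently per channel, including for shared foci (the two labels
#' are distinct fluorophores).
#'
#' @param params A [foci_sim_params()] list.
#' @return List with `image` (a [multichannel_image()]) and `truth`
#'   (foci coordinates per channel, `shared_indices` as an n x 2 matrix
#'   of row indices into the two coordinate sets, and
#'   `nucleus_mask_true`).
#' @export
simulate_two_channel <- function(params) {
  p <- do.call(foci_sim_params, params[setdiff(names(params), "")])
  area <- pi * prod(p$nucleus$semi_axes)
  if (max(p$n_foci_a, p$n_foci_b) > 0.05 * area)
    abort_placement("foci count exceeds the nucleus area heuristic (n > 0.05 * area)")
  set.seed(p$seed)

  n_shared <- round(p$f_true * min(p$n_foci_a, p$n_foci_b))
  shared <- sample_in_ellipse(n_shared, p$nucleus)
  extra_a <- sample_in_ellipse(p$n_foci_a - n_shared, p$nucleus)
  extra_b <- sample_in_ellipse(p$n_foci_b - n_shared, p$nucleus)
  coords_a <- rbind(shared, extra_a)
  shared_b <- shared
  if (p$jitter_nm > 0 && n_shared > 0) {
    shared_b <- shared_b + matrix(stats::rnorm(2 * n_shared, 0,
                                               p$jitter_nm / p$pixel_size_nm),
                                  n_shared, 2)
  }
  coords_b <- rbind(shared_b, extra_b)

  base <- matrix(p$background, p$image_size_px[1], p$image_size_px[2])
  amp_a <- rlnorm_mean_cv(p$n_foci_a, p$amplitude_mean, p$amplitude_cv)
  amp_b <- rlnorm_mean_cv(p$n_foci_b, p$amplitude_mean, p$amplitude_cv)
  ch_a <- apply_noise(render_foci(base, coords_a, amp_a, p$psf_sigma_px),
                      p$noise, p$gaussian_sd)
  ch_b <- apply_noise(render_foci(base, coords_b, amp_b, p$psf_sigma_px),
                      p$noise, p$gaussian_sd)
  channels <- list(ch_a, ch_b)
  labels <- c("A", "B")
  mask_true <- ellipse_mask(p$image_size_px, p$nucleus)
  if (p$include_dna_channel) {
    dna <- matrix(p$background, p$image_size_px[1], p$image_size_px[2])
    dna[mask_true] <- dna[mask_true] + 100
    dna <- apply_noise(gaussian_blur(dna, 2), p$noise, p$gaussian_sd)
    channels <- c(channels, list(dna))
    labels <- c(labels, "DNA")
  }
  truth <- list(
    foci_coords_a = coords_a, foci_coords_b = coords_b,
    shared_indices = if (n_shared > 0) cbind(a = seq_len(n_shared), b = seq_len(n_shared))
                     else matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b"))),
    nucleus_mask_true = mask_true, f_true = p$f_true, seed = p$seed)
  list(image = multichannel_image(channels, pixel_size_nm = p$pixel_size_nm,
                                  channel_labels = labels),
       truth = truth)
}

#' Simulate a PLA-like z-stack of well-separated bright puncta
#'
#' Puncta are placed by rejection sampling at pairwise (3D, isotropic
#' pixel-unit) distance `>= min_separation_px`, with a margin of two
#' lateral sigmas from every stack face, and rendered as anisotropic
#' Gaussians (wider axially, as a confocal PSF is). Defaults describe a
#' counting-oriented acquisition at ~120 nm lateral voxels: PSF sigma
#' 1 px laterally and 1.2 px axially, so the default 6 px separation is
#' at least six lateral sigmas -- well separated in the sense that
#' threshold-level isophotes of neighbouring puncta cannot bridge even
#' under shot noise.
#'
#' @param n_spots Number of puncta (0 gives a background-only stack).
#' @param stack_size Integer triple (z, y, x).
#' @param psf_sigma Pair (sigma_z, sigma_xy) in pixels.
#' @param min_separation_px Minimum pairwise centre distance.
#' @param amplitude Peak amplitude above background (default 200; with
#'   background 10 and shot noise the peak SNR is ~14).
#' @param background Constant background level.
#' @param noise,gaussian_sd As in [foci_sim_params()].
#' @param seed RNG seed.
#' @param max_tries Rejection-sampling cap per spot.
#' @return List with `stack` (a [spot_stack()]) and `truth`
#'   (`planted_spot_coords`, n x 3 matrix (z, y, x)).
#' @export
simulate_pla_stack <- function(n_spots = 15, stack_size = c(12, 128, 128),
                               psf_sigma = c(1.2, 1), min_separation_px = 6,
                               amplitude = 200, background = 10,
                               noise = "poisson", gaussian_sd = 2,
                               seed = 1, max_tries = 2000) {
  if (n_spots < 0) abort_validation("n_spots must be >= 0")
  if (min_separation_px <= 0) abort_validation("min_separation_px must be positive")
  set.seed(as.integer(seed))
  d <- as.integer(stack_size)
  margin_xy <- 2 * psf_sigma[2]
  margin_z <- 2 * psf_sigma[1]
  if (n_spots > 0 &&
      (d[1] - margin_z <= 1 + margin_z || d[2] - margin_xy <= 1 + margin_xy ||
       d[3] - margin_xy <= 1 + margin_xy))
    abort_placement("stack too small for the PSF margins")
  coords <- matrix(0, 0, 3, dimnames = list(NULL, c("z", "y", "x")))
  tries <- 0L
  while (nrow(coords) < n_spots) {
    cand <- c(stats::runif(1, 1 + margin_z, d[1] - margin_z),
              stats::runif(1, 1 + margin_xy, d[2] - margin_xy),
              stats::runif(1, 1 + margin_xy, d[3] - margin_xy))
    ok <- !nrow(coords) ||
      min(sqrt(colSums((t(coords) - cand)^2))) >= min_separation_px
    if (ok) coords <- rbind(coords, cand)
    tries <- tries + 1L
    if (tries > max_tries * max(1, n_spots))
      abort_placement("could not place puncta at the requested separation")
  }
  vox <- array(background, dim = d)
  rz <- ceiling(4 * psf_sigma[1]); rxy <- ceiling(4 * psf_sigma[2])
  for (k in seq_len(nrow(coords))) {
    c0 <- coords[k, ]
    zs <- max(1, floor(c0[1]) - rz):min(d[1], ceiling(c0[1]) + rz)
    ys <- max(1, floor(c0[2]) - rxy):min(d[2], ceiling(c0[2]) + rxy)
    xs <- max(1, floor(c0[3]) - rxy):min(d[3], ceiling(c0[3]) + rxy)
    kernel <- outer(exp(-(zs - c0[1])^2 / (2 * psf_sigma[1]^2)),
                    exp(-(ys - c0[2])^2 / (2 * psf_sigma[2]^2))) %o%
      exp(-(xs - c0[3])^2 / (2 * psf_sigma[2]^2))
    vox[zs, ys, xs] <- vox[zs, ys, xs] + amplitude * kernel
  }
  flat <- apply_noise(matrix(vox, nrow = d[1]), noise, gaussian_sd)
  vox <- array(flat, dim = d)
  list(stack = spot_stack(vox),
       truth = list(planted_spot_coords = coords, seed = as.integer(seed)))
}

#' Cohort-level generator for per-cell PLA counts and ICCS fractions
#'
#' Draws per-cell values from group-wise normal distributions: counts
#' are rounded and floored at zero, fractions clamped to [0, 1]. The
#' published group summaries are means and SDs of per-cell values with
#' SDs far above count-limited, so a normal draw is the minimal model.
#'
#' @param groups List of group descriptors from [cohort_group()].
#' @param seed RNG seed.
#' @return Data frame (group, cell_id, pla_count, f_iccs); `f_iccs` is
#'   NA for groups without fraction parameters.
#' @export
simulate_cohort <- function(groups, seed = 1) {
  if (!length(groups)) abort_validation("groups must be non-empty")
  nms <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(nms)) abort_validation("group names must be unique")
  set.seed(as.integer(seed))
  rows <- lapply(groups, function(g) {
    pla <- pmax(0, round(stats::rnorm(g$n_cells, g$pla_mean, g$pla_sd)))
    f <- if (is.na(g$f_mean)) rep(NA_real_, g$n_cells) else
      pmin(1, pmax(0, stats::rnorm(g$n_cells, g$f_mean, g$f_sd)))
    data.frame(group = g$name, cell_id = seq_len(g$n_cells),
               pla_count = as.integer(pla), f_iccs = f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname simulate_cohort
#' @param name Group (cell line) name.
#' @param n_cells Cells per group (default 20; the study does not report
#'   per-group n, so this choice is surfaced in every report).
#' @param pla_mean,pla_sd Per-cell PLA count distribution.
#' @param f_mean,f_sd Per-cell colocalized-fraction distribution.
#' @export
cohort_group <- function(name, n_cells = 20, pla_mean, pla_sd,
                         f_mean = NA_real_, f_sd = NA_real_) {
  if (n_cells < 2) abort_validation("n_cells must be >= 2")
  if (pla_sd < 0 || (!is.na(f_sd) && f_sd < 0)) abort_validation("sds must be >= 0")
  list(name = name, n_cells = as.integer(n_cells),
       pla_mean = pla_mean, pla_sd = pla_sd, f_mean = f_mean, f_sd = f_sd)
}

#' Published group summaries used as generator presets
#'
#' Per-cell-line means and SDs of PLA spot counts (and, for the
#' enhancer mark, ICCS colocalized fractions) reported for the
#' MCF10A / MCF7 / MDA-MB-231 breast model lines: the DEK-H3K9ac pair
#' (19.9 +/- 7.9, 21.1 +/- 5.9, 40.5 +/- 8.9 spots) and the DEK-H3K27ac
#' pair (10.1 +/- 4.3, 17.3 +/- 5.5, 16.5 +/- 6.6 spots; fractions
#' 0.26 +/- 0.06, 0.30 +/- 0.08, 0.59 +/- 0.09).
#'
#' @param n_cells Cells per group.
#' @return A list of [cohort_group()] descriptors.
#' @export
cohort_preset_h3k9ac <- function(n_cells = 20) {
  list(cohort_group("MCF10A", n_cells, pla_mean = 19.9, pla_sd = 7.9),
       cohort_group("MCF7", n_cells, pla_mean = 21.1, pla_sd = 5.9),
       cohort_group("MDA-MB-231", n_cells, pla_mean = 40.5, pla_sd = 8.9))
}

#' @rdname cohort_preset_h3k9ac
#' @export
cohort_preset_h3k27ac <- function(n_cells = 20) {
  list(cohort_group("MCF10A", n_cells, pla_mean = 10.1, pla_sd = 4.3,
                    f_mean = 0.26, f_sd = 0.06),
       cohort_group("MCF7", n_cells, pla_mean = 17.3, pla_sd = 5.5,
                    f_mean = 0.30, f_sd = 0.08),
       cohort_group("MDA-MB-231", n_cells, pla_mean = 16.5, pla_sd = 6.6,
                    f_mean = 0.59, f_sd = 0.09))
}
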