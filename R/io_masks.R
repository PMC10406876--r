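#' Read a multi-channel image from a TIFF file
#'
#' Pages of a multi-page TIFF are taken as channels; `channel_indices`
#' selects and orders them (1-based). Bit depth is preserved. The pixel
#' size is taken from the file's description metadata when present,
#' otherwise the 40 nm default is used with a warning.
#'
#' @param path Path to a single- or multi-page grayscale TIFF.
#' @param channel_indices Integer vector of pages to load, in the
#'   desired channel order; `NULL` loads all pages.
#' @param default_pixel_size_nm Fallback pixel size.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, channel_indices = NULL, default_pixel_size_nm = 40) {
  tif <- read_tiff(path)
  n <- length(tif$pages)
  if (is.null(channel_indices)) channel_indices <- seq_len(n)
  channel_indices <- as.integer(channel_indices)
  if (any(is.na(channel_indices)) || any(channel_indices < 1) ||
      any(channel_indices > n))
    abort_validation(sprintf(
      "channel index out of range: file has %d page(s), requested [%s]",
      n, paste(channel_indices, collapse = ", ")))
  px <- tif$pixel_size_nm
  if (is.na(px)) {
    warning(sprintf("no pixel size in TIFF metadata; assuming %g nm",
                    default_pixel_size_nm))
    px <- default_pixel_size_nm
  }
  multichannel_image(lapply(channel_indices, function(i) tif$pages[[i]]),
                     pixel_size_nm = px,
                     channel_labels = paste0("ch", channel_indices))
}

#' Write a multi-channel image to a multi-page TIFF
#'
#' @param image A [multichannel_image()] with integer-valued intensities.
#' @param path Output path.
#' @param bits_per_sample 8 or 16.
#' @export
write_image <- function(image, path, bits_per_sample = 16) {
  if (!inherits(image, "multichannel_image"))
    abort_validation("image must be a multichannel_image")
  write_tiff(image$channels, path, bits_per_sample = bits_per_sample,
             pixel_size_nm = image$pixel_size_nm)
}

#' Read a z-stack from a multi-page TIFF
#'
#' Pages are z-planes in z-major order.
#' @inheritParams read_image
#' @param voxel_size_nm Triple (z, y, x); the lateral sizes default to
#'   the file's pixel size when present.
#' @export
read_stack <- function(path, voxel_size_nm = NULL) {
  tif <- read_tiff(path)
  d <- dim(tif$pages[[1]])
  vox <- array(0, dim = c(length(tif$pages), d[1], d[2]))
  for (z in seq_along(tif$pages)) vox[z, , ] <- tif$pages[[z]]
  if (is.null(voxel_size_nm)) {
    lateral <- if (is.na(tif$pixel_size_nm)) 120 else tif$pixel_size_nm
    voxel_size_nm <- c(300, lateral, lateral)
  }
  spot_stack(vox, voxel_size_nm)
}

#' Segment the nucleus from a DNA counterstain channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, then the
#' largest 8-connected component. The result is insensitive to adding a
#' constant offset to the channel.
#'
#' @param dna_channel Numeric matrix (e.g. a TO-PRO-3 / DAPI channel).
#' @param smoothing_sigma_px Gaussian sigma in pixels (default 2).
#' @param min_area_px Minimum accepted nucleus area (default 1000 px;
#'   at 40 nm pixels this is ~1.6 um^2, far below any real nucleus).
#' @param n_nuclei Number of largest components to keep. The default 1
#'   returns a single [nuclear_mask()]; larger values return a list of
#'   masks ordered by decreasing area.
#' @return A [nuclear_mask()], or a list of them when `n_nuclei > 1`.
#' @export
segment_nucleus <- function(dna_channel, smoothing_sigma_px = 2,
                            min_area_px = 1000, n_nuclei = 1) {
  if (!is.matrix(dna_channel)) abort_validation("dna_channel must be a matrix")
  if (!all(is.finite(dna_channel))) abort_validation("dna_channel must be finite")
  if (min_area_px < 1) abort_validation("min_area_px must be positive")
  if (diff(range(dna_channel)) == 0)
    abort_degenerate("constant DNA channel: threshold undefined")
  smoothed <- gaussian_blur(dna_channel, smoothing_sigma_px)
  thr <- otsu_threshold(smoothed) # degenerate-input error on constant images
  binary <- fill_holes(smoothed > thr)
  comp <- label_components(binary, connectivity = 8)
  keep <- which(comp$sizes >= min_area_px)
  if (!length(keep))
    abort_segmentation(sprintf(
      "largest component has %d px, below min_area_px = %d",
      if (length(comp$sizes)) comp$sizes[1] else 0L, as.integer(min_area_px)))
  keep <- keep[seq_len(min(n_nuclei, length(keep)))]
  masks <- lapply(keep, function(l) nuclear_mask(comp$labels == l))
  if (n_nuclei == 1) masks[[1]] else masks
}

#' Persist / load a nuclear mask as an 8-bit TIFF (0/255)
#'
#' @param mask A [nuclear_mask()].
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "nuclear_mask")) abort_validation("mask must be a nuclear_mask")
  write_tiff(matrix(ifelse(mask$mask, 255L, 0L), nrow(mask$mask)), path,
             bits_per_sample = 8)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  nuclear_mask(read_tiff(path)$pages[[1]] > 0)
}
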