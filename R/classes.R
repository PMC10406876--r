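#' Multi-channel image container
#'
#' Registered 2D intensity planes sharing dimensions and a physical
#' pixel size. Intensities must be finite and non-negative; 12-bit data
#' stored in 16-bit containers is kept as-is (the correlation
#' normalization is scale invariant, so no rescaling is applied).
#'
#' @param channels List of numeric matrices with identical dimensions.
#' @param pixel_size_nm Physical pixel size in nanometres (default 40,
#'   typical of closed-pinhole confocal sampling of nuclei).
#' @param channel_labels Optional character labels, one per channel.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size_nm = 40, channel_labels = NULL) {
  if (is.matrix(channels)) channels <- list(channels)
  if (!is.list(channels) || !length(channels))
    abort_validation("channels must be a non-empty list of matrices")
  dims <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1))))
    abort_validation("every channel must be a 2D matrix")
  if (length(unique(dims)) != 1)
    abort_validation("all channels must share identical dimensions")
  for (ch in channels) check_finite_nonneg(ch, "channel intensities")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 || pixel_size_nm <= 0)
    abort_validation("pixel_size_nm must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_along(channels))
  if (length(channel_labels) != length(channels))
    abort_validation("channel_labels length must match channels")
  structure(list(channels = channels,
                 pixel_size_nm = pixel_size_nm,
                 channel_labels = as.character(channel_labels)),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_image> %d channel(s) [%s], %d x %d px, %.1f nm/px\n",
              length(x$channels), paste(x$channel_labels, collapse = ", "),
              d[1], d[2], x$pixel_size_nm))
  invisible(x)
}

#' Nuclear pixel mask
#'
#' The set of "selected pixels" over which all correlation averages run:
#' one nucleus per mask.
#'
#' @param mask Logical matrix.
#' @return An object of class `nuclear_mask` with fields `mask` and
#'   `area_px`.
#' @export
nuclear_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    abort_validation("mask must be a logical matrix")
  if (anyNA(mask)) abort_validation("mask must not contain NA")
  area <- sum(mask)
  if (area == 0) abort_validation("mask is empty")
  structure(list(mask = mask, area_px = as.integer(area)), class = "nuclear_mask")
}

#' @export
print.nuclear_mask <- function(x, ...) {
  cat(sprintf("<nuclear_mask> %d x %d px, area %d px\n",
              nrow(x$mask), ncol(x$mask), x$area_px))
  invisible(x)
}

#' PLA z-stack container
#'
#' @param voxels 3D numeric array indexed (z, y, x).
#' @param voxel_size_nm Numeric triple (z, y, x) of voxel edge lengths.
#' @export
spot_stack <- function(voxels, voxel_size_nm = c(300, 120, 120)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    abort_validation("voxels must be a 3D array (z, y, x)")
  check_finite_nonneg(voxels, "voxel intensities")
  if (length(voxel_size_nm) != 3 || any(voxel_size_nm <= 0))
    abort_validation("voxel_size_nm must be three positive numbers")
  structure(list(voxels = voxels, voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "spot_stack")
}

#' @export
print.spot_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<spot_stack> %d z-planes of %d x %d px\n", d[1], d[2], d[3]))
  invisible(x)
}
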