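#' Minimal reader/writer for uncompressed grayscale TIFF stacks
#'
#' The pipeline exchanges images as plain multi-page TIFF (one page per
#' channel or z-plane, single-sample grayscale, 8- or 16-bit unsigned,
#' no compression). No TIFF library is assumed; this is a small baseline
#' TIFF 6.0 codec restricted to that subset, which is what confocal
#' export tools produce for raw intensity data. 12-bit acquisitions
#' stored in 16-bit containers read back unchanged.
#'
#' @param path File path.
#' @return `read_tiff()` returns a list with elements `pages` (list of
#'   integer matrices, row = y, column = x), `bits_per_sample`,
#'   `pixel_size_nm` (NA when the file carries no pixel-size
#'   description) and `description`.
#' @name tiff_io
NULL

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L) # BYTE, ASCII, SHORT, LONG, RATIONAL

ru16 <- function(raw, pos, endian) {
  b <- as.integer(raw[pos + 0:1])
  if (endian == "little") b[1] + 256L * b[2] else b[2] + 256L * b[1]
}

ru32 <- function(raw, pos, endian) {
  b <- as.numeric(raw[pos + 0:3])
  if (endian == "big") b <- rev(b)
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

read_tag_values <- function(raw, type, count, value_field_pos, endian) {
  size <- TIFF_TYPE_SIZES[type]
  nbytes <- size * count
  pos <- if (nbytes <= 4) value_field_pos else ru32(raw, value_field_pos, endian) + 1
  if (type == 2L) { # ASCII
    bytes <- raw[pos:(pos + count - 1)]
    return(rawToChar(bytes[bytes != as.raw(0)]))
  }
  vapply(seq_len(count), function(k) {
    p <- pos + (k - 1) * size
    switch(as.character(type),
      "1" = as.numeric(raw[p]),
      "3" = as.numeric(ru16(raw, p, endian)),
      "4" = ru32(raw, p, endian),
      "5" = ru32(raw, p, endian) / ru32(raw, p + 4, endian),
      abort_format(sprintf("unsupported TIFF tag type %d", type))
    )
  }, numeric(1))
}

#' @rdname tiff_io
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) abort_format("not a TIFF file (truncated header)")
  order_mark <- rawToChar(raw[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   abort_format("not a TIFF file (bad byte-order mark)"))
  if (ru16(raw, 3, endian) != 42L) abort_format("not a TIFF file (bad magic)")

  pages <- list()
  bits_seen <- integer(0)
  description <- NA_character_
  pixel_size_nm <- NA_real_
  ifd_offset <- ru32(raw, 5, endian)
  while (ifd_offset != 0) {
    pos <- ifd_offset + 1
    ntags <- ru16(raw, pos, endian)
    tags <- list()
    for (t in seq_len(ntags)) {
      tpos <- pos + 2 + (t - 1) * 12
      id <- ru16(raw, tpos, endian)
      type <- ru16(raw, tpos + 2, endian)
      count <- ru32(raw, tpos + 4, endian)
      tags[[as.character(id)]] <- read_tag_values(raw, type, count, tpos + 8, endian)
    }
    getf <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    width <- getf(256); height <- getf(257)
    if (is.null(width) || is.null(height)) abort_format("TIFF page missing dimensions")
    bits <- getf(258, 1)
    if (!bits %in% c(8, 16)) abort_format(sprintf("unsupported bit depth %s", bits))
    if (getf(259, 1) != 1) abort_format("compressed TIFF not supported")
    if (getf(277, 1) != 1) abort_format("only single-sample grayscale TIFF supported")
    if (!is.null(getf(322))) abort_format("tiled TIFF not supported")
    offsets <- getf(273); counts <- getf(279)
    if (is.null(offsets) || is.null(counts)) abort_format("TIFF page missing strip layout")
    desc <- getf(270)
    if (!is.null(desc) && is.na(description)) description <- desc

    bytes <- raw[unlist(lapply(seq_along(offsets), function(s) {
      offsets[s] + seq_len(counts[s])
    }))]
    expected <- width * height * (bits / 8)
    if (length(bytes) < expected) abort_format("TIFF strip data truncated")
    vals <- if (bits == 8) {
      as.integer(bytes[seq_len(expected)])
    } else {
      v <- readBin(bytes, "integer", n = width * height, size = 2,
                   signed = FALSE, endian = endian)
      as.integer(v)
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    bits_seen <- union(bits_seen, as.integer(bits))
    ifd_offset <- ru32(raw, pos + 2 + ntags * 12, endian)
  }
  if (!is.na(description)) {
    m <- regmatches(description,
                    regexec("pixel_size_nm=([0-9.eE+-]+)", description))[[1]]
    if (length(m) == 2) pixel_size_nm <- as.numeric(m[2])
  }
  list(pages = pages, bits_per_sample = max(bits_seen),
       pixel_size_nm = pixel_size_nm, description = description)
}

wu16 <- function(v) {
  v <- as.integer(round(v))
  writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2, endian = "little")
}

wu32 <- function(v) {
  v <- as.numeric(v)
  b <- raw(4 * length(v))
  for (k in seq_along(v)) {
    x <- v[k]
    b[4 * k - 3:0] <- as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  }
  b
}

tiff_tag <- function(id, type, values, data_offset = NULL) {
  count <- length(values)
  size <- TIFF_TYPE_SIZES[type]
  value_bytes <- switch(as.character(type),
    "3" = wu16(values),
    "4" = wu32(values),
    "2" = c(charToRaw(values), as.raw(0)), # single string, NUL appended
    abort_validation("unsupported tag type for writing"))
  if (type == 2L) count <- length(value_bytes)
  inline <- length(value_bytes) <= 4
  field <- if (inline) {
    c(value_bytes, raw(4 - length(value_bytes)))
  } else {
    wu32(data_offset)
  }
  list(bytes = c(wu16(id), wu16(type), wu32(count), field),
       extra = if (inline) raw(0) else value_bytes)
}

#' Write an uncompressed grayscale multi-page TIFF
#'
#' @param pages A matrix, a list of equally sized matrices, or a 3D array
#'   indexed (z, y, x); values must be integers in the range of the
#'   chosen bit depth.
#' @param bits_per_sample 8 or 16.
#' @param pixel_size_nm Optional physical pixel size recorded in the
#'   ImageDescription tag and recovered by [read_tiff()].
#' @rdname tiff_io
#' @export
write_tiff <- function(pages, path, bits_per_sample = 16, pixel_size_nm = NULL) {
  if (is.array(pages) && length(dim(pages)) == 3) {
    pages <- lapply(seq_len(dim(pages)[1]), function(z) pages[z, , ])
  }
  if (is.matrix(pages)) pages <- list(pages)
  if (!length(pages)) abort_validation("no pages to write")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort_validation("all pages must share dimensions")
  if (!bits_per_sample %in% c(8, 16)) abort_validation("bits_per_sample must be 8 or 16")
  maxval <- 2^bits_per_sample - 1
  for (p in pages) {
    check_finite_nonneg(p, "pixel data")
    if (any(p > maxval))
      abort_validation(sprintf("pixel values exceed %d-bit range", bits_per_sample))
  }
  height <- dims[1, 1]; width <- dims[2, 1]
  desc <- if (is.null(pixel_size_nm)) NULL else {
    paste0("pixel_size_nm=", format(pixel_size_nm, digits = 10), "\n")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(wu16(42), wu32(8)), con)
  offset <- 8
  for (k in seq_along(pages)) {
    page <- pages[[k]]
    tag_specs <- list(
      list(256, 4L, width), list(257, 4L, height),
      list(258, 3L, bits_per_sample), list(259, 3L, 1),
      list(262, 3L, 1))
    if (!is.null(desc) && k == 1) tag_specs <- c(tag_specs, list(list(270, 2L, NA)))
    tag_specs <- c(tag_specs,
                   list(list(273, 4L, NA), list(277, 3L, 1),
                        list(278, 4L, height), list(279, 4L, NA)))
    ntags <- length(tag_specs)
    ifd_size <- 2 + 12 * ntags + 4
    extra_offset <- offset + ifd_size
    desc_raw <- if (!is.null(desc) && k == 1) c(charToRaw(desc), as.raw(0)) else raw(0)
    if (length(desc_raw) %% 2) desc_raw <- c(desc_raw, as.raw(0))
    data_offset <- extra_offset + length(desc_raw)
    nbytes <- width * height * (bits_per_sample / 8)
    pad <- nbytes %% 2
    next_ifd <- if (k < length(pages)) data_offset + nbytes + pad else 0

    tag_bytes <- raw(0)
    for (spec in tag_specs) {
      id <- spec[[1]]
      tag <- switch(as.character(id),
        "270" = tiff_tag(270, 2L, desc, extra_offset),
        "273" = tiff_tag(273, 4L, data_offset),
        "279" = tiff_tag(279, 4L, nbytes),
        tiff_tag(id, spec[[2]], spec[[3]]))
      tag_bytes <- c(tag_bytes, tag$bytes)
    }
    writeBin(c(wu16(ntags), tag_bytes, wu32(next_ifd), desc_raw), con)
    vals <- as.vector(t(page))
    pixel_raw <- if (bits_per_sample == 8) as.raw(round(vals)) else wu16(vals)
    writeBin(c(pixel_raw, raw(pad)), con)
    offset <- data_offset + nbytes + pad
  }
  invisible(path)
}
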