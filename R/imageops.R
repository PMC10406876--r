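#' Gaussian blur of a 2D image
#'
#' Separable Gaussian convolution with edge replication. Used for
#' pre-smoothing before thresholding; `sigma = 0` is the identity.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels (>= 0).
#' @return Matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  if (!is.matrix(img)) abort_validation("img must be a matrix")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    abort_validation("sigma must be a single non-negative number")
  if (sigma == 0) return(img)
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smear <- function(n) {
    # banded convolution operator with replicated edges
    K <- matrix(0, n, n)
    for (o in seq(-radius, radius)) {
      j <- pmin(pmax(seq_len(n) + o, 1L), n)
      idx <- cbind(seq_len(n), j)
      K[idx] <- K[idx] + k[o + radius + 1]
    }
    K
  }
  smear(nrow(img)) %*% img %*% t(smear(ncol(img)))
}

#' Otsu's threshold
#'
#' Maximizes the between-class variance of the intensity histogram.
#' Returns an intensity value; the foreground is `x > threshold`.
#' The result is invariant to adding a constant offset to `x`.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @param nbins Number of histogram bins.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) abort_validation("intensities must be finite")
  lo <- min(x); hi <- max(x)
  if (hi == lo) abort_degenerate("constant image: Otsu threshold undefined")
  breaks <- seq(lo, hi, length.out = nbins + 1)
  h <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                     nbins), nbins)
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  m <- cumsum(h * mids)
  total_w <- w[nbins]; total_m <- m[nbins]
  # candidate cuts between bin t and t+1
  w0 <- w[-nbins]; m0 <- m[-nbins]
  w1 <- total_w - w0; m1 <- total_m - m0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1)
  sigma_b[valid] <- (m0[valid] / w0[valid] - m1[valid] / w1[valid])^2 *
    w0[valid] * w1[valid]
  breaks[which.max(sigma_b) + 1L]
}

#' @keywords internal
#' @noRd
connectivity_offsets <- function(ndim, connectivity) {
  if (ndim == 2) {
    stopifnot(connectivity %in% c(4, 8))
    g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  } else {
    if (!connectivity %in% c(6, 18, 26))
      abort_validation("3D connectivity must be 6, 18 or 26")
    g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  }
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "4" = nz == 1, "8" = nz >= 1,
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary array
#'
#' Works on 2D matrices (4- or 8-connectivity) and 3D arrays (6-, 18-
#' or 26-connectivity). Component graph construction is vectorized and
#' the components are extracted with igraph.
#'
#' @param mask Logical matrix or 3D array.
#' @param connectivity 4/8 for 2D, 6/18/26 for 3D.
#' @return List with `labels` (integer array, 0 = background, components
#'   numbered by decreasing size, ties broken by first occurrence) and
#'   `sizes` (integer vector per label).
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 2) 8 else 26) {
  d <- dim(mask)
  if (is.null(d) || !length(d) %in% c(2, 3)) abort_validation("mask must be 2D or 3D")
  if (!is.logical(mask)) abort_validation("mask must be logical")
  labels <- array(0L, dim = d)
  fg <- which(mask)
  if (!length(fg)) return(list(labels = labels, sizes = integer(0)))

  offsets <- connectivity_offsets(length(d), connectivity)
  # half the neighborhood is enough for an undirected edge list
  first_nonzero_positive <- apply(offsets, 1, function(o) o[which(o != 0)[1]] > 0)
  offsets <- offsets[first_nonzero_positive, , drop = FALSE]

  coords <- arrayInd(fg, d)
  strides <- cumprod(c(1, d[-length(d)]))
  id <- seq_along(fg)
  edges <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[k, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (j in seq_along(d)) ok <- ok & nb[, j] >= 1 & nb[, j] <= d[j]
    if (!any(ok)) next
    nb_lin <- as.integer((nb[ok, , drop = FALSE] - 1) %*% strides) + 1L
    nb_id <- match(nb_lin, fg)
    hit <- !is.na(nb_id)
    if (any(hit)) edges[[k]] <- rbind(id[ok][hit], nb_id[hit])
  }
  edge_vec <- unlist(edges, use.names = FALSE)
  g <- igraph::make_graph(edges = if (is.null(edge_vec)) integer(0) else edge_vec,
                          n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(-comp$csize, seq_along(comp$csize))
  relabel <- integer(length(comp$csize))
  relabel[ord] <- seq_along(ord)
  labels[fg] <- relabel[comp$membership]
  list(labels = labels, sizes = as.integer(comp$csize[ord]))
}

#' Fill holes in a 2D binary mask
#'
#' A hole is a background component (4-connectivity) not touching the
#' image border.
#' @param mask Logical matrix.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4)
  d <- dim(mask)
  border <- unique(c(bg$labels[1, ], bg$labels[d[1], ], bg$labels[, 1], bg$labels[, d[2]]))
  border <- border[border > 0]
  mask | (bg$labels > 0 & !(bg$labels %in% border))
}
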