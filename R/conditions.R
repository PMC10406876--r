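#' @keywords internal
#' @noRd
stop_iccs <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "iccscoloc_error"), call = call))
}

# Invalid arguments / contract violations supplied by the caller.
abort_validation <- function(msg) stop_iccs(msg, "iccscoloc_validation_error")

# Inputs that are formally valid but carry no usable signal
# (constant images, zero-mean channels, ...).
abort_degenerate <- function(msg) stop_iccs(msg, "iccscoloc_degenerate_error")

# Files that cannot be read / parsed.
abort_io <- function(msg) stop_iccs(msg, "iccscoloc_io_error")
abort_format <- function(msg) stop_iccs(msg, "iccscoloc_format_error")

# Segmentation / placement failures.
abort_segmentation <- function(msg) stop_iccs(msg, "iccscoloc_segmentation_error")
abort_placement <- function(msg) stop_iccs(msg, "iccscoloc_placement_error")

#' @keywords internal
#' @noRd
check_finite_nonneg <- function(x, what) {
  if (!all(is.finite(x))) abort_validation(sprintf("%s contains non-finite values", what))
  if (any(x < 0)) abort_validation(sprintf("%s contains negative values", what))
  invisible(TRUE)
}
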