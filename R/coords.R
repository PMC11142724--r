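#' Convert normalized coordinates to pixel coordinates
#'
#' The normalized convention places the origin at the frame center with
#' align-corners endpoints: `-1` maps to the center of the first pixel and
#' `+1` to the center of the last pixel of each axis. A degenerate axis
#' (size 1) maps to pixel 0 regardless of the normalized value.
#'
#' @param pos numeric matrix `n x 3` (or length-3 vector) of `(x, y, z)`
#'   normalized coordinates.
#' @param shape integer `(Z, Y, X)` frame shape in pixels.
#' @return matrix `n x 3` of `(x, y, z)` pixel coordinates (0-based, float).
#' @export
normalized_to_pixel <- function(pos, shape) {
  pos <- as_coord_matrix(pos)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  sz <- c(shape[3L], shape[2L], shape[1L])  # (X, Y, Z) to match (x, y, z)
  out <- pos
  for (a in 1:3) {
    out[, a] <- if (sz[a] > 1L) (pos[, a] + 1) / 2 * (sz[a] - 1L) else 0
  }
  out
}

#' Convert pixel coordinates to normalized coordinates
#'
#' Inverse of [normalized_to_pixel()]; a degenerate axis (size 1) has
#' normalized coordinate identically 0.
#'
#' @inheritParams normalized_to_pixel
#' @param pos numeric matrix `n x 3` (or length-3 vector) of `(x, y, z)`
#'   pixel coordinates.
#' @return matrix `n x 3` of normalized coordinates.
#' @export
pixel_to_normalized <- function(pos, shape) {
  pos <- as_coord_matrix(pos)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  sz <- c(shape[3L], shape[2L], shape[1L])
  out <- pos
  for (a in 1:3) {
    out[, a] <- if (sz[a] > 1L) 2 * pos[, a] / (sz[a] - 1L) - 1 else 0
  }
  out
}

# pixels-per-normalized-unit scale factor per (x, y, z) axis; 0 for
# degenerate axes so gradients there vanish.
norm_scale <- function(shape) {
  sz <- c(shape[3L], shape[2L], shape[1L])
  ifelse(sz > 1L, (sz - 1L) / 2, 0)
}

as_coord_matrix <- function(pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  if (ncol(pos) != 3L) stop("coordinates must have 3 columns (x, y, z)")
  storage.mode(pos) <- "double"
  pos
}
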