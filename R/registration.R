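#' Build a descriptor sampling grid for one keypoint
#'
#' The grid is a regular `d x h x w` lattice of points spaced one pixel
#' apart (in frame pixel units), centered at the keypoint and optionally
#' rotated in-plane. Points are returned in normalized frame coordinates,
#' ready for [sample_descriptor()].
#'
#' @param center `(x, y, z)` keypoint position, normalized coordinates.
#' @param grid_shape `(d, h, w)` descriptor extent in `(z, y, x)` pixels;
#'   every entry must be odd so the lattice has a center point.
#' @param frame_shape `(Z, Y, X)` frame shape in pixels.
#' @param angle in-plane rotation of the lattice, radians (default 0).
#' @return `prod(grid_shape) x 3` matrix of `(x, y, z)` normalized
#'   coordinates with attribute `grid_shape`; rows are ordered z-fastest,
#'   then y, then x, matching the descriptor array layout `(d, h, w)`.
#' @export
grid_from_params <- function(center, grid_shape, frame_shape, angle = 0) {
  if (any(grid_shape %% 2L == 0L)) stop("grid_shape must be odd in each axis")
  off <- grid_offsets(grid_shape)
  if (angle != 0) off <- rotate_offsets(off, angle)
  center_px <- normalized_to_pixel(center, frame_shape)
  pts <- sweep(off, 2L, as.vector(center_px), "+")
  out <- pixel_to_normalized(pts, frame_shape)
  attr(out, "grid_shape") <- as.integer(grid_shape)
  out
}

# (x, y, z) pixel offsets of a (d, h, w) lattice, z varying fastest
grid_offsets <- function(grid_shape) {
  d <- grid_shape[1L]; h <- grid_shape[2L]; w <- grid_shape[3L]
  g <- expand.grid(dz = seq_len(d) - (d + 1) / 2,
                   dy = seq_len(h) - (h + 1) / 2,
                   dx = seq_len(w) - (w + 1) / 2)
  cbind(x = g$dx, y = g$dy, z = g$dz)
}

rotate_offsets <- function(off, angle) {
  ca <- cos(angle); sa <- sin(angle)
  cbind(x = ca * off[, 1L] - sa * off[, 2L],
        y = sa * off[, 1L] + ca * off[, 2L],
        z = off[, 3L])
}

#' Sample an image descriptor on a grid
#'
#' Multilinear (bilinear when `Z = 1`, trilinear otherwise) interpolation
#' of the frame at each grid point, per channel.
#'
#' @param frame array `(C, Z, Y, X)` (a 3-D array is treated as a single
#'   channel).
#' @param grid normalized-coordinate grid from [grid_from_params()].
#' @param pad_policy `"border"` (clamp out-of-bounds points to the edge
#'   value) or `"zero"`.
#' @return descriptor array `(C, d, h, w)`.
#' @export
sample_descriptor <- function(frame, grid, pad_policy = c("border", "zero")) {
  pad_policy <- match.arg(pad_policy)
  if (length(dim(frame)) == 3L) dim(frame) <- c(1L, dim(frame))
  d <- dim(frame)
  gs <- attr(grid, "grid_shape")
  if (is.null(gs)) stop("grid must carry a grid_shape attribute")
  pts <- normalized_to_pixel(grid, d[2:4])
  pad <- if (pad_policy == "border") 1L else 0L
  out <- array(0, c(d[1L], gs))
  for (ci in seq_len(d[1L])) {
    vol <- frame[ci, , , ]
    dim(vol) <- d[2:4]
    res <- cpp_sample_multilinear(vol, d[2:4], pts, pad)
    out[ci, , , ] <- array(res$value, gs)
  }
  out
}

#' Foveation blur schedule
#'
#' Descriptors are blurred at the start of optimization to reduce their
#' effective resolution, and the blur is stepped down in equal epoch
#' blocks until the final block runs at the original resolution. The
#' stage values decay linearly from `sigma_start` to 0.
#'
#' @param epoch 0-based iteration index, `0 <= epoch < n_epoch`.
#' @param schedule `(sigma_start, n_stages, n_epoch)`.
#' @return blur standard deviation in pixels for this epoch.
#' @export
blur_sigma <- function(epoch, schedule) {
  sigma_start <- schedule[[1L]]; n_stages <- as.integer(schedule[[2L]])
  n_epoch <- as.integer(schedule[[3L]])
  stopifnot(epoch >= 0, epoch < n_epoch, n_stages >= 1L)
  if (n_stages == 1L) return(0)
  s <- floor(epoch * n_stages / n_epoch)
  max(0, sigma_start * (1 - s / (n_stages - 1L)))
}

# Row-normalized truncated Gaussian blur matrix along one axis.
blur_matrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) return(diag(n))
  r <- ceiling(3 * sigma)
  i <- seq_len(n)
  w <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  w[abs(outer(i, i, "-")) > r] <- 0
  w / rowSums(w)
}

# Apply per-axis blur matrices to a (d, h, w, m) stack; transpose = TRUE
# applies the exact adjoint (needed for gradient backpropagation).
blur_stack <- function(arr, mats, transpose = FALSE) {
  d <- dim(arr)
  for (ax in 1:3) {
    w <- mats[[ax]]
    if (nrow(w) == 1L || identical(w, diag(nrow(w)))) next
    if (transpose) w <- t(w)
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- w %*% matrix(a, da[1L])
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Gaussian-blur a descriptor
#'
#' Separable Gaussian blur applied to the sampled descriptor array (per
#' channel), the foveation primitive paired with [blur_sigma()].
#'
#' @param desc descriptor array `(C, d, h, w)` or `(d, h, w)`.
#' @param sigma blur standard deviation in pixels (`0` = identity).
#' @return blurred array of the same shape.
#' @export
blur_descriptor <- function(desc, sigma) {
  if (sigma <= 0) return(desc)
  d3 <- length(dim(desc)) == 3L
  if (d3) dim(desc) <- c(1L, dim(desc))
  dd <- dim(desc)
  mats <- lapply(dd[2:4], blur_matrix, sigma = sigma)
  stack <- aperm(desc, c(2, 3, 4, 1))
  stack <- blur_stack(stack, mats)
  out <- aperm(stack, c(4, 1, 2, 3))
  if (d3) dim(out) <- dd[2:4]
  out
}

#' Registration loss between child and reference descriptors
#'
#' `sum_i [1 - r_i]` where `r_i` is the Pearson correlation between the
#' flattened descriptor pair of keypoint `i` (all channels jointly). A
#' zero-variance member makes that pair's correlation 0, so the term
#' contributes 1.
#'
#' @param child_descriptors,ref_descriptors lists of descriptor arrays of
#'   matching shapes (one per keypoint).
#' @return scalar loss.
#' @export
loss_registration <- function(child_descriptors, ref_descriptors) {
  if (length(child_descriptors) != length(ref_descriptors))
    stop("descriptor lists must have equal length")
  childM <- vapply(child_descriptors, as.vector,
                   numeric(length(as.vector(child_descriptors[[1L]]))))
  refM <- vapply(ref_descriptors, as.vector,
                 numeric(length(as.vector(ref_descriptors[[1L]]))))
  if (!identical(dim(childM), dim(refM))) stop("descriptor shape mismatch")
  sum(1 - corr_columns(childM, refM)$r)
}

# Column-wise (optionally weighted) Pearson correlation between two
# matrices plus the gradient of each r with respect to the child column.
# Zero-variance columns give r = 0 with zero gradient. Weights implement
# foveation: center grid points count more than the periphery.
corr_columns <- function(childM, refM, weights = NULL) {
  childM <- as.matrix(childM); refM <- as.matrix(refM)
  w <- if (is.null(weights)) rep(1, nrow(childM)) else weights
  sw <- sum(w)
  cc <- sweep(childM, 2L, colSums(w * childM) / sw)
  rc <- sweep(refM, 2L, colSums(w * refM) / sw)
  nc <- sqrt(colSums(w * cc^2))
  nr <- sqrt(colSums(w * rc^2))
  ok <- nc > 0 & nr > 0
  denom <- ifelse(ok, nc * nr, 1)
  r <- colSums(w * cc * rc) / denom
  r[!ok] <- 0
  # d r / d child_j = w_j (ref_c/(|ref_c||child_c|) - r child_c/|child_c|^2)
  grad <- w * (sweep(rc, 2L, denom, "/") -
                 sweep(cc, 2L, ifelse(ok, r / nc^2, 0), "*"))
  grad[, !ok] <- 0
  list(r = r, grad = grad)
}

# Gaussian foveal weights over the descriptor lattice: in-plane width
# sigma (px), z width scaled by the grid aspect ratio.
fovea_weights <- function(offsets, grid_shape, sigma) {
  if (is.null(sigma) || !is.finite(sigma) || sigma <= 0) return(numeric(0))
  sz <- max(sigma * grid_shape[1L] / grid_shape[2L], 0.5)
  exp(-(offsets[, 1L]^2 + offsets[, 2L]^2) / (2 * sigma^2) -
        offsets[, 3L]^2 / (2 * sz^2))
}

# --- batched registration term used by the tracker -------------------------

# Sample raw (unblurred) descriptors for all keypoints at given pixel
# centers; returns (G*C) x n matrix (grid index fastest, channels stacked)
# plus the per-point sampling gradients per channel.
sample_descriptor_batch <- function(frame, centers_px, offsets, pad = 1L,
                                    angles = NULL, want_grad = FALSE) {
  d <- dim(frame)
  n <- nrow(centers_px)
  g_n <- nrow(offsets)
  if (is.null(angles) || all(angles == 0)) {
    pts <- offsets[rep(seq_len(g_n), n), , drop = FALSE] +
      centers_px[rep(seq_len(n), each = g_n), , drop = FALSE]
  } else {
    pts <- matrix(0, g_n * n, 3L)
    for (i in seq_len(n)) {
      o <- rotate_offsets(offsets, angles[i])
      pts[(i - 1L) * g_n + seq_len(g_n), ] <-
        sweep(o, 2L, centers_px[i, ], "+")
    }
  }
  vals <- vector("list", d[1L])
  grads <- if (want_grad) vector("list", d[1L]) else NULL
  for (ci in seq_len(d[1L])) {
    vol <- frame[ci, , , ]
    dim(vol) <- d[2:4]
    res <- cpp_sample_multilinear(vol, d[2:4], pts, pad)
    vals[[ci]] <- matrix(res$value, g_n, n)
    if (want_grad) grads[[ci]] <- res$grad
  }
  list(values = do.call(rbind, vals), grads = grads, g_n = g_n, n = n)
}

# Fast path: identical computation to registration_term() but performed
# in one compiled pass (translation-only grids).
registration_term_fast <- function(frame, centers_px, refM, offsets,
                                   grid_shape, sigma, pad = 1L,
                                   fovea_w = numeric(0)) {
  d <- dim(frame)
  vols <- lapply(seq_len(d[1L]), function(ci) {
    v <- frame[ci, , , ]
    dim(v) <- d[2:4]
    v
  })
  cpp_registration_term(vols, d[2:4], centers_px, offsets,
                        as.integer(grid_shape), refM, sigma, pad, fovea_w)
}

# Registration loss + gradient w.r.t. pixel-space keypoint centers.
# refM: (G*C) x n reference descriptor matrix already blurred at the
# current sigma. Returns loss, per-keypoint correlations, grad (n x 3).
registration_term <- function(frame, centers_px, refM, offsets, grid_shape,
                              sigma, pad = 1L, angles = NULL,
                              fovea_w = NULL) {
  sm <- sample_descriptor_batch(frame, centers_px, offsets, pad,
                                angles, want_grad = TRUE)
  g_n <- sm$g_n; n <- sm$n
  n_ch <- length(sm$grads)
  mats <- lapply(grid_shape, blur_matrix, sigma = sigma)
  childM <- sm$values
  if (sigma > 0) {
    for (ci in seq_len(n_ch)) {
      sl <- (ci - 1L) * g_n + seq_len(g_n)
      a <- array(childM[sl, ], c(grid_shape, n))
      childM[sl, ] <- matrix(blur_stack(a, mats), g_n)
    }
  }
  if (!is.null(fovea_w) && length(fovea_w) == 0L) fovea_w <- NULL
  wfull <- if (is.null(fovea_w)) NULL else rep(fovea_w, n_ch)
  cr <- corr_columns(childM, refM, wfull)
  grad_px <- matrix(0, n, 3L)
  for (ci in seq_len(n_ch)) {
    sl <- (ci - 1L) * g_n + seq_len(g_n)
    gd <- -cr$grad[sl, , drop = FALSE]  # d(1 - r)/d D
    if (sigma > 0) {
      a <- array(gd, c(grid_shape, n))
      gd <- matrix(blur_stack(a, mats, transpose = TRUE), g_n)
    }
    sg <- sm$grads[[ci]]
    for (ax in 1:3)
      grad_px[, ax] <- grad_px[, ax] +
        colSums(gd * matrix(sg[, ax], g_n, n))
  }
  list(loss = sum(1 - cr$r), r = cr$r, grad_px = grad_px)
}
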