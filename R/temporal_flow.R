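#' Temporal smoothness loss
#'
#' Penalizes deviation of each keypoint's interpolated intensity in the
#' center frame from its intensity in the surrounding `+/- epsilon`
#' frames (a zeroth-order fit): `sum_i sum_t |I_t[rho_i_t] - I_c[rho_i_c]|`.
#' The patch is truncated at the video ends. The gradient is taken with
#' respect to the center frame's positions only; neighbor positions are
#' treated as fixed context.
#'
#' @param video a `video_store`.
#' @param positions_patch named list mapping frame index (as character,
#'   0-based) to an `n x 3` matrix of normalized keypoint positions; must
#'   cover the center frame and every in-range patch frame.
#' @param center 0-based center frame index.
#' @param epsilon patch half-width in frames (default 2).
#' @param channel 1-based channel used for the intensity lookups.
#' @param grad if `TRUE`, also return the gradient with respect to the
#'   center positions in pixel units (`n x 3`).
#' @return scalar loss, or list `(loss, grad_px)`.
#' @export
loss_temporal <- function(video, positions_patch, center, epsilon = 2L,
                          channel = 1L, grad = FALSE) {
  shp <- video_shape(video)
  t_set <- intersect(seq(center - epsilon, center + epsilon),
                     seq_len(n_frames(video)) - 1L)
  t_set <- setdiff(t_set, center)
  pos_c <- as_coord_matrix(positions_patch[[as.character(center)]])
  px_c <- normalized_to_pixel(pos_c, shp)
  fr_c <- get_frame(video, center)[channel, , , ]
  dim(fr_c) <- shp
  res_c <- cpp_sample_multilinear(fr_c, shp, px_c, 1L)
  l <- 0
  g <- matrix(0, nrow(pos_c), 3L)
  for (t in t_set) {
    pos_t <- positions_patch[[as.character(t)]]
    if (is.null(pos_t)) stop("positions_patch missing frame ", t)
    px_t <- normalized_to_pixel(as_coord_matrix(pos_t), shp)
    fr_t <- get_frame(video, t)[channel, , , ]
    dim(fr_t) <- shp
    v_t <- cpp_sample_multilinear(fr_t, shp, px_t, 1L)$value
    diff <- v_t - res_c$value
    l <- l + sum(abs(diff))
    if (grad) g <- g - sign(diff) * res_c$grad
  }
  if (!grad) return(l)
  list(loss = l, grad_px = g)
}

#' Interpolate a flow field from partial annotations
#'
#' Given the coordinates of a few annotated keypoints in a parent frame
#' and their manually annotated coordinates in the child frame, builds a
#' smooth displacement field exact at the control points. The field is a
#' thin-plate radial-basis interpolant (kernel `r^2 log r` on the 3D
#' control-point distance, which reduces to the classic in-plane
#' thin-plate spline when `z` is degenerate) plus a linear polynomial in
#' `(x, y, z)`. With a single control point the field is constant.
#'
#' @param parent_coords `n x 3` normalized coordinates of the annotated
#'   keypoints in the parent frame.
#' @param child_coords their `n x 3` annotated coordinates in the child.
#' @return a `flow_field` object; evaluate it with [flow_evaluate()] or
#'   apply it with [apply_flow()].
#' @export
interpolate_flow <- function(parent_coords, child_coords) {
  ctrl <- as_coord_matrix(parent_coords)
  disp <- as_coord_matrix(child_coords) - ctrl
  n <- nrow(ctrl)
  stopifnot(nrow(disp) == n, n >= 1L)
  if (anyDuplicated(round(ctrl, 12L)))
    stop("duplicate control points in parent frame")
  if (n == 1L) {
    return(structure(list(type = "constant", disp = disp[1L, ],
                          control_points = ctrl,
                          control_displacements = disp),
                     class = "flow_field"))
  }
  k <- tps_kernel(ctrl, ctrl)
  p_full <- cbind(1, ctrl)
  # restrict the polynomial to the directions the controls determine
  # (pivoted QR), so e.g. a constant displacement field stays constant
  # when extrapolated away from few or degenerate control points
  qr_p <- qr(p_full)
  keep <- qr_p$pivot[seq_len(qr_p$rank)]
  p <- p_full[, keep, drop = FALSE]
  m <- length(keep)
  kkt <- rbind(cbind(k, p), cbind(t(p), matrix(0, m, m)))
  rhs <- rbind(disp, matrix(0, m, 3L))
  sol <- MASS::ginv(kkt) %*% rhs
  a <- matrix(0, 4L, 3L)
  a[keep, ] <- sol[n + seq_len(m), , drop = FALSE]
  structure(list(type = "tps", control_points = ctrl,
                 control_displacements = disp,
                 w = sol[seq_len(n), , drop = FALSE], a = a),
            class = "flow_field")
}

tps_kernel <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2 <- pmax(d2, 0)
  k <- 0.5 * d2 * log(pmax(d2, 1e-300))   # r^2 log r = d2 log(d2)/2
  k[d2 == 0] <- 0
  k
}

#' Evaluate a flow field
#'
#' @param field a `flow_field` from [interpolate_flow()].
#' @param positions `m x 3` normalized positions to evaluate at.
#' @return `m x 3` matrix of displacement vectors.
#' @export
flow_evaluate <- function(field, positions) {
  pos <- as_coord_matrix(positions)
  if (field$type == "constant")
    return(matrix(field$disp, nrow(pos), 3L, byrow = TRUE))
  k <- tps_kernel(pos, field$control_points)
  k %*% field$w + cbind(1, pos) %*% field$a
}

#' Displace positions by a flow field
#'
#' @inheritParams flow_evaluate
#' @return `positions + flow_evaluate(field, positions)`.
#' @export
apply_flow <- function(field, positions) {
  pos <- as_coord_matrix(positions)
  pos + flow_evaluate(field, pos)
}
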