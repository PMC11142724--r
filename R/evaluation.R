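coords_table <- function(x) {
  if (inherits(x, "tracking_result")) x$coords
  else if (inherits(x, "synthetic_movie")) x$truth
  else as.data.frame(x)
}

paired_pixel_error <- function(pred, truth, shape) {
  p <- coords_table(pred); tr <- coords_table(truth)
  kp <- paste(p$t, p$worldline_id); kt <- paste(tr$t, tr$worldline_id)
  if (!setequal(kp, kt))
    stop("pred and truth tables do not cover the same (t, worldline) keys")
  tr <- tr[match(kp, kt), ]
  dpx <- normalized_to_pixel(as.matrix(p[c("x", "y", "z")]), shape) -
    normalized_to_pixel(as.matrix(tr[c("x", "y", "z")]), shape)
  data.frame(t = p$t, worldline_id = p$worldline_id,
             err = sqrt(rowSums(dpx^2)))
}

#' Tracking accuracy
#'
#' Fraction of (frame, worldline) pairs whose predicted position lies
#' within `radius` pixels (Euclidean) of the true position, averaged over
#' frames. The radius stands in for the physical extent of the tracked
#' object (e.g. a nucleus).
#'
#' @param pred,truth annotation-style tables (or a `tracking_result` /
#'   `synthetic_movie`) covering the same `(t, worldline_id)` keys.
#' @param radius matching radius in pixels.
#' @param shape `(Z, Y, X)` frame shape used to convert normalized
#'   coordinates to pixels.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(pred, truth, radius = 3, shape) {
  pe <- paired_pixel_error(pred, truth, shape)
  mean(tapply(pe$err <= radius, pe$t, mean))
}

#' Tracking precision (RMS error)
#'
#' Root-mean-square Euclidean pixel distance between predicted and true
#' positions over all (frame, worldline) pairs.
#'
#' @inheritParams accuracy
#' @return RMS error in pixels.
#' @export
precision_rmse <- function(pred, truth, shape) {
  pe <- paired_pixel_error(pred, truth, shape)
  sqrt(mean(pe$err^2))
}

#' Fit and return a photobleach decay curve
#'
#' Bounded double-exponential fit `a*exp(-t/tau1) + b*exp(-t/tau2) + c`
#' to an intensity trace; falls back to a single exponential, then to a
#' constant, when the fit fails to converge.
#'
#' @param y intensity trace.
#' @return fitted values (same length as `y`), never zero or negative.
#' @export
fit_photobleach <- function(y) {
  tt <- seq_along(y) - 1
  t_n <- length(y)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ a * exp(-tt / tau1) + b * exp(-tt / tau2) + c0,
      start = list(a = max(y[1] - y[t_n], 0.1) / 2, tau1 = t_n / 5,
                   b = max(y[1] - y[t_n], 0.1) / 2, tau2 = t_n * 2,
                   c0 = min(y)),
      lower = c(0, 1e-2, 0, 1e-2, 0),
      upper = c(Inf, t_n * 100, Inf, t_n * 100, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    as.numeric(stats::fitted(m))
  }, error = function(e) NULL)
  if (is.null(fit)) fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ a * exp(-tt / tau1) + c0,
      start = list(a = max(y[1] - y[t_n], 0.1), tau1 = t_n / 3,
                   c0 = min(y)),
      lower = c(0, 1e-2, 0), upper = c(Inf, t_n * 100, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    as.numeric(stats::fitted(m))
  }, error = function(e) NULL)
  if (is.null(fit)) fit <- rep(mean(y), t_n)
  pmax(fit, 1e-12)
}

#' Extract ratiometric activity traces from tracked coordinates
#'
#' For each worldline and frame, crops a `roi` box (default 3 x 7 x 7
#' voxels, roughly a nucleus) around the tracked pixel position in both
#' channels, masks out voxels that fall inside the boxes of the
#' `n_mask_neighbors` nearest other worldlines, and averages the
#' `n_brightest` channel-1 voxels; the raw trace is
#' `mean(ch1) / mean(ch2)` over those voxels. Each trace is then divided
#' by its fitted double-exponential photobleach curve
#' ([fit_photobleach()], normalized to its first-frame value) and
#' reported as fold change over the first frame.
#'
#' @param video a 2-channel `video_store` (channel 1 = activity-dependent
#'   fluorophore, channel 2 = stable reference).
#' @param result a `tracking_result` (or annotation table) with
#'   coordinates for every frame and worldline.
#' @param roi `(z, y, x)` box size in voxels (odd).
#' @param n_brightest number of brightest channel-1 voxels averaged.
#' @param n_mask_neighbors number of nearest neighbor worldlines whose
#'   boxes are masked out.
#' @param correct_bleach divide out the photobleach fit (default TRUE).
#' @return matrix `n_worldlines x T` of fold-change traces (rownames =
#'   worldline ids), with the raw ratio traces in attribute `"raw"`.
#' @export
extract_traces <- function(video, result, roi = c(3L, 7L, 7L),
                           n_brightest = 9L, n_mask_neighbors = 5L,
                           correct_bleach = TRUE) {
  if (video$n_channels < 2L)
    stop("trace extraction requires a 2-channel video")
  stopifnot(all(roi %% 2L == 1L))
  coords <- coords_table(result)
  shp <- video_shape(video)
  t_n <- n_frames(video)
  wl <- sort(unique(coords$worldline_id))
  n <- length(wl)
  half <- (as.integer(roi) - 1L) %/% 2L        # (z, y, x)
  raw <- matrix(NA_real_, n, t_n, dimnames = list(wl, NULL))
  for (t in seq_len(t_n) - 1L) {
    rows <- coords[coords$t == t, ]
    px <- normalized_to_pixel(
      as.matrix(rows[match(wl, rows$worldline_id), c("x", "y", "z")]), shp)
    ctr <- round(px)                            # (x, y, z) integer centers
    fr <- get_frame(video, t)
    dm <- as.matrix(stats::dist(px))
    diag(dm) <- Inf
    for (i in seq_len(n)) {
      zr <- max(0L, ctr[i, 3L] - half[1L]):min(shp[1L] - 1L, ctr[i, 3L] + half[1L])
      yr <- max(0L, ctr[i, 2L] - half[2L]):min(shp[2L] - 1L, ctr[i, 2L] + half[2L])
      xr <- max(0L, ctr[i, 1L] - half[3L]):min(shp[3L] - 1L, ctr[i, 1L] + half[3L])
      vox <- as.matrix(expand.grid(z = zr, y = yr, x = xr))
      keep <- rep(TRUE, nrow(vox))
      nb <- order(dm[i, ])[seq_len(min(n_mask_neighbors, n - 1L))]
      for (j in nb) {
        inside <- abs(vox[, "z"] - ctr[j, 3L]) <= half[1L] &
          abs(vox[, "y"] - ctr[j, 2L]) <= half[2L] &
          abs(vox[, "x"] - ctr[j, 1L]) <= half[3L]
        keep <- keep & !inside
      }
      if (!any(keep)) keep <- rep(TRUE, nrow(vox))
      vv <- vox[keep, , drop = FALSE]
      idx1 <- cbind(1L, vv[, "z"] + 1L, vv[, "y"] + 1L, vv[, "x"] + 1L)
      idx2 <- cbind(2L, vv[, "z"] + 1L, vv[, "y"] + 1L, vv[, "x"] + 1L)
      v1 <- fr[idx1]; v2 <- fr[idx2]
      top <- order(v1, decreasing = TRUE)[seq_len(min(n_brightest, length(v1)))]
      raw[i, t + 1L] <- mean(v1[top]) / max(mean(v2[top]), 1e-12)
    }
  }
  out <- raw
  if (correct_bleach) {
    for (i in seq_len(n)) {
      fit <- fit_photobleach(raw[i, ])
      out[i, ] <- raw[i, ] / (fit / fit[1L])
    }
  }
  out <- out / out[, 1L]
  attr(out, "raw") <- raw
  out
}
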