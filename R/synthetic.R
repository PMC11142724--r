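# Smooth a (T x m) matrix of noise along time with a Gaussian kernel.
smooth_time <- function(x, sigma) {
  if (sigma <= 0) return(x)
  w <- blur_matrix(nrow(x), sigma)
  w %*% x
}

#' Parameters for the synthetic movie generator
#'
#' Builds the parameter list for [generate_movie()]. Two presets:
#' * `"worm3d"` — the benchmark condition: 60 keypoints on a bending 3D
#'   backbone, 80 frames of shape 16 x 128 x 128, Gaussian blobs of
#'   sigma 1.5 px in-plane, per-frame ground-truth displacement capped at
#'   4 px, traveling-wave body bending plus slow global drift/rotation.
#' * `"posture2d"` — a 2D movie that cycles through a small set of
#'   discrete postures (for exercising similarity sorting and k-medoids
#'   reference recommendation).
#'
#' @param preset `"worm3d"` or `"posture2d"`.
#' @param ... named overrides of any default.
#' @return named list of generator parameters.
#' @export
movie_params <- function(preset = c("worm3d", "posture2d"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    worm3d = list(
      n_keypoints = 60L, n_frames = 80L, shape = c(16L, 128L, 128L),
      n_channels = 1L, blob_sigma = c(1.0, 1.5, 1.5),
      amp_range = c(0.6, 1.0), noise_sd = 0.03,
      max_step = 4, margin = 12,
      bend_amp = 5, bend_amp_z = 1.2, wave_number = 1.2,
      cycle_period = 20, n_postures = NULL,
      drift_amp = 2, rot_amp = 0.04, poly_amp = 1.5, jitter_sd = 0.25,
      activity_amp = c(0.2, 0.5), activity_period = c(15, 40),
      bleach = c(a = 0.3, tau1 = 30, b = 0.7, tau2 = 300),
      seed = 0L),
    posture2d = list(
      n_keypoints = 15L, n_frames = 30L, shape = c(1L, 64L, 64L),
      n_channels = 1L, blob_sigma = c(1.0, 1.5, 1.5),
      amp_range = c(0.6, 1.0), noise_sd = 0.02,
      max_step = NULL, margin = 8,
      bend_amp = 7, bend_amp_z = 0, wave_number = 1.0,
      cycle_period = 3, n_postures = 3L,
      drift_amp = 0.5, rot_amp = 0.01, poly_amp = 0.5, jitter_sd = 0.15,
      activity_amp = c(0.2, 0.5), activity_period = c(10, 25),
      bleach = c(a = 0.3, tau1 = 15, b = 0.7, tau2 = 150),
      seed = 0L))
  p$preset <- preset
  utils::modifyList(p, list(...))
}

#' Render one frame of Gaussian blobs
#'
#' @param points `n x 3` pixel coordinates `(x, y, z)` of blob centers.
#' @param intensities blob peak intensities.
#' @param blob_sigma `(z, y, x)` Gaussian widths in pixels.
#' @param shape `(Z, Y, X)` frame shape.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed RNG seed for the noise (`NULL` = use the current RNG
#'   state).
#' @return `(Z, Y, X)` array, clipped to `[0, 1]` and quantized to the
#'   16-bit grid so frames survive a TIFF round trip bit-for-bit.
#' @export
render_frame <- function(points, intensities, blob_sigma, shape,
                         noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fr <- cpp_render_blobs(as.integer(shape), as_coord_matrix(points),
                         intensities, blob_sigma)
  if (noise_sd > 0)
    fr <- fr + array(stats::rnorm(prod(shape), sd = noise_sd), dim(fr))
  round(pmin(pmax(fr, 0), 1) * 65535) / 65535
}

#' Generate a deformable sparse-blob movie with ground-truth tracks
#'
#' Keypoints are placed on a smooth backbone curve with transverse
#' jitter; over time they move under a traveling-wave (or discrete
#' posture-cycle) bending deformation, a slow global rotation and drift,
#' a low-order polynomial field along the backbone, and small smooth
#' per-keypoint jitter — neighbors therefore move coherently, as cells in
#' deforming tissue do. Frames render each keypoint as an anisotropic
#' Gaussian blob plus Gaussian noise. With `n_channels = 2`, channel 2
#' holds stable blob intensities (reference fluorophore) and channel 1 is
#' modulated by slow per-keypoint activity signals under double-
#' exponential photobleach decay. When `max_step` is set, the whole
#' displacement field is rescaled so no ground-truth point moves more
#' than `max_step` px between consecutive frames.
#'
#' @param params list from [movie_params()].
#' @return a `synthetic_movie`: list with `video` (a [video_store()]),
#'   `truth` (full annotation table, provenance `"manual"`), `signals`
#'   (`n x T` activity matrix or `NULL`), `bleach` (length-`T` decay
#'   curve or `NULL`), `clamped` (logical, any truth position clamped to
#'   the frame margin), and `params`.
#' @export
generate_movie <- function(params = movie_params()) {
  p <- params
  stopifnot(p$n_keypoints >= 2L, p$n_frames >= 2L)
  set.seed(p$seed)
  n <- p$n_keypoints; t_n <- p$n_frames
  shape <- p$shape; zdim <- shape[1L]; ydim <- shape[2L]; xdim <- shape[3L]

  # backbone placement
  s <- sort((seq_len(n) - 0.5) / n + stats::runif(n, -0.2 / n, 0.2 / n))
  ph <- stats::runif(2, 0, 2 * pi)
  base <- cbind(
    x = p$margin + s * (xdim - 2 * p$margin),
    y = ydim / 2 + 0.15 * ydim * sin(2 * pi * 0.8 * s + ph[1L]),
    z = if (zdim > 1L) zdim / 2 + 0.12 * zdim * sin(2 * pi * 0.6 * s + ph[2L])
        else rep(0, n))
  jit_sd <- c(2.0, 2.5, if (zdim > 1L) 0.8 else 0)
  base <- base + cbind(stats::rnorm(n, sd = jit_sd[1L]),
                       stats::rnorm(n, sd = jit_sd[2L]),
                       stats::rnorm(n, sd = jit_sd[3L]))
  # enforce a minimum blob separation (nuclei must not overlap)
  for (it in 1:100) {
    dm <- as.matrix(stats::dist(base))
    diag(dm) <- Inf
    close <- which(apply(dm, 1L, min) < 5)
    if (!length(close)) break
    base[close, 1:2] <- base[close, 1:2] +
      matrix(stats::rnorm(2 * length(close), sd = 1.5), ncol = 2L)
  }

  # time-varying deformation (T x n per axis, pixels)
  phase <- if (!is.null(p$n_postures)) {
    (seq_len(t_n) - 1L) %% p$n_postures / p$n_postures
  } else {
    (seq_len(t_n) - 1L) / p$cycle_period
  }
  bend_y <- p$bend_amp *
    sin(2 * pi * (outer(phase, p$wave_number * s, "+")))     # T x n
  bend_z <- if (zdim > 1L && p$bend_amp_z > 0)
    p$bend_amp_z * sin(2 * pi * (outer(phase, p$wave_number * s, "+") + 0.3))
  else matrix(0, t_n, n)
  ang <- p$rot_amp * sin(2 * pi * (seq_len(t_n) - 1L) / t_n * 1.3 +
                           stats::runif(1, 0, 2 * pi))
  drift <- smooth_time(matrix(stats::rnorm(t_n * 2), t_n), sigma = 4)
  # floor the normalization scale: very short movies can leave the
  # smoothed noise with near-zero sample sd, which would blow the drift up
  drift_sd <- pmax(apply(drift, 2L, stats::sd), 0.1)
  drift <- sweep(drift, 2L, drift_sd / p$drift_amp, "/")
  poly_c <- smooth_time(matrix(stats::rnorm(t_n * 2), t_n), sigma = 5) *
    p$poly_amp
  jit <- array(stats::rnorm(t_n * n * 3, sd = p$jitter_sd), c(t_n, n, 3L))
  for (ax in 1:3) jit[, , ax] <- smooth_time(jit[, , ax], sigma = 2)
  if (zdim == 1L) jit[, , 3L] <- 0

  ctr <- c(mean(base[, 1L]), mean(base[, 2L]))
  pos <- array(0, c(t_n, n, 3L))  # pixel (x, y, z)
  for (t in seq_len(t_n)) {
    px <- base[, 1L]
    py <- base[, 2L] + bend_y[t, ]
    pz <- base[, 3L] + bend_z[t, ]
    # in-plane rotation about the backbone centroid
    ca <- cos(ang[t]); sa <- sin(ang[t])
    rx <- ctr[1L] + ca * (px - ctr[1L]) - sa * (py - ctr[2L])
    ry <- ctr[2L] + sa * (px - ctr[1L]) + ca * (py - ctr[2L])
    # low-order polynomial field along the backbone
    rx <- rx + poly_c[t, 1L] * (s - 0.5)^2 * 4
    ry <- ry + poly_c[t, 2L] * (s - 0.5) * 2
    pos[t, , ] <- cbind(rx + drift[t, 1L], ry + drift[t, 2L], pz) +
      jit[t, , ]
  }

  # cap the per-frame ground-truth displacement
  if (!is.null(p$max_step) && is.finite(p$max_step) && t_n > 1L) {
    mean_pos <- apply(pos, c(2L, 3L), mean)
    steps <- sqrt(apply((pos[-1L, , , drop = FALSE] -
                           pos[-t_n, , , drop = FALSE])^2, c(1L, 2L), sum))
    f <- min(1, p$max_step / max(steps))
    if (f < 1)
      for (t in seq_len(t_n))
        pos[t, , ] <- mean_pos + f * (pos[t, , ] - mean_pos)
  }

  # separation repair: blobs must never overlap at any time point; push
  # persistently close pairs apart by a constant offset (constant shifts
  # leave per-frame step sizes unchanged)
  min_sep <- 3
  for (it in 1:30) {
    mind <- matrix(Inf, n, n)
    for (t in seq_len(t_n))
      mind <- pmin(mind, as.matrix(stats::dist(pos[t, , ])))
    diag(mind) <- Inf
    pairs <- which(mind < min_sep & upper.tri(mind), arr.ind = TRUE)
    if (!nrow(pairs)) break
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      u <- colMeans(pos[, i, ] - pos[, j, ])
      nu <- sqrt(sum(u^2))
      u <- if (nu > 0) u / nu else c(1, 0, 0)
      if (zdim == 1L) u[3L] <- 0
      need <- (min_sep - mind[i, j]) / 2 + 0.1
      pos[, i, ] <- sweep(pos[, i, ], 2L, u * need, "+")
      pos[, j, ] <- sweep(pos[, j, ], 2L, u * need, "-")
    }
  }

  # clamp to the frame with a margin flag
  lim_lo <- c(2, 2, if (zdim > 1L) 1 else 0)
  lim_hi <- c(xdim - 3, ydim - 3, if (zdim > 1L) zdim - 2 else 0)
  clamped <- FALSE
  for (ax in 1:3) {
    bad <- pos[, , ax] < lim_lo[ax] | pos[, , ax] > lim_hi[ax]
    if (any(bad)) {
      clamped <- TRUE
      pos[, , ax] <- pmin(pmax(pos[, , ax], lim_lo[ax]), lim_hi[ax])
    }
  }
  if (clamped) warning("some blob positions were clamped to the frame margin")

  # intensities, activity, photobleach
  base_amp <- stats::runif(n, p$amp_range[1L], p$amp_range[2L])
  signals <- NULL; bleach <- NULL
  if (p$n_channels == 2L) {
    aa <- stats::runif(n, p$activity_amp[1L], p$activity_amp[2L])
    per <- stats::runif(n, p$activity_period[1L], p$activity_period[2L])
    ph2 <- stats::runif(n, 0, 2 * pi)
    tt <- seq_len(t_n) - 1L
    signals <- t(vapply(seq_len(n),
                        function(i) 1 + aa[i] * sin(2 * pi * tt / per[i] + ph2[i]),
                        numeric(t_n)))
    b <- p$bleach
    bleach <- (b["a"] * exp(-tt / b["tau1"]) + b["b"] * exp(-tt / b["tau2"])) /
      (b["a"] + b["b"])
    bleach <- unname(bleach)
  }

  dat <- array(0, c(t_n, p$n_channels, shape))
  for (t in seq_len(t_n)) {
    pts <- pos[t, , ]
    dim(pts) <- c(n, 3L)
    if (p$n_channels == 2L) {
      dat[t, 1L, , , ] <- render_frame(pts, base_amp * signals[, t] * bleach[t] * 0.7,
                                       p$blob_sigma, shape, p$noise_sd)
      dat[t, 2L, , , ] <- render_frame(pts, base_amp, p$blob_sigma, shape,
                                       p$noise_sd)
    } else {
      dat[t, 1L, , , ] <- render_frame(pts, base_amp, p$blob_sigma, shape,
                                       p$noise_sd)
    }
  }

  truth <- do.call(rbind, lapply(seq_len(t_n), function(t) {
    pts <- pos[t, , ]
    dim(pts) <- c(n, 3L)
    nm <- pixel_to_normalized(pts, shape)
    data.frame(t = t - 1L, worldline_id = seq_len(n) - 1L,
               x = nm[, 1L], y = nm[, 2L], z = nm[, 3L],
               provenance = "manual")
  }))

  structure(
    list(video = video_store(dat), truth = validate_annotations(truth),
         signals = signals, bleach = bleach, clamped = clamped,
         params = p),
    class = "synthetic_movie")
}
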