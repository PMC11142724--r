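# Separable Gaussian blur of a (Z, Y, X) volume; sigma is scalar or
# (z, y, x). Truncated row-normalized kernels (edge renormalization).
gauss_blur3 <- function(vol, sigma) {
  d <- dim(vol)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  mats <- mapply(function(n, s) blur_matrix(n, if (n > 1L) s else 0),
                 d, sigma, SIMPLIFY = FALSE)
  dim(vol) <- c(d, 1L)
  out <- blur_stack(vol, mats)
  dim(out) <- d
  out
}

rescale01 <- function(v) {
  rng <- range(v)
  # a dynamic range at floating-point noise level is a constant response
  if (rng[2L] - rng[1L] <= 1e-10 * max(abs(rng), 1))
    return(array(0, dim(v)))
  (v - rng[1L]) / (rng[2L] - rng[1L])
}

# 6/4-neighbor discrete Laplacian with replicate edges.
laplacian3 <- function(vol) {
  d <- dim(vol)
  out <- array(0, d)
  for (ax in which(d > 1L)) {
    n <- d[ax]
    lo <- c(1L, seq_len(n - 1L)); hi <- c(seq_len(n - 1L) + 1L, n)
    sl <- function(idx) {
      args <- rep(list(quote(expr = )), 3L)
      args[[ax]] <- idx
      do.call(`[`, c(list(vol), args, drop = FALSE))
    }
    out <- out + sl(lo) + sl(hi) - 2 * vol
  }
  out
}

detector_registry <- c("log", "dog", "rl_peaks", "intensity")

#' Run candidate feature detectors on a frame
#'
#' Classical, identity-blind detectors whose responses feed the trainable
#' combiner ([train_selector()]):
#' * `log` — scale-normalized Laplacian-of-Gaussian (fixed sigma set
#'   1, 1.5, 2 px; maximum response over scales, sign-flipped so bright
#'   blobs are positive),
#' * `dog` — difference of Gaussians (sigma 1.5 vs 2.4 px),
#' * `rl_peaks` — Richardson-Lucy deconvolution with a Gaussian PSF
#'   (sigma 1.5 px, 10 iterations), which concentrates blob mass at
#'   blob centers,
#' * `intensity` — percentile-normalized raw intensity (1st-99th).
#'
#' Each response map is rescaled to `[0, 1]` per frame. Detection runs on
#' the first channel.
#'
#' @param frame array `(C, Z, Y, X)` (or 3-D, treated as one channel).
#' @param detectors subset of `c("log", "dog", "rl_peaks", "intensity")`.
#' @return array `(n_det, Z, Y, X)` with attribute `detectors`.
#' @export
run_candidate_detectors <- function(frame, detectors = detector_registry) {
  unknown <- setdiff(detectors, detector_registry)
  if (length(unknown)) stop("unknown detector tag(s): ",
                            paste(unknown, collapse = ", "))
  if (length(dim(frame)) == 3L) dim(frame) <- c(1L, dim(frame))
  vol <- frame[1L, , , ]
  dim(vol) <- dim(frame)[2:4]
  out <- array(0, c(length(detectors), dim(vol)))
  for (k in seq_along(detectors)) {
    resp <- switch(detectors[k],
      intensity = {
        q <- stats::quantile(vol, c(0.01, 0.99), names = FALSE)
        if (q[2L] > q[1L]) pmin(1, pmax(0, (vol - q[1L]) / (q[2L] - q[1L])))
        else array(0, dim(vol))
      },
      log = {
        r <- array(-Inf, dim(vol))
        for (s in c(1, 1.5, 2))
          r <- pmax(r, -s^2 * laplacian3(gauss_blur3(vol, s)))
        rescale01(r)
      },
      dog = rescale01(gauss_blur3(vol, 1.5) - gauss_blur3(vol, 2.4)),
      rl_peaks = {
        eps <- 1e-8
        obs <- vol - min(vol) + eps
        u <- obs
        for (it in 1:10) {
          conv <- gauss_blur3(u, 1.5)
          u <- u * gauss_blur3(obs / pmax(conv, eps), 1.5)
        }
        rescale01(u)
      })
    out[k, , , ] <- resp
  }
  attr(out, "detectors") <- detectors
  out
}

# ---- small convolutional combiner ----------------------------------------
# Architecture: 1x1 convolution mixing the detector channels into
# `hidden` channels (ReLU), then one 3x3(x3) convolution to a single
# channel, then sigmoid.

shift3 <- function(vol, o) {
  # result[p] = vol[p + o], zero outside; o = (dz, dy, dx)
  d <- dim(vol)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    if (o[ax] >= 0) { dst[[ax]] <- seq_len(n - o[ax]); src[[ax]] <- seq_len(n - o[ax]) + o[ax] }
    else { dst[[ax]] <- seq_len(n + o[ax]) - o[ax]; src[[ax]] <- seq_len(n + o[ax]) }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- vol[src[[1L]], src[[2L]], src[[3L]]]
  out
}

conv_offsets <- function(shape) {
  kz <- if (shape[1L] > 1L) -1:1 else 0L
  as.matrix(expand.grid(dz = kz, dy = -1:1, dx = -1:1))
}

selector_init <- function(n_det, hidden = 4L, seed = 0L) {
  set.seed(seed)
  offs <- NULL
  list(w1 = matrix(stats::rnorm(hidden * n_det, sd = 0.5), hidden, n_det),
       b1 = stats::rnorm(hidden, sd = 0.1),
       w2 = NULL,  # filled on first forward (depends on 2D/3D kernel)
       b2 = 0,
       hidden = hidden, n_det = n_det, seed = seed)
}

selector_forward <- function(model, responses, keep = FALSE) {
  d <- dim(responses)
  shp <- d[2:4]
  x <- matrix(responses, d[1L])        # n_det x Nvox
  a <- model$w1 %*% x + model$b1       # hidden x Nvox
  h <- pmax(a, 0)
  offs <- conv_offsets(shp)
  if (is.null(model$w2)) {
    set.seed(model$seed + 1L)
    model$w2 <- matrix(stats::rnorm(model$hidden * nrow(offs),
                                    sd = 1 / sqrt(model$hidden * nrow(offs))),
                       model$hidden, nrow(offs))
  }
  s <- array(model$b2, shp)
  dims <- as.integer(shp)
  for (ci in seq_len(model$hidden)) {
    hc <- array(h[ci, ], shp)
    for (k in seq_len(nrow(offs)))
      cpp_shift_add(s, hc, dims, as.integer(offs[k, ]), model$w2[ci, k])
  }
  p <- 1 / (1 + exp(-s))
  if (!keep) return(list(model = model, prob = p))
  list(model = model, prob = p, x = x, a = a, h = h, offs = offs, s = s)
}

selector_backward <- function(model, fw, dmap_grad) {
  # dmap_grad: d Loss / d s  (pre-sigmoid), array (Z, Y, X)
  shp <- dim(dmap_grad)
  offs <- fw$offs
  dims <- as.integer(shp)
  g_w2 <- matrix(0, model$hidden, nrow(offs))
  dh <- matrix(0, prod(shp), model$hidden)
  for (ci in seq_len(model$hidden)) {
    hc <- array(fw$h[ci, ], shp)
    dci <- array(0, shp)
    for (k in seq_len(nrow(offs))) {
      o <- as.integer(offs[k, ])
      g_w2[ci, k] <- cpp_shift_dot(dmap_grad, hc, dims, o)
      cpp_shift_add(dci, dmap_grad, dims, -o, model$w2[ci, k])
    }
    dh[, ci] <- as.vector(dci)
  }
  g_b2 <- sum(dmap_grad)
  dhm <- t(dh)                               # hidden x Nvox
  da <- dhm * (fw$a > 0)
  g_w1 <- da %*% t(fw$x)
  g_b1 <- rowSums(da)
  list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
}

#' Train the model-selector combiner on a fully annotated frame
#'
#' The combiner (a 1x1 channel-mixing convolution, ReLU, one 3x3(x3)
#' convolution, sigmoid) learns to merge the candidate detector responses
#' into a single feature-probability map. The training target is a sum of
#' unit-height Gaussian bumps (width `target_sigma`) at the annotated
#' keypoint pixel positions, clipped to `[0, 1]`; the objective is mean
#' pixelwise binary cross-entropy, minimized by Adam. When one input
#' channel already matches the target well, training drives its effective
#' weight up and suppresses the others.
#'
#' @param responses detector response stack from
#'   [run_candidate_detectors()].
#' @param annotations annotation data.frame (one fully annotated frame)
#'   or an `n x 3` matrix of normalized keypoint positions.
#' @param target_sigma Gaussian bump width in pixels.
#' @param seed RNG seed for weight initialization.
#' @param n_epoch training iterations (0 returns the initialized model).
#' @param lr Adam learning rate.
#' @param hidden hidden channels in the mixing layer.
#' @param pos_weight weight of the positive (feature) class in the
#'   cross-entropy (features occupy a tiny fraction of the frame, so
#'   unweighted training leaves the map under-confident everywhere;
#'   `NULL` balances the classes exactly, which tends to over-detect).
#' @return a `selector_model` with fields `loss_curve` and `detectors`.
#' @export
train_selector <- function(responses, annotations, target_sigma = 2,
                           seed = 0L, n_epoch = 120L, lr = 0.05,
                           hidden = 4L, pos_weight = 2) {
  d <- dim(responses)
  shp <- d[2:4]
  pos <- if (is.data.frame(annotations))
    as.matrix(annotations[c("x", "y", "z")]) else as_coord_matrix(annotations)
  if (nrow(pos) == 0L) stop("at least one annotated keypoint is required")
  target <- detection_target(pos, shp, target_sigma)
  model <- selector_init(d[1L], hidden = hidden, seed = seed)
  n_vox <- prod(shp)
  if (is.null(pos_weight)) {
    s_pos <- sum(target)
    pos_weight <- if (s_pos > 0) (n_vox - s_pos) / s_pos else 1
  }
  mstate <- NULL
  loss_curve <- numeric(0)
  for (ep in seq_len(max(n_epoch, 1L))) {
    fw <- selector_forward(model, responses, keep = TRUE)
    model <- fw$model
    p <- pmin(pmax(fw$prob, 1e-7), 1 - 1e-7)
    bce <- -mean(pos_weight * target * log(p) + (1 - target) * log(1 - p))
    loss_curve <- c(loss_curve, bce)
    if (n_epoch == 0L) break
    # d BCE / d s through the sigmoid, with the positive class upweighted
    ds <- ((1 - target) * fw$prob -
             pos_weight * target * (1 - fw$prob)) / n_vox
    gr <- selector_backward(model, fw, ds)
    if (is.null(mstate))
      mstate <- list(m = lapply(gr, function(g) g * 0),
                     v = lapply(gr, function(g) g * 0), t = 0)
    upd <- adam_update(gr, mstate, lr)
    mstate <- upd$state
    for (nm in names(gr)) model[[nm]] <- model[[nm]] - upd$step[[nm]]
    if (ep >= n_epoch) break
  }
  structure(
    list(w1 = model$w1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
         hidden = model$hidden, n_det = model$n_det, seed = model$seed,
         detectors = attr(responses, "detectors"),
         target_sigma = target_sigma, pos_weight = pos_weight,
         loss_curve = loss_curve),
    class = "selector_model")
}

# Target probability map: unit-height Gaussian bumps at annotation pixel
# positions, clipped to [0, 1].
detection_target <- function(pos_norm, shape, sigma) {
  px <- normalized_to_pixel(pos_norm, shape)
  tgt <- cpp_render_blobs(as.integer(shape), px, rep(1, nrow(px)),
                          c(sigma, sigma, sigma))
  pmin(tgt, 1)
}

#' Compute the feature-detection probability map for a frame
#'
#' Runs the model's detector list on the frame and applies the trained
#' combiner; output values lie in `(0, 1)`.
#'
#' @param frame array `(C, Z, Y, X)`.
#' @param model a `selector_model` from [train_selector()].
#' @param detectors detector tags; must match the list the model was
#'   trained with.
#' @return probability array `(Z, Y, X)` of class `detection_map`.
#' @export
detection_map <- function(frame, model, detectors = model$detectors) {
  if (!identical(as.character(detectors), as.character(model$detectors)))
    stop("detector list does not match the trained model")
  responses <- run_candidate_detectors(frame, detectors)
  fw <- selector_forward(model, responses)
  structure(fw$prob, class = c("detection_map", "array"))
}

#' Detection loss
#'
#' `sum_i (1 - C[rho_i])` where `C` is the detection probability map
#' interpolated multilinearly at each keypoint position: keypoints sitting
#' on detected features cost nothing, keypoints in empty space cost 1.
#'
#' @param dmap probability array `(Z, Y, X)`.
#' @param positions `n x 3` normalized keypoint coordinates.
#' @param grad if `TRUE`, also return the gradient with respect to the
#'   pixel-space positions (`n x 3`).
#' @return scalar loss, or list `(loss, grad_px)`.
#' @export
loss_detection <- function(dmap, positions, grad = FALSE) {
  shp <- dim(dmap)
  pos <- as_coord_matrix(positions)
  px <- normalized_to_pixel(pos, shp)
  res <- cpp_sample_multilinear(as.vector(unclass(dmap)), shp, px, 1L)
  l <- sum(1 - res$value)
  if (!grad) return(l)
  list(loss = l, grad_px = -res$grad)
}

#' Precision and recall of a detection map against known centers
#'
#' Peaks are local maxima of the map above probability 0.5, reduced by
#' non-maximum suppression at `match_radius`; peaks and true centers are
#' then greedily matched one-to-one (closest pairs first) within
#' `match_radius`.
#'
#' @param dmap probability array `(Z, Y, X)`.
#' @param true_centers `n x 3` normalized coordinates of true features.
#' @param match_radius matching radius in pixels.
#' @return named vector `c(precision, recall)`; precision is reported as
#'   0 when there are no peaks.
#' @export
detection_precision_recall <- function(dmap, true_centers, match_radius = 3) {
  shp <- dim(dmap)
  peaks <- find_peaks(unclass(dmap), threshold = 0.5, nms_radius = match_radius)
  truth_px <- normalized_to_pixel(as_coord_matrix(true_centers), shp)
  n_true <- nrow(truth_px)
  if (nrow(peaks) == 0L) return(c(precision = 0, recall = 0))
  dm <- outer(rowSums(peaks^2), rowSums(truth_px^2), "+") -
    2 * peaks %*% t(truth_px)
  dm <- sqrt(pmax(dm, 0))
  cand <- which(dm <= match_radius, arr.ind = TRUE)
  cand <- cand[order(dm[cand]), , drop = FALSE]
  used_p <- logical(nrow(peaks)); used_t <- logical(n_true)
  matched <- 0L
  for (r in seq_len(nrow(cand))) {
    pi <- cand[r, 1L]; ti <- cand[r, 2L]
    if (!used_p[pi] && !used_t[ti]) {
      used_p[pi] <- used_t[ti] <- TRUE
      matched <- matched + 1L
    }
  }
  c(precision = matched / nrow(peaks), recall = matched / n_true)
}

# Local maxima above threshold with greedy NMS; returns m x 3 pixel
# coordinates (x, y, z).
find_peaks <- function(vol, threshold = 0.5, nms_radius = 3) {
  d <- dim(vol)
  is_max <- vol > threshold
  offs <- conv_offsets(d)
  for (k in seq_len(nrow(offs))) {
    if (all(offs[k, ] == 0L)) next
    is_max <- is_max & vol >= shift3(vol, offs[k, ])
  }
  idx <- which(is_max, arr.ind = TRUE)     # (z, y, x) 1-based
  if (nrow(idx) == 0L) return(matrix(0, 0L, 3L))
  pts <- cbind(x = idx[, 3L] - 1, y = idx[, 2L] - 1, z = idx[, 1L] - 1)
  ord <- order(-vol[idx])
  pts <- pts[ord, , drop = FALSE]
  keep <- logical(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    if (r == 1L) { keep[1L] <- TRUE; next }
    kept <- pts[keep, , drop = FALSE]
    keep[r] <- all(sqrt(rowSums(sweep(kept, 2L, pts[r, ])^2)) > nms_radius)
  }
  pts[keep, , drop = FALSE]
}
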