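#' Loss-term weights
#'
#' Relative weights of the four loss terms: registration (`lambda_R`),
#' spring network (`lambda_N`), feature detection (`lambda_D`) and
#' temporal smoothness (`lambda_T`). All must be non-negative. An
#' optional schedule (list of `list(epoch_start =, weights =)` entries
#' with strictly increasing `epoch_start`) lets the weights change while
#' a single frame is being tracked.
#'
#' @param lambda_R,lambda_N,lambda_D,lambda_T non-negative scalars.
#' @param schedule optional per-epoch schedule, see above.
#' @return a `loss_weights` object.
#' @export
loss_weights <- function(lambda_R = 1, lambda_N = 0.1, lambda_D = 0.1,
                         lambda_T = 0, schedule = NULL) {
  w <- c(R = lambda_R, N = lambda_N, D = lambda_D, T = lambda_T)
  if (any(w < 0)) stop("loss weights must be non-negative")
  if (!is.null(schedule)) {
    starts <- vapply(schedule, function(s) s$epoch_start, numeric(1))
    if (any(diff(starts) <= 0)) stop("schedule epochs must be strictly increasing")
  }
  structure(list(w = w, schedule = schedule), class = "loss_weights")
}

weights_at <- function(weights, epoch) {
  w <- weights$w
  if (!is.null(weights$schedule)) {
    for (s in weights$schedule)
      if (epoch >= s$epoch_start) w <- s$weights$w
  }
  w
}

#' Tracking configuration
#'
#' @param grid_shape `(d, h, w)` descriptor size in `(z, y, x)` pixels
#'   (odd in each axis); `d` is reduced to 1 automatically for 2D videos.
#' @param n_epoch optimization epochs per frame.
#' @param lr base learning rate in pixels (Adam step scale).
#' @param lr_floor,lr_ceil,dist_ref parent-child learning-rate scaling,
#'   see [lr_scale()]; `dist_ref = NULL` uses the 90th percentile of the
#'   plan's parent-child distances.
#' @param j_neighbors spring-network neighbors per keypoint.
#' @param blur_start,blur_stages foveation schedule: starting blur sigma
#'   (pixels) and number of equal resolution stages (the last stage is
#'   unblurred), see [blur_sigma()].
#' @param epsilon temporal patch half-width in frames.
#' @param sort_mode `"chronological"` or `"similarity"` branch sorting.
#' @param detectors detector tags used when `lambda_D > 0`.
#' @param thumbnail_size thumbnail size for the similarity matrix.
#' @param pad_policy descriptor sampling border policy.
#' @param reference_frames optional explicit 0-based reference frame ids;
#'   `NULL` infers them as the fully annotated frames.
#' @param n_epoch_refine epochs of the temporal refinement pass (run when
#'   `lambda_T > 0`).
#' @param selector_epochs,target_sigma detector-combiner training
#'   settings, see [train_selector()].
#' @param fovea_sigma in-plane width (pixels) of the Gaussian foveal
#'   weighting applied to the descriptor correlation during tracking, so
#'   the keypoint itself dominates over neighboring features inside the
#'   patch; `NULL` disables weighting.
#' @param lr_decay_floor final fraction of the learning rate (linear
#'   decay across epochs ends here, so late epochs make sub-pixel
#'   adjustments).
#' @param seed RNG seed (selector initialization).
#' @return a `tracking_config` object.
#' @export
tracking_config <- function(grid_shape = c(5L, 25L, 25L), n_epoch = 40L,
                            lr = 1.0, lr_floor = 0.3, lr_ceil = 1.5,
                            dist_ref = NULL, j_neighbors = 5L,
                            blur_start = 2, blur_stages = 4L,
                            epsilon = 2L,
                            sort_mode = c("chronological", "similarity"),
                            detectors = c("log", "dog", "intensity"),
                            thumbnail_size = c(32L, 32L),
                            pad_policy = c("border", "zero"),
                            reference_frames = NULL,
                            n_epoch_refine = 10L,
                            selector_epochs = 120L, target_sigma = 2,
                            fovea_sigma = 6,
                            seed = 0L, lr_decay_floor = 0.1) {
  stopifnot(n_epoch >= 1L, all(grid_shape %% 2L == 1L), lr > 0)
  structure(list(
    grid_shape = as.integer(grid_shape), n_epoch = as.integer(n_epoch),
    lr = lr, lr_floor = lr_floor, lr_ceil = lr_ceil, dist_ref = dist_ref,
    j_neighbors = as.integer(j_neighbors),
    blur_start = blur_start, blur_stages = as.integer(blur_stages),
    epsilon = as.integer(epsilon), sort_mode = match.arg(sort_mode),
    detectors = detectors, thumbnail_size = as.integer(thumbnail_size),
    pad_policy = match.arg(pad_policy),
    reference_frames = reference_frames,
    n_epoch_refine = as.integer(n_epoch_refine),
    selector_epochs = as.integer(selector_epochs),
    target_sigma = target_sigma, fovea_sigma = fovea_sigma,
    seed = as.integer(seed),
    lr_decay_floor = lr_decay_floor), class = "tracking_config")
}

#' Initialize a child frame from its parent
#'
#' Without annotations every keypoint starts at its parent coordinates.
#' With partial manual annotations, the annotated keypoints are pinned at
#' their annotations and the displacements between those annotations and
#' the same keypoints' parent coordinates are interpolated into a flow
#' field that displaces the remaining keypoints' initializations.
#'
#' @param parent_pos `n x 3` matrix of the parent frame's tracked
#'   positions, rows ordered by worldline; `rownames` are worldline ids.
#' @param child_annotations annotation rows for the child frame (may be
#'   empty).
#' @return list with `theta` (`n x 3` initial positions) and `pinned`
#'   (logical per keypoint).
#' @export
initialize_child <- function(parent_pos, child_annotations = NULL) {
  theta <- as_coord_matrix(parent_pos)
  rownames(theta) <- rownames(parent_pos)
  n <- nrow(theta)
  pinned <- rep(FALSE, n)
  if (!is.null(child_annotations) && nrow(child_annotations) > 0L) {
    ids <- rownames(theta)
    sel <- match(as.character(child_annotations$worldline_id), ids)
    if (anyNA(sel)) stop("child annotation for unknown worldline id")
    ann_pos <- as.matrix(child_annotations[c("x", "y", "z")])
    field <- interpolate_flow(theta[sel, , drop = FALSE], ann_pos)
    theta <- apply_flow(field, theta)
    theta[sel, ] <- ann_pos
    pinned[sel] <- TRUE
    rownames(theta) <- ids
  }
  list(theta = theta, pinned = pinned)
}

# Reference descriptor cache: raw descriptors sampled once, blurred per
# foveation stage on demand.
ref_descriptor_cache <- function(video, ref_t, ref_pos, offsets, grid_shape,
                                 pad) {
  frame <- get_frame(video, ref_t)
  centers_px <- normalized_to_pixel(ref_pos, video_shape(video))
  raw <- sample_descriptor_batch(frame, centers_px, offsets, pad)$values
  cache <- new.env(parent = emptyenv())
  g_n <- prod(grid_shape)
  function(sigma) {
    key <- sprintf("s%.6f", sigma)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- raw
    if (sigma > 0) {
      mats <- lapply(grid_shape, blur_matrix, sigma = sigma)
      n_ch <- nrow(raw) / g_n
      for (ci in seq_len(n_ch)) {
        sl <- (ci - 1L) * g_n + seq_len(g_n)
        a <- array(raw[sl, ], c(grid_shape, ncol(raw)))
        out[sl, ] <- matrix(blur_stack(a, mats), g_n)
      }
    }
    cache[[key]] <- out
    out
  }
}

#' Track one child frame against a reference
#'
#' Runs `n_epoch` first-order optimization steps on the unpinned keypoint
#' positions. Each epoch: compute the foveation blur for the stage,
#' sample (and blur) child descriptors at the current positions, evaluate
#' the weighted loss `lambda_R L_R + lambda_N L_N + lambda_D L_D`
#' (plus `lambda_T L_T` when temporal context is supplied), and take one
#' Adam step scaled by the parent-child learning-rate factor with a
#' linear epoch decay. Pinned keypoints never move but still exert spring
#' forces on their neighbors.
#'
#' @param video a `video_store`.
#' @param child_t 0-based frame to track.
#' @param theta0 `n x 3` initial normalized positions.
#' @param pinned logical per keypoint; pinned rows are never updated.
#' @param ref_desc reference descriptor provider from the internal cache
#'   (a function `sigma -> matrix`), or `NULL` when `lambda_R = 0`.
#' @param network `spring_network` for the frame's reference (or `NULL`).
#' @param dmap detection probability map for this frame (or `NULL`).
#' @param config a `tracking_config`.
#' @param weights a `loss_weights`.
#' @param lr_scale_t learning-rate scale for this frame.
#' @param temporal_ctx optional list(`positions_patch`, `channel`) for
#'   the temporal term (refinement pass).
#' @return list with `positions` (`n x 3` normalized), `diagnostics`
#'   (final loss terms), and `loss_trace` (total weighted loss per
#'   epoch).
#' @export
track_frame <- function(video, child_t, theta0, pinned = NULL,
                        ref_desc = NULL, network = NULL, dmap = NULL,
                        config = tracking_config(),
                        weights = loss_weights(), lr_scale_t = 1,
                        temporal_ctx = NULL) {
  shp <- video_shape(video)
  gs <- config$grid_shape
  if (shp[1L] == 1L) gs[1L] <- 1L
  offsets <- grid_offsets(gs)
  fov <- fovea_weights(offsets, gs, config$fovea_sigma)
  pad <- if (config$pad_policy == "border") 1L else 0L
  frame <- get_frame(video, child_t)
  theta_px <- normalized_to_pixel(theta0, shp)
  n <- nrow(theta_px)
  if (is.null(pinned)) pinned <- rep(FALSE, n)
  scale_px <- norm_scale(shp)          # pixels per normalized unit
  inv_scale <- ifelse(scale_px > 0, 1 / scale_px, 0)
  n_epoch <- config$n_epoch
  state <- NULL
  loss_trace <- numeric(n_epoch)
  diag_terms <- c(R = 0, N = 0, D = 0, T = 0)
  for (ep in seq_len(n_epoch) - 1L) {
    w <- weights_at(weights, ep)
    sigma <- blur_sigma(ep, c(config$blur_start, config$blur_stages, n_epoch))
    grad_px <- matrix(0, n, 3L)
    terms <- c(R = 0, N = 0, D = 0, T = 0)
    if (w["R"] > 0 && !is.null(ref_desc)) {
      reg <- registration_term_fast(frame, theta_px, ref_desc(sigma),
                                    offsets, gs, sigma, pad, fov)
      terms["R"] <- reg$loss
      grad_px <- grad_px + w["R"] * reg$grad_px
    }
    if (w["N"] > 0 && !is.null(network)) {
      pos_norm <- pixel_to_normalized(theta_px, shp)
      sp <- loss_spring(pos_norm, network, grad = TRUE)
      terms["N"] <- sp$loss
      grad_px <- grad_px + w["N"] * sweep(sp$grad, 2L, inv_scale, "*")
    }
    if (w["D"] > 0 && !is.null(dmap)) {
      det <- loss_detection(dmap, pixel_to_normalized(theta_px, shp),
                            grad = TRUE)
      terms["D"] <- det$loss
      grad_px <- grad_px + w["D"] * det$grad_px
    }
    if (w["T"] > 0 && !is.null(temporal_ctx)) {
      patch <- temporal_ctx$positions_patch
      patch[[as.character(child_t)]] <- pixel_to_normalized(theta_px, shp)
      tmp <- loss_temporal(video, patch, child_t, config$epsilon,
                           channel = temporal_ctx$channel %||% 1L,
                           grad = TRUE)
      terms["T"] <- tmp$loss
      grad_px <- grad_px + w["T"] * tmp$grad_px
    }
    total <- sum(w * terms)
    if (!is.finite(total))
      stop("non-finite loss while tracking frame ", child_t,
           " (epoch ", ep, ")")
    loss_trace[ep + 1L] <- total
    diag_terms <- terms
    if (is.null(state)) state <- adam_row_state(n)
    decay <- if (n_epoch > 1L)
      1 - (1 - config$lr_decay_floor) * ep / (n_epoch - 1L) else 1
    upd <- adam_row_update(grad_px, state,
                           lr = config$lr * lr_scale_t * decay)
    state <- upd$state
    step <- upd$step
    step[pinned, ] <- 0
    # a keypoint whose gradient norm is at convergence level stays put:
    # Adam's normalized steps would otherwise turn numerical noise into
    # full-size displacements
    step[rowSums(grad_px^2) < 1e-12, ] <- 0
    theta_px <- theta_px - step
  }
  out <- pixel_to_normalized(theta_px, shp)
  rownames(out) <- rownames(theta0)
  list(positions = out, diagnostics = as.list(diag_terms),
       loss_trace = loss_trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Track all frames of a video
#'
#' The full tracking loop: compute the thumbnail similarity matrix, sort
#' frames into parent-child branches rooted at the reference frames,
#' build a spring network on each reference (stiffened by cross-reference
#' covariance when at least two references exist), optionally train the
#' feature-detection combiner on the first reference and compute a
#' detection map per frame, then track every frame in queue order — each
#' child initialized from its parent (through a flow field when the child
#' carries partial manual annotations, which stay pinned) and registered
#' against its branch's reference. When `lambda_T > 0` a refinement pass
#' re-optimizes each frame with the temporal term after its neighbors
#' have been tracked.
#'
#' @param video a `video_store`.
#' @param annotations annotation table: the reference frames must be
#'   fully annotated (every worldline present); any other annotated
#'   frame contributes pinned partial annotations.
#' @param config a `tracking_config`; `config$reference_frames` may name
#'   the references explicitly (0-based), otherwise every fully annotated
#'   frame is a reference.
#' @param weights a `loss_weights`.
#' @return a `tracking_result`: list with `coords` (data.frame
#'   `t, worldline_id, x, y, z, provenance` covering every frame and
#'   worldline; input annotations pass through unchanged), `frames`
#'   (per-frame diagnostics: parent, reference, learning-rate scale,
#'   final loss terms, fraction of epochs with non-increasing loss),
#'   `plan`, `networks`, `selector`, `config`, `weights`.
#' @export
track_all <- function(video, annotations, config = tracking_config(),
                      weights = loss_weights()) {
  ann <- validate_annotations(annotations)
  set.seed(config$seed)
  shp <- video_shape(video)
  t_n <- n_frames(video)
  wl_ids <- sort(unique(ann$worldline_id))
  n <- length(wl_ids)
  if (n == 0L) stop("no annotations supplied")
  counts <- table(factor(ann$t, levels = as.character(seq_len(t_n) - 1L)))

  refs <- config$reference_frames
  if (is.null(refs)) {
    refs <- as.integer(names(counts))[counts == n]
  } else {
    refs <- as.integer(refs)
    for (r in refs) {
      have <- ann$worldline_id[ann$t == r]
      miss <- setdiff(wl_ids, have)
      if (length(miss))
        stop("reference frame ", r, " is missing worldline id(s): ",
             paste(miss, collapse = ", "))
    }
  }
  if (length(refs) == 0L)
    stop("no fully annotated reference frame found")

  ann_pos <- function(t) {
    rows <- ann[ann$t == t, ]
    m <- as.matrix(rows[match(wl_ids, rows$worldline_id), c("x", "y", "z")])
    rownames(m) <- wl_ids
    m
  }

  simmat <- similarity_matrix(video, config$thumbnail_size)
  plan <- build_branches(simmat, refs, config$sort_mode)
  dist_ref <- config$dist_ref
  if (is.null(dist_ref)) {
    dd <- plan$dist[!is.na(plan$dist) & plan$dist > 1e-9]
    dist_ref <- if (length(dd)) stats::quantile(dd, 0.9, names = FALSE) else 1
  }

  # spring networks per reference, covariance-stiffened across references
  nets <- list()
  for (r in refs) nets[[as.character(r)]] <-
    build_network(ann_pos(r), config$j_neighbors)
  if (length(refs) >= 2L) {
    pr <- array(0, c(length(refs), n, 3L))
    for (i in seq_along(refs)) pr[i, , ] <- ann_pos(refs[i])
    nets <- lapply(nets, function(nw) stiffness_from_covariance(pr, nw))
  }

  # detection maps (identity-blind), one combiner trained on a reference
  selector <- NULL
  dmaps <- NULL
  if (weights$w["D"] > 0) {
    r0 <- refs[1L]
    responses <- run_candidate_detectors(get_frame(video, r0),
                                         config$detectors)
    selector <- train_selector(responses, ann_pos(r0),
                               target_sigma = config$target_sigma,
                               seed = config$seed,
                               n_epoch = config$selector_epochs)
    dmaps <- vector("list", t_n)
  }
  get_dmap <- function(t) {
    if (is.null(selector)) return(NULL)
    if (is.null(dmaps[[t + 1L]]))
      dmaps[[t + 1L]] <<- detection_map(get_frame(video, t), selector)
    dmaps[[t + 1L]]
  }

  gs <- config$grid_shape
  if (shp[1L] == 1L) gs[1L] <- 1L
  offsets <- grid_offsets(gs)
  pad <- if (config$pad_policy == "border") 1L else 0L
  ref_caches <- list()
  for (r in refs) ref_caches[[as.character(r)]] <-
    ref_descriptor_cache(video, r, ann_pos(r), offsets, gs, pad)

  results <- vector("list", t_n)   # n x 3 normalized positions per frame
  prov <- vector("list", t_n)
  fdiag <- vector("list", t_n)
  for (r in refs) {
    rows <- ann[ann$t == r, ]
    results[[r + 1L]] <- ann_pos(r)
    prov[[r + 1L]] <- rows$provenance[match(wl_ids, rows$worldline_id)]
    fdiag[[r + 1L]] <- data.frame(
      t = r, parent_id = NA_integer_, reference_id = r, lr_scale = NA_real_,
      loss_R = NA_real_, loss_N = NA_real_, loss_D = NA_real_,
      loss_T = NA_real_, frac_nonincreasing = NA_real_)
  }

  children <- plan[!is.na(plan$parent_id), , drop = FALSE]
  for (qi in seq_len(nrow(children))) {
    ct <- children$t[qi]
    pt <- children$parent_id[qi]
    rt <- children$reference_id[qi]
    lsc <- lr_scale(children$dist[qi], config$lr_floor, config$lr_ceil,
                    dist_ref)
    child_ann <- ann[ann$t == ct & ann$provenance != "tracked", ]
    init <- initialize_child(results[[pt + 1L]], child_ann)
    tr <- track_frame(video, ct, init$theta, init$pinned,
                      ref_desc = ref_caches[[as.character(rt)]],
                      network = nets[[as.character(rt)]],
                      dmap = get_dmap(ct),
                      config = config, weights = weights,
                      lr_scale_t = lsc)
    pos <- tr$positions
    pv <- rep("tracked", n)
    if (nrow(child_ann)) {
      sel <- match(as.character(child_ann$worldline_id), rownames(pos))
      pos[sel, ] <- as.matrix(child_ann[c("x", "y", "z")])
      pv[sel] <- child_ann$provenance
    }
    results[[ct + 1L]] <- pos
    prov[[ct + 1L]] <- pv
    lt <- tr$loss_trace
    fdiag[[ct + 1L]] <- data.frame(
      t = ct, parent_id = pt, reference_id = rt, lr_scale = lsc,
      loss_R = tr$diagnostics$R, loss_N = tr$diagnostics$N,
      loss_D = tr$diagnostics$D, loss_T = tr$diagnostics$T,
      frac_nonincreasing = if (length(lt) > 1L)
        mean(diff(lt) <= 1e-9) else 1)
  }

  # temporal refinement pass
  if (weights$w["T"] > 0) {
    ref_w <- weights
    for (qi in seq_len(nrow(children))) {
      ct <- children$t[qi]
      rt <- children$reference_id[qi]
      patch_ts <- intersect(seq(ct - config$epsilon, ct + config$epsilon),
                            seq_len(t_n) - 1L)
      patch <- stats::setNames(
        lapply(patch_ts, function(t) results[[t + 1L]]),
        as.character(patch_ts))
      cfg2 <- config
      cfg2$n_epoch <- config$n_epoch_refine
      cfg2$blur_start <- 0
      pin2 <- prov[[ct + 1L]] != "tracked"
      tr <- track_frame(video, ct, results[[ct + 1L]], pin2,
                        ref_desc = ref_caches[[as.character(rt)]],
                        network = nets[[as.character(rt)]],
                        dmap = get_dmap(ct),
                        config = cfg2, weights = ref_w,
                        lr_scale_t = fdiag[[ct + 1L]]$lr_scale %||% 1,
                        temporal_ctx = list(positions_patch = patch))
      results[[ct + 1L]][!pin2, ] <- tr$positions[!pin2, ]
      fdiag[[ct + 1L]]$loss_T <- tr$diagnostics$T
    }
  }

  coords <- do.call(rbind, lapply(seq_len(t_n) - 1L, function(t) {
    data.frame(t = t, worldline_id = wl_ids,
               x = results[[t + 1L]][, 1L], y = results[[t + 1L]][, 2L],
               z = results[[t + 1L]][, 3L], provenance = prov[[t + 1L]])
  }))
  rownames(coords) <- NULL
  structure(
    list(coords = coords, frames = do.call(rbind, fdiag), plan = plan,
         networks = nets, selector = selector, simmat = simmat,
         references = refs, config = config, weights = weights),
    class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result: %d frames, %d worldlines, refs {%s}>\n",
              length(unique(x$coords$t)),
              length(unique(x$coords$worldline_id)),
              paste(x$references, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.tracking_result <- function(x, ...) x$coords
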