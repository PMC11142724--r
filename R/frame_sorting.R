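#' Make a standardized low-resolution thumbnail of a frame
#'
#' Channels and z slices are collapsed by maximum projection, the in-plane
#' image is area-downsampled by block averaging to `target_size`, and the
#' result is standardized to zero mean and unit variance (an all-constant
#' image becomes all zeros). Thumbnails are the working representation for
#' frame-to-frame similarity.
#'
#' @param frame array `(C, Z, Y, X)` (or `(Z, Y, X)` / `(Y, X)`).
#' @param target_size `(y, x)` thumbnail size in pixels; must not exceed
#'   the in-plane frame size.
#' @return `target_size` matrix, standardized.
#' @export
make_thumbnail <- function(frame, target_size = c(32L, 32L)) {
  d <- dim(frame)
  if (length(d) == 2L) dim(frame) <- c(1L, 1L, d)
  if (length(dim(frame)) == 3L) dim(frame) <- c(1L, dim(frame))
  d <- dim(frame)
  proj <- apply(frame, c(3L, 4L), max)  # max over channel and z
  ty <- as.integer(target_size[1L]); tx <- as.integer(target_size[2L])
  if (ty > d[3L] || tx > d[4L]) stop("target_size exceeds frame size")
  if (ty < d[3L] || tx < d[4L]) {
    # block-average: source row/col i goes to bin floor(i * t / n)
    by <- floor((seq_len(d[3L]) - 1L) * ty / d[3L]) + 1L
    bx <- floor((seq_len(d[4L]) - 1L) * tx / d[4L]) + 1L
    sums <- rowsum(proj, by)                 # ty x X
    sums <- t(rowsum(t(sums), bx))           # ty x tx
    cnt <- outer(tabulate(by, ty), tabulate(bx, tx))
    proj <- sums / cnt
  }
  s <- stats::sd(as.vector(proj))
  if (!is.finite(s) || s == 0) return(matrix(0, ty, tx))
  (proj - mean(proj)) / s
}

#' Pairwise frame similarity-distance matrix
#'
#' `D[a, b] = 1 - r(a, b)` where `r` is the Pearson correlation between
#' the thumbnails of frames `a` and `b`; a zero-variance thumbnail has
#' correlation defined as 0 (distance 1) against any other frame.
#'
#' @param video a `video_store` with at least 2 frames.
#' @param target_size thumbnail size, see [make_thumbnail()].
#' @return symmetric `T x T` matrix with zero diagonal, values in
#'   `[0, 2]`, of class `similarity_matrix`.
#' @export
similarity_matrix <- function(video, target_size = c(32L, 32L)) {
  t_n <- n_frames(video)
  stopifnot(t_n >= 2L)
  ts <- pmin(as.integer(target_size),
             c(video$shape[2L], video$shape[3L]))
  thumbs <- vapply(seq_len(t_n) - 1L,
                   function(t) as.vector(make_thumbnail(get_frame(video, t), ts)),
                   numeric(prod(ts)))
  ctr <- sweep(thumbs, 2L, colMeans(thumbs))
  nrm <- sqrt(colSums(ctr^2))
  unit <- sweep(ctr, 2L, ifelse(nrm > 0, nrm, 1), "/")
  r <- crossprod(unit)
  r[nrm == 0, ] <- 0
  r[, nrm == 0] <- 0
  d <- 1 - r
  diag(d) <- 0
  d <- pmin(pmax((d + t(d)) / 2, 0), 2)
  structure(d, class = c("similarity_matrix", "matrix", "array"))
}

#' Recommend reference frames by k-medoids clustering
#'
#' PAM-style k-medoids on the frame similarity-distance matrix: a greedy
#' build phase (each new medoid is the frame that most reduces the score)
#' followed by best-improvement swaps. The score is the mean distance of
#' every frame to its nearest medoid, so the recommended frames are the
#' median exemplars of the movie's recurring postures. Ties break toward
#' the lower frame index; the procedure is deterministic.
#'
#' @param simmat `T x T` distance matrix from [similarity_matrix()].
#' @param k number of reference frames, `1 <= k <= T`.
#' @param seed accepted for interface stability; the algorithm is fully
#'   deterministic and does not consume randomness.
#' @return list with `references` (0-based frame ids, ascending), `score`
#'   (mean nearest-medoid distance), and `score_trace` (score after the
#'   build phase and after each accepted swap; non-increasing).
#' @export
recommend_references <- function(simmat, k, seed = NULL) {
  d <- unclass(simmat)
  t_n <- nrow(d)
  k <- as.integer(k)
  if (k < 1L || k > t_n) stop("k must be in [1, T]")
  score_of <- function(med) mean(apply(d[, med, drop = FALSE], 1L, min))
  # build
  med <- which.min(colSums(d))
  while (length(med) < k) {
    cand <- setdiff(seq_len(t_n), med)
    sc <- vapply(cand, function(h) score_of(c(med, h)), numeric(1))
    med <- c(med, cand[which.min(sc)])
  }
  trace <- score_of(med)
  # swap
  repeat {
    best <- list(gain = 0)
    cur <- trace[length(trace)]
    for (m_i in seq_along(med)) {
      for (h in setdiff(seq_len(t_n), med)) {
        trial <- med; trial[m_i] <- h
        sc <- score_of(trial)
        if (cur - sc > best$gain + 1e-15) best <- list(gain = cur - sc, med = trial, sc = sc)
      }
    }
    if (best$gain <= 0) break
    med <- best$med
    trace <- c(trace, best$sc)
  }
  list(references = sort(med) - 1L, score = trace[length(trace)],
       score_trace = trace)
}

#' Sort frames into parent-child tracking branches
#'
#' Builds the ordered queue of frames to track. Each branch is rooted at a
#' reference frame; every non-reference frame gets a parent (whose tracked
#' result initializes it) and a reference (its registration target).
#'
#' Modes:
#' * `"chronological"`: each reference spawns forward and backward chains
#'   (`r -> r+1 -> r+2 ...` and `r -> r-1 ...`) until the sequence ends or
#'   another reference's territory begins; a frame belongs to the
#'   reference closest in time (ties to the earlier reference).
#' * `"similarity"`: greedy growth — repeatedly attach the unassigned
#'   frame with the smallest similarity distance to any already-assigned
#'   frame, which becomes its parent. Ties break toward the lower frame
#'   index. This naturally clusters similar frames around each reference.
#'
#' @param simmat distance matrix from [similarity_matrix()].
#' @param reference_ids 0-based ids of the (fully annotated) reference
#'   frames.
#' @param mode `"chronological"` or `"similarity"`.
#' @return a `branch_plan`: data.frame with one row per frame in queue
#'   order, columns `t`, `parent_id` (NA for references), `reference_id`
#'   (branch root), and `dist` (parent-child similarity distance).
#' @export
build_branches <- function(simmat, reference_ids,
                           mode = c("chronological", "similarity")) {
  mode <- match.arg(mode)
  d <- unclass(simmat)
  t_n <- nrow(d)
  refs <- sort(as.integer(reference_ids))
  if (length(refs) == 0L) stop("reference_ids must be non-empty")
  if (any(refs < 0L | refs >= t_n)) stop("reference id out of range [0, T)")

  rows <- data.frame(t = refs, parent_id = NA_integer_,
                     reference_id = refs, dist = NA_real_)
  if (mode == "chronological") {
    others <- setdiff(seq_len(t_n) - 1L, refs)
    if (length(others)) {
      near <- vapply(others, function(t) refs[which.min(abs(t - refs))],
                     integer(1))
      parent <- ifelse(others > near, others - 1L, others + 1L)
      ord <- order(abs(others - near), others)
      rows <- rbind(rows, data.frame(
        t = others, parent_id = parent, reference_id = near,
        dist = d[cbind(others + 1L, parent + 1L)])[ord, ])
    }
  } else {
    assigned <- refs
    root <- stats::setNames(refs, refs)
    todo <- setdiff(seq_len(t_n) - 1L, refs)
    while (length(todo)) {
      sub <- d[todo + 1L, assigned + 1L, drop = FALSE]
      j <- which(sub == min(sub), arr.ind = TRUE)
      # ties: lowest child frame index, then lowest parent frame index
      j <- j[order(todo[j[, 1L]], assigned[j[, 2L]]), , drop = FALSE][1L, ]
      child <- todo[j[1L]]; parent <- assigned[j[2L]]
      rows <- rbind(rows, data.frame(
        t = child, parent_id = parent,
        reference_id = unname(root[as.character(parent)]),
        dist = d[child + 1L, parent + 1L]))
      root[as.character(child)] <- root[as.character(parent)]
      assigned <- c(assigned, child)
      todo <- setdiff(todo, child)
    }
  }
  rownames(rows) <- NULL
  structure(rows, class = c("branch_plan", "data.frame"), mode = mode)
}

#' Parent-child distance to learning-rate scale
#'
#' Clamped linear map: a child nearly identical to its parent gets the
#' floor learning rate (keypoints are expected close to their initialized
#' positions), a dissimilar pair saturates at the ceiling so keypoints can
#' travel farther.
#'
#' @param d parent-child similarity distance(s), `>= 0`.
#' @param lr_floor,lr_ceil learning-rate multipliers at `d = 0` and at
#'   saturation; `0 <= lr_floor <= lr_ceil`.
#' @param dist_ref distance at which the scale saturates (`> 0`).
#' @return `lr_floor + (lr_ceil - lr_floor) * min(1, d / dist_ref)`.
#' @export
lr_scale <- function(d, lr_floor = 0.5, lr_ceil = 1.5, dist_ref = 1) {
  stopifnot(lr_floor >= 0, lr_ceil >= lr_floor, dist_ref > 0)
  lr_floor + (lr_ceil - lr_floor) * pmin(1, d / dist_ref)
}

#' Serialize a branch plan to JSON
#' @param plan a `branch_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_branch_plan <- function(plan, path) {
  jsonlite::write_json(
    list(mode = attr(plan, "mode"), queue = as.data.frame(plan)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
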