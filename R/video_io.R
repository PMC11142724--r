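#' Create a video store from an in-memory array
#'
#' A `video_store` is the frame container shared by all tracking
#' functions: `T` frames of identical shape `(C, Z, Y, X)`, accessed one
#' frame at a time via [get_frame()].
#'
#' @param data 5-D numeric array `(T, C, Z, Y, X)`, or 4-D `(T, Z, Y, X)`
#'   (single channel), or 3-D `(T, Y, X)` (single channel, 2D video).
#' @return a `video_store` object with fields `n_frames`, `n_channels`,
#'   and `shape` (`(Z, Y, X)` in pixels).
#' @export
video_store <- function(data) {
  d <- dim(data)
  if (is.null(d) || length(d) < 3L || length(d) > 5L)
    stop("data must be a 3-D, 4-D or 5-D array")
  if (length(d) == 3L) dim(data) <- c(d[1L], 1L, 1L, d[2L], d[3L])
  if (length(d) == 4L) dim(data) <- c(d[1L], 1L, d[2L], d[3L], d[4L])
  d <- dim(data)
  structure(
    list(backend = "array", data = data,
         n_frames = d[1L], n_channels = d[2L], shape = d[3:5]),
    class = "video_store")
}

#' Number of frames, channels and frame shape of a video
#' @param video a `video_store`.
#' @return `n_frames()`: integer count. `video_shape()`: integer
#'   `(Z, Y, X)`.
#' @export
n_frames <- function(video) video$n_frames

#' @rdname n_frames
#' @export
video_shape <- function(video) video$shape

#' Extract one frame from a video store
#'
#' @param video a `video_store`.
#' @param t 0-based frame index, `0 <= t < n_frames`.
#' @return numeric array `(C, Z, Y, X)`.
#' @export
get_frame <- function(video, t) {
  stopifnot(length(t) == 1L, t >= 0, t < video$n_frames)
  if (video$backend == "array") {
    fr <- video$data[t + 1L, , , , , drop = FALSE]
    dim(fr) <- dim(video$data)[-1L]
    return(fr)
  }
  # tiff backend: pages are stored in the order given by the layout tag
  idx <- video$page_index[[t + 1L]]
  pages <- tiff::readTIFF(video$path, all = idx)
  if (!is.list(pages)) pages <- list(pages)
  fr <- array(0, c(video$n_channels, video$shape))
  p <- 1L
  for (ci in seq_len(video$n_channels)) for (zi in seq_len(video$shape[1L])) {
    pg <- pages[[p]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # greyscale stored per page
    fr[ci, zi, , ] <- pg
    p <- p + 1L
  }
  fr
}

#' Load a multi-page TIFF video
#'
#' Pages must enumerate `T x C x Z` planes of constant `(Y, X)` shape; the
#' layout tag states the loop order (first letter outermost): `"TCZ"`
#' (frame, then channel, then slice), `"TZ"` (single channel) or `"ZT"`
#' (single channel, slice-major). Frame shape is read from the page
#' headers without decoding pixel data; frames are decoded on access.
#'
#' @param path path to a multi-page TIFF file.
#' @param layout one of `"TCZ"`, `"TZ"`, `"ZT"`.
#' @param n_z number of z slices per volume.
#' @param n_channels number of channels (layout `"TCZ"` only).
#' @return a `video_store`.
#' @export
load_video <- function(path, layout = c("TCZ", "TZ", "ZT"), n_z = 1L,
                       n_channels = 1L) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("cannot read video file: ", path)
  info <- tryCatch(tiff::readTIFF(path, all = TRUE, payload = FALSE),
                   error = function(e) stop("not a readable TIFF: ", path))
  if (is.data.frame(info)) {
    n_pages <- nrow(info)
    ys <- info$length
    xs <- info$width
  } else {
    if (!is.null(info$width)) info <- list(info)
    n_pages <- length(info)
    ys <- vapply(info, function(p) p$length, numeric(1))
    xs <- vapply(info, function(p) p$width, numeric(1))
  }
  if (length(unique(ys)) != 1L || length(unique(xs)) != 1L)
    stop("inconsistent page shapes in ", path)
  if (layout != "TCZ") n_channels <- 1L
  per_frame <- n_z * n_channels
  if (n_pages %% per_frame != 0L)
    stop("page count ", n_pages, " not divisible by C*Z = ", per_frame)
  t_n <- n_pages %/% per_frame
  # page indices for frame t, ordered (channel, z) to fill (C, Z, Y, X)
  page_index <- lapply(seq_len(t_n) - 1L, function(t) {
    switch(layout,
      TCZ = t * per_frame + seq_len(per_frame),
      TZ  = t * n_z + seq_len(n_z),
      ZT  = (seq_len(n_z) - 1L) * t_n + t + 1L)
  })
  structure(
    list(backend = "tiff", path = path, page_index = page_index,
         n_frames = t_n, n_channels = n_channels,
         shape = c(n_z, ys[1L], xs[1L])),
    class = "video_store")
}

#' Write a video to a multi-page TIFF
#'
#' Pages are written in `"TCZ"` order as 16-bit greyscale; intensities
#' must already lie in `[0, 1]`. Values on the 16-bit grid (multiples of
#' `1/65535`) round-trip exactly through [load_video()].
#'
#' @param video a `video_store` or an array accepted by [video_store()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  if (!inherits(video, "video_store")) video <- video_store(video)
  pages <- list()
  for (t in seq_len(video$n_frames) - 1L) {
    fr <- get_frame(video, t)
    for (ci in seq_len(video$n_channels)) for (zi in seq_len(video$shape[1L]))
      pages[[length(pages) + 1L]] <- fr[ci, zi, , ]
  }
  if (any(vapply(pages, function(p) any(p < 0 | p > 1), logical(1))))
    stop("write_video expects intensities in [0, 1]")
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @export
print.video_store <- function(x, ...) {
  cat(sprintf("<video_store: T=%d C=%d Z=%d Y=%d X=%d (%s)>\n",
              x$n_frames, x$n_channels, x$shape[1L], x$shape[2L],
              x$shape[3L], x$backend))
  invisible(x)
}

annotation_columns <- c("t", "worldline_id", "x", "y", "z", "provenance")
provenance_levels <- c("manual", "tracked", "verified")

#' Validate a keypoint annotation table
#'
#' Checks the shared annotation schema: columns
#' `t, worldline_id, x, y, z, provenance`, unique `(t, worldline_id)`
#' pairs, coordinates within `[-1 - tol, 1 + tol]` (tracked points may
#' drift slightly out of frame), and known provenance labels.
#'
#' @param ann data.frame of keypoint records.
#' @param tol coordinate overshoot tolerance beyond `[-1, 1]`.
#' @return the validated table (provenance filled with `"manual"` where
#'   missing), with rows ordered by `(t, worldline_id)`.
#' @export
validate_annotations <- function(ann, tol = 0.1) {
  if (is.null(ann$provenance)) ann$provenance <- "manual"
  miss <- setdiff(annotation_columns, names(ann))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  ann <- ann[annotation_columns]
  ann$t <- as.integer(ann$t)
  ann$worldline_id <- as.integer(ann$worldline_id)
  ann$provenance <- as.character(ann$provenance)
  ann$provenance[is.na(ann$provenance) | ann$provenance == ""] <- "manual"
  if (any(!ann$provenance %in% provenance_levels))
    stop("unknown provenance label(s): ",
         paste(setdiff(ann$provenance, provenance_levels), collapse = ", "))
  key <- paste(ann$t, ann$worldline_id)
  if (anyDuplicated(key))
    stop("duplicate (t, worldline_id) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  xyz <- as.matrix(ann[c("x", "y", "z")])
  if (any(!is.finite(xyz)) || any(abs(xyz) > 1 + tol))
    stop("coordinates outside [-1 - tol, 1 + tol]")
  ann <- ann[order(ann$t, ann$worldline_id), ]
  rownames(ann) <- NULL
  ann
}

#' Load a keypoint annotation table from CSV
#'
#' The CSV header is `t,worldline_id,x,y,z,provenance` (`provenance` may
#' be absent and defaults to `"manual"`). Frame indices are 0-based.
#'
#' @param path CSV file path.
#' @param tol forwarded to [validate_annotations()].
#' @return validated annotation data.frame.
#' @export
load_annotations <- function(path, tol = 0.1) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(ann, tol = tol)
}

#' Save a keypoint annotation table to CSV
#'
#' Coordinates are written with 17 significant digits so that doubles
#' round-trip exactly.
#'
#' @param ann annotation data.frame (validated before writing).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  out <- data.frame(
    t = ann$t, worldline_id = ann$worldline_id,
    x = sprintf("%.17g", ann$x), y = sprintf("%.17g", ann$y),
    z = sprintf("%.17g", ann$z), provenance = ann$provenance)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
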