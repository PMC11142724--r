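#' Build an elastic spring network from reference annotations
#'
#' Each keypoint is connected by directed edges to its `j_neighbors`
#' nearest neighbors (Euclidean distance in normalized coordinates) in
#' the reference configuration. Rest lengths are the reference pairwise
#' distances; stiffnesses start at 1.0 and may later be reweighted by
#' cross-reference covariance ([stiffness_from_covariance()]).
#'
#' @param ref_positions `n x 3` matrix of keypoint `(x, y, z)` positions
#'   in one reference frame (normalized coordinates), `n >= 2`.
#' @param j_neighbors neighbors per keypoint (capped at `n - 1`).
#' @return a `spring_network`: list with `edges` (`m x 2` matrix of
#'   1-based keypoint index pairs `(i, j)`), `k` (stiffness per edge),
#'   `d_ref` (rest length per edge), `n` (keypoint count).
#' @export
build_network <- function(ref_positions, j_neighbors = 5L) {
  pos <- as_coord_matrix(ref_positions)
  n <- nrow(pos)
  stopifnot(n >= 2L)
  j_neighbors <- min(as.integer(j_neighbors), n - 1L)
  dm <- as.matrix(stats::dist(pos))
  edges <- matrix(0L, n * j_neighbors, 2L)
  for (i in seq_len(n)) {
    d_i <- dm[i, ]
    d_i[i] <- Inf
    nb <- order(d_i)[seq_len(j_neighbors)]  # order() breaks ties by index
    if (any(d_i[nb] == 0))
      stop("coincident keypoints (zero distance) in reference positions")
    edges[(i - 1L) * j_neighbors + seq_len(j_neighbors), ] <- cbind(i, nb)
  }
  # rest lengths via the same norm expression loss_spring() uses, so a
  # configuration identical to the reference scores exactly zero
  dvec <- pos[edges[, 1L], , drop = FALSE] - pos[edges[, 2L], , drop = FALSE]
  structure(
    list(edges = edges, k = rep(1.0, nrow(edges)),
         d_ref = sqrt(rowSums(dvec^2)), n = n),
    class = "spring_network")
}

#' Reweight spring stiffnesses by cross-reference covariance
#'
#' With several fully annotated reference frames available, each edge's
#' stiffness becomes a correlation-like measure of how coherently its two
#' keypoints move across those frames: the per-axis sample covariance of
#' the two keypoints' centered displacements, averaged over axes and
#' normalized by the geometric mean of the two keypoints' displacement
#' variances. The result lies in `[-1, 1]`; negative values (keypoints
#' moving in opposition) are clipped to 0, cutting the connection, and a
#' keypoint with zero displacement variance keeps stiffness 1. With a
#' single reference, stiffnesses stay at 1.
#'
#' @param positions_over_refs array `(n_refs, n_keypoints, 3)` of
#'   normalized positions of every keypoint in every reference frame.
#' @param network a `spring_network`.
#' @return the network with updated `k`.
#' @export
stiffness_from_covariance <- function(positions_over_refs, network) {
  p <- positions_over_refs
  stopifnot(length(dim(p)) == 3L, dim(p)[2L] == network$n)
  n_refs <- dim(p)[1L]
  if (n_refs < 2L) return(network)
  ctr <- sweep(p, c(2L, 3L), apply(p, c(2L, 3L), mean))
  v <- apply(ctr^2, c(2L, 3L), sum) / (n_refs - 1L)   # n x 3 per-axis var
  v_bar <- rowMeans(v)
  k <- numeric(nrow(network$edges))
  for (e in seq_len(nrow(network$edges))) {
    i <- network$edges[e, 1L]; j <- network$edges[e, 2L]
    if (v_bar[i] == 0 || v_bar[j] == 0) { k[e] <- 1.0; next }
    cv <- mean(colSums(ctr[, i, ] * ctr[, j, , drop = TRUE]) / (n_refs - 1L))
    k[e] <- max(0, cv / sqrt(v_bar[i] * v_bar[j]))
  }
  network$k <- k
  network
}

#' Spring-network loss
#'
#' `sum_e k_e * |d_e(current) - d_e(rest)| / d_e(rest)` over all edges:
#' the stiffness-weighted relative change of every edge length. Zero when
#' the current configuration preserves all reference edge lengths, and
#' invariant under global rigid motion.
#'
#' @param positions `n x 3` matrix of current keypoint positions
#'   (normalized coordinates).
#' @param network a `spring_network` built on the same keypoints.
#' @param grad if `TRUE`, also return the gradient with respect to
#'   `positions`.
#' @return scalar loss, or (with `grad = TRUE`) list `(loss, grad)`.
#' @export
loss_spring <- function(positions, network, grad = FALSE) {
  pos <- as_coord_matrix(positions)
  stopifnot(nrow(pos) == network$n)
  i <- network$edges[, 1L]; j <- network$edges[, 2L]
  dvec <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
  d_c <- sqrt(rowSums(dvec^2))
  term <- network$k * abs(d_c - network$d_ref) / network$d_ref
  l <- sum(term)
  if (!grad) return(l)
  # d|d_c - d_r|/d pos_i = sign(d_c - d_r) * (pos_i - pos_j)/d_c
  coefs <- network$k * sign(d_c - network$d_ref) / network$d_ref
  coefs[d_c == 0] <- 0
  unit <- dvec / ifelse(d_c > 0, d_c, 1)
  g <- matrix(0, network$n, 3L)
  for (ax in 1:3) {
    contrib <- coefs * unit[, ax]
    si <- rowsum(contrib, i)
    sj <- rowsum(contrib, j)
    g[as.integer(rownames(si)), ax] <- si
    g[as.integer(rownames(sj)), ax] <-
      g[as.integer(rownames(sj)), ax] - sj
  }
  list(loss = l, grad = g)
}

#' Serialize a spring network to JSON
#' @param network a `spring_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(
    list(n = network$n,
         edges = data.frame(i = network$edges[, 1L] - 1L,
                            j = network$edges[, 2L] - 1L,
                            k = network$k, d_ref = network$d_ref)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
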