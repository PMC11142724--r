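# Independent brute-force oracles, written as plain loops so they share no
# code path with the package internals they check.

oracle_pearson <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  if (da == 0 || db == 0) return(0)
  num / sqrt(da * db)
}

oracle_loss_registration <- function(child, ref) {
  tot <- 0
  for (i in seq_along(child)) tot <- tot + 1 - oracle_pearson(child[[i]], ref[[i]])
  tot
}

oracle_loss_spring <- function(pos, network) {
  tot <- 0
  for (e in seq_len(nrow(network$edges))) {
    i <- network$edges[e, 1L]; j <- network$edges[e, 2L]
    dc <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    tot <- tot + network$k[e] * abs(dc - network$d_ref[e]) / network$d_ref[e]
  }
  tot
}

# trilinear interpolation of vol (Z, Y, X) at one pixel point (x, y, z),
# clamping out-of-range corner indices to the border
oracle_trilinear <- function(vol, p) {
  d <- dim(vol)
  sizes <- c(d[3L], d[2L], d[1L])          # (x, y, z)
  i0 <- numeric(3); fr <- numeric(3)
  for (ax in 1:3) {
    if (sizes[ax] == 1L) { i0[ax] <- 0; fr[ax] <- 0 }
    else { i0[ax] <- floor(p[ax]); fr[ax] <- p[ax] - i0[ax] }
  }
  acc <- 0
  for (cz in 0:(if (d[1L] > 1) 1 else 0))
    for (cy in 0:(if (d[2L] > 1) 1 else 0))
      for (cx in 0:(if (d[3L] > 1) 1 else 0)) {
        w <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr)[
          c(d[3L] > 1, d[2L] > 1, d[1L] > 1)])
        zi <- min(max(i0[3] + cz, 0), d[1L] - 1)
        yi <- min(max(i0[2] + cy, 0), d[2L] - 1)
        xi <- min(max(i0[1] + cx, 0), d[3L] - 1)
        acc <- acc + w * vol[zi + 1, yi + 1, xi + 1]
      }
  acc
}

oracle_loss_detection <- function(dmap, pos_norm) {
  shp <- dim(dmap)
  tot <- 0
  for (i in seq_len(nrow(pos_norm))) {
    p <- normalized_to_pixel(pos_norm[i, ], shp)
    tot <- tot + 1 - oracle_trilinear(dmap, as.vector(p))
  }
  tot
}

oracle_loss_temporal <- function(video, patch, center, eps, channel = 1L) {
  shp <- video_shape(video)
  tot <- 0
  pos_c <- patch[[as.character(center)]]
  fr_c <- get_frame(video, center)[channel, , , ]
  dim(fr_c) <- shp
  ts <- intersect(seq(center - eps, center + eps), seq_len(n_frames(video)) - 1L)
  ts <- setdiff(ts, center)
  for (t in ts) {
    fr_t <- get_frame(video, t)[channel, , , ]
    dim(fr_t) <- shp
    pos_t <- patch[[as.character(t)]]
    for (i in seq_len(nrow(pos_c))) {
      vt <- oracle_trilinear(fr_t, as.vector(normalized_to_pixel(pos_t[i, ], shp)))
      vc <- oracle_trilinear(fr_c, as.vector(normalized_to_pixel(pos_c[i, ], shp)))
      tot <- tot + abs(vt - vc)
    }
  }
  tot
}

# standalone thin-plate solve (kernel r^2 log r in 3D + linear polynomial)
oracle_tps <- function(ctrl, disp, query) {
  n <- nrow(ctrl)
  phi <- function(r2) if (r2 <= 0) 0 else 0.5 * r2 * log(r2)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- phi(sum((ctrl[i, ] - ctrl[j, ])^2))
  P <- cbind(1, ctrl)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  sol <- MASS::ginv(A) %*% rbind(disp, matrix(0, 4, 3))
  w <- sol[1:n, , drop = FALSE]; a <- sol[n + 1:4, , drop = FALSE]
  out <- matrix(0, nrow(query), 3)
  for (q in seq_len(nrow(query))) {
    v <- c(1, query[q, ]) %*% a
    for (i in 1:n) v <- v + w[i, ] * phi(sum((query[q, ] - ctrl[i, ])^2))
    out[q, ] <- v
  }
  out
}

# exhaustive k-medoids score minimum over all candidate subsets
oracle_best_medoids <- function(d, k) {
  t_n <- nrow(d)
  best <- NULL; best_score <- Inf
  for (sub in utils::combn(t_n, k, simplify = FALSE)) {
    sc <- mean(apply(d[, sub, drop = FALSE], 1, min))
    if (sc < best_score - 1e-12) { best_score <- sc; best <- sub }
  }
  list(medoids = best - 1L, score = best_score)
}

# central finite differences of f at x (a matrix), h per axis
fd_gradient <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    xp <- x; xp[i, j] <- xp[i, j] + h
    xm <- x; xm[i, j] <- xm[i, j] - h
    g[i, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
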