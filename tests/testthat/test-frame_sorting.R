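test_that("thumbnails standardize and area-downsample correctly", {
  expect_equal(make_thumbnail(array(7, c(1, 1, 16, 16)), c(8, 8)),
               matrix(0, 8, 8))
  # frame already at target size: standardized copy
  fr <- array(runif(12 * 12), c(1, 1, 12, 12))
  th <- make_thumbnail(fr, c(12, 12))
  img <- fr[1, 1, , ]
  expect_equal(th, (img - mean(img)) / sd(img), tolerance = 1e-12)
  # 16-px-period checkerboard 64x64 -> 8x8 equals explicit block averaging
  cb <- outer(seq_len(64), seq_len(64),
              function(i, j) ((i - 1) %/% 8 + (j - 1) %/% 8) %% 2)
  th2 <- make_thumbnail(array(cb, c(1, 1, 64, 64)), c(8, 8))
  blocks <- matrix(0, 8, 8)
  for (a in 1:8) for (b in 1:8)
    blocks[a, b] <- mean(cb[(a - 1) * 8 + 1:8, (b - 1) * 8 + 1:8])
  expect_equal(th2, (blocks - mean(blocks)) / sd(blocks),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(make_thumbnail(fr, c(20, 20)), "exceeds")
})

test_that("similarity matrix matches the direct Pearson formula", {
  set.seed(3)
  arr <- array(runif(5 * 1 * 1 * 16 * 16), c(5, 1, 1, 16, 16))
  arr[3, , , , ] <- arr[1, , , , ]       # duplicated frame pair
  arr[4, , , , ] <- -arr[1, , , , ] + 1  # intensity negation
  v <- video_store(arr)
  d <- similarity_matrix(v, c(16, 16))
  expect_equal(dim(d), c(5L, 5L))
  expect_equal(diag(unclass(d)), rep(0, 5))
  expect_equal(unclass(d), t(unclass(d)))
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(d[1, 3], 0, tolerance = 1e-12)
  expect_equal(d[1, 4], 2, tolerance = 1e-12)
  for (a in 1:5) for (b in 1:5) {
    ta <- make_thumbnail(get_frame(v, a - 1), c(16, 16))
    tb <- make_thumbnail(get_frame(v, b - 1), c(16, 16))
    ref <- if (a == b) 0 else 1 - oracle_pearson(ta, tb)
    expect_equal(d[a, b], ref, tolerance = 1e-6)
  }
})

test_that("k-medoids matches exhaustive search on a two-cluster toy", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(8, 0), 4), matrix(rnorm(8, 10), 4))
  d <- as.matrix(dist(pts))
  rec <- recommend_references(d, 2)
  oracle <- oracle_best_medoids(d, 2)
  expect_setequal(rec$references, oracle$medoids)
  expect_equal(rec$score, oracle$score, tolerance = 1e-12)
  expect_true(all(diff(rec$score_trace) <= 1e-12))
})

test_that("k-medoids degenerate cases and errors", {
  d0 <- matrix(0, 6, 6)
  expect_equal(recommend_references(d0, 2)$score, 0)
  set.seed(8)
  pts <- matrix(rnorm(16), 8)
  d <- as.matrix(dist(pts))
  expect_equal(recommend_references(d, 8)$score, 0)
  expect_error(recommend_references(d, 9), "k must be")
})

test_that("recommended references beat random sets and agree with cluster::pam", {
  set.seed(21)
  pts <- matrix(rnorm(60), 30)
  d <- as.matrix(dist(pts))
  rec <- recommend_references(d, 3)
  rand_scores <- replicate(200, {
    s <- sample(30, 3)
    mean(apply(d[, s, drop = FALSE], 1, min))
  })
  expect_lte(rec$score, median(rand_scores))
  # independent cross-check: PAM from the cluster package
  pam_fit <- cluster::pam(as.dist(d), 3)
  pam_score <- mean(apply(d[, pam_fit$id.med, drop = FALSE], 1, min))
  expect_lte(rec$score, pam_score + 1e-9)
})

test_that("adding a reference never increases the k-medoids score", {
  set.seed(13)
  for (rep in 1:5) {
    pts <- matrix(rnorm(40), 20)
    d <- as.matrix(dist(pts))
    meds <- recommend_references(d, 1)$references + 1
    score <- function(m) mean(apply(d[, m, drop = FALSE], 1, min))
    prev <- score(meds)
    for (k in 2:5) {
      cand <- setdiff(1:20, meds)
      sc <- vapply(cand, function(h) score(c(meds, h)), numeric(1))
      meds <- c(meds, cand[which.min(sc)])
      expect_lte(score(meds), prev + 1e-12)
      prev <- score(meds)
    }
  }
})

test_that("chronological branches grow forward and backward from references", {
  d <- matrix(runif(25), 5); d <- (d + t(d)) / 2; diag(d) <- 0
  p1 <- build_branches(d, 0, "chronological")
  expect_equal(p1$t, 0:4)
  expect_equal(p1$parent_id, c(NA, 0:3))
  p2 <- build_branches(d, 2, "chronological")
  expect_equal(p2$t[1], 2)
  expect_equal(p2$parent_id[match(1, p2$t)], 2)
  expect_equal(p2$parent_id[match(0, p2$t)], 1)
  expect_equal(p2$parent_id[match(3, p2$t)], 2)
  expect_equal(p2$parent_id[match(4, p2$t)], 3)
  expect_error(build_branches(d, 7, "chronological"), "out of range")
})

test_that("similarity branches follow the greedy minimum-distance rule", {
  # hand-built distance matrix, ref = frame 0:
  # step 1: closest unassigned to {0} is 2 (0.1); step 2: closest to {0,2}
  # is 1 via 2 (0.2); step 3: 3 attaches to 1 (0.15)
  d <- matrix(c(
    0.0, 0.9, 0.1, 0.8,
    0.9, 0.0, 0.2, 0.15,
    0.1, 0.2, 0.0, 0.7,
    0.8, 0.15, 0.7, 0.0), 4, 4, byrow = TRUE)
  p <- build_branches(d, 0, "similarity")
  expect_equal(p$t, c(0, 2, 1, 3))
  expect_equal(p$parent_id, c(NA, 0, 2, 1))
  expect_equal(p$reference_id, c(0, 0, 0, 0))
  expect_equal(p$dist, c(NA, 0.1, 0.2, 0.15))
})

test_that("branch queues are valid topological orders for random inputs", {
  set.seed(99)
  for (rep in 1:100) {
    t_n <- sample(4:12, 1)
    d <- matrix(runif(t_n^2), t_n); d <- (d + t(d)) / 2; diag(d) <- 0
    refs <- sort(sample(0:(t_n - 1), sample(1:3, 1)))
    mode <- sample(c("chronological", "similarity"), 1)
    p <- build_branches(d, refs, mode)
    expect_setequal(p$t, 0:(t_n - 1))
    seen <- c()
    for (i in seq_len(nrow(p))) {
      if (!is.na(p$parent_id[i])) expect_true(p$parent_id[i] %in% seen)
      seen <- c(seen, p$t[i])
    }
    # every parent chain roots at a reference
    expect_true(all(p$reference_id %in% refs))
  }
})

test_that("learning-rate scale is the clamped linear map", {
  expect_equal(lr_scale(0, 0.3, 1.5, 0.4), 0.3)
  expect_equal(lr_scale(0.4, 0.3, 1.5, 0.4), 1.5)
  expect_equal(lr_scale(1, 0.3, 1.5, 0.4), 1.5)
  expect_equal(lr_scale(0.2, 0.3, 1.5, 0.4), 0.9)
  d <- seq(0, 1, 0.05)
  expect_true(all(diff(lr_scale(d, 0.2, 1.2, 0.5)) >= 0))
})
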