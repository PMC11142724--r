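# small 2D test scene: well-separated Gaussian blobs
blob_scene <- function(seed = 42, n = 10, size = 64L) {
  set.seed(seed)
  pts <- cbind(x = runif(n, 8, size - 9), y = runif(n, 8, size - 9), z = 0)
  fr <- render_frame(pts, runif(n, 0.6, 1), c(1, 1.5, 1.5),
                     c(1L, size, size), noise_sd = 0.01, seed = seed)
  list(frame = array(fr, c(1L, 1L, size, size)), centers_px = pts,
       centers = pixel_to_normalized(pts, c(1L, size, size)),
       shape = c(1L, size, size))
}

test_that("candidate detectors respond at blob centers and rescale to [0,1]", {
  sc <- blob_scene()
  resp <- run_candidate_detectors(sc$frame)
  expect_equal(dim(resp)[1], 4L)
  expect_equal(attr(resp, "detectors"), c("log", "dog", "rl_peaks", "intensity"))
  expect_true(all(resp >= 0 & resp <= 1))
  # LoG argmax lies within 1 px of the brightest blob center
  lg <- resp[1, 1, , ]
  am <- which(lg == max(lg), arr.ind = TRUE)[1, ]   # (y, x)
  d_all <- sqrt((sc$centers_px[, 1] - (am[2] - 1))^2 +
                  (sc$centers_px[, 2] - (am[1] - 1))^2)
  expect_lt(min(d_all), 1.01)
  # constant frame -> constant responses
  const <- run_candidate_detectors(array(3, c(1, 1, 16, 16)))
  expect_true(all(apply(const, 1, function(m) diff(range(m)) == 0)))
  # requesting two detectors yields two channels
  expect_equal(dim(run_candidate_detectors(sc$frame, c("log", "dog")))[1], 2L)
  expect_error(run_candidate_detectors(sc$frame, "sobel"), "unknown detector")
})

test_that("selector training is deterministic and zero epochs is the init", {
  sc <- blob_scene()
  resp <- run_candidate_detectors(sc$frame, c("log", "intensity"))
  m1 <- train_selector(resp, sc$centers, seed = 7, n_epoch = 30)
  m2 <- train_selector(resp, sc$centers, seed = 7, n_epoch = 30)
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
  m0a <- train_selector(resp, sc$centers, seed = 7, n_epoch = 0)
  m0b <- train_selector(resp, sc$centers, seed = 9, n_epoch = 0)
  expect_length(m0a$loss_curve, 1)
  expect_false(identical(m0a$w1, m0b$w1))
  expect_error(train_selector(resp, sc$centers[0, , drop = FALSE]),
               "at least one")
  # trained model rejects a mismatched detector list
  expect_error(detection_map(sc$frame, m1, c("dog", "intensity")),
               "does not match")
})

test_that("training recovers a planted target channel", {
  sc <- blob_scene(seed = 5)
  target <- elastrack:::detection_target(sc$centers, sc$shape, 2)
  set.seed(33)
  resp <- array(0, c(3, sc$shape))
  resp[1, , , ] <- array(runif(prod(sc$shape)), sc$shape)
  resp[2, , , ] <- target                       # the planted channel
  resp[3, , , ] <- array(runif(prod(sc$shape)), sc$shape)
  attr(resp, "detectors") <- c("noise1", "planted", "noise2")
  model <- train_selector(resp, sc$centers, seed = 3, n_epoch = 2000,
                          lr = 0.2, pos_weight = 1)

  # held-out scene with the same planted structure
  sc2 <- blob_scene(seed = 6)
  target2 <- elastrack:::detection_target(sc2$centers, sc2$shape, 2)
  resp2 <- array(0, c(3, sc2$shape))
  resp2[1, , , ] <- array(runif(prod(sc2$shape)), sc2$shape)
  resp2[2, , , ] <- target2
  resp2[3, , , ] <- array(runif(prod(sc2$shape)), sc2$shape)
  out <- elastrack:::selector_forward(model, resp2)$prob
  expect_gt(cor(as.vector(out), as.vector(target2)), 0.99)

  # ablating the planted channel hurts far more than ablating noise
  bce <- function(r) {
    p <- pmin(pmax(elastrack:::selector_forward(model, r)$prob, 1e-7), 1 - 1e-7)
    -mean(model$pos_weight * target2 * log(p) + (1 - target2) * log(1 - p))
  }
  base <- bce(resp2)
  degr <- vapply(1:3, function(ch) {
    r <- resp2; r[ch, , , ] <- 0; bce(r) - base
  }, numeric(1))
  expect_gt(degr[2], 5 * max(degr[c(1, 3)]))
})

test_that("detection maps peak at blob centers on synthetic frames", {
  sc <- blob_scene(seed = 8, n = 12)
  resp <- run_candidate_detectors(sc$frame, c("log", "dog", "intensity"))
  model <- train_selector(resp, sc$centers, seed = 2)
  dmap <- detection_map(sc$frame, model)
  expect_true(all(dmap > 0 & dmap < 1))
  expect_equal(dim(dmap), as.integer(sc$shape), ignore_attr = TRUE)
  # constant frame gives a constant map away from the zero-padded border
  cmap <- detection_map(array(0.5, c(1, 1, 64, 64)), model)
  expect_lt(diff(range(cmap[, 2:63, 2:63])), 1e-9)
  # local maxima near >= 90% of blob centers
  peaks <- elastrack:::find_peaks(unclass(dmap), 0.5, 2)
  hit <- vapply(seq_len(nrow(sc$centers_px)), function(i) {
    any(sqrt(rowSums(sweep(peaks, 2, sc$centers_px[i, ])^2)) <= 1.5)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("detection loss matches interpolation and its gradient checks out", {
  dmap <- array(runif(16 * 16), c(1, 16, 16))
  pos <- pixel_to_normalized(cbind(runif(6, 2.2, 13.4), runif(6, 2.2, 13.4), 0),
                             c(1, 16, 16))
  expect_equal(loss_detection(array(1, c(1, 16, 16)), pos), 0)
  expect_equal(loss_detection(array(0, c(1, 16, 16)), pos), 6)
  expect_equal(loss_detection(dmap, pos), oracle_loss_detection(dmap, pos),
               tolerance = 1e-9)
  # midway between pixel values 0 and 1 the term is 0.5
  half <- array(0, c(1, 3, 3))
  half[1, 2, 2] <- 0   # target point between (x=1, y=1) value 0 ...
  half[1, 2, 3] <- 1   # ... and (x=2, y=1) value 1
  p_half <- pixel_to_normalized(c(1.5, 1, 0), c(1, 3, 3))
  expect_equal(loss_detection(half, p_half), 0.5)
  # finite-difference gradient in pixel space
  res <- loss_detection(dmap, pos, grad = TRUE)
  px <- normalized_to_pixel(pos, dim(dmap))
  fd <- fd_gradient(function(p) {
    s <- elastrack:::cpp_sample_multilinear(as.vector(dmap), dim(dmap), p, 1L)
    sum(1 - s$value)
  }, px, h = 1e-6)
  expect_lt(max(abs(fd - res$grad_px)) / max(abs(fd)), 1e-4)
})

test_that("precision/recall uses greedy one-to-one matching", {
  shp <- c(1L, 32L, 32L)
  centers_px <- cbind(seq(4, 28, length.out = 10), seq(26, 6, length.out = 10), 0)
  centers <- pixel_to_normalized(centers_px, shp)
  dmap <- array(0, shp)
  for (i in 1:10)
    dmap[1, round(centers_px[i, 2]) + 1, round(centers_px[i, 1]) + 1] <- 0.9
  expect_equal(detection_precision_recall(dmap, centers, 2),
               c(precision = 1, recall = 1))
  expect_equal(detection_precision_recall(array(0, shp), centers, 2),
               c(precision = 0, recall = 0))
  # one spurious peak among 10 true: precision 10/11, recall 1
  dmap2 <- dmap
  dmap2[1, 3, 30] <- 0.9
  expect_equal(detection_precision_recall(dmap2, centers, 2),
               c(precision = 10 / 11, recall = 1))
})
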