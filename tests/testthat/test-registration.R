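test_that("sampling grids center on the keypoint and rotate in-plane", {
  g <- grid_from_params(c(0, 0, 0), c(1, 3, 3), c(1, 11, 11))
  px <- normalized_to_pixel(g, c(1, 11, 11))
  expect_equal(px[5, 1:2], c(x = 5, y = 5))
  expect_equal(attr(g, "grid_shape"), c(1L, 3L, 3L))

  # rotation by pi negates the x offsets of a 1x1x3 grid
  g0 <- normalized_to_pixel(grid_from_params(c(0.2, -0.1, 0), c(1, 1, 3),
                                             c(1, 21, 21)), c(1, 21, 21))
  gp <- normalized_to_pixel(grid_from_params(c(0.2, -0.1, 0), c(1, 1, 3),
                                             c(1, 21, 21), angle = pi),
                            c(1, 21, 21))
  ctr <- g0[2, ]
  expect_equal(gp[, 1] - ctr[1], -(g0[, 1] - ctr[1]), tolerance = 1e-12)
  expect_error(grid_from_params(c(0, 0, 0), c(1, 4, 3), c(1, 11, 11)), "odd")

  # arbitrary rotation equals an explicit rotation-matrix construction
  set.seed(2)
  ang <- runif(1, -pi, pi)
  ctr_n <- c(0.1, 0.3, 0)
  ga <- normalized_to_pixel(grid_from_params(ctr_n, c(1, 5, 5), c(1, 33, 33),
                                             angle = ang), c(1, 33, 33))
  ctr_px <- normalized_to_pixel(ctr_n, c(1, 33, 33))
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  k <- 1
  for (dx in -2:2) for (dy in -2:2) {
    # grid rows run z fastest, then y, then x
    row <- (dx + 2) * 5 + (dy + 2) + 1
    o <- rot %*% c(dx, dy)
    expect_equal(unname(ga[row, 1:2]),
                 unname(c(ctr_px[1] + o[1], ctr_px[2] + o[2])),
                 tolerance = 1e-9)
  }
})

test_that("descriptor sampling interpolates, pads, and crops exactly", {
  fr <- array(5, c(1, 4, 9, 9))
  g <- grid_from_params(c(0, 0, 0), c(1, 3, 3), c(4, 9, 9))
  expect_equal(as.vector(sample_descriptor(fr, g)), rep(5, 9))

  # integer-aligned grid on a ramp equals the direct array slice
  ramp <- array(0, c(1, 1, 11, 11))
  ramp[1, 1, , ] <- outer(seq_len(11), seq_len(11), function(y, x) 3 * x + y)
  gi <- grid_from_params(pixel_to_normalized(c(5, 6, 0), c(1, 11, 11)),
                         c(1, 3, 3), c(1, 11, 11))
  d <- sample_descriptor(ramp, gi)
  expect_equal(d[1, 1, , ], ramp[1, 1, 6:8, 5:7], ignore_attr = TRUE)

  # grid fully outside with zero padding samples zeros
  gout <- grid_from_params(c(5, 5, 0), c(1, 3, 3), c(1, 11, 11))
  expect_equal(as.vector(sample_descriptor(ramp, gout, "zero")), rep(0, 9))
})

test_that("foveation blur schedule hits its endpoints and stage values", {
  expect_equal(blur_sigma(0, c(3, 3, 30)), 3)
  expect_equal(blur_sigma(29, c(3, 3, 30)), 0)
  expect_equal(blur_sigma(15, c(3, 3, 30)), 1.5)
  sig <- vapply(0:39, blur_sigma, numeric(1), schedule = c(2, 4, 40))
  expect_true(all(diff(sig) <= 0))
  expect_equal(sig[1], 2)
  expect_equal(sig[40], 0)
})

test_that("registration loss matches the brute-force correlation oracle", {
  set.seed(4)
  child <- lapply(1:10, function(i) array(rnorm(2 * 3 * 3), c(1, 2, 3, 3)))
  ref <- lapply(1:10, function(i) array(rnorm(2 * 3 * 3), c(1, 2, 3, 3)))
  expect_equal(loss_registration(child, ref),
               oracle_loss_registration(child, ref), tolerance = 1e-6)
  expect_equal(loss_registration(child[1], child[1]), 0, tolerance = 1e-12)
  neg <- list(-child[[1]])
  expect_equal(loss_registration(neg, child[1]), 2, tolerance = 1e-12)
  # zero-variance member contributes exactly 1
  expect_equal(loss_registration(list(array(2, c(1, 2, 3, 3))), ref[1]), 1)
  expect_error(loss_registration(child[1:2], ref[1]), "equal length")
})

test_that("compiled registration term equals the R reference path", {
  mv <- small_movie()
  shp <- video_shape(mv$video)
  fr <- get_frame(mv$video, 2)
  set.seed(9)
  centers <- normalized_to_pixel(truth_positions(mv, 2), shp) +
    matrix(rnorm(36, 0, 0.8), 12)
  gs <- c(3L, 7L, 7L)
  offs <- elastrack:::grid_offsets(gs)
  refM <- elastrack:::sample_descriptor_batch(
    get_frame(mv$video, 0), normalized_to_pixel(truth_positions(mv, 0), shp),
    offs, 1L)$values
  for (sg in c(0, 1.2)) {
    for (fov in list(NULL, elastrack:::fovea_weights(offs, gs, 2.5))) {
      refb <- if (sg > 0) {
        mats <- lapply(gs, elastrack:::blur_matrix, sigma = sg)
        matrix(elastrack:::blur_stack(array(refM, c(gs, 12)), mats), nrow(refM))
      } else refM
      a <- elastrack:::registration_term(fr, centers, refb, offs, gs, sg, 1L,
                                         fovea_w = fov)
      b <- elastrack:::registration_term_fast(fr, centers, refb, offs, gs, sg,
                                              1L, fovea_w = fov %||% numeric(0))
      expect_equal(a$loss, b$loss, tolerance = 1e-10)
      expect_equal(max(abs(a$grad_px - b$grad_px)), 0, tolerance = 1e-10)
    }
  }
})

test_that("descriptors are shift-equivariant for integer translations", {
  mv <- small_movie()
  shp <- video_shape(mv$video)
  fr <- get_frame(mv$video, 1)
  shifted <- array(0, dim(fr))
  shifted[1, , , ] <- 0
  shifted[1, , 3:shp[2], 5:shp[3]] <- fr[1, , 1:(shp[2] - 2), 1:(shp[3] - 4)]
  pos <- truth_positions(mv, 1)
  px <- normalized_to_pixel(pos, shp)
  interior <- px[, 1] > 8 & px[, 1] < shp[3] - 10 &
    px[, 2] > 8 & px[, 2] < shp[2] - 10
  px <- px[interior, , drop = FALSE]
  offs <- elastrack:::grid_offsets(c(1L, 5L, 5L))
  d0 <- elastrack:::sample_descriptor_batch(fr, px, offs, 1L)$values
  px_sh <- px
  px_sh[, 1] <- px_sh[, 1] + 4
  px_sh[, 2] <- px_sh[, 2] + 2
  d1 <- elastrack:::sample_descriptor_batch(shifted, px_sh, offs, 1L)$values
  expect_lt(max(abs(d0 - d1)), 1e-6)
})

test_that("analytic registration gradient matches finite differences", {
  mv <- small_movie()
  shp <- video_shape(mv$video)
  fr <- get_frame(mv$video, 3)
  set.seed(17)
  centers <- normalized_to_pixel(truth_positions(mv, 3), shp) +
    matrix(runif(36, 0.1, 0.4), 12)   # keep away from integer lattice kinks
  gs <- c(3L, 7L, 7L)
  offs <- elastrack:::grid_offsets(gs)
  refM <- elastrack:::sample_descriptor_batch(
    get_frame(mv$video, 0), normalized_to_pixel(truth_positions(mv, 0), shp),
    offs, 1L)$values
  for (sg in c(0, 1.5)) {
    refb <- if (sg > 0) {
      mats <- lapply(gs, elastrack:::blur_matrix, sigma = sg)
      matrix(elastrack:::blur_stack(array(refM, c(gs, 12)), mats), nrow(refM))
    } else refM
    res <- elastrack:::registration_term_fast(fr, centers, refb, offs, gs,
                                              sg, 1L)
    fd <- fd_gradient(function(cc) {
      elastrack:::registration_term_fast(fr, cc, refb, offs, gs, sg, 1L)$loss
    }, centers, h = 1e-5)
    denom <- max(abs(fd), 1)
    expect_lt(max(abs(fd - res$grad_px)) / denom, 1e-4)
  }
})
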