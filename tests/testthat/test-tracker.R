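test_that("child initialization copies parents, pins annotations, flows the rest", {
  parent <- matrix(runif(30, -0.5, 0.5), 10)
  rownames(parent) <- 0:9

  init0 <- initialize_child(parent, NULL)
  expect_equal(init0$theta, parent, ignore_attr = TRUE)
  expect_false(any(init0$pinned))

  # all keypoints annotated: everything pinned at the annotations
  ann_all <- data.frame(t = 1, worldline_id = 0:9,
                        x = parent[, 1] + 0.05, y = parent[, 2],
                        z = parent[, 3], provenance = "manual")
  init1 <- initialize_child(parent, ann_all)
  expect_true(all(init1$pinned))
  expect_equal(unname(init1$theta[, 1]), unname(parent[, 1]) + 0.05)

  # 3 of 10 annotated with a constant displacement: the constant flow
  # carries the remaining 7
  d <- c(0.04, -0.03, 0.02)
  ann3 <- data.frame(t = 1, worldline_id = c(1, 4, 7),
                     x = parent[c(2, 5, 8), 1] + d[1],
                     y = parent[c(2, 5, 8), 2] + d[2],
                     z = parent[c(2, 5, 8), 3] + d[3],
                     provenance = "manual")
  init3 <- initialize_child(parent, ann3)
  expect_equal(sum(init3$pinned), 3)
  expect_equal(unname(init3$theta), unname(sweep(parent, 2, d, "+")),
               tolerance = 1e-6)
  expect_error(initialize_child(parent, transform(ann3, worldline_id = 90)),
               "unknown worldline")
})

test_that("a frame identical to its reference stays at the annotations", {
  mv <- small_movie()
  fr0 <- get_frame(mv$video, 0)
  arr <- array(0, c(3, 1, video_shape(mv$video)))
  for (t in 1:3) arr[t, 1, , , ] <- fr0[1, , , ]
  vid <- video_store(arr)
  ann <- mv$truth[mv$truth$t == 0, ]
  res <- track_all(vid, ann, tracking_config(seed = 1, grid_shape = c(3, 9, 9)),
                   loss_weights(1, 0.1, 0, 0))
  truth0 <- truth_positions(mv, 0)
  for (t in 0:2) {
    got <- res$coords[res$coords$t == t, ]
    m <- as.matrix(got[match(0:11, got$worldline_id), c("x", "y", "z")])
    expect_lt(max(abs(m - truth0)), 1e-3)
  }
})

test_that("registration recovers a pure integer translation to sub-pixel", {
  mv <- shift_movie()
  shp <- video_shape(mv$video)
  fr0 <- get_frame(mv$video, 0)
  shifted <- array(0, dim(fr0))
  shifted[1, , 3:shp[2], 4:shp[3]] <- fr0[1, , 1:(shp[2] - 2), 1:(shp[3] - 3)]
  arr <- array(0, c(2, 1, shp))
  arr[1, 1, , , ] <- fr0[1, , , ]
  arr[2, 1, , , ] <- shifted
  vid <- video_store(arr)
  ann <- mv$truth[mv$truth$t == 0, ]
  res <- track_all(vid, ann, tracking_config(seed = 1, grid_shape = c(3, 9, 9)),
                   loss_weights(1, 0, 0, 0))
  got <- res$coords[res$coords$t == 1, ]
  wl <- sort(unique(ann$worldline_id))
  pred_px <- normalized_to_pixel(
    as.matrix(got[match(wl, got$worldline_id), c("x", "y", "z")]), shp)
  true_px <- normalized_to_pixel(truth_positions(mv, 0), shp)
  true_px[, 1] <- true_px[, 1] + 3
  true_px[, 2] <- true_px[, 2] + 2
  inb <- true_px[, 1] > 8 & true_px[, 1] < shp[3] - 8 &
    true_px[, 2] > 8 & true_px[, 2] < shp[2] - 8
  err <- sqrt(rowSums((pred_px - true_px)^2))[inb]
  expect_lt(max(err), 0.5)
})

test_that("springs pull an unpinned keypoint toward a pinned correction", {
  # two keypoints, blank video (no image gradients), lambda_R = 0:
  # pinning one 2 px away drags its neighbor to restore the rest length
  shp <- c(1L, 41L, 41L)
  arr <- array(0, c(2, 1, shp))
  vid <- video_store(arr)
  p0 <- pixel_to_normalized(rbind(c(15, 20, 0), c(25, 20, 0)), shp)
  nw <- build_network(p0, 1)
  pinned_pos <- pixel_to_normalized(rbind(c(17, 20, 0), c(25, 20, 0)), shp)
  cfg <- tracking_config(seed = 1, grid_shape = c(1, 5, 5), n_epoch = 30,
                         lr = 0.5)
  tr <- track_frame(vid, 1, pinned_pos, pinned = c(TRUE, FALSE),
                    ref_desc = NULL, network = nw, dmap = NULL,
                    config = cfg, weights = loss_weights(0, 1, 0, 0))
  out_px <- normalized_to_pixel(tr$positions, shp)
  expect_equal(out_px[1, ], c(17, 20, 0), ignore_attr = TRUE)  # pinned fixed
  expect_gt(out_px[2, 1], 25.5)            # neighbor moved away to x ~ 27
  expect_lt(tr$loss_trace[length(tr$loss_trace)], tr$loss_trace[1])
})

test_that("manual records pass through unchanged and runs are deterministic", {
  mv <- small_movie()
  ann <- rbind(mv$truth[mv$truth$t == 0, ],
               mv$truth[mv$truth$t == 4 & mv$truth$worldline_id %in% 0:2, ])
  cfg <- tracking_config(seed = 3, grid_shape = c(3, 9, 9))
  w <- loss_weights(1, 0.1, 0, 0)
  r1 <- track_all(mv$video, ann, cfg, w)
  r2 <- track_all(mv$video, ann, cfg, w)
  expect_identical(r1$coords, r2$coords)

  keys <- paste(ann$t, ann$worldline_id)
  out <- r1$coords[paste(r1$coords$t, r1$coords$worldline_id) %in% keys, ]
  out <- out[order(out$t, out$worldline_id), ]
  ann_s <- validate_annotations(ann)
  rownames(out) <- NULL
  expect_identical(out$x, ann_s$x)
  expect_identical(out$provenance, ann_s$provenance)
  # everything else is tracked
  expect_true(all(r1$coords$provenance[
    !paste(r1$coords$t, r1$coords$worldline_id) %in% keys] == "tracked"))
})

test_that("missing worldlines in a declared reference are reported", {
  mv <- small_movie()
  # frame 0 lacks worldline 5, which appears as a partial annotation at t 3
  ann <- rbind(mv$truth[mv$truth$t == 0 & mv$truth$worldline_id != 5, ],
               mv$truth[mv$truth$t == 3 & mv$truth$worldline_id == 5, ])
  cfg <- tracking_config(seed = 1, reference_frames = 0)
  expect_error(track_all(mv$video, ann, cfg), "missing worldline id")
  expect_error(track_all(mv$video, ann[0, ], tracking_config(seed = 1)),
               "no annotations")
})

test_that("weight schedules swap in mid-optimization", {
  w <- loss_weights(1, 0, 0, 0, schedule = list(
    list(epoch_start = 0, weights = loss_weights(1, 0, 0, 0)),
    list(epoch_start = 10, weights = loss_weights(0.5, 0.2, 0, 0))))
  expect_equal(unname(elastrack:::weights_at(w, 0)), c(1, 0, 0, 0))
  expect_equal(unname(elastrack:::weights_at(w, 9)), c(1, 0, 0, 0))
  expect_equal(unname(elastrack:::weights_at(w, 10)), c(0.5, 0.2, 0, 0))
  expect_error(loss_weights(schedule = list(
    list(epoch_start = 5, weights = loss_weights()),
    list(epoch_start = 5, weights = loss_weights()))), "strictly increasing")
  expect_error(loss_weights(lambda_R = -1), "non-negative")
})
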