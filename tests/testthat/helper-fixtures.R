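# Shared fixtures, built once per test session. The benchmark movie and
# its tracking runs are cached because several acceptance properties
# reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small deformable movie for module-level tracker tests (fast)
small_movie <- function(seed = 11) {
  fixture(paste0("small", seed), function() {
    suppressWarnings(generate_movie(movie_params(
      "worm3d", seed = seed, n_keypoints = 12L, n_frames = 8L,
      shape = c(8L, 48L, 48L), margin = 8)))
  })
}

# sparser scene for translation-recovery tests: keypoints well separated
# so descriptor matching is unambiguous and only the optimizer is probed
shift_movie <- function() {
  fixture("shift_movie", function() {
    suppressWarnings(generate_movie(movie_params(
      "worm3d", seed = 31, n_keypoints = 10L, n_frames = 4L,
      shape = c(8L, 64L, 64L), margin = 12)))
  })
}

# full benchmark movie + similarity matrix + recommended references
benchmark_movie <- function(seed) {
  fixture(paste0("bench_movie", seed), function() {
    mv <- suppressWarnings(generate_movie(movie_params("worm3d", seed = seed)))
    sm <- similarity_matrix(mv$video)
    refs <- recommend_references(sm, 2)$references
    list(movie = mv, simmat = sm, refs = refs,
         ann = mv$truth[mv$truth$t %in% refs, ])
  })
}

benchmark_config <- function(seed) {
  tracking_config(seed = seed, sort_mode = "similarity")
}

# cached benchmark tracking run for a given seed and weight setting
benchmark_run <- function(seed, weights = loss_weights(), tag = "default",
                          annotations = NULL) {
  fixture(paste0("bench_run", seed, "_", tag), function() {
    bm <- benchmark_movie(seed)
    ann <- if (is.null(annotations)) bm$ann else annotations
    track_all(bm$movie$video, ann, benchmark_config(seed), weights)
  })
}

truth_positions <- function(movie, t) {
  rows <- movie$truth[movie$truth$t == t, ]
  m <- as.matrix(rows[, c("x", "y", "z")])
  rownames(m) <- rows$worldline_id
  m
}

random_annotations <- function(n, t_max = 4, seed = 1) {
  set.seed(seed)
  data.frame(
    t = sample(0:t_max, n, replace = TRUE),
    worldline_id = seq_len(n) - 1L,
    x = runif(n, -0.9, 0.9), y = runif(n, -0.9, 0.9),
    z = runif(n, -0.9, 0.9),
    provenance = sample(c("manual", "tracked", "verified"), n, replace = TRUE))
}
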