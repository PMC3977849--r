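test_that("local score is zero at identity, gated at one cell length", {
  a <- make_obs(100)
  expect_equal(local_score(a, a), 0)
  b51 <- make_obs(151)
  expect_equal(local_score(a, b51), Inf)   # 51 px > 50 px gate
  b50 <- make_obs(149.9)
  expect_true(is.finite(local_score(a, b50)))
  # strictly increasing in centroid distance, all else fixed
  s <- vapply(seq(0, 40, by = 2), function(d) {
    local_score(a, make_obs(100 + d))
  }, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("greedy local matching enforces the printed gates", {
  a <- make_obs(100)
  res <- match_local(a, make_obs(100.5, id_start = 10L))
  expect_equal(nrow(res$pairs), 1L)
  expect_length(res$unpaired_a, 0L)
  expect_length(res$unpaired_b, 0L)

  # 45% area change: rejected, both left unpaired
  b <- make_obs(100.5, area = a$area * 0.55, id_start = 10L)
  res <- match_local(a, b)
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(res$unpaired_a, a$obs_id)
  expect_equal(res$unpaired_b, b$obs_id)

  # score at/above 65 rejected even when overlap and area pass
  cfg <- tracker_config()
  b_far <- make_obs(130, id_start = 10L)    # 30+30 px terms -> score 60
  expect_lt(local_score(a, b_far, cfg), cfg$local_score_threshold)
  expect_equal(nrow(match_local(a, b_far, cfg)$pairs), 1L)
  b_hot <- make_obs(130, angle = 12, id_start = 10L)  # + 0.5 * 12 -> 66
  expect_gte(local_score(a, b_hot, cfg), cfg$local_score_threshold)
  expect_equal(nrow(match_local(a, b_hot, cfg)$pairs), 0L)

  # noiseless small drift: pairing equals ground truth identity
  x <- seq(40, 360, by = 45)
  resd <- match_local(make_obs(x), make_obs(x + 1, id_start = 100L))
  expect_equal(resd$pairs$obs_b - resd$pairs$obs_a, rep(99L, length(x)))
})

test_that("global fallback triggers on >30 unpaired or large displacement", {
  cfg <- tracker_config()
  far_b <- make_obs(5000, id_start = 500L)
  res31 <- match_local(make_obs(seq(30, 30 + 30 * 16, by = 16)), far_b, cfg)
  expect_length(res31$unpaired_a, 31L)
  expect_true(needs_global_fallback(res31, cfg))
  res30 <- match_local(make_obs(seq(30, 30 + 29 * 16, by = 16)), far_b, cfg)
  expect_length(res30$unpaired_a, 30L)
  expect_false(needs_global_fallback(res30, cfg))   # strict >30
  # mean displacement above 8 px triggers even with everything paired
  res9 <- match_local(make_obs(100), make_obs(109, id_start = 9L), cfg)
  expect_equal(res9$mean_displacement, 9)
  expect_true(needs_global_fallback(res9, cfg))
  res7 <- match_local(make_obs(100), make_obs(107, id_start = 9L), cfg)
  expect_false(needs_global_fallback(res7, cfg))
})

test_that("global score normalises area by the larger cell", {
  a <- make_obs(100, area = 1000)
  b <- make_obs(100, area = 500, id_start = 2L)
  cfg <- tracker_config()
  expect_equal(global_score(a, a, cfg), 0)
  expect_equal(global_score(a, b, cfg), cfg$global_weights[["area"]] * 0.5)
  set.seed(5)
  for (k in 1:10) {
    p <- make_obs(stats::runif(1, 50, 300), len = stats::runif(1, 7, 14),
                  area = stats::runif(1, 500, 1500))
    q <- make_obs(stats::runif(1, 50, 300), len = stats::runif(1, 7, 14),
                  area = stats::runif(1, 500, 1500), id_start = 2L)
    expect_equal(global_score(p, q, cfg), global_score(q, p, cfg))
  }
})

test_that("global assignment is optimal and honours displacement limits", {
  cfg <- tracker_config(min_disp_max = 0,
                        global_rerun_min_paired_fraction = 0)
  set.seed(17)
  for (k in 1:30) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    a <- make_obs(stats::runif(n, 30, 260), len = stats::runif(n, 7, 14),
                  area = stats::runif(n, 600, 1400))
    b <- make_obs(stats::runif(m, 30, 260), len = stats::runif(m, 7, 14),
                  area = stats::runif(m, 600, 1400), id_start = 50L)
    res <- match_global(a, b, cfg)
    expect_equal(pairing_objective(res, cfg), brute_force_global(a, b, cfg),
                 tolerance = 1e-8)
  }

  # bulk advection of 12 px: local mean displacement trips the fallback and
  # the global tracker recovers the ground-truth pairing
  x <- seq(40, 355, by = 45)
  a <- make_obs(x)
  b <- make_obs(x + 12, id_start = 100L)
  loc <- match_local(a, b)
  expect_true(needs_global_fallback(loc))
  glo <- match_global(a, b, tracker_config(chamber_length = 420))
  expect_equal(glo$pairs$obs_b - glo$pairs$obs_a, rep(99L, length(x)))

  # poor pairing with mean displacement above 8 px: exactly one re-run
  a4 <- make_obs(c(60, 120, 180, 240))
  b4 <- make_obs(c(69, 1060, 1200, 1340), id_start = 10L)
  res <- match_global(a4, b4, tracker_config(min_disp_max = 0))
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$displacement, 9)
  expect_equal(res$reruns, 1L)
})

test_that("track assembly keeps chains contiguous and restarts lost cells", {
  obs1 <- do.call(rbind, lapply(1:100, function(f) {
    make_obs(10 + 0.5 * f, frame = f, id_start = f)
  }))
  tm <- track_movie(list(observations = obs1))
  expect_equal(length(unique(tm$tracks$track_id)), 1L)
  expect_equal(nrow(tm$tracks), 100L)

  # lost for 60 frames mid-movie: the reappearance starts a second track
  obs2 <- do.call(rbind, lapply(c(1:20, 81:100), function(f) {
    make_obs(100, frame = f, id_start = f)
  }))
  tm2 <- track_movie(list(observations = obs2))
  expect_equal(length(unique(tm2$tracks$track_id)), 2L)

  # no observation is ever assigned to two tracks
  tp <- small_pipeline()
  expect_equal(anyDuplicated(tp$tracked$tracks$obs_id), 0L)
  expect_true(all(tp$tracked$tracks$frame >= 1))
})

test_that("local and global trackers agree on slow noiseless movies", {
  cfg <- tracker_config(min_disp_max = 0)  # disable the displacement ramp
  x <- seq(50, 350, by = 60)
  a <- make_obs(x, len = seq(8, 13, length.out = length(x)))
  b <- make_obs(x + 1, len = seq(8, 13, length.out = length(x)),
                id_start = 30L)
  loc <- match_local(a, b, cfg)
  glo <- match_global(a, b, cfg)
  ord <- function(p) p[order(p$obs_a), c("obs_a", "obs_b")]
  expect_equal(ord(loc$pairs), ord(glo$pairs), ignore_attr = TRUE)
})

test_that("tracking recovers ground-truth links on a default-noise colony", {
  tp <- small_pipeline()
  v <- validate_against_truth(tp)
  m <- stats::setNames(v$metrics$value, v$metrics$metric)
  expect_gte(m[["link_recall"]], 0.95)
  expect_lte(m[["false_link_rate"]], 0.01)
})
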