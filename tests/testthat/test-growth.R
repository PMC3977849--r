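test_that("plateau detection finds the changepoint of piecewise growth", {
  # clean ramp-then-plateau: breakpoint recovered within 2 frames
  t <- 0:129
  lengths <- 7 + 0.05 * pmin(t, 100)
  pl <- detect_plateau(lengths)
  expect_false(is.null(pl))
  expect_lte(abs(pl$plateau_start - 101), 2)
  expect_equal(pl$division_length, 12, tolerance = 1e-9)
  expect_equal(pl$elongation_rate, 0.05, tolerance = 1e-6)

  # monotone growth with no flat segment: incomplete
  expect_null(detect_plateau(7 + 0.05 * (0:129)))

  # noiseless plateau exactly at the plateau mean
  lp <- c(seq(7, 12.9, length.out = 90), rep(12.9, 40))
  expect_equal(detect_plateau(lp)$division_length, 12.9)
})

test_that("growth records decompose the cycle into its phases", {
  t <- 0:129
  lengths <- 7 + 0.05 * pmin(t, 100)
  rec <- extract_record(lengths, birth_frame = 1L, division_frame = 131L)
  expect_true(rec$complete)
  expect_equal(rec$elongation_time, 100)
  expect_equal(rec$septation_time, 30)
  expect_equal(rec$doubling_time, 130)
  expect_equal(rec$elongation_rate, 0.05, tolerance = 1e-6)
  expect_equal(rec$birth_length, 7)
})

test_that("a zero-CV cycle reproduces the configured parameters", {
  p <- one_cell_params(n_frames = 135, age_frac = 0, noise = 0, seed = 6,
                       mean_birth_length = 7.3)
  sim <- simulate_colony(p)
  seg <- segment_movie(sim$stack, sim$geometry$lanes)
  tm <- track_movie(seg)
  dv <- detect_divisions(tm)
  rec <- records_from_tracks(tm, dv, require_birth_division = FALSE)
  rec <- rec[rec$complete, ]
  expect_equal(nrow(rec), 1L)
  px <- p$pixel_size
  expect_lt(abs(rec$birth_length - 7.3), px)
  expect_lt(abs(rec$division_length - 12.9), px)
  expect_lt(abs(rec$fission_length - 14.2), px)
  # frame quantization plus the rendered breakpoint can shift the phase
  # boundary by up to ~2 frames at 1 frame/min
  expect_lt(abs(rec$elongation_time - 94.3), 3)
  expect_lt(abs(rec$septation_time - 35), 3)
  expect_equal(rec$doubling_time, rec$elongation_time + rec$septation_time)
  expect_lt(abs(rec$elongation_rate - (12.9 - 7.3) / 94.3) /
              ((12.9 - 7.3) / 94.3), 0.03)
})

test_that("doubling = elongation + septation holds for every record", {
  rec <- small_pipeline()$records
  expect_gt(nrow(rec), 0)
  cmp <- rec[rec$complete, ]
  expect_identical(cmp$doubling_time, cmp$elongation_time + cmp$septation_time)
})

test_that("summaries report mean, SD, CV per parameter and condition", {
  same <- make_records(rep(130, 5))
  s <- summarize_records(same)
  expect_true(all(s$sd == 0))
  expect_true(all(s$cv == 0))
  expect_true(all(s$n == 5))

  both <- rbind(make_records(c(120, 130, 140)),
                make_records(c(170, 180, 190)))
  s2 <- summarize_records(both, condition = rep(c("30C", "25C"), each = 3))
  expect_equal(nrow(s2), 14L)  # 7 parameters x 2 conditions
  expect_setequal(unique(s2$condition), c("30C", "25C"))
  # permutation invariance of record order
  perm <- sample(nrow(both))
  s3 <- summarize_records(both[perm, ],
                          condition = rep(c("30C", "25C"), each = 3)[perm])
  expect_equal(s2[order(s2$parameter, s2$condition), ],
               s3[order(s3$parameter, s3$condition), ], ignore_attr = TRUE)
})

test_that("time CVs are recovered from a sampled population", {
  p <- sim_params(n_lanes = 8, lane_length = 1000, n_frames = 600,
                  cv_times = 0.18, seed = 31)
  s <- simulate_colony(p, render = FALSE, keep_trajectories = FALSE)
  tr <- truth_records(s$truth)
  tr <- tr[tr$complete, ]
  expect_gt(nrow(tr), 400)
  cv_est <- stats::sd(tr$doubling_time) / mean(tr$doubling_time)
  # doubling = elongation + septation with independent CV-0.18 phases:
  # closed-form CV of the sum is the oracle
  cv_expected <- sqrt((0.18 * p$mean_elongation_time)^2 +
                        (0.18 * p$mean_septation_time)^2) /
    (p$mean_elongation_time + p$mean_septation_time)
  expect_lt(abs(cv_est - cv_expected), 0.03)
})

test_that("shift alignment clips cycle fractions into [0, 1]", {
  rec <- make_records(c(100, 100, 100))
  rec$division_time_abs <- c(150, 350, 260)
  al <- align_to_shift(rec, t_shift = 200, window = 30)
  expect_equal(al$records$fraction_of_cycle_after_shift, c(0, 1, 0.6))
  # monotone in division time for fixed doubling time
  rec2 <- make_records(rep(100, 50))
  rec2$division_time_abs <- seq(0, 490, by = 10)
  al2 <- align_to_shift(rec2, t_shift = 200)
  fr <- al2$records$fraction_of_cycle_after_shift
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_gt(nrow(al2$series), 0)
})

test_that("birth-division regression is exact on collinear data", {
  set.seed(44)
  n <- 60
  births <- stats::runif(n, 6, 10)
  rec <- make_records(rep(130, n))
  rec$birth_length <- births
  rec$division_length <- 0.61 * births + 8.2
  fit <- birth_division_regression(rec)
  expect_equal(fit$slope, 0.61, tolerance = 1e-9)
  expect_equal(fit$intercept, 8.2, tolerance = 1e-9)
  expect_gt(nrow(fit$bins), 3)

  rec$division_length <- rep(12.9, n)
  expect_equal(birth_division_regression(rec)$slope, 0, tolerance = 1e-9)

  expect_error(birth_division_regression(make_records(rep(130, 5))),
               "fewer than 10")
})

test_that("sister tables pair daughters with mother division length", {
  # five families with perfectly heritable doubling times
  nodes <- integer(0); parent <- integer(0)
  recs <- list()
  for (f in 1:5) {
    m <- 10L * f
    nodes <- c(nodes, m, m + 1L, m + 2L)
    parent <- c(parent, NA_integer_, m, m)
    r <- make_records(rep(100 + f * 10, 3))
    r$track_id <- c(m, m + 1L, m + 2L)
    recs[[f]] <- r
  }
  fo <- lineage_forest(nodes, parent)
  rec <- do.call(rbind, recs)
  st <- sister_table(fo, rec)
  expect_equal(nrow(st), 5L)
  expect_true(all(st$sister1 < st$sister2))
  expect_equal(st$doubling_time_1, st$doubling_time_2)
  co <- attr(st, "correlations")
  expect_equal(unname(co[["doubling_time"]]), 1)

  # no complete sister pairs -> empty table
  st0 <- sister_table(lineage_forest(1:3, c(NA, 1, 1)), make_records(130))
  expect_equal(nrow(st0), 0L)
})
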