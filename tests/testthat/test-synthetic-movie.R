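# mask-based length: extent of a ground-truth mask along the lane axis
mask_lengths <- function(mask, pixel_size = 0.2304) {
  ids <- setdiff(unique(as.vector(mask)), 0L)
  out <- numeric(0)
  for (id in ids) {
    w <- which(mask == id, arr.ind = TRUE)
    out[as.character(id)] <- (diff(range(w[, 2])) + 1) * pixel_size
  }
  out
}

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(mean_division_length = -1), "positive")
  expect_error(sim_params(frame_interval = 0), "positive")
  expect_error(sim_params(mean_fission_length = 10,
                          mean_division_length = 12.9), "fission")
  expect_error(sim_params(cv_lengths = -0.1), "CV")
})

test_that("identical seed and parameters give identical stacks and truth", {
  p <- sim_params(n_lanes = 2, lane_length = 300, n_frames = 30, seed = 7)
  a <- simulate_colony(p)
  b <- simulate_colony(p)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$cycles, b$truth$cycles)
  expect_identical(a$truth$divisions, b$truth$divisions)
})

test_that("a noiseless single cell grows linearly at the configured rate", {
  p <- one_cell_params(n_frames = 80, age_frac = 0, noise = 0, seed = 5)
  s <- simulate_colony(p, keep_masks = TRUE)
  expect_equal(nrow(s$truth$cycles), 1L)
  cy <- s$truth$cycles
  expect_lt(p$n_frames, cy$elongation_time)  # no division in the window
  tr <- s$truth$trajectories
  fit <- stats::lm(length_um ~ frame, data = tr)
  expect_lt(max(abs(stats::resid(fit))), 1e-9)  # exactly linear truth
  expect_equal(unname(stats::coef(fit)[2]), cy$elongation_rate,
               tolerance = 1e-9)
  # and the rendered masks grow at the same rate
  ml <- vapply(s$truth$masks, function(m) mask_lengths(m)[["1"]], numeric(1))
  mfit <- stats::lm(ml ~ seq_along(ml))
  expect_equal(unname(stats::coef(mfit)[2]), cy$elongation_rate,
               tolerance = 0.005)
})

test_that("symmetric zero-CV division conserves length exactly", {
  p <- one_cell_params(n_frames = 20, age_frac = 0.97, noise = 0, seed = 11)
  s <- simulate_colony(p, keep_masks = TRUE)
  dv <- s$truth$divisions
  expect_equal(nrow(dv), 1L)
  cy <- s$truth$cycles
  kids <- cy[match(c(dv$d1, dv$d2), cy$id), ]
  # daughters are each exactly half the fission length
  expect_equal(kids$birth_length, rep(dv$fission_length / 2, 2))
  expect_equal(sum(kids$birth_length), dv$fission_length)
  # and the rendered masks agree up to pixel quantization
  ml_before <- mask_lengths(s$truth$masks[[dv$frame - 1L]])
  ml_after <- mask_lengths(s$truth$masks[[dv$frame]])
  px <- p$pixel_size
  expect_lt(abs(ml_before[[as.character(dv$parent)]] - dv$fission_length),
            1.5 * px)
  for (d in c(dv$d1, dv$d2)) {
    expect_lt(abs(ml_after[[as.character(d)]] - dv$fission_length / 2),
              1.5 * px)
  }
})

test_that("every division record appears exactly once in the lineage", {
  s <- small_sim()
  dv <- s$truth$divisions
  fo <- truth_forest(s$truth)
  kids <- fo$nodes$node[!is.na(fo$nodes$parent)]
  expect_setequal(kids, c(dv$d1, dv$d2))
  expect_equal(anyDuplicated(c(dv$d1, dv$d2)), 0L)
  # growth-phase partition holds exactly for every cycle
  tr <- truth_records(s$truth)
  expect_equal(tr$doubling_time, tr$elongation_time + tr$septation_time)
})

test_that("noiseless masks reproduce configured lengths within 2 px", {
  p <- sim_params(n_lanes = 2, lane_length = 420, n_frames = 40,
                  noise_sd = 0, seed = 13)
  s <- simulate_colony(p, keep_masks = TRUE)
  worst <- 0
  for (f in seq(1, p$n_frames, by = 5)) {
    ml <- mask_lengths(s$truth$masks[[f]])
    tt <- s$truth$trajectories[s$truth$trajectories$frame == f, ]
    hl <- tt$length_um / p$pixel_size / 2
    tt <- tt[tt$x - hl >= 1 & tt$x + hl <= p$lane_length, ]
    for (i in seq_len(nrow(tt))) {
      m <- ml[[as.character(tt$id[i])]]
      worst <- max(worst, abs(m - tt$length_um[i]))
    }
  }
  expect_lt(worst, 2 * p$pixel_size)
})

test_that("rendering is deterministic and septa appear at mid-cell", {
  p <- sim_params(n_lanes = 1, lane_width = 24, lane_length = 200,
                  noise_sd = 0)
  cells <- tibble::tibble(id = 1L, lane = 1L, x = 100, length_um = 12.9,
                          width_um = 3.6, septum_amp = 1)
  img1 <- render_frame(cells, p, noise = FALSE)
  img2 <- render_frame(cells, p, noise = FALSE)
  expect_identical(img1, img2)
  # lengthwise profile through the cell axis peaks at mid-cell
  geom <- lane_geometry(p)
  yc <- round((geom$lanes$y0[1] + geom$lanes$y1[1]) / 2)
  hl <- 12.9 / p$pixel_size / 2
  cols <- ceiling(100 - hl + 3):floor(100 + hl - 3)
  prof <- img1[yc, cols]
  expect_equal(cols[which.max(prof)], 100, tolerance = 1)
  expect_gt(max(prof), p$interior_level + 0.8 * p$septum_peak_amp)
  # without a septum the mid-cell transverse maximum stays at cell levels
  cells$septum_amp <- 0
  img3 <- render_frame(cells, p, noise = FALSE)
  mid <- img3[geom$lanes$y0[1]:geom$lanes$y1[1], 99:101]
  expect_lte(max(mid), p$bg_level)
})

test_that("ground truth round-trips through plain-text files", {
  dir <- withr::local_tempdir()
  fam <- family_pipeline()
  write_truth(fam$truth, dir, params = sim_params())
  back <- read_truth(dir)
  expect_equal(nrow(back$divisions), nrow(fam$truth$divisions))
  fo1 <- truth_forest(fam$truth)
  fo2 <- lineage_forest(back$cycles$id, back$cycles$parent)
  expect_identical(forest_newick(fo1), forest_newick(fo2))
  expect_true(file.exists(file.path(dir, "params.txt")))

  # a three-generation complete lineage has 4 leaves (tree-traversal oracle)
  tree <- ape::read.tree(file.path(dir, "lineage.nwk"))
  expect_equal(ape::Ntip(tree), 4L)

  # empty truth still writes valid, header-only tables
  p0 <- one_cell_params(n_frames = 5, age_frac = 0, seed = 2)
  s0 <- simulate_colony(p0, render = FALSE)
  d0 <- withr::local_tempdir()
  write_truth(s0$truth, d0)
  expect_equal(nrow(read_truth(d0)$divisions), 0L)
})
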