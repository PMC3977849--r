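# a rendered frame with explicit cell states, for controlled inputs
draw_cells <- function(cells, lane_width = 24, lane_length = 200,
                       noise_sd = 0, n_lanes = 1) {
  p <- sim_params(n_lanes = n_lanes, lane_width = lane_width,
                  lane_length = lane_length, noise_sd = noise_sd)
  list(img = render_frame(cells, p, noise = noise_sd > 0), params = p)
}

# pixel set of a capsule rotated by `angle` degrees, on a blank image
capsule_pixels <- function(L_px, W_px, angle, cx = 70, cy = 70, size = 140) {
  th <- angle * pi / 180
  g <- expand.grid(row = seq_len(size), col = seq_len(size))
  dx <- g$col - cx; dy <- g$row - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  r <- W_px / 2
  du <- pmax(abs(u) - (L_px / 2 - r), 0)
  inside <- sqrt(du^2 + v^2) <= r - 1
  as.matrix(g[inside, c("row", "col")])
}

test_that("split_lanes partitions the chamber and validates geometry", {
  frame <- matrix(128, 500, 60)
  lanes <- split_lanes(frame, n_lanes = 5)
  expect_length(lanes, 5L)
  expect_equal(vapply(lanes, function(l) l$y1 - l$y0 + 1, numeric(1)),
               rep(100, 5))
  rows <- unlist(lapply(lanes, function(l) l$y0:l$y1))
  expect_identical(sort(rows), 1:500)         # disjoint cover
  bad <- tibble::tibble(lane = 1L, y0 = 0L, y1 = 600L)
  expect_error(split_lanes(frame, bad), "bounds")
})

test_that("lane auto-detection recovers the highway geometry within 2 px", {
  s <- small_sim()
  det <- detect_lanes(s$stack[[1]])
  truth <- s$geometry$lanes
  expect_equal(nrow(det), nrow(truth))
  expect_true(all(abs(det$y0 - truth$y0) <= 2))
  expect_true(all(abs(det$y1 - truth$y1) <= 2))
})

test_that("segment_lane finds each separated cell and nothing else", {
  expect_length(segment_lane(matrix(128, 24, 100)), 0L)   # blank lane

  cells <- tibble::tibble(id = 1:3, lane = 1L, x = c(40, 100, 160),
                          length_um = c(8, 10, 12), width_um = 3.6,
                          septum_amp = 0)
  d <- draw_cells(cells)
  p <- d$params
  lane <- split_lanes(d$img, lane_geometry(p)$lanes)[[1]]
  comps <- segment_lane(lane$img)
  expect_length(comps, 3L)
  # one component per rendered cell, at the right position
  cx <- sort(vapply(comps, function(cc) mean(cc$pixels[, 2]), numeric(1)))
  expect_equal(cx, cells$x, tolerance = 1)

  # a highway-wall sliver (thin dark line, no enclosed interior) is no cell
  art <- matrix(128, 24, 100)
  art[12, 5:95] <- 30
  expect_length(segment_lane(art), 0L)
})

test_that("contour measurement is calibrated and rotation invariant", {
  cells <- tibble::tibble(id = 1L, lane = 1L, x = 100, length_um = 10,
                          width_um = 3.6, septum_amp = 0)
  d <- draw_cells(cells)
  obs <- segment_frame(d$img, lane_geometry(d$params)$lanes)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$length_um, 10, tolerance = 0.05)       # 10.0 +- 0.5 um
  expect_equal(obs$width_um, 3.6, tolerance = 0.15)
  expect_equal(obs$category, "single")

  # a perfect square has equal extents along any principal axis
  sq <- as.matrix(expand.grid(row = 10:29, col = 40:59))
  img <- matrix(120, 60, 100)
  mo <- measure_contour(sq, img)
  expect_equal(mo$length_um, mo$width_um, tolerance = 1e-9)

  # rotation by 30 degrees changes the measured length by < 2%
  L <- 10 / 0.2304; W <- 3.6 / 0.2304
  img <- matrix(120, 140, 140)
  m0 <- measure_contour(capsule_pixels(L, W, 0), img)
  m30 <- measure_contour(capsule_pixels(L, W, 30), img)
  expect_lt(abs(m30$length_um - m0$length_um) / m0$length_um, 0.02)
  # orientation in image coordinates (rows grow downward)
  expect_equal(m30$orientation, 30, tolerance = 2)

  expect_equal(measure_contour(sq[1:3, ], img)$category, "rejected_non_cell")
})

test_that("triage applies the printed width and length thresholds", {
  expect_equal(triage_contour(12, 4.0), "single")
  expect_equal(triage_contour(10, 5.0), "too_large")
  expect_equal(triage_contour(14, 4.0), "too_long")
  expect_equal(triage_contour(14, 5.0), "too_large")  # width takes precedence
  # pure function: same inputs, same category
  expect_equal(triage_contour(c(12, 14), c(4, 4)), c("single", "too_long"))
})

test_that("refinement cuts merged chains at intensity valleys", {
  p <- sim_params(n_lanes = 1, lane_width = 24, lane_length = 200,
                  noise_sd = 0)
  geom <- lane_geometry(p)$lanes
  paint_junctions <- function(total_um, junctions_px) {
    cells <- tibble::tibble(id = 1L, lane = 1L, x = 100,
                            length_um = total_um, width_um = 3.6,
                            septum_amp = 0)
    img <- render_frame(cells, p, noise = FALSE)
    for (j in junctions_px) {
      cols <- (j - 1):(j + 1)
      block <- img[, cols]
      block[block == p$interior_level] <- 100  # dim but supra-threshold
      img[, cols] <- block
    }
    img
  }
  # two abutting 8-um rods seen as one 16-um contour -> two ~8-um cells
  img <- paint_junctions(16, 100)
  obs <- segment_frame(img, geom)
  expect_equal(nrow(obs), 2L)
  expect_equal(sort(obs$length_um), c(8, 8), tolerance = 0.15)
  expect_true(all(obs$category == "single"))

  # three-cell chain -> three single pieces
  L3 <- 24 / 0.2304
  img3 <- paint_junctions(24, round(c(100 - L3 / 6, 100 + L3 / 6)))
  obs3 <- segment_frame(img3, geom)
  expect_equal(nrow(obs3), 3L)
  expect_true(all(obs3$category == "single"))
  expect_equal(obs3$length_um, rep(8, 3), tolerance = 0.2)

  # a genuinely long pre-division cell (bright septum, no dark valley)
  # is returned unsplit and flagged
  cells <- tibble::tibble(id = 1L, lane = 1L, x = 100, length_um = 13.5,
                          width_um = 3.6, septum_amp = 1)
  imgl <- render_frame(cells, p, noise = FALSE)
  obsl <- segment_frame(imgl, geom)
  expect_equal(nrow(obsl), 1L)
  expect_equal(obsl$category, "too_long")
  expect_true(obsl$flagged)
  expect_equal(obsl$length_um, 13.5, tolerance = 0.25)
})

test_that("segmentation recall and precision reach 99% on noiseless movies", {
  p <- sim_params(n_lanes = 2, lane_length = 420, n_frames = 60,
                  noise_sd = 0, seed = 21)
  s <- simulate_colony(p)
  seg <- segment_movie(s$stack, s$geometry$lanes)
  obs <- seg$observations
  tt <- s$truth$trajectories
  hl <- tt$length_um / p$pixel_size / 2
  tt <- tt[tt$x - hl >= 1 & tt$x + hl <= p$lane_length, ]
  n_match <- 0L
  for (f in unique(obs$frame)) {
    o <- obs[obs$frame == f, ]
    tf <- tt[tt$frame == f, ]
    for (i in seq_len(nrow(o))) {
      d2 <- (tf$x - o$x[i])^2 + (tf$y - o$y[i])^2
      if (length(d2) && min(d2) <= 16) n_match <- n_match + 1L
    }
  }
  expect_gte(n_match / nrow(tt), 0.99)   # recall
  expect_gte(n_match / nrow(obs), 0.99)  # precision
})

test_that("length measurement is unbiased over 6-15 um rods", {
  set.seed(33)
  lens <- stats::runif(100, 6, 15)
  p <- sim_params(n_lanes = 1, lane_width = 24, lane_length = 200,
                  noise_sd = 0)
  geom <- lane_geometry(p)$lanes
  err <- vapply(lens, function(L) {
    cells <- tibble::tibble(id = 1L, lane = 1L,
                            x = 100 + stats::runif(1, -0.5, 0.5),
                            length_um = L, width_um = 3.6, septum_amp = 0)
    obs <- segment_frame(render_frame(cells, p, noise = FALSE), geom)
    obs$length_um[1] - L
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.25)
  expect_lt(stats::sd(err), 0.2)
})
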