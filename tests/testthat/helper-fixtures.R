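# Shared fixtures (built once per test run) and small oracles.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# a small default-noise colony movie with ground truth and masks
small_sim <- function() {
  fixture("small_sim", function() {
    simulate_colony(sim_params(n_lanes = 2, lane_length = 420,
                               n_frames = 170, seed = 3),
                    keep_masks = TRUE)
  })
}

# the small movie pushed through the whole measurement chain
small_pipeline <- function() {
  fixture("small_pipeline", function() {
    sim <- small_sim()
    seg <- segment_movie(sim$stack, sim$geometry$lanes)
    tm <- track_movie(seg)
    dv <- detect_divisions(tm)
    fo <- build_forest(tm, dv)
    rec <- records_from_tracks(tm, dv, fo)
    structure(list(segmented = seg, tracked = tm, divisions = dv,
                   forest = fo, records = rec, truth = sim$truth,
                   manifest = list(config = list(sim = unclass(sim$params)))),
              class = "pipeline_result")
  })
}

# single founder cell in one lane, controlled phase / noise / CV
one_cell_params <- function(n_frames = 150, age_frac = 0, noise = 0,
                            cv = 0, seed = 5, ...) {
  sim_params(n_lanes = 1L, lane_length = 420L, n_frames = n_frames,
             cv_lengths = cv, cv_times = cv, size_control_slope = 0,
             noise_sd = noise, advection_max = 0.3, initial_fill = 0.1,
             founder_age_frac = age_frac, seed = seed, ...)
}

# a three-generation family movie (founder divides early, daughters divide)
family_pipeline <- function() {
  fixture("family_pipeline", function() {
    p <- one_cell_params(n_frames = 150, age_frac = 0.95, noise = 3, seed = 9)
    sim <- simulate_colony(p, keep_masks = TRUE)
    seg <- segment_movie(sim$stack, sim$geometry$lanes)
    tm <- track_movie(seg)
    dv <- detect_divisions(tm)
    fo <- build_forest(tm, dv)
    rec <- records_from_tracks(tm, dv, fo)
    structure(list(segmented = seg, tracked = tm, divisions = dv,
                   forest = fo, records = rec, truth = sim$truth,
                   manifest = list(config = list(sim = unclass(p)))),
              class = "pipeline_result")
  })
}

# synthetic observation tables for tracker unit tests
make_obs <- function(x, y = 12, lane = 1L, frame = 1L, len = 10,
                     width = 3.6, area = NULL, angle = 0, id_start = 1L) {
  n <- length(x)
  len_px <- len / 0.2304
  wid_px <- width / 0.2304
  if (is.null(area)) area <- len_px * wid_px * 0.9
  tibble::tibble(
    obs_id = id_start - 1L + seq_len(n), frame = frame,
    lane = rep_len(lane, n), x = x, y = rep_len(y, n),
    area = rep_len(area, n), length_um = rep_len(len, n),
    width_um = rep_len(width, n), orientation = rep_len(angle, n),
    mean_intensity = 120,
    x0 = x - len_px / 2, x1 = x + len_px / 2,
    y0 = rep_len(y, n) - wid_px / 2, y1 = rep_len(y, n) + wid_px / 2,
    category = "single", flagged = FALSE,
    profile = replicate(n, numeric(0), simplify = FALSE))
}

# exhaustive minimal-total-cost assignment with a no-match alternative,
# mirroring the gates of match_global (independent of the LAP solver)
brute_force_global <- function(a, b, cfg) {
  n <- nrow(a); m <- nrow(b)
  chamber <- cfg$chamber_length
  if (is.null(chamber)) chamber <- max(a$x1, b$x1)
  S <- matrix(Inf, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (cfg$restrict_to_lane && a$lane[i] != b$lane[j]) next
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
      if (d > cfg$max_displacement) next
      if (d < cfg$min_disp_max * min(1, max(0, a$x[i] / chamber))) next
      S[i, j] <- global_score(a[i, ], b[j, ], cfg)
    }
  }
  best <- Inf
  rec <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n) {
      total <- cost + cfg$nomatch_cost * (m - sum(used))
      if (total < best) best <<- total
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(S[i, j])) {
        used[j] <- TRUE
        rec(i + 1L, used, cost + S[i, j])
        used[j] <- FALSE
      }
    }
    rec(i + 1L, used, cost + cfg$nomatch_cost)
  }
  rec(1L, logical(m), 0)
  best
}

# total objective of a pairing_result under the global cost model
pairing_objective <- function(res, cfg) {
  sum(res$pairs$score) +
    cfg$nomatch_cost * (length(res$unpaired_a) + length(res$unpaired_b))
}

# flood-fill connected components, the slow oracle for label_components
flood_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (mask[r, cc] && lab[r, cc] == 0L) {
      k <- k + 1L
      queue <- list(c(r, cc))
      lab[r, cc] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (q in seq_len(nrow(nb))) {
          rr <- p[1] + nb[q, 1]; ccx <- p[2] + nb[q, 2]
          if (rr >= 1 && rr <= nr && ccx >= 1 && ccx <= nc &&
              mask[rr, ccx] && lab[rr, ccx] == 0L) {
            lab[rr, ccx] <- k
            queue[[length(queue) + 1L]] <- c(rr, ccx)
          }
        }
      }
    }
  }
  lab
}

# partition check: same labelling up to renumbering
same_partition <- function(a, b) {
  fa <- as.integer(factor(a[a > 0], levels = unique(a[a > 0])))
  fb <- as.integer(factor(b[b > 0], levels = unique(b[b > 0])))
  all((a > 0) == (b > 0)) && identical(fa, fb)
}

# growth-record tables with prescribed doubling times (for summary tests)
make_records <- function(doubling, elong_frac = 0.73, birth = 7.1,
                         division = 12.9, fission = 14.2) {
  n <- length(doubling)
  el <- doubling * elong_frac
  tibble::tibble(
    track_id = seq_len(n), lane = 1L, generation = 2L,
    birth_time = 0, division_time_abs = doubling,
    birth_length = rep_len(birth, n),
    division_length = rep_len(division, n),
    fission_length = rep_len(fission, n),
    elongation_time = el, septation_time = doubling - el,
    doubling_time = doubling,
    elongation_rate = (rep_len(division, n) - rep_len(birth, n)) / el,
    complete = TRUE)
}

# the incomplete example tree: both daughters observed, three of four
# granddaughters, two great-granddaughters on one branch only
example_tree <- function() {
  lineage_forest(
    nodes  = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    parent = c(NA, 1L, 1L, 2L, 2L, 3L, 4L, 4L))
}
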