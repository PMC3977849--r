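## Synthetic microchemostat movie generator.
##
## The generator states a simple world that matches the assumptions of the
## analysis pipeline: monolayer rod cells in 5 wall-separated lanes, linear
## elongation from birth length to a division-length plateau, a transient
## bright septum band at mid-cell during the plateau, a terminal snap to the
## fission length, symmetric fission into two daughters, and lane-wise
## advection toward the chamber outlet. Every frame comes with full ground
## truth (trajectories, cycles, divisions, lineage).

#' Simulation parameters
#'
#' Defaults are the steady-state values reported for wild-type
#' *S. pombe* at 30 deg C: division length 12.9 um, fission length
#' 14.2 um (birth length = half the fission length, 7.1 um), elongation
#' time 94.3 min and septation time 35 min (doubling time 129.3 min,
#' ~73% / ~27% of the cycle), length CVs of ~10% and time CVs of ~18%.
#' The pixel scale of 0.2304 um/px corresponds to 50 px = 11.52 um.
#'
#' @param n_lanes number of highway lanes per chamber.
#' @param lane_width lane height, pixels.
#' @param lane_length lane length (sieve at x = 0, outlet at x = lane_length), pixels.
#' @param wall_width dark highway-wall thickness, pixels.
#' @param n_frames frames to simulate.
#' @param frame_interval minutes between frames.
#' @param pixel_size um per pixel.
#' @param mean_birth_length,mean_division_length,mean_fission_length um.
#' @param mean_elongation_time,mean_septation_time minutes.
#' @param cv_lengths,cv_times coefficients of variation (fractions).
#' @param size_control_slope slope of division length on birth length
#'   (0 = pure sizer; 0.61 = the steady-state value measured on chip).
#' @param division_asymmetry_sd SD of the fission split fraction around 0.5.
#' @param cell_width_um rod diameter, um.
#' @param septum_frac position of septum appearance within the plateau
#'   (fraction of septation time).
#' @param septum_peak_delay minutes from septum appearance to peak intensity.
#' @param septum_fall_time minutes from peak back to background.
#' @param septum_width septum band SD along the cell axis, pixels.
#' @param septum_peak_amp peak septum brightness above the interior level,
#'   intensity units.
#' @param fission_snap minutes before fission during which the length shows
#'   the sharp pre-division peak at the fission length.
#' @param border_halfwidth half-width of the dark contour line, pixels.
#' @param bg_level,border_level,interior_level 8-bit intensity levels.
#' @param advection_max advection speed at the outlet, px/frame (linear ramp
#'   from 0 at the sieve).
#' @param cell_gap minimal clearance between neighbouring cell surfaces, px.
#' @param initial_fill fraction of each lane filled at t = 0.
#' @param founder_age_frac cycle phase of the founder cells at t = 0 as a
#'   fraction of their doubling time; `NULL` (default) draws phases
#'   uniformly (an unsynchronised culture), 0 starts founders as newborns.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param bit_depth 8 or 16.
#' @param seed RNG seed used by [simulate_colony()].
#' @return object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_lanes = 5L,
                       lane_width = 24L,
                       lane_length = 1500L,
                       wall_width = 3L,
                       n_frames = 360L,
                       frame_interval = 1,
                       pixel_size = 0.2304,
                       mean_fission_length = 14.2,
                       mean_division_length = 12.9,
                       mean_birth_length = mean_fission_length / 2,
                       mean_elongation_time = 94.3,
                       mean_septation_time = 35,
                       cv_lengths = 0.10,
                       cv_times = 0.18,
                       size_control_slope = 0.61,
                       division_asymmetry_sd = 0,
                       cell_width_um = 3.6,
                       septum_frac = 0.5,
                       septum_peak_delay = 14,
                       septum_fall_time = 4,
                       septum_width = 2,
                       septum_peak_amp = 90,
                       fission_snap = 2,
                       border_halfwidth = 1,
                       bg_level = 128,
                       border_level = 30,
                       interior_level = 120,
                       advection_max = 1.5,
                       cell_gap = 3,
                       initial_fill = 0.55,
                       founder_age_frac = NULL,
                       noise_sd = 3,
                       bit_depth = 8L,
                       seed = 1L) {
  p <- as.list(environment())
  lens <- c(p$mean_birth_length, p$mean_division_length, p$mean_fission_length,
            p$cell_width_um, p$pixel_size)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop_param("sim_params: lengths and pixel_size must be positive")
  }
  if (p$mean_fission_length < p$mean_division_length) {
    stop_param("sim_params: fission length must be >= division length")
  }
  tims <- c(p$mean_elongation_time, p$mean_septation_time, p$frame_interval)
  if (any(!is.finite(tims)) || any(tims <= 0)) {
    stop_param("sim_params: durations and frame_interval must be positive")
  }
  if (p$cv_lengths < 0 || p$cv_times < 0) stop_param("sim_params: CVs must be >= 0")
  if (p$n_lanes < 1L || p$lane_width < 8L || p$lane_length < 50L) {
    stop_param("sim_params: implausible chamber geometry")
  }
  if (p$septum_fall_time + p$fission_snap >= p$mean_septation_time) {
    stop_param("sim_params: septation time too short for septum fall + fission snap")
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>",
      sprintf("  chamber: %d lanes x %d px, %d frames @ %g min",
              x$n_lanes, x$lane_length, x$n_frames, x$frame_interval),
      sprintf("  lengths (um): birth %.2f, division %.2f, fission %.2f (CV %.0f%%)",
              x$mean_birth_length, x$mean_division_length, x$mean_fission_length,
              100 * x$cv_lengths),
      sprintf("  times (min): elongation %.1f + septation %.1f = doubling %.1f (CV %.0f%%)",
              x$mean_elongation_time, x$mean_septation_time,
              x$mean_elongation_time + x$mean_septation_time, 100 * x$cv_times),
      sep = "\n")
  invisible(x)
}

#' Chamber lane geometry implied by simulation parameters
#'
#' @param params a [sim_params()] object.
#' @return list with `lanes` (tibble: lane, y0, y1, inclusive pixel rows),
#'   `n_rows`, `n_cols`.
#' @export
lane_geometry <- function(params) {
  w <- params$wall_width
  lw <- params$lane_width
  y0 <- w + 1L + (seq_len(params$n_lanes) - 1L) * (lw + w)
  lanes <- tibble::tibble(lane = seq_len(params$n_lanes), y0 = y0, y1 = y0 + lw - 1L)
  list(lanes = lanes,
       n_rows = params$n_lanes * (lw + w) + w,
       n_cols = as.integer(params$lane_length))
}

## sample the cycle parameters of a newborn cell of birth length Lb
draw_cycle <- function(params, Lb) {
  inc <- params$mean_fission_length - params$mean_division_length
  Ld <- params$mean_division_length +
    params$size_control_slope * (Lb - params$mean_birth_length) +
    stats::rnorm(1, 0, params$cv_lengths * params$mean_division_length)
  Ld <- max(Ld, Lb + 1)
  Lf <- Ld + max(0.2, stats::rnorm(1, inc, params$cv_lengths * inc))
  Te <- max(10, stats::rnorm(1, params$mean_elongation_time,
                             params$cv_times * params$mean_elongation_time))
  Ts <- max(params$septum_fall_time + params$fission_snap + 2,
            stats::rnorm(1, params$mean_septation_time,
                         params$cv_times * params$mean_septation_time))
  list(Ld = Ld, Lf = Lf, Te = Te, Ts = Ts, rate = (Ld - Lb) / Te)
}

## cell length (um) at age (min) for the three-phase growth law
cell_length_at <- function(age, Lb, Ld, Lf, Te, Ts, rate, snap) {
  ifelse(age < Te, Lb + rate * age,
         ifelse(age < Te + Ts - snap, Ld, Lf))
}

## septum band amplitude in [0, 1] at age (min)
septum_amp_at <- function(age, Te, Ts, params) {
  appear <- Te + params$septum_frac * Ts
  fall_start <- Te + Ts - params$septum_fall_time
  peak <- pmin(appear + params$septum_peak_delay, fall_start)
  rise <- pmax(peak - appear, 1e-9)
  a <- ifelse(age <= appear, 0,
              ifelse(age < peak, (age - appear) / rise,
                     ifelse(age < fall_start, 1,
                            pmax(0, 1 - (age - fall_start) / params$septum_fall_time))))
  clamp(a, 0, 1)
}

## rasterize cells onto a canvas; optionally produce a labelled truth mask
render_cells <- function(cells, params, canvas, mask = NULL) {
  geom <- lane_geometry(params)
  hw <- params$border_halfwidth
  nc <- geom$n_cols
  for (k in seq_len(nrow(cells))) {
    lane <- cells$lane[k]
    y0 <- geom$lanes$y0[lane]; y1 <- geom$lanes$y1[lane]
    yc <- (y0 + y1) / 2
    hl <- cells$length_um[k] / params$pixel_size / 2
    r <- cells$width_um[k] / params$pixel_size / 2
    x <- cells$x[k]
    c0 <- max(1L, floor(x - hl - hw - 1))
    c1 <- min(nc, ceiling(x + hl + hw + 1))
    if (c1 < c0) next
    px <- c0:c1
    py <- y0:y1
    dx <- pmax(abs(px - x) - (hl - r), 0)
    dy <- py - yc
    d <- sqrt(outer(dy^2, dx^2, "+")) - r
    interior <- d < -hw
    border <- !interior & d <= hw
    block <- canvas[py, px, drop = FALSE]
    block[border] <- params$border_level
    amp <- cells$septum_amp[k]
    if (amp > 0) {
      band <- amp * params$septum_peak_amp *
        exp(-(px - x)^2 / (2 * params$septum_width^2))
      vals <- params$interior_level + matrix(band, nrow = length(py),
                                             ncol = length(px), byrow = TRUE)
      block[interior] <- vals[interior]
    } else {
      block[interior] <- params$interior_level
    }
    canvas[py, px] <- block
    if (!is.null(mask)) {
      mblock <- mask[py, px, drop = FALSE]
      mblock[d <= 0] <- cells$id[k]
      mask[py, px] <- mblock
    }
  }
  list(canvas = canvas, mask = mask)
}

blank_canvas <- function(params) {
  geom <- lane_geometry(params)
  canvas <- matrix(params$bg_level, geom$n_rows, geom$n_cols)
  w <- params$wall_width
  for (i in 0:params$n_lanes) {
    r0 <- i * (params$lane_width + w) + 1L
    canvas[r0:(r0 + w - 1L), ] <- params$border_level
  }
  canvas
}

#' Render a single chamber frame from explicit cell states
#'
#' @param cells tibble/data.frame with columns `id`, `lane`, `x` (centre,
#'   px along the lane), `length_um`, `width_um`, `septum_amp` (0..1).
#'   Cells must not overlap; [simulate_colony()] guarantees this by
#'   hard-core displacement before rendering.
#' @param params a [sim_params()] object.
#' @param noise add Gaussian intensity noise of SD `params$noise_sd`?
#'   Drawn from the current RNG state.
#' @return integer intensity matrix (rows = image rows).
#' @export
render_frame <- function(cells, params, noise = TRUE) {
  canvas <- render_cells(cells, params, blank_canvas(params))$canvas
  if (noise && params$noise_sd > 0) {
    canvas <- canvas + stats::rnorm(length(canvas), 0, params$noise_sd)
  }
  top <- 2^params$bit_depth - 1
  matrix(as.integer(round(clamp(canvas, 0, top))), nrow(canvas), ncol(canvas))
}

#' Simulate a growing monolayer colony with ground truth
#'
#' Each cell elongates linearly from its birth length to its division
#' length, holds that length through a septation plateau (with a transient
#' bright septum band at mid-cell), snaps to its fission length just before
#' fission, and splits into two daughters of half the fission length
#' (optionally asymmetric). Cells advect along their lane toward the
#' outlet with position-dependent speed, never overlap (hard-core
#' displacement), and are removed once fully past the outlet.
#'
#' @param params a [sim_params()] object; `params$seed` seeds the RNG.
#' @param render render image frames? (`FALSE` gives a fast state-only run
#'   with full ground truth, useful for statistics at large n.)
#' @param keep_masks also keep per-frame labelled ground-truth masks
#'   (memory-heavy; intended for small runs).
#' @param keep_trajectories keep the per-frame trajectory table? (`FALSE`
#'   speeds up very large state-only runs that only need cycles and
#'   divisions.)
#' @return object of class `pombe_sim`: list with `stack` (list of integer
#'   matrices or NULL), `truth` (list: `trajectories`, `cycles`,
#'   `divisions`, `masks`), `params`, `geometry`.
#' @export
simulate_colony <- function(params = sim_params(), render = TRUE,
                            keep_masks = FALSE, keep_trajectories = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  geom <- lane_geometry(params)
  px <- params$pixel_size
  gap <- params$cell_gap
  next_id <- 0L
  cyc <- list()   # per-cell cycle registry
  new_cell <- function(lane, x, birth_time, Lb, parent) {
    next_id <<- next_id + 1L
    d <- draw_cycle(params, Lb)
    cyc[[next_id]] <<- list(id = next_id, parent = parent, lane = lane,
                            birth_time = birth_time, Lb = Lb, Ld = d$Ld,
                            Lf = d$Lf, Te = d$Te, Ts = d$Ts, rate = d$rate,
                            fate = "alive", d1 = NA_integer_, d2 = NA_integer_)
    list(id = next_id, lane = lane, x = x, birth_time = birth_time,
         Lb = Lb, Ld = d$Ld, Lf = d$Lf, Te = d$Te, Ts = d$Ts,
         rate = d$rate)
  }
  as_cell_df <- function(rows) {
    data.frame(id = vapply(rows, `[[`, integer(1), "id"),
               lane = vapply(rows, `[[`, integer(1), "lane"),
               x = vapply(rows, `[[`, numeric(1), "x"),
               birth_time = vapply(rows, `[[`, numeric(1), "birth_time"),
               Lb = vapply(rows, `[[`, numeric(1), "Lb"),
               Ld = vapply(rows, `[[`, numeric(1), "Ld"),
               Lf = vapply(rows, `[[`, numeric(1), "Lf"),
               Te = vapply(rows, `[[`, numeric(1), "Te"),
               Ts = vapply(rows, `[[`, numeric(1), "Ts"),
               rate = vapply(rows, `[[`, numeric(1), "rate"))
  }

  # seed lanes with cells at random cycle phases
  cells <- list()
  for (ln in seq_len(params$n_lanes)) {
    cursor <- 20
    while (cursor < params$initial_fill * params$lane_length) {
      Lb <- max(3, stats::rnorm(1, params$mean_birth_length,
                                params$cv_lengths * params$mean_birth_length))
      cl <- new_cell(ln, 0, 0, Lb, NA_integer_)
      age <- if (is.null(params$founder_age_frac)) {
        stats::runif(1, 0, cl$Te + cl$Ts)
      } else {
        params$founder_age_frac * (cl$Te + cl$Ts)
      }
      cl$birth_time <- -age
      cyc[[cl$id]]$birth_time <- -age
      len <- cell_length_at(age, cl$Lb, cl$Ld, cl$Lf, cl$Te, cl$Ts, cl$rate,
                            params$fission_snap)
      hl <- len / px / 2
      cl$x <- cursor + hl
      cursor <- cursor + 2 * hl + gap
      cells[[length(cells) + 1L]] <- cl
    }
  }
  cells <- as_cell_df(cells)

  traj <- vector("list", params$n_frames)
  divs <- list()
  stack <- if (render) vector("list", params$n_frames) else NULL
  masks <- if (keep_masks) vector("list", params$n_frames) else NULL

  for (f in seq_len(params$n_frames)) {
    t <- (f - 1) * params$frame_interval

    # fission: cells whose cycle ended by time t split into two daughters
    due <- which(t >= cells$birth_time + cells$Te + cells$Ts)
    if (length(due)) {
      newborn <- list()
      for (i in due) {
        p_id <- cells$id[i]; p_lane <- cells$lane[i]; p_x <- cells$x[i]
        p_Lf <- cells$Lf[i]
        tdiv <- cells$birth_time[i] + cells$Te[i] + cells$Ts[i]
        fl <- clamp(0.5 + stats::rnorm(1, 0, params$division_asymmetry_sd),
                    0.35, 0.65)
        if (stats::runif(1) < 0.5) fl <- 1 - fl
        Lf_px <- p_Lf / px
        d_left <- new_cell(p_lane, p_x - (1 - fl) * Lf_px / 2 - gap / 2,
                           tdiv, fl * p_Lf, p_id)
        d_right <- new_cell(p_lane, p_x + fl * Lf_px / 2 + gap / 2,
                            tdiv, (1 - fl) * p_Lf, p_id)
        cyc[[p_id]]$fate <- "divided"
        cyc[[p_id]]$d1 <- d_left$id
        cyc[[p_id]]$d2 <- d_right$id
        divs[[length(divs) + 1L]] <- list(
          parent = p_id, frame = f, d1 = d_left$id, d2 = d_right$id,
          lane = p_lane, x = p_x, fission_length = p_Lf, time = tdiv)
        newborn[[length(newborn) + 1L]] <- d_left
        newborn[[length(newborn) + 1L]] <- d_right
      }
      cells <- rbind(cells[-due, , drop = FALSE], as_cell_df(newborn))
    }

    # current lengths and septum state
    age <- t - cells$birth_time
    len <- cell_length_at(age, cells$Lb, cells$Ld, cells$Lf, cells$Te,
                          cells$Ts, cells$rate, params$fission_snap)
    samp <- septum_amp_at(age, cells$Te, cells$Ts, params)

    # advection + hard-core push toward the outlet, lane by lane; the
    # pairwise constraints x[i] >= x[i-1] + hl[i-1] + hl[i] + gap reduce
    # to a running maximum after subtracting the cumulative spacing
    hl <- len / px / 2
    v <- params$advection_max * clamp(cells$x / params$lane_length, 0, 1)
    cells$x <- cells$x + v
    for (ln in unique(cells$lane)) {
      sel <- which(cells$lane == ln)
      if (length(sel) < 2L) next
      sel <- sel[order(cells$x[sel])]
      h <- hl[sel]
      spacing <- cumsum(c(0, h[-length(h)] + h[-1] + gap))
      cells$x[sel] <- cummax(cells$x[sel] - spacing) + spacing
    }

    # elute cells fully past the outlet
    gone <- which(cells$x - hl > params$lane_length)
    if (length(gone)) {
      for (i in gone) cyc[[cells$id[i]]]$fate <- "eluted"
      cells <- cells[-gone, , drop = FALSE]
      age <- age[-gone]; len <- len[-gone]; samp <- samp[-gone]; hl <- hl[-gone]
    }

    if (keep_trajectories || render || keep_masks) {
      yc <- (geom$lanes$y0[cells$lane] + geom$lanes$y1[cells$lane]) / 2
      state <- tibble::tibble(id = cells$id, lane = cells$lane, x = cells$x,
                              y = yc, length_um = len,
                              width_um = params$cell_width_um,
                              septum_amp = samp)
      if (keep_trajectories) traj[[f]] <- tibble::tibble(frame = f, state)
    }

    if (render || keep_masks) {
      res <- render_cells(state, params, blank_canvas(params),
                          mask = if (keep_masks) matrix(0L, geom$n_rows, geom$n_cols))
      if (keep_masks) masks[[f]] <- res$mask
      if (render) {
        canvas <- res$canvas
        if (params$noise_sd > 0) {
          canvas <- canvas + stats::rnorm(length(canvas), 0, params$noise_sd)
        }
        top <- 2^params$bit_depth - 1
        stack[[f]] <- matrix(as.integer(round(clamp(canvas, 0, top))),
                             geom$n_rows, geom$n_cols)
      }
    }
  }

  for (i in seq_along(cyc)) {
    if (cyc[[i]]$fate == "alive") cyc[[i]]$fate <- "end_of_movie"
  }
  cycles <- do.call(rbind, lapply(cyc, function(z) {
    tibble::tibble(id = z$id, parent = z$parent, lane = z$lane,
                   birth_time = z$birth_time,
                   division_time = z$birth_time + z$Te + z$Ts,
                   birth_length = z$Lb, division_length = z$Ld,
                   fission_length = z$Lf, elongation_time = z$Te,
                   septation_time = z$Ts, elongation_rate = z$rate,
                   fate = z$fate, d1 = z$d1, d2 = z$d2)
  }))
  divisions <- if (length(divs)) {
    tibble::tibble(
      parent = vapply(divs, `[[`, integer(1), "parent"),
      frame = vapply(divs, `[[`, integer(1), "frame"),
      d1 = vapply(divs, `[[`, integer(1), "d1"),
      d2 = vapply(divs, `[[`, integer(1), "d2"),
      lane = vapply(divs, `[[`, integer(1), "lane"),
      x = vapply(divs, `[[`, numeric(1), "x"),
      fission_length = vapply(divs, `[[`, numeric(1), "fission_length"),
      time = vapply(divs, `[[`, numeric(1), "time"))
  } else {
    tibble::tibble(parent = integer(), frame = integer(), d1 = integer(),
                   d2 = integer(), lane = integer(), x = numeric(),
                   fission_length = numeric(), time = numeric())
  }
  truth <- list(trajectories = if (keep_trajectories) do.call(rbind, traj),
                cycles = cycles, divisions = divisions, masks = masks)
  structure(list(stack = stack, truth = truth, params = params,
                 geometry = geom),
            class = "pombe_sim")
}

#' @export
print.pombe_sim <- function(x, ...) {
  cat("<pombe_sim>",
      sprintf("  %d frames, %d cells, %d divisions, %s",
              x$params$n_frames, nrow(x$truth$cycles), nrow(x$truth$divisions),
              if (is.null(x$stack)) "state only" else "rendered"),
      sep = "\n")
  invisible(x)
}

#' Write ground truth to plain-text files
#'
#' Writes `trajectories.csv`, `cycles.csv`, `divisions.csv`, a Newick
#' lineage file `lineage.nwk` (track ids as tip/node labels), and, when
#' `params` is given, a flat `params.txt` manifest (key=value).
#'
#' @param truth the `truth` element of a [simulate_colony()] result.
#' @param dir output directory (created if missing).
#' @param params optional [sim_params()] echoed into `params.txt`.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir, params = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(truth$trajectories)) {
    utils::write.csv(truth$trajectories, file.path(dir, "trajectories.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(truth$cycles, file.path(dir, "cycles.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$divisions, file.path(dir, "divisions.csv"),
                   row.names = FALSE)
  fo <- truth_forest(truth)
  writeLines(forest_newick(fo), file.path(dir, "lineage.nwk"))
  if (!is.null(params)) {
    keep <- vapply(params, function(v) is.numeric(v) || is.character(v), logical(1))
    writeLines(sprintf("%s=%s", names(params)[keep],
                       vapply(unclass(params)[keep], format, character(1))),
               file.path(dir, "params.txt"))
  }
  invisible(dir)
}

#' Read ground truth written by [write_truth()]
#' @param dir directory containing the truth CSVs.
#' @return list with `trajectories`, `cycles`, `divisions`.
#' @export
read_truth <- function(dir) {
  rd <- function(f) tibble::as_tibble(utils::read.csv(file.path(dir, f)))
  list(trajectories = rd("trajectories.csv"),
       cycles = rd("cycles.csv"),
       divisions = rd("divisions.csv"))
}

#' Lineage forest of the ground truth
#' @param truth truth list from [simulate_colony()] or [read_truth()].
#' @return a [lineage_forest()] over ground-truth cell ids.
#' @export
truth_forest <- function(truth) {
  lineage_forest(truth$cycles$id, truth$cycles$parent)
}

#' Per-cycle growth records straight from ground truth
#'
#' Converts the generator's cycle registry into the same record layout the
#' measurement pipeline emits, restricted to complete cycles (birth and
#' fission both inside the movie). Useful for desk-scale statistical tests
#' that do not need the imaging steps.
#'
#' @param truth truth list from [simulate_colony()].
#' @return tibble of growth records.
#' @export
truth_records <- function(truth) {
  cy <- truth$cycles
  fo <- truth_forest(truth)
  dep <- forest_depths(fo)
  complete <- !is.na(cy$parent) & cy$fate == "divided"
  tibble::tibble(
    track_id = cy$id,
    lane = cy$lane,
    generation = dep[match(cy$id, fo$nodes$node)],
    birth_time = cy$birth_time,
    division_time_abs = cy$division_time,
    birth_length = cy$birth_length,
    division_length = cy$division_length,
    fission_length = cy$fission_length,
    elongation_time = cy$elongation_time,
    septation_time = cy$septation_time,
    doubling_time = cy$elongation_time + cy$septation_time,
    elongation_rate = cy$elongation_rate,
    complete = complete
  )
}
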