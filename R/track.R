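## Two-tier frame-to-frame tracking: a fast greedy local scorer with strict
## acceptance gates, backed by a global linear-assignment tracker (the
## standard LAP-with-no-match formulation, applied frame by frame) with
## position-dependent displacement constraints.

#' Tracker configuration
#'
#' The printed gates of the published pipeline are kept as defaults: local
#' score threshold 65, maximal displacement 50 px (11.52 um, about one cell
#' length), maximal area change 40%, global fallback after more than 30
#' unpaired cells, mean-displacement scale 8 px (1.85 um), reseeding every
#' 50 frames. The score-term coefficients are expressed in pixel-equivalent
#' units so that true pairs on slowly drifting cells score far below 65.
#'
#' @param local_weights coefficients for (dist, distx, disty, area
#'   difference, angular difference). Area difference is normalised by the
#'   larger area; the angular difference is the acute angle in degrees.
#' @param local_score_threshold accept a local pair only below this score.
#' @param max_displacement px; larger displacements score infinite.
#' @param max_area_change maximal relative area difference
#'   `|A1 - A2| / max(A1, A2)`.
#' @param fallback_unpaired_threshold strictly more unpaired cells than
#'   this triggers the global tracker.
#' @param fallback_mean_displacement px; larger local mean displacement
#'   triggers the global tracker.
#' @param global_weights coefficients for (length difference (um),
#'   max-normalised area difference, displacement (px)).
#' @param nomatch_cost cost of leaving a cell unassigned in the global
#'   assignment.
#' @param min_disp_max px; minimal-displacement constraint at the outlet
#'   (linear ramp from 0 at the sieve).
#' @param global_rerun_mean_displacement px; with poor pairing above this
#'   mean displacement the global tracker is re-run once with enlarged
#'   minimal displacements.
#' @param global_rerun_min_paired_fraction "too few cells paired" bound.
#' @param rerun_scale factor applied to the minimal displacements on re-run.
#' @param reseed_interval frames between reseed bookkeeping events.
#' @param restrict_to_lane forbid pairs across lanes (highway walls are
#'   impassable).
#' @param chamber_length px; lane length used by the displacement ramp
#'   (`NULL`: taken from the data).
#' @return list of class `tracker_config`.
#' @export
tracker_config <- function(local_weights = c(dist = 1, distx = 1, disty = 1,
                                             area = 20, angle = 0.5),
                           local_score_threshold = 65,
                           max_displacement = 50,
                           max_area_change = 0.40,
                           fallback_unpaired_threshold = 30,
                           fallback_mean_displacement = 8,
                           global_weights = c(length = 4, area = 20, dist = 1),
                           nomatch_cost = 65,
                           min_disp_max = 3,
                           global_rerun_mean_displacement = 8,
                           global_rerun_min_paired_fraction = 0.5,
                           rerun_scale = 2,
                           reseed_interval = 50,
                           restrict_to_lane = TRUE,
                           chamber_length = NULL) {
  cfg <- as.list(environment())
  if (any(cfg$local_weights < 0) || any(cfg$global_weights < 0)) {
    stop_param("tracker_config: weights must be non-negative")
  }
  if (cfg$max_area_change <= 0 || cfg$max_area_change >= 1) {
    stop_param("tracker_config: max_area_change must be in (0, 1)")
  }
  for (nm in c("local_score_threshold", "max_displacement",
               "fallback_unpaired_threshold", "fallback_mean_displacement",
               "reseed_interval")) {
    if (cfg[[nm]] <= 0) stop_param("tracker_config: ", nm, " must be > 0")
  }
  structure(cfg, class = "tracker_config")
}

acute_angle <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Local pairing score between two observations
#'
#' Weighted sum of centroid distance, |dx|, |dy|, normalised area
#' difference and acute angular difference; infinite when the displacement
#' exceeds about one cell length (`max_displacement`, 50 px). Zero for
#' identical observations.
#'
#' @param a,b one-row observation tibbles from consecutive frames.
#' @param cfg a [tracker_config()].
#' @return non-negative score (possibly `Inf`).
#' @export
local_score <- function(a, b, cfg = tracker_config()) {
  w <- cfg$local_weights
  dx <- abs(a$x - b$x); dy <- abs(a$y - b$y)
  d <- sqrt(dx^2 + dy^2)
  s <- w[["dist"]] * d + w[["distx"]] * dx + w[["disty"]] * dy +
    w[["area"]] * abs(a$area - b$area) / pmax(a$area, b$area) +
    w[["angle"]] * acute_angle(a$orientation, b$orientation)
  s[d > cfg$max_displacement] <- Inf
  unname(s)
}

#' Global pairing score between two observations
#'
#' Weighted sum of length difference, area difference normalised by the
#' maximum area of the two cells, and displacement. Zero for identical
#' observations.
#'
#' @inheritParams local_score
#' @return non-negative score.
#' @export
global_score <- function(a, b, cfg = tracker_config()) {
  w <- cfg$global_weights
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  unname(w[["length"]] * abs(a$length_um - b$length_um) +
           w[["area"]] * abs(a$area - b$area) / pmax(a$area, b$area) +
           w[["dist"]] * d)
}

## all candidate pairs between two observation tables, with geometry terms
candidate_pairs <- function(a, b, cfg) {
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  if (cfg$restrict_to_lane) {
    keep <- a$lane[ia] == b$lane[ib]
    ia <- ia[keep]; ib <- ib[keep]
  }
  dx <- abs(a$x[ia] - b$x[ib]); dy <- abs(a$y[ia] - b$y[ib])
  disp <- sqrt(dx^2 + dy^2)
  keep <- disp <= cfg$max_displacement
  list(ia = ia[keep], ib = ib[keep], dx = dx[keep], dy = dy[keep],
       disp = disp[keep])
}

empty_pairs <- function() {
  tibble::tibble(obs_a = integer(), obs_b = integer(), score = numeric(),
                 displacement = numeric())
}

pairing_result <- function(pairs, a, b, tracker, reruns = 0L) {
  structure(list(
    pairs = pairs,
    unpaired_a = setdiff(a$obs_id, pairs$obs_a),
    unpaired_b = setdiff(b$obs_id, pairs$obs_b),
    tracker = tracker,
    mean_displacement = if (nrow(pairs)) mean(pairs$displacement) else NA_real_,
    n_a = nrow(a), n_b = nrow(b), reruns = reruns
  ), class = "pairing_result")
}

#' Greedy local matching between consecutive frames
#'
#' Candidate pairs are taken in ascending score order; a pair is accepted
#' only if its score is below the threshold (65), the two contours overlap,
#' and their areas differ by at most 40%. Cells failing the gates for every
#' candidate are left unpaired rather than guessed. Ties are broken by
#' smaller displacement, then lower observation ids.
#'
#' @param a,b observation tibbles for frames n and n + 1.
#' @param cfg a [tracker_config()].
#' @return a `pairing_result`: `pairs` (tibble `obs_a`, `obs_b`, `score`,
#'   `displacement`), `unpaired_a`, `unpaired_b`, `tracker`,
#'   `mean_displacement`.
#' @export
match_local <- function(a, b, cfg = tracker_config()) {
  if (!nrow(a) || !nrow(b)) {
    return(pairing_result(empty_pairs(), a, b, "local"))
  }
  cp <- candidate_pairs(a, b, cfg)
  if (!length(cp$ia)) return(pairing_result(empty_pairs(), a, b, "local"))
  w <- cfg$local_weights
  area_diff <- abs(a$area[cp$ia] - b$area[cp$ib]) /
    pmax(a$area[cp$ia], b$area[cp$ib])
  score <- w[["dist"]] * cp$disp + w[["distx"]] * cp$dx +
    w[["disty"]] * cp$dy + w[["area"]] * area_diff +
    w[["angle"]] * acute_angle(a$orientation[cp$ia], b$orientation[cp$ib])
  overlap <- a$x0[cp$ia] <= b$x1[cp$ib] & b$x0[cp$ib] <= a$x1[cp$ia] &
    a$y0[cp$ia] <= b$y1[cp$ib] & b$y0[cp$ib] <= a$y1[cp$ia]
  ok <- score < cfg$local_score_threshold & overlap &
    area_diff <= cfg$max_area_change
  ord <- order(score, cp$disp, a$obs_id[cp$ia], b$obs_id[cp$ib])
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  sel <- integer(0)
  for (k in ord) {
    if (!ok[k]) next
    if (used_a[cp$ia[k]] || used_b[cp$ib[k]]) next
    used_a[cp$ia[k]] <- TRUE
    used_b[cp$ib[k]] <- TRUE
    sel <- c(sel, k)
  }
  pairs <- tibble::tibble(obs_a = a$obs_id[cp$ia[sel]],
                          obs_b = b$obs_id[cp$ib[sel]],
                          score = score[sel],
                          displacement = cp$disp[sel])
  pairing_result(pairs, a, b, "local")
}

#' Should the global tracker replace this local pairing?
#'
#' True iff strictly more than `fallback_unpaired_threshold` (30) cells of
#' frame n are unpaired, or the mean displacement of the paired cells
#' exceeds `fallback_mean_displacement`.
#'
#' @param res a `pairing_result` from [match_local()].
#' @param cfg a [tracker_config()].
#' @return logical.
#' @export
needs_global_fallback <- function(res, cfg = tracker_config()) {
  too_many <- length(res$unpaired_a) > cfg$fallback_unpaired_threshold
  too_far <- is.finite(res$mean_displacement) &&
    res$mean_displacement > cfg$fallback_mean_displacement
  too_many || too_far
}

#' Global linear-assignment matching between consecutive frames
#'
#' Minimises the total global score over all pairings with a no-match
#' alternative per cell (cost `nomatch_cost`). Pairs whose displacement
#' exceeds `max_displacement`, crosses a lane, or falls below the
#' position-dependent minimal displacement (a linear ramp from 0 at the
#' sieve to `min_disp_max` at the outlet) are forbidden. If fewer than
#' `global_rerun_min_paired_fraction` of the cells pair and the mean
#' displacement of the paired cells exceeds 8 px, the assignment is re-run
#' once with minimal displacements enlarged by `rerun_scale`.
#'
#' @inheritParams match_local
#' @return a `pairing_result` with `tracker = "global"`.
#' @export
match_global <- function(a, b, cfg = tracker_config()) {
  if (!nrow(a) || !nrow(b)) {
    return(pairing_result(empty_pairs(), a, b, "global"))
  }
  chamber <- cfg$chamber_length
  if (is.null(chamber)) chamber <- max(a$x1, b$x1)
  run <- function(scale) {
    n <- nrow(a); m <- nrow(b)
    BIG <- lap_big()
    C <- matrix(BIG, n + m, m + n)
    cp <- candidate_pairs(a, b, cfg)
    if (length(cp$ia)) {
      w <- cfg$global_weights
      score <- w[["length"]] * abs(a$length_um[cp$ia] - b$length_um[cp$ib]) +
        w[["area"]] * abs(a$area[cp$ia] - b$area[cp$ib]) /
          pmax(a$area[cp$ia], b$area[cp$ib]) +
        w[["dist"]] * cp$disp
      min_disp <- scale * cfg$min_disp_max * clamp(a$x[cp$ia] / chamber, 0, 1)
      allowed <- cp$disp >= min_disp
      C[cbind(cp$ia[allowed], cp$ib[allowed])] <- score[allowed]
    }
    C[cbind(seq_len(n), m + seq_len(n))] <- cfg$nomatch_cost
    C[cbind(n + seq_len(m), seq_len(m))] <- cfg$nomatch_cost
    C[n + seq_len(m), m + seq_len(n)] <- 0
    assign <- solve_lap(C)
    ia <- which(assign[seq_len(n)] <= m)
    ib <- assign[ia]
    real <- C[cbind(ia, ib)] < BIG
    ia <- ia[real]; ib <- ib[real]
    disp <- sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2)
    tibble::tibble(obs_a = a$obs_id[ia], obs_b = b$obs_id[ib],
                   score = C[cbind(ia, ib)], displacement = disp)
  }
  pairs <- run(1)
  reruns <- 0L
  frac <- nrow(pairs) / min(nrow(a), nrow(b))
  md <- if (nrow(pairs)) mean(pairs$displacement) else NA_real_
  if (frac < cfg$global_rerun_min_paired_fraction && is.finite(md) &&
      md > cfg$global_rerun_mean_displacement) {
    pairs <- run(cfg$rerun_scale)
    reruns <- 1L
  }
  pairing_result(pairs, a, b, "global", reruns = reruns)
}

#' Track a segmented movie
#'
#' Frame-by-frame matching (local tracker, replaced by the global tracker
#' whenever [needs_global_fallback()] fires), linked into tracks. An
#' observation with no accepted predecessor starts a new track immediately
#' with a fresh id, so daughter tracks exist from the division frame on;
#' `reseed_interval` marks the bookkeeping cadence reported in the
#' diagnostics. A track ends when its observation has no accepted
#' successor.
#'
#' @param segmented result of [segment_movie()] (or any list with an
#'   `observations` tibble).
#' @param cfg a [tracker_config()].
#' @return object of class `track_matrix`: `tracks` (tibble `track_id`,
#'   `frame`, `obs_id`), `links`, `diagnostics`, `observations`.
#' @export
track_movie <- function(segmented, cfg = tracker_config()) {
  obs <- segmented$observations
  frames <- sort(unique(obs$frame))
  by_frame <- split(obs, obs$frame)
  links <- list()
  diags <- list()
  for (k in seq_along(frames)[-length(frames)]) {
    if (frames[k + 1] != frames[k] + 1L) next  # only adjacent frames link
    a <- by_frame[[as.character(frames[k])]]
    b <- by_frame[[as.character(frames[k + 1])]]
    res <- match_local(a, b, cfg)
    if (needs_global_fallback(res, cfg)) res <- match_global(a, b, cfg)
    if (nrow(res$pairs)) {
      links[[length(links) + 1L]] <-
        tibble::tibble(frame = frames[k], res$pairs, tracker = res$tracker)
    }
    diags[[length(diags) + 1L]] <- tibble::tibble(
      frame = frames[k], tracker = res$tracker,
      n_pairs = nrow(res$pairs),
      n_unpaired_a = length(res$unpaired_a),
      n_unpaired_b = length(res$unpaired_b),
      mean_displacement = res$mean_displacement,
      reseed_event = (frames[k] %% cfg$reseed_interval) == 0L)
  }
  links <- if (length(links)) do.call(rbind, links) else {
    tibble::tibble(frame = integer(), obs_a = integer(), obs_b = integer(),
                   score = numeric(), displacement = numeric(),
                   tracker = character())
  }
  # assemble chains: track id propagates along links, fresh id otherwise
  track_of <- integer(0)
  track_of[obs$obs_id] <- NA_integer_
  next_track <- 0L
  pred <- integer(0)
  pred[links$obs_b] <- links$obs_a
  for (f in frames) {
    ids <- by_frame[[as.character(f)]]$obs_id
    for (id in ids) {
      p <- if (id <= length(pred)) pred[id] else NA_integer_
      if (!is.na(p) && !is.na(track_of[p])) {
        track_of[id] <- track_of[p]
      } else {
        next_track <- next_track + 1L
        track_of[id] <- next_track
      }
    }
  }
  tracks <- tibble::tibble(track_id = track_of[obs$obs_id],
                           frame = obs$frame, obs_id = obs$obs_id)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  structure(list(tracks = tracks, links = links,
                 diagnostics = do.call(rbind, diags),
                 observations = obs, cfg = cfg),
            class = "track_matrix")
}

#' @export
print.track_matrix <- function(x, ...) {
  cat(sprintf("<track_matrix> %d tracks over %d frames (%d observations)\n",
              length(unique(x$tracks$track_id)),
              length(unique(x$tracks$frame)), nrow(x$tracks)))
  invisible(x)
}
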