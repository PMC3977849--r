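## Division detection: Mexican-hat (Ricker) filtering of lengthwise
## intensity profiles, septum traces, division calls, and assembly of
## tracks + divisions into lineage forests.

#' Division-detection configuration
#'
#' @param kernel_width Ricker kernel scale (SD, px), matched to the septum
#'   band width.
#' @param appearance_k septum appearance threshold: baseline + `k` * MAD of
#'   the per-track response.
#' @param min_peak_response absolute floor on the peak response (intensity
#'   units) so flat noisy traces never fire.
#' @param mid_band maximal |position - 0.5| of the response maximum for it
#'   to count as a septum (fraction of cell length).
#' @param min_episode_frames minimal number of consecutive supra-threshold
#'   frames.
#' @param plateau_frac septum frames must carry at least this fraction of
#'   the track's maximal length (septation happens on the length plateau).
#' @param fall_frames a track ending within this many frames of the last
#'   supra-threshold frame counts as fission-with-septum-still-visible
#'   (the septum falls to background within ~4 min).
#' @param daughter_window daughters must start within this many frames of
#'   the division frame.
#' @param daughter_margin bbox expansion (px) when searching for daughters.
#' @return list of class `division_config`.
#' @export
division_config <- function(kernel_width = 3,
                            appearance_k = 5,
                            min_peak_response = 20,
                            mid_band = 0.2,
                            min_episode_frames = 3L,
                            plateau_frac = 0.85,
                            fall_frames = 4L,
                            daughter_window = 2L,
                            daughter_margin = 6) {
  structure(as.list(environment()), class = "division_config")
}

#' Mexican-hat (Ricker) kernel
#'
#' Zero-mean, unit-L2-norm Ricker wavelet sampled at 1-px steps. The exact
#' zero mean guarantees a flat profile convolves to exactly zero.
#'
#' @param width kernel scale (SD), px.
#' @param radius half-support, px (default `ceiling(3.5 * width)`).
#' @return numeric kernel of length `2 * radius + 1`.
#' @export
ricker_kernel <- function(width, radius = ceiling(3.5 * width)) {
  t <- (-radius):radius
  k <- (1 - (t / width)^2) * exp(-t^2 / (2 * width^2))
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' Convolve a lengthwise intensity profile with a Ricker kernel
#'
#' @param profile numeric intensity profile sampled at 1-px steps along the
#'   cell axis.
#' @param width kernel scale, px.
#' @return list with `response` (same length as `profile`; `NA` where the
#'   kernel support leaves the profile), `argmax` (index), `position`
#'   (argmax as a fraction of the profile length), `max` (peak response).
#' @export
ricker_response <- function(profile, width = 3) {
  k <- ricker_kernel(width)
  n <- length(profile)
  if (n < length(k)) {
    stop_param("ricker_response: profile (", n,
               ") shorter than kernel support (", length(k), ")")
  }
  resp <- as.numeric(stats::filter(profile, k, sides = 2))
  valid <- which(!is.na(resp))
  am <- valid[which.max(resp[valid])]
  list(response = resp, argmax = am, position = (am - 0.5) / n,
       max = resp[am])
}

#' Septum trace of a track
#'
#' Per-frame position and magnitude of the Ricker response maximum, with a
#' 3-frame running median on the magnitude to suppress single-frame
#' glitches (at 1 frame/min the 4-min septum fall spans several frames).
#' Frames whose profile is shorter than the kernel support give `NA`.
#'
#' @param frames frame indices of the track (ascending).
#' @param profiles list of lengthwise profiles, one per frame.
#' @param cfg a [division_config()].
#' @return tibble `frame`, `position`, `response`.
#' @export
septum_trace <- function(frames, profiles, cfg = division_config()) {
  k_len <- 2 * ceiling(3.5 * cfg$kernel_width) + 1
  pos <- resp <- rep(NA_real_, length(frames))
  for (i in seq_along(frames)) {
    p <- profiles[[i]]
    if (length(p) >= k_len) {
      r <- ricker_response(p, cfg$kernel_width)
      pos[i] <- r$position
      resp[i] <- r$max
    }
  }
  tibble::tibble(frame = frames, position = pos, response = runmed3(resp))
}

#' Call a division from a septum trace
#'
#' A division is called when the trace shows a single septum episode: the
#' response exceeds baseline + `appearance_k` * MAD (and an absolute
#' floor), stays near mid-cell, coincides with the length plateau, peaks,
#' and then either falls back to baseline within the track (the fission
#' frame) or the track ends within `fall_frames` of the peak (the parent
#' contour split, so the fission frame is the first frame after the
#' track). Ambiguous traces with two distinct episodes give no call.
#'
#' @param trace tibble from [septum_trace()].
#' @param lengths per-frame cell lengths (um), aligned with `trace`.
#' @param cfg a [division_config()].
#' @return `NULL`, or a list with `division_frame`, `peak_frame`,
#'   `peak_response`, `septum_position`.
#' @export
call_division <- function(trace, lengths, cfg = division_config()) {
  resp <- trace$response
  ok <- !is.na(resp)
  if (sum(ok) < cfg$min_episode_frames + 2L) return(NULL)
  # baseline from sub-floor frames so a septum episode spanning most of a
  # (truncated) track cannot contaminate its own reference level
  quiet <- ok & resp < cfg$min_peak_response
  if (sum(quiet) >= 3L) {
    base <- stats::median(resp[quiet])
    s <- stats::mad(resp[quiet])
  } else {
    base <- 0
    s <- 1
  }
  thr <- max(base + cfg$appearance_k * s, cfg$min_peak_response)
  Lmax <- max(lengths)
  hot <- ok & resp > thr & !is.na(trace$position) &
    abs(trace$position - 0.5) <= cfg$mid_band &
    lengths >= cfg$plateau_frac * Lmax
  if (!any(hot)) return(NULL)
  runs <- rle(hot)
  ridx <- which(runs$values & runs$lengths >= cfg$min_episode_frames)
  if (length(ridx) != 1L) return(NULL)   # none long enough, or ambiguous
  ends <- cumsum(runs$lengths)
  i1 <- ends[ridx] - runs$lengths[ridx] + 1L
  i2 <- ends[ridx]
  peak_i <- (i1:i2)[which.max(resp[i1:i2])]
  # fission: response back at baseline, or the parent contour split (track end)
  # "complete disappearance": back within noise of baseline. During the
  # 4-min fall the response stays far above this, so a cell that splits
  # before the septum fully vanishes ends its track first (div = end + 1).
  fall_thr <- base + max(2 * s, 3)
  after <- which(seq_along(resp) > peak_i & ok & resp < fall_thr)
  n <- length(resp)
  if (length(after)) {
    div_i <- after[1]
    div_frame <- trace$frame[div_i]
  } else if (n - i2 <= cfg$fall_frames) {
    # septum still present when the contour split: fission is the first
    # frame after the parent track
    div_frame <- trace$frame[n] + 1L
  } else {
    return(NULL)
  }
  list(division_frame = div_frame,
       peak_frame = trace$frame[peak_i],
       peak_response = resp[peak_i],
       septum_position = trace$position[peak_i])
}

## per-track observation table (ordered by frame), as a list of tibbles
split_tracks <- function(tm) {
  tr <- tm$tracks
  obs <- tm$observations
  o <- obs[match(tr$obs_id, obs$obs_id), ]
  split(o, tr$track_id)
}

#' Detect division events in a tracked movie
#'
#' Runs [septum_trace()] and [call_division()] on every track, then
#' identifies the two daughter tracks: tracks starting within
#' `daughter_window` frames of the division whose first observation
#' overlaps the parent's final bounding box, assigned to the two sides of
#' the septum by position. Events without two identifiable daughters are
#' dropped (reported in the attribute `log`).
#'
#' @param tm a [track_movie()] result.
#' @param cfg a [division_config()].
#' @return tibble of division events: `parent_track`, `division_frame`,
#'   `daughter1`, `daughter2`, `peak_frame`, `peak_response`,
#'   `septum_position`; attribute `log` counts calls and drop reasons.
#' @export
detect_divisions <- function(tm, cfg = division_config()) {
  tracks <- split_tracks(tm)
  starts <- vapply(tracks, function(t) t$frame[1], numeric(1))
  start_frame <- as.numeric(starts)
  track_ids <- as.integer(names(tracks))
  events <- list()
  n_called <- 0L; n_no_daughters <- 0L
  claimed <- integer(0)
  # process calls in division-frame order so simultaneous divisions of
  # neighbouring cells cannot claim each other's daughters
  calls <- list()
  for (ti in seq_along(tracks)) {
    t <- tracks[[ti]]
    if (nrow(t) < cfg$min_episode_frames + 2L) next
    trace <- septum_trace(t$frame, t$profile, cfg)
    ev <- call_division(trace, t$length_um, cfg)
    if (is.null(ev)) next
    n_called <- n_called + 1L
    calls[[length(calls) + 1L]] <- c(ev, list(ti = ti))
  }
  calls <- calls[order(vapply(calls, `[[`, numeric(1), "division_frame"))]
  for (ev in calls) {
    t <- tracks[[ev$ti]]
    last <- t[nrow(t), ]
    cut_x <- last$x0 + ev$septum_position * (last$x1 - last$x0)
    cand <- which(start_frame >= ev$division_frame &
                    start_frame <= ev$division_frame + cfg$daughter_window &
                    track_ids != track_ids[ev$ti] &
                    !(track_ids %in% claimed))
    lefts <- rights <- numeric(0)
    left_ov <- right_ov <- numeric(0)
    for (ci in cand) {
      fo <- tracks[[ci]][1, ]
      if (fo$lane != last$lane) next
      # genuine overlap with the parent's final contour (small slack for
      # one frame of advection)
      ov <- min(fo$x1, last$x1) - max(fo$x0, last$x0)
      if (ov <= -cfg$daughter_margin) next
      centre <- (fo$x0 + fo$x1) / 2
      if (centre <= cut_x) {
        lefts <- c(lefts, track_ids[ci]); left_ov <- c(left_ov, ov)
      } else {
        rights <- c(rights, track_ids[ci]); right_ov <- c(right_ov, ov)
      }
    }
    if (!length(lefts) || !length(rights)) {
      n_no_daughters <- n_no_daughters + 1L
      next
    }
    d1 <- lefts[which.max(left_ov)]
    d2 <- rights[which.max(right_ov)]
    claimed <- c(claimed, d1, d2)
    events[[length(events) + 1L]] <- tibble::tibble(
      parent_track = track_ids[ev$ti],
      division_frame = ev$division_frame,
      daughter1 = d1, daughter2 = d2,
      peak_frame = ev$peak_frame,
      peak_response = ev$peak_response,
      septum_position = ev$septum_position)
  }
  out <- if (length(events)) do.call(rbind, events) else {
    tibble::tibble(parent_track = integer(), division_frame = integer(),
                   daughter1 = integer(), daughter2 = integer(),
                   peak_frame = integer(), peak_response = numeric(),
                   septum_position = numeric())
  }
  attr(out, "log") <- list(n_called = n_called,
                           n_without_daughters = n_no_daughters)
  out
}

#' Build a lineage forest from tracks and division events
#'
#' Each division links a parent track to its two daughter tracks; tracks
#' with no detected parent (movie founders, reseeded tracks) become roots.
#' A daughter claimed by two events keeps the earlier one.
#'
#' @param tm a [track_movie()] result.
#' @param divisions tibble from [detect_divisions()].
#' @return a [lineage_forest()] over track ids.
#' @export
build_forest <- function(tm, divisions) {
  nodes <- sort(unique(tm$tracks$track_id))
  parent <- rep(NA_integer_, length(nodes))
  if (nrow(divisions)) {
    dv <- divisions[order(divisions$division_frame), ]
    for (i in seq_len(nrow(dv))) {
      for (d in c(dv$daughter1[i], dv$daughter2[i])) {
        j <- match(d, nodes)
        if (!is.na(j) && is.na(parent[j])) parent[j] <- dv$parent_track[i]
      }
    }
  }
  lineage_forest(nodes, parent)
}
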