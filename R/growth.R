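## Per-cycle growth parameters and population statistics: plateau
## detection, growth records (birth/division/fission length, elongation/
## septation/doubling time, elongation rate), summaries, temperature-shift
## alignment, birth-vs-division regression, and sister-pair tables.

#' Growth-extraction configuration
#'
#' @param head_exclude frames after birth excluded from fits (newly split
#'   sisters can still appear linked, inflating the first lengths).
#' @param fission_exclude frames before division excluded from the plateau
#'   fit (the terminal snap to fission length).
#' @param fission_window frames before division searched for the fission
#'   length (the maximum of the terminal length peak).
#' @param min_cycle_frames shortest usable birth-to-division track.
#' @param min_plateau_frames minimal plateau length for a valid changepoint.
#' @param min_rate minimal believable elongation rate, um/min.
#' @return list of class `growth_config`.
#' @export
growth_config <- function(head_exclude = 3L,
                          fission_exclude = 3L,
                          fission_window = 10L,
                          min_cycle_frames = 12L,
                          min_plateau_frames = 4L,
                          min_rate = 0.005) {
  structure(as.list(environment()), class = "growth_config")
}

#' Detect the growth plateau of a length series
#'
#' Fits a two-segment model (linear elongation ramp, then a flat plateau)
#' by exact least-squares over all changepoints; the plateau start is the
#' first frame of the flat segment and the division length is the mean
#' plateau length. The first `head_exclude` and last `fission_exclude`
#' frames are ignored (linked-newborn artifact; terminal fission peak).
#' Series with no flat segment (truncated cycles) return `NULL`.
#'
#' @param lengths per-frame lengths, um.
#' @param cfg a [growth_config()].
#' @return `NULL`, or list with `plateau_start` (index into `lengths`),
#'   `division_length` (um), `elongation_rate` (um/frame, ramp slope).
#' @export
detect_plateau <- function(lengths, cfg = growth_config()) {
  n <- length(lengths)
  i0 <- cfg$head_exclude + 1L
  i1 <- n - cfg$fission_exclude
  if (i1 - i0 + 1L < cfg$min_cycle_frames) return(NULL)
  y <- lengths[i0:i1]
  m <- length(y)
  t <- seq_len(m)
  # cumulative sums give O(1) segment SSE for every candidate changepoint
  cy <- cumsum(y); cy2 <- cumsum(y^2); cty <- cumsum(t * y)
  ct <- cumsum(t); ct2 <- cumsum(t^2)
  best <- NULL
  ks <- 3L:(m - cfg$min_plateau_frames)
  if (!length(ks)) return(NULL)
  sse <- rep(Inf, length(ks))
  slope <- numeric(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    # ramp on 1..k
    sx <- ct[k]; sxx <- ct2[k]; sy <- cy[k]; syy <- cy2[k]; sxy <- cty[k]
    den <- k * sxx - sx^2
    b <- if (den > 0) (k * sxy - sx * sy) / den else 0
    a <- (sy - b * sx) / k
    sse1 <- syy - 2 * a * sy - 2 * b * sxy + k * a^2 + 2 * a * b * sx + b^2 * sxx
    # plateau on (k+1)..m
    np <- m - k
    py <- cy[m] - cy[k]; pyy <- cy2[m] - cy2[k]
    sse2 <- pyy - py^2 / np
    sse[j] <- sse1 + sse2
    slope[j] <- b
  }
  # earliest changepoint among (numerically) tied fits: growth "ceases"
  # at the first flat frame
  j <- which(sse <= min(sse) + 1e-9)[1]
  k <- ks[j]
  if (slope[j] < cfg$min_rate) return(NULL)
  plateau_mean <- (cy[m] - cy[k]) / (m - k)
  # a genuine plateau must flatten relative to the ramp: reject monotone
  # series whose best "plateau" still climbs at a comparable rate
  pl <- y[(k + 1L):m]
  pslope <- ols_line(seq_along(pl), pl)[["slope"]]
  if (abs(pslope) > 0.4 * slope[j]) return(NULL)
  list(plateau_start = i0 + k,      # first flat frame, index into `lengths`
       division_length = plateau_mean,
       elongation_rate = slope[j])
}

#' Extract a growth record from one tracked cell cycle
#'
#' @param lengths per-frame lengths (um) from the birth frame to the last
#'   frame before fission.
#' @param birth_frame,division_frame absolute frame indices (the division
#'   frame is the first frame of the daughters).
#' @param frame_interval minutes per frame.
#' @param cfg a [growth_config()].
#' @return one-row tibble; `complete = FALSE` (with `NA` parameters) when
#'   no plateau is found.
#' @export
extract_record <- function(lengths, birth_frame, division_frame,
                           frame_interval = 1, cfg = growth_config()) {
  empty <- tibble::tibble(
    birth_time = (birth_frame - 1) * frame_interval,
    division_time_abs = (division_frame - 1) * frame_interval,
    birth_length = lengths[1], division_length = NA_real_,
    fission_length = NA_real_, elongation_time = NA_real_,
    septation_time = NA_real_, doubling_time = NA_real_,
    elongation_rate = NA_real_, complete = FALSE)
  pl <- detect_plateau(lengths, cfg)
  if (is.null(pl)) return(empty)
  n <- length(lengths)
  plateau_abs <- birth_frame + pl$plateau_start - 1L
  elongation_time <- (plateau_abs - birth_frame) * frame_interval
  septation_time <- (division_frame - plateau_abs) * frame_interval
  if (septation_time <= 0) return(empty)
  ramp <- (cfg$head_exclude + 1L):(pl$plateau_start - 1L)
  rate <- if (length(ramp) >= 4L) {
    ols_line(ramp * frame_interval, lengths[ramp])[["slope"]]
  } else {
    pl$elongation_rate / frame_interval
  }
  fission <- max(lengths[max(1L, n - cfg$fission_window + 1L):n])
  tibble::tibble(
    birth_time = (birth_frame - 1) * frame_interval,
    division_time_abs = (division_frame - 1) * frame_interval,
    birth_length = lengths[1],
    division_length = pl$division_length,
    fission_length = fission,
    elongation_time = elongation_time,
    septation_time = septation_time,
    doubling_time = elongation_time + septation_time,
    elongation_rate = rate,
    complete = TRUE)
}

#' Growth records for every tracked cycle of a movie
#'
#' A cycle is complete when the track starts at a detected division (its
#' birth) and ends at its own detected division; founders, reseeded tracks
#' and eluted cells are emitted with `complete = FALSE` and excluded from
#' summaries. Generations are depths in the lineage forest.
#'
#' @param tm a [track_movie()] result.
#' @param divisions tibble from [detect_divisions()].
#' @param forest optional [build_forest()] result (built if missing).
#' @param frame_interval minutes per frame.
#' @param cfg a [growth_config()].
#' @param require_birth_division when `FALSE`, tracks starting at the first
#'   movie frame are also treated as observed births (useful for
#'   controlled single-cell simulations).
#' @return tibble of growth records (one row per track with a division
#'   out; see [extract_record()]), plus `track_id`, `lane`, `generation`.
#' @export
records_from_tracks <- function(tm, divisions, forest = NULL,
                                frame_interval = 1, cfg = growth_config(),
                                require_birth_division = TRUE) {
  if (is.null(forest)) forest <- build_forest(tm, divisions)
  depths <- forest_depths(forest)
  tracks <- split_tracks(tm)
  track_ids <- as.integer(names(tracks))
  born_at_division <- c(divisions$daughter1, divisions$daughter2)
  div_of_parent <- stats::setNames(divisions$division_frame,
                                   divisions$parent_track)
  rows <- list()
  for (i in seq_along(tracks)) {
    t <- tracks[[i]]
    id <- track_ids[i]
    dframe <- div_of_parent[as.character(id)]
    if (is.na(dframe)) next
    birth_ok <- id %in% born_at_division ||
      (!require_birth_division && t$frame[1] == 1L)
    rec <- extract_record(t$length_um, t$frame[1], unname(dframe),
                          frame_interval, cfg)
    rec$complete <- rec$complete && birth_ok
    rows[[length(rows) + 1L]] <- tibble::tibble(
      track_id = id, lane = t$lane[1],
      generation = depths[match(id, forest$nodes$node)], rec)
  }
  if (!length(rows)) {
    return(tibble::tibble(track_id = integer(), lane = integer(),
                          generation = integer(), birth_time = numeric(),
                          division_time_abs = numeric(),
                          birth_length = numeric(),
                          division_length = numeric(),
                          fission_length = numeric(),
                          elongation_time = numeric(),
                          septation_time = numeric(),
                          doubling_time = numeric(),
                          elongation_rate = numeric(), complete = logical()))
  }
  do.call(rbind, rows)
}

growth_parameters <- c("birth_length", "division_length", "fission_length",
                       "elongation_time", "septation_time", "doubling_time",
                       "elongation_rate")

#' Population summary of growth records
#'
#' Mean, SD, CV and n for each growth parameter, optionally split by a
#' condition label (e.g. pre/post temperature shift). Incomplete records
#' are excluded.
#'
#' @param records tibble from [records_from_tracks()] or [truth_records()].
#' @param condition optional factor/character vector aligned with
#'   `records`, or the name of a column in `records`.
#' @return tibble `parameter`, `condition`, `mean`, `sd`, `cv`, `n`.
#' @export
summarize_records <- function(records, condition = NULL) {
  if (is.character(condition) && length(condition) == 1L &&
      condition %in% names(records)) {
    condition <- records[[condition]]
  }
  if (is.null(condition)) condition <- rep("all", nrow(records))
  keep <- records$complete
  records <- records[keep, , drop = FALSE]
  condition <- condition[keep]
  out <- list()
  for (cond in unique(condition)) {
    sub <- records[condition == cond, , drop = FALSE]
    if (!nrow(sub)) {
      warning("summarize_records: empty condition '", cond, "' omitted")
      next
    }
    for (p in growth_parameters) {
      v <- sub[[p]]
      m <- mean(v)
      s <- stats::sd(v)
      out[[length(out) + 1L]] <- tibble::tibble(
        parameter = p, condition = cond, mean = m,
        sd = ifelse(is.na(s), 0, s),
        cv = ifelse(m != 0, ifelse(is.na(s), 0, s) / m, NA_real_),
        n = length(v))
    }
  }
  do.call(rbind, out)
}

#' Align growth records to a temperature (or medium) shift
#'
#' Adds `fraction_of_cycle_after_shift`: the fraction of the division cycle
#' spent after the shift, `(division_time - t_shift) / doubling_time`
#' clipped to `[0, 1]` (0 = cycle entirely before the shift, 1 = entirely
#' after), and computes moving average / SD series of each parameter
#' against absolute division time.
#'
#' @param records growth records.
#' @param t_shift shift time, minutes.
#' @param window moving-average window, minutes.
#' @return list with `records` (augmented) and `series` (tibble
#'   `parameter`, `time`, `mean`, `sd`, `n`).
#' @export
align_to_shift <- function(records, t_shift, window = 30) {
  frac <- clamp((records$division_time_abs - t_shift) /
                  records$doubling_time, 0, 1)
  records$fraction_of_cycle_after_shift <- frac
  cmp <- records[records$complete, , drop = FALSE]
  series <- list()
  if (nrow(cmp)) {
    centers <- seq(min(cmp$division_time_abs), max(cmp$division_time_abs),
                   by = max(window / 3, 1))
    for (p in growth_parameters) {
      for (tc in centers) {
        sel <- abs(cmp$division_time_abs - tc) <= window / 2
        if (!any(sel)) next
        series[[length(series) + 1L]] <- tibble::tibble(
          parameter = p, time = tc, mean = mean(cmp[[p]][sel]),
          sd = stats::sd(cmp[[p]][sel]), n = sum(sel))
      }
    }
  }
  list(records = records,
       series = if (length(series)) do.call(rbind, series) else
         tibble::tibble(parameter = character(), time = numeric(),
                        mean = numeric(), sd = numeric(), n = integer()))
}

#' Regression of division length on birth length
#'
#' Ordinary least squares restricted to the configured birth-length range
#' (6-10 um by default, where the bulk of the population lies), plus a
#' per-birth-length-bin distribution table of division lengths.
#'
#' @param records growth records.
#' @param range birth-length range (um) used for the fit.
#' @param bin_width birth-length bin width (um) for the table.
#' @return list with `slope`, `intercept`, `n`, `fit` (the `lm` object) and
#'   `bins` (tibble `bin_center`, `n`, `mean`, `median`, `q25`, `q75`).
#' @export
birth_division_regression <- function(records, range = c(6, 10),
                                      bin_width = 0.5) {
  r <- records[records$complete, , drop = FALSE]
  sel <- r$birth_length >= range[1] & r$birth_length <= range[2]
  if (sum(sel) < 10L) {
    stop_param("birth_division_regression: fewer than 10 records in the ",
               "birth-length range")
  }
  fit <- stats::lm(division_length ~ birth_length, data = r[sel, ])
  co <- stats::coef(fit)
  edges <- seq(range[1], range[2], by = bin_width)
  bin <- findInterval(r$birth_length[sel], edges, rightmost.closed = TRUE)
  bins <- list()
  for (bcode in sort(unique(bin))) {
    v <- r$division_length[sel][bin == bcode]
    bins[[length(bins) + 1L]] <- tibble::tibble(
      bin_center = edges[bcode] + bin_width / 2, n = length(v),
      mean = mean(v), median = stats::median(v),
      q25 = unname(stats::quantile(v, 0.25)),
      q75 = unname(stats::quantile(v, 0.75)))
  }
  list(slope = unname(co[2]), intercept = unname(co[1]), n = sum(sel),
       fit = fit, bins = do.call(rbind, bins))
}

#' Sister-pair table
#'
#' One row per division whose two daughters both completed a cycle, pairing
#' the sisters' doubling times and elongation rates together with the
#' mother's division length; sisters are ordered by track id.
#'
#' @param forest a [lineage_forest()] over track ids.
#' @param records growth records for the same tracks.
#' @return tibble with `parent`, `sister1`, `sister2`,
#'   `doubling_time_1/2`, `elongation_rate_1/2`, `mother_division_length`;
#'   attribute `correlations` holds the two Pearson coefficients.
#' @export
sister_table <- function(forest, records) {
  nd <- forest$nodes
  rec <- records[records$complete, , drop = FALSE]
  rows <- list()
  for (p in unique(nd$parent[!is.na(nd$parent)])) {
    kids <- sort(nd$node[!is.na(nd$parent) & nd$parent == p])
    if (length(kids) != 2L) next
    r1 <- rec[rec$track_id == kids[1], ]
    r2 <- rec[rec$track_id == kids[2], ]
    if (nrow(r1) != 1L || nrow(r2) != 1L) next
    rp <- rec[rec$track_id == p, ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parent = p, sister1 = kids[1], sister2 = kids[2],
      doubling_time_1 = r1$doubling_time, doubling_time_2 = r2$doubling_time,
      elongation_rate_1 = r1$elongation_rate,
      elongation_rate_2 = r2$elongation_rate,
      mother_division_length = if (nrow(rp) == 1L) rp$division_length
        else NA_real_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(
    parent = integer(), sister1 = integer(), sister2 = integer(),
    doubling_time_1 = numeric(), doubling_time_2 = numeric(),
    elongation_rate_1 = numeric(), elongation_rate_2 = numeric(),
    mother_division_length = numeric())
  attr(out, "correlations") <- if (nrow(out) >= 3L) {
    c(doubling_time = stats::cor(out$doubling_time_1, out$doubling_time_2),
      elongation_rate = stats::cor(out$elongation_rate_1,
                                   out$elongation_rate_2))
  } else {
    c(doubling_time = NA_real_, elongation_rate = NA_real_)
  }
  out
}
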