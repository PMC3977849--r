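## Segmentation: lane splitting, thresholding/outlining, contour features,
## non-cell rejection, and the single / too-large / too-long triage with
## refinement of merged contours.

#' Segmentation configuration
#'
#' @param threshold fixed dark threshold; `NULL` = per-lane Otsu.
#' @param min_area smallest interior area (px^2) accepted as a cell; smaller
#'   features are rejected as non-cell (contours under 4 px^2 are always
#'   rejected).
#' @param min_width smallest transverse extent (px) accepted as a cell;
#'   rejects highway-wall slivers and other line artifacts.
#' @param min_extent_ratio minimal area / (bounding-box area) fill ratio;
#'   texture-free analogue of a solidity filter for rod-shaped contours.
#' @param max_width_um triage threshold: wider features are `too_large`
#'   (20 px = 4.6 um at the default pixel scale).
#' @param max_length_um triage threshold: longer features are `too_long`
#'   (13 um).
#' @param border_halfwidth half-width of the dark contour line, px; the cell
#'   edge runs through the middle of the dark band, so measured extents are
#'   calibrated by `2 * border_halfwidth + 1`.
#' @param valley_depth minimal intensity-profile valley prominence used to
#'   cut merged contours.
#' @param min_piece_um refinement never produces pieces shorter than this.
#' @param pixel_size um per pixel.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(threshold = NULL,
                       min_area = 30,
                       min_width = 5,
                       min_extent_ratio = 0.3,
                       max_width_um = 4.6,
                       max_length_um = 13,
                       border_halfwidth = 1,
                       valley_depth = 8,
                       min_piece_um = 2,
                       pixel_size = 0.2304) {
  structure(as.list(environment()), class = "seg_config")
}

#' Detect lane boundaries from highway walls
#'
#' Highway walls are dark rows spanning the chamber; lanes are the maximal
#' runs of non-wall rows.
#'
#' @param frame intensity matrix.
#' @param min_lane_height ignore runs thinner than this (px).
#' @return tibble with columns `lane`, `y0`, `y1` (inclusive pixel rows).
#' @export
detect_lanes <- function(frame, min_lane_height = 6L) {
  thr <- otsu_threshold(frame)
  dark_frac <- rowMeans(frame < thr)
  is_wall <- dark_frac > 0.5
  d <- diff(c(TRUE, is_wall, TRUE))
  y0 <- which(d == -1L)
  y1 <- which(d == 1L) - 1L
  keep <- (y1 - y0 + 1L) >= min_lane_height
  tibble::tibble(lane = seq_len(sum(keep)), y0 = y0[keep], y1 = y1[keep])
}

#' Split a chamber frame into lanes
#'
#' @param frame intensity matrix.
#' @param geometry tibble with `lane`, `y0`, `y1` (e.g. from
#'   [detect_lanes()] or [lane_geometry()]); `NULL` partitions the frame
#'   rows into `n_lanes` equal contiguous ranges.
#' @param n_lanes used when `geometry` is `NULL`.
#' @return list of lanes, each a list with `lane`, `y0`, `y1`, `img`.
#' @export
split_lanes <- function(frame, geometry = NULL, n_lanes = 5L) {
  nr <- nrow(frame)
  if (is.null(geometry)) {
    if (nr %% n_lanes != 0L) {
      stop_param("split_lanes: ", nr, " rows not divisible into ", n_lanes,
                 " equal lanes; supply geometry")
    }
    h <- nr %/% n_lanes
    geometry <- tibble::tibble(lane = seq_len(n_lanes),
                               y0 = (seq_len(n_lanes) - 1L) * h + 1L,
                               y1 = seq_len(n_lanes) * h)
  }
  if (any(geometry$y0 < 1L) || any(geometry$y1 > nr) ||
      any(geometry$y1 < geometry$y0)) {
    stop_param("split_lanes: lane geometry out of frame bounds")
  }
  lapply(seq_len(nrow(geometry)), function(i) {
    list(lane = geometry$lane[i], y0 = geometry$y0[i], y1 = geometry$y1[i],
         img = frame[geometry$y0[i]:geometry$y1[i], , drop = FALSE])
  })
}

#' Segment one lane by thresholding and outlining
#'
#' Dark pixels trace the cell contours; each cell interior is an enclosed
#' bright component. Components touching the lane boundary (ambient
#' background, cells partially outside the field) and components failing
#' the non-cell filters (area, width, fill ratio) are removed.
#'
#' @param img lane intensity matrix.
#' @param cfg a [seg_config()].
#' @return list of components; each has `pixels` (matrix of `row`, `col`
#'   within the lane image) and `n` (area). Empty list for blank lanes.
#' @export
segment_lane <- function(img, cfg = seg_config()) {
  if (length(img) == 0L) return(list())
  thr <- if (is.null(cfg$threshold)) otsu_threshold(img) else cfg$threshold
  open <- img >= thr
  if (all(open) || !any(open)) return(list())
  labs <- label_components(open)
  k <- max(labs)
  if (k == 0L) return(list())
  edge <- unique(c(labs[1, ], labs[nrow(labs), ], labs[, 1], labs[, ncol(labs)]))
  out <- list()
  pix <- which(labs > 0L)
  coord <- arrayInd(pix, dim(labs))
  lab_of <- labs[pix]
  for (id in setdiff(seq_len(k), edge)) {
    sel <- lab_of == id
    p <- coord[sel, , drop = FALSE]
    n <- nrow(p)
    if (n < cfg$min_area) next
    h <- diff(range(p[, 1])) + 1L
    w <- diff(range(p[, 2])) + 1L
    if (min(h, w) < cfg$min_width) next
    if (n / (h * w) < cfg$min_extent_ratio) next
    out[[length(out) + 1L]] <- list(pixels = p, n = n)
  }
  out
}

#' Measure a contour into a cell observation
#'
#' Features follow the principal axis of the interior pixel cloud: length
#' and width are the extents along the major and minor axes plus the
#' contour-line calibration (`2 * border_halfwidth + 1` px), converted with
#' the pixel size; the lengthwise intensity profile is the mean interior
#' intensity in 1-px bins along the major axis.
#'
#' @param pixels matrix of interior pixel coordinates (`row`, `col`).
#' @param image the intensity matrix the coordinates index into.
#' @param cfg a [seg_config()].
#' @return one-row tibble (a CellObservation) with a `profile` list column;
#'   contours under 4 px^2 get `category = "rejected_non_cell"`.
#' @export
measure_contour <- function(pixels, image, cfg = seg_config()) {
  n <- nrow(pixels)
  if (n < 4L) {
    return(tibble::tibble(x = NA_real_, y = NA_real_, area = n,
                          length_um = NA_real_, width_um = NA_real_,
                          orientation = NA_real_, mean_intensity = NA_real_,
                          x0 = NA_real_, x1 = NA_real_, y0 = NA_real_,
                          y1 = NA_real_, category = "rejected_non_cell",
                          flagged = FALSE, profile = list(numeric(0))))
  }
  ys <- pixels[, 1]; xs <- pixels[, 2]
  vals <- image[pixels]
  cx <- mean(xs); cy <- mean(ys)
  dx <- xs - cx; dy <- ys - cy
  cov <- matrix(c(mean(dx^2), mean(dx * dy), mean(dx * dy), mean(dy^2)), 2)
  eg <- eigen(cov, symmetric = TRUE)
  major <- eg$vectors[, 1]
  # orientation of the major axis vs the x axis, degrees in [-90, 90)
  ang <- atan2(major[2], major[1]) * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  s <- dx * major[1] + dy * major[2]           # along-axis coordinate
  tq <- -dx * major[2] + dy * major[1]         # transverse coordinate
  # the cell edge runs through the middle of the dark contour line
  # (2 * halfwidth), and the pixel-centre extent undershoots the region
  # boundary by an orientation-dependent lattice gap (1 px for lattice-
  # aligned rods, shrinking toward diagonal orientations)
  lattice <- abs(abs(major[1]) - abs(major[2]))
  calib <- 2 * cfg$border_halfwidth + lattice
  len_px <- diff(range(s)) + calib
  wid_px <- diff(range(tq)) + calib
  nb <- max(3L, ceiling(diff(range(s))) + 1L)
  bins <- findInterval(s, seq(min(s), max(s), length.out = nb + 1L),
                       rightmost.closed = TRUE)
  prof <- as.numeric(tapply(vals, factor(bins, levels = seq_len(nb)), mean))
  prof[is.na(prof)] <- mean(vals)
  obs <- tibble::tibble(
    x = cx, y = cy, area = n,
    length_um = len_px * cfg$pixel_size,
    width_um = wid_px * cfg$pixel_size,
    orientation = ang,
    mean_intensity = mean(vals),
    x0 = min(xs), x1 = max(xs), y0 = min(ys), y1 = max(ys),
    category = NA_character_, flagged = FALSE,
    profile = list(prof))
  obs$category <- triage_contour(obs$length_um, obs$width_um, cfg)
  obs
}

#' Triage a contour into single / too-large / too-long
#'
#' Pure function of length and width: features wider than 4.6 um (20 px)
#' are `too_large`, features longer than 13 um are `too_long` (width takes
#' precedence when both hold), everything else is a `single` cell.
#'
#' @param length_um,width_um measured extents, um.
#' @param cfg a [seg_config()].
#' @return character vector of categories.
#' @export
triage_contour <- function(length_um, width_um, cfg = seg_config()) {
  ifelse(width_um > cfg$max_width_um, "too_large",
         ifelse(length_um > cfg$max_length_um, "too_long", "single"))
}

#' Refine a too-large / too-long contour toward single cells
#'
#' Merged objects (abutting cells whose shared border leaked) are cut at
#' dark valleys of the lengthwise intensity profile, perpendicular to the
#' major axis; `too_large` objects are additionally tried along the
#' transverse profile. Pieces are re-measured and re-triaged. Objects with
#' no usable valley -- e.g. a genuinely long pre-division cell whose only
#' internal structure is the bright septum -- are returned unsplit with
#' `flagged = TRUE`. No cut producing a piece shorter than
#' `cfg$min_piece_um` is applied.
#'
#' @param pixels interior pixel coordinate matrix of the contour.
#' @param image intensity matrix.
#' @param cfg a [seg_config()].
#' @return list of one-row observation tibbles (as [measure_contour()]).
#' @export
refine_contour <- function(pixels, image, cfg = seg_config()) {
  obs <- measure_contour(pixels, image, cfg)
  if (obs$category == "single" || obs$category == "rejected_non_cell") {
    return(list(obs))
  }
  split_axis <- function(axis) {
    ys <- pixels[, 1]; xs <- pixels[, 2]
    cx <- mean(xs); cy <- mean(ys)
    dx <- xs - cx; dy <- ys - cy
    cov <- matrix(c(mean(dx^2), mean(dx * dy), mean(dx * dy), mean(dy^2)), 2)
    eg <- eigen(cov, symmetric = TRUE)
    vec <- eg$vectors[, axis]
    s <- dx * vec[1] + dy * vec[2]
    vals <- image[pixels]
    nb <- max(5L, ceiling(diff(range(s))) + 1L)
    edges <- seq(min(s), max(s), length.out = nb + 1L)
    bins <- findInterval(s, edges, rightmost.closed = TRUE)
    prof <- as.numeric(tapply(vals, factor(bins, levels = seq_len(nb)), mean))
    prof[is.na(prof)] <- max(prof, na.rm = TRUE)
    sm <- stats::filter(prof, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- prof[is.na(sm)]
    sm <- as.numeric(sm)
    guard <- max(2L, ceiling(cfg$min_piece_um / cfg$pixel_size / 2))
    cand <- (guard + 1L):(nb - guard)
    if (!length(cand)) return(NULL)
    cuts <- integer(0)
    for (i in cand) {
      if (sm[i] <= min(sm[i - 1L], sm[i + 1L])) {
        prom <- min(max(sm[1:(i - 1L)]), max(sm[(i + 1L):nb])) - sm[i]
        if (prom >= cfg$valley_depth) cuts <- c(cuts, i)
      }
    }
    if (!length(cuts)) return(NULL)
    # drop cuts closer together than the minimal piece
    min_bins <- cfg$min_piece_um / cfg$pixel_size
    keep <- cuts[c(TRUE, diff(cuts) >= min_bins)]
    grp <- findInterval(bins, keep + 0.5) + 1L
    split(seq_len(nrow(pixels)), grp)
  }
  pieces <- split_axis(1L)
  if (is.null(pieces) && obs$category == "too_large") pieces <- split_axis(2L)
  if (is.null(pieces) || length(pieces) < 2L) {
    obs$flagged <- TRUE
    return(list(obs))
  }
  out <- list()
  for (idx in pieces) {
    po <- measure_contour(pixels[idx, , drop = FALSE], image, cfg)
    if (po$category == "rejected_non_cell") next
    if (!is.na(po$length_um) && po$length_um < cfg$min_piece_um) next
    if (po$category != "single") po$flagged <- TRUE
    out[[length(out) + 1L]] <- po
  }
  if (!length(out)) {
    obs$flagged <- TRUE
    return(list(obs))
  }
  out
}

#' Segment one chamber frame into cell observations
#'
#' @param frame intensity matrix.
#' @param geometry lane geometry tibble (`lane`, `y0`, `y1`).
#' @param cfg a [seg_config()].
#' @param frame_idx frame number stored in the output.
#' @param id_start first observation id to assign.
#' @return tibble of observations in frame coordinates (one row per cell,
#'   `profile` list column), ids `id_start`, `id_start + 1`, ...
#' @export
segment_frame <- function(frame, geometry, cfg = seg_config(),
                          frame_idx = 1L, id_start = 1L) {
  lanes <- split_lanes(frame, geometry)
  rows <- list()
  for (ln in lanes) {
    comps <- segment_lane(ln$img, cfg)
    for (cp in comps) {
      oo <- refine_contour(cp$pixels, ln$img, cfg)
      for (o in oo) {
        if (o$category == "rejected_non_cell") next
        o$y <- o$y + ln$y0 - 1
        o$y0 <- o$y0 + ln$y0 - 1
        o$y1 <- o$y1 + ln$y0 - 1
        o <- tibble::tibble(lane = ln$lane, o)
        rows[[length(rows) + 1L]] <- o
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(obs_id = integer(), frame = integer(),
                          lane = integer(), x = numeric(), y = numeric(),
                          area = numeric(), length_um = numeric(),
                          width_um = numeric(), orientation = numeric(),
                          mean_intensity = numeric(), x0 = numeric(),
                          x1 = numeric(), y0 = numeric(), y1 = numeric(),
                          category = character(), flagged = logical(),
                          profile = list()))
  }
  obs <- do.call(rbind, rows)
  tibble::tibble(obs_id = id_start - 1L + seq_len(nrow(obs)),
                 frame = frame_idx, obs)
}

#' Segment a movie
#'
#' @param stack list of intensity matrices (frames), e.g. from
#'   [simulate_colony()] or [read_tiff()].
#' @param geometry lane geometry tibble; `NULL` auto-detects from the first
#'   frame via [detect_lanes()].
#' @param cfg a [seg_config()].
#' @return list with `observations` (tibble over all frames) and `geometry`.
#' @export
segment_movie <- function(stack, geometry = NULL, cfg = seg_config()) {
  if (is.null(geometry)) geometry <- detect_lanes(stack[[1]])
  obs <- vector("list", length(stack))
  id0 <- 1L
  for (f in seq_along(stack)) {
    o <- segment_frame(stack[[f]], geometry, cfg, frame_idx = f, id_start = id0)
    id0 <- id0 + nrow(o)
    obs[[f]] <- o
  }
  list(observations = do.call(rbind, obs), geometry = geometry)
}
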