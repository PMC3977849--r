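## End-to-end pipeline: simulate (or load) -> segment -> track -> divide ->
## lineage -> growth statistics, with run manifests and truth validation.

#' Pipeline run configuration
#'
#' @param input path to a multi-page TIFF movie, or `NULL` to simulate.
#' @param sim [sim_params()] used when `input` is `NULL`.
#' @param geometry lane geometry tibble; `NULL` = auto-detect (simulated
#'   movies use the generator's geometry).
#' @param seg a [seg_config()].
#' @param tracker a [tracker_config()].
#' @param division a [division_config()].
#' @param growth a [growth_config()].
#' @param frame_interval minutes per frame (ignored for simulated input,
#'   which carries its own).
#' @param t_shift optional shift time (minutes) for [align_to_shift()].
#' @param outdir output directory, or `NULL` for in-memory results only.
#' @param write_stack write the (simulated) movie as `frames.tif`?
#' @param seed RNG seed recorded in the manifest; overrides `sim$seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL,
                       sim = sim_params(),
                       geometry = NULL,
                       seg = seg_config(),
                       tracker = tracker_config(),
                       division = division_config(),
                       growth = growth_config(),
                       frame_interval = 1,
                       t_shift = NULL,
                       outdir = NULL,
                       write_stack = FALSE,
                       seed = NULL) {
  if (!is.null(input) && !file.exists(input)) {
    stop_param("run_config: input file not found: ", input)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate/load, segment, track, divide,
#' lineage, growth statistics), optionally writing all intermediate tables
#' as CSV plus a JSON manifest (config echo, package version, per-stage
#' counts and timings). Deterministic for a fixed seed.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages?
#' @return list of class `pipeline_result` with `segmented`, `tracked`,
#'   `divisions`, `forest`, `records`, `summary`, `census`, `truth` (for
#'   simulated input), `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  say <- function(...) if (!quiet) message(...)
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(tic() - t0, 2)
    say(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    out
  }

  truth <- NULL
  frame_interval <- cfg$frame_interval
  geometry <- cfg$geometry
  if (is.null(cfg$input)) {
    sim_p <- cfg$sim
    if (!is.null(cfg$seed)) sim_p$seed <- cfg$seed
    simr <- stage("simulate", simulate_colony(sim_p))
    stack <- simr$stack
    truth <- simr$truth
    frame_interval <- sim_p$frame_interval
    if (is.null(geometry)) geometry <- simr$geometry$lanes
  } else {
    stack <- stage("load", read_tiff(cfg$input))
  }

  segmented <- stage("segment", segment_movie(stack, geometry, cfg$seg))
  tracked <- stage("track", track_movie(segmented, cfg$tracker))
  divisions <- stage("divide", detect_divisions(tracked, cfg$division))
  forest <- stage("lineage", build_forest(tracked, divisions))
  records <- stage("growth", records_from_tracks(
    tracked, divisions, forest, frame_interval, cfg$growth))
  summary_tbl <- if (sum(records$complete) >= 2L) {
    summarize_records(records)
  } else {
    NULL
  }
  census_tbl <- census(forest)
  shift <- if (!is.null(cfg$t_shift)) {
    align_to_shift(records, cfg$t_shift)
  }
  if (!is.null(shift)) records <- shift$records

  manifest <- list(
    package = "pombetrack",
    version = as.character(utils::packageVersion("pombetrack")),
    seed = if (is.null(cfg$input)) {
      if (!is.null(cfg$seed)) cfg$seed else cfg$sim$seed
    } else {
      cfg$seed
    },
    input = if (is.null(cfg$input)) "simulated" else cfg$input,
    frame_interval = frame_interval,
    counts = list(
      frames = length(stack),
      observations = nrow(segmented$observations),
      tracks = length(unique(tracked$tracks$track_id)),
      divisions = nrow(divisions),
      complete_records = sum(records$complete)),
    timings_s = as.list(timings),
    config = list(
      sim = if (is.null(cfg$input)) unclass(cfg$sim),
      seg = unclass(cfg$seg),
      tracker = lapply(unclass(cfg$tracker), function(v) {
        if (is.null(v)) NULL else unname(v)
      }),
      division = unclass(cfg$division),
      growth = unclass(cfg$growth))
  )

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    tdir <- file.path(cfg$outdir, "tables")
    dir.create(tdir, showWarnings = FALSE)
    obs_out <- segmented$observations
    obs_out$profile <- NULL
    utils::write.csv(obs_out, file.path(tdir, "observations.csv"),
                     row.names = FALSE)
    utils::write.csv(tracked$tracks, file.path(tdir, "tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(tracked$diagnostics, file.path(tdir, "tracking_log.csv"),
                     row.names = FALSE)
    utils::write.csv(divisions, file.path(tdir, "divisions.csv"),
                     row.names = FALSE)
    utils::write.csv(records, file.path(tdir, "records.csv"),
                     row.names = FALSE)
    if (!is.null(summary_tbl)) {
      utils::write.csv(summary_tbl, file.path(tdir, "summary.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(census_tbl, file.path(tdir, "census.csv"),
                     row.names = FALSE)
    ldir <- file.path(cfg$outdir, "lineages")
    dir.create(ldir, showWarnings = FALSE)
    writeLines(forest_newick(forest), file.path(ldir, "forest.nwk"))
    writeLines(forest_text(forest), file.path(ldir, "forest.txt"))
    if (!is.null(truth)) write_truth(truth, file.path(cfg$outdir, "truth"))
    if (cfg$write_stack) {
      write_tiff(stack, file.path(cfg$outdir, "frames.tif"))
    }
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }

  say(sprintf("pipeline finished in %.1fs", tic() - t_all))
  structure(list(segmented = segmented, tracked = tracked,
                 divisions = divisions, forest = forest, records = records,
                 summary = summary_tbl, census = census_tbl,
                 shift = shift, truth = truth, stack_frames = length(stack),
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cn <- x$manifest$counts
  cat("<pipeline_result>",
      sprintf("  %d frames -> %d observations -> %d tracks",
              cn$frames, cn$observations, cn$tracks),
      sprintf("  %d divisions, %d complete growth records",
              cn$divisions, cn$complete_records),
      sep = "\n")
  invisible(x)
}

## map each observation to the ground-truth cell whose centroid is nearest
## in the same frame (within tol px); NA when no truth cell is close enough
map_obs_to_truth <- function(observations, trajectories, tol = 6) {
  truth_id <- rep(NA_integer_, nrow(observations))
  tr_by_frame <- split(trajectories, trajectories$frame)
  ob_by_frame <- split(seq_len(nrow(observations)), observations$frame)
  for (f in names(ob_by_frame)) {
    tr <- tr_by_frame[[f]]
    if (is.null(tr)) next
    oi <- ob_by_frame[[f]]
    for (i in oi) {
      d2 <- (tr$x - observations$x[i])^2 + (tr$y - observations$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) truth_id[i] <- tr$id[j]
    }
  }
  truth_id
}

#' Validate pipeline results against simulator ground truth
#'
#' Plays the role of the manual-annotation comparison used to estimate the
#' published pipeline's accuracy, with the simulator's ground truth
#' replacing the manual annotation. Observations are mapped to truth cells
#' by nearest centroid; links, divisions and lineage edges are then scored
#' against the truth. Division recall is computed over *observable*
#' divisions: those whose daughters both stay fully inside the imaged
#' frame for at least `min_daughter_frames` frames (a division whose
#' products are immediately eluted past the outlet is invisible to any
#' in-frame analysis).
#'
#' @param result a [run_pipeline()] result for a simulated movie.
#' @param truth the simulator truth (defaults to `result$truth`).
#' @param frame_tol accepted |called - true| division-frame difference.
#' @param min_daughter_frames observability requirement (frames).
#' @return list of class `truth_validation`: `metrics` (tibble) and
#'   `parameters` (per-parameter recovered vs configured means).
#' @export
validate_against_truth <- function(result, truth = result$truth,
                                   frame_tol = 2L,
                                   min_daughter_frames = 3L) {
  if (is.null(truth)) stop_param("validate_against_truth: no ground truth")
  obs <- result$segmented$observations
  tid <- map_obs_to_truth(obs, truth$trajectories)

  # observability: frames where a cell is fully inside the imaged lane
  p_sim <- result$manifest$config$sim
  tt <- truth$trajectories
  fully_in <- if (!is.null(p_sim)) {
    hl <- tt$length_um / p_sim$pixel_size / 2
    tt$x + hl <= p_sim$lane_length & tt$x - hl >= 1
  } else {
    rep(TRUE, nrow(tt))
  }

  # link accuracy: a link is true when both ends map to the same truth cell
  links <- result$tracked$links
  la <- tid[match(links$obs_a, obs$obs_id)]
  lb <- tid[match(links$obs_b, obs$obs_id)]
  good <- !is.na(la) & !is.na(lb) & la == lb
  links_true <- sum(good)
  link_precision <- if (nrow(links)) links_true / nrow(links) else NA_real_
  # recall: truth links between consecutive fully-in-frame appearances of
  # cells the segmentation saw at least once, recovered by the tracker
  seen <- unique(stats::na.omit(tid))
  tr <- truth$trajectories[truth$trajectories$id %in% seen & fully_in, ]
  tr <- tr[order(tr$id, tr$frame), ]
  same <- tr$id[-1] == tr$id[-nrow(tr)] & diff(tr$frame) == 1L
  truth_keys <- paste(tr$id[-nrow(tr)][same], tr$frame[-nrow(tr)][same])
  det_keys <- paste(la[good], links$frame[good])
  link_recall <- if (length(truth_keys)) {
    mean(truth_keys %in% det_keys)
  } else {
    NA_real_
  }

  # division detection
  div <- result$divisions
  tracks <- split(result$tracked$tracks, result$tracked$tracks$track_id)
  last_obs <- vapply(tracks, function(t) t$obs_id[nrow(t)], numeric(1))
  parent_truth <- tid[match(last_obs[as.character(div$parent_track)],
                            obs$obs_id)]
  truth_div <- truth$divisions
  traj_count <- table(tt$id[fully_in])
  nd_frames <- function(ids) {
    n <- traj_count[as.character(ids)]
    n[is.na(n)] <- 0
    as.numeric(n)
  }
  observable <- truth_div$frame <= max(obs$frame) - min_daughter_frames &
    nd_frames(truth_div$d1) >= min_daughter_frames &
    nd_frames(truth_div$d2) >= min_daughter_frames
  matched <- logical(nrow(truth_div))
  call_true <- logical(nrow(div))
  if (nrow(div)) {
    for (i in seq_len(nrow(div))) {
      j <- which(truth_div$parent == parent_truth[i] &
                   abs(truth_div$frame - div$division_frame[i]) <= frame_tol)
      if (length(j)) {
        matched[j[1]] <- TRUE
        call_true[i] <- TRUE
      }
    }
  }
  division_recall <- if (any(observable)) {
    sum(matched & observable) / sum(observable)
  } else {
    NA_real_
  }
  division_precision <- if (nrow(div)) mean(call_true) else NA_real_

  # lineage edges: detected parent-daughter pairs vs truth parent links
  track_truth <- vapply(tracks, function(t) {
    v <- tid[match(t$obs_id, obs$obs_id)]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    as.integer(names(sort(table(v), decreasing = TRUE))[1])
  }, integer(1))
  nd <- result$forest$nodes
  edges <- nd[!is.na(nd$parent), , drop = FALSE]
  edge_ok <- 0L
  if (nrow(edges)) {
    et_child <- track_truth[as.character(edges$node)]
    et_parent <- track_truth[as.character(edges$parent)]
    truth_parent <- truth$cycles$parent[match(et_child, truth$cycles$id)]
    edge_ok <- sum(!is.na(et_parent) & !is.na(truth_parent) &
                     truth_parent == et_parent)
  }
  lineage_edge_precision <- if (nrow(edges)) edge_ok / nrow(edges) else NA_real_

  # growth-parameter recovery: measured means vs the generator's ground
  # truth for the very cells that were measured (isolates measurement
  # accuracy from the sampling noise of which cycles completed on screen)
  rec <- result$records[result$records$complete, , drop = FALSE]
  p <- if (!is.null(result$manifest$config$sim)) result$manifest$config$sim
  par_tbl <- NULL
  if (nrow(rec) >= 2L) {
    rec_truth_id <- track_truth[as.character(rec$track_id)]
    cyc <- truth$cycles[match(rec_truth_id, truth$cycles$id), ]
    ok <- !is.na(rec_truth_id)
    truth_cols <- c(birth_length = "birth_length",
                    division_length = "division_length",
                    fission_length = "fission_length",
                    elongation_time = "elongation_time",
                    septation_time = "septation_time",
                    doubling_time = NA, elongation_rate = "elongation_rate")
    truth_means <- vapply(names(truth_cols), function(nm) {
      if (nm == "doubling_time") {
        mean(cyc$elongation_time[ok] + cyc$septation_time[ok])
      } else {
        mean(cyc[[truth_cols[[nm]]]][ok])
      }
    }, numeric(1))
    configured <- if (!is.null(p)) c(
      birth_length = p$mean_fission_length / 2,
      division_length = p$mean_division_length,
      fission_length = p$mean_fission_length,
      elongation_time = p$mean_elongation_time,
      septation_time = p$mean_septation_time,
      doubling_time = p$mean_elongation_time + p$mean_septation_time,
      elongation_rate = truth_means[["elongation_rate"]])
    est <- vapply(names(truth_cols), function(nm) mean(rec[[nm]][ok]),
                  numeric(1))
    par_tbl <- tibble::tibble(
      parameter = names(truth_cols),
      configured = if (!is.null(p)) unname(configured) else NA_real_,
      truth_mean = unname(truth_means),
      estimated = unname(est),
      rel_error = unname(abs(est - truth_means) / truth_means))
  }

  metrics <- tibble::tibble(
    metric = c("division_recall", "division_precision", "false_link_rate",
               "link_recall", "lineage_edge_precision",
               "n_observable_divisions", "n_called_divisions", "n_links"),
    value = c(division_recall, division_precision, 1 - link_precision,
              link_recall, lineage_edge_precision,
              sum(observable), nrow(div), nrow(links)))
  structure(list(metrics = metrics, parameters = par_tbl),
            class = "truth_validation")
}

#' @export
print.truth_validation <- function(x, ...) {
  cat("<truth_validation>\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-24s %.4g\n", m$metric[i], m$value[i]))
  }
  if (!is.null(x$parameters)) {
    cat("  parameter recovery (|rel err|):\n")
    p <- x$parameters
    for (i in seq_len(nrow(p))) {
      cat(sprintf("    %-18s %.4g vs %.4g (%.2f%%)\n", p$parameter[i],
                  p$estimated[i], p$configured[i], 100 * p$rel_error[i]))
    }
  }
  invisible(x)
}
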