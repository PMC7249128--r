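#' Default pipeline configuration
#'
#' Returns the full configuration tree with every stage's defaults: camera
#' constants, a 5x5 depth median filter, CLAHE clip limit 40 with an 8x8
#' tile grid, dynamic-histogram peak range 50, flood-fill brightness bounds
#' 10 (low) / 30 (up) with 4-connectivity, a 15x2 (rows x cols) closing
#' kernel applied once, and a 600-px minimum contour area. The histogram
#' `low_limit` (10) and `count_difference` (50) have no published
#' reference values and are deliberately explicit config entries.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    camera = list(fov_x = 87, fov_y = 58, tilt = 28.5, depth_scale = 0.001,
                  frame_width = 1280L, frame_height = 720L,
                  row_distance = 1.22, bottom_plane_distance = 1.23,
                  top_plane_distance = NULL),
    median_kernel = 5L,
    clahe = list(clip_limit = 40, tiles = 8L),
    histogram = list(peak_range = 50, low_limit = 10, count_difference = 50),
    histogram_scope = "masked",
    flood = list(lowdiff = 10, updiff = 30, connectivity = 4L),
    detection = list(min_area = 600, close_kernel = c(15L, 2L),
                     iterations = 1L)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as YAML mirroring the [default_config()]
#' structure; missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return For `read_config`, a `pipeline_config`; for `write_config`,
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg$detection$close_kernel <- as.integer(unlist(cfg$detection$close_kernel))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_camera <- function(config) do.call(camera_model, config$camera)

#' Run the full detection pipeline over a set of frames
#'
#' For every frame: segmentation ([segment_frame()]), detection
#' ([detect_trees()]) and diameter measurement ([measure_trees()]); when an
#' NMEA log is supplied the per-frame detections are geotagged into a yield
#' transect. One log line per frame reports seed counts, contour counts and
#' the final tree count.
#'
#' @param frames List of [frame_pair()] objects, or a manifest data.frame
#'   with columns `frame_id`, `gray_path`, `depth_path`, `timestamp` (or a
#'   path to such a CSV).
#' @param config A [default_config()]-style configuration.
#' @param nmea Optional character vector of NMEA sentences or a log file
#'   path.
#' @param outdir Optional output directory for `detections.csv` (one row
#'   per tree) and, with `nmea`, `transect.csv` + `transect.geojson`.
#' @param verbose Emit one log line per frame (default `TRUE`).
#' @return List with `detections` (data.frame: `frame_id`, `tree_id`,
#'   `area`, `bbox_*`, `span_start`, `span_end`, `pixel_width`,
#'   `depth_raw`, `depth_was_missing`, `diameter_mm`), `transect` (or
#'   `NULL`), and `n_frames`.
#' @export
run_pipeline <- function(frames, config = default_config(), nmea = NULL,
                         outdir = NULL, verbose = TRUE) {
  if (is.character(frames) && length(frames) == 1L)
    frames <- utils::read.csv(frames)
  if (is.data.frame(frames)) {
    if (nrow(frames) == 0L) stop("empty manifest: no frames to process")
    manifest <- frames
    loader <- function(i) read_frame_pair(manifest$gray_path[i],
                                          manifest$depth_path[i],
                                          manifest$timestamp[i],
                                          manifest$frame_id[i])
    n <- nrow(manifest)
  } else {
    if (length(frames) == 0L) stop("no frames to process")
    loader <- function(i) frames[[i]]
    n <- length(frames)
  }
  camera <- config_camera(config)
  plane <- build_threshold_plane(camera)
  hp <- do.call(histogram_params, config$histogram)
  fp <- do.call(flood_params, config$flood)

  rows <- list()
  times <- numeric(n)
  ids <- integer(n)
  failed <- 0L
  for (i in seq_len(n)) {
    fr <- tryCatch(loader(i), error = function(e) e)
    if (inherits(fr, "error")) {
      warning(sprintf("frame %d unreadable, skipped: %s", i,
                      conditionMessage(fr)))
      failed <- failed + 1L
      next
    }
    times[i] <- fr$timestamp
    ids[i] <- fr$frame_id
    seg <- segment_frame(fr, camera, hp, fp,
                         median_kernel = config$median_kernel,
                         clip_limit = config$clahe$clip_limit,
                         tiles = config$clahe$tiles,
                         histogram_scope = config$histogram_scope,
                         plane = plane)
    trees <- detect_trees(seg, min_area = config$detection$min_area,
                          close_kernel = config$detection$close_kernel,
                          iterations = config$detection$iterations)
    trees <- measure_trees(trees, seg$depth_median, camera)
    if (verbose)
      message(sprintf(
        "frame %d: seeds=%d flooded=%d trees=%d",
        fr$frame_id, nrow(seg$seed_points), seg$seeds_flooded,
        length(trees)))
    rows[[length(rows) + 1L]] <- if (length(trees) == 0L) NULL else
      do.call(rbind, lapply(trees, function(tr) {
        m <- tr$measurement
        data.frame(frame_id = fr$frame_id, tree_id = tr$tree_id,
                   area = tr$contour$area,
                   bbox_top = tr$contour$bbox[["top"]],
                   bbox_left = tr$contour$bbox[["left"]],
                   bbox_height = tr$contour$bbox[["height"]],
                   bbox_width = tr$contour$bbox[["width"]],
                   span_start = m$span[["start_col"]],
                   span_end = m$span[["end_col"]],
                   pixel_width = m$pixel_width,
                   depth_raw = m$depth_value,
                   depth_was_missing = m$depth_was_missing,
                   diameter_mm = m$diameter_mm)
      }))
  }
  if (failed == n) stop("all frames failed to load")
  detections <- do.call(rbind, rows)
  if (is.null(detections))
    detections <- data.frame(frame_id = integer(0), tree_id = integer(0),
                             area = integer(0), bbox_top = integer(0),
                             bbox_left = integer(0), bbox_height = integer(0),
                             bbox_width = integer(0), span_start = integer(0),
                             span_end = integer(0), pixel_width = integer(0),
                             depth_raw = numeric(0),
                             depth_was_missing = logical(0),
                             diameter_mm = numeric(0))

  transect <- NULL
  if (!is.null(nmea)) {
    fixes <- parse_nmea(nmea)
    pos <- tag_frames(times, fixes)
    pos <- data.frame(frame_id = ids, lat = pos$lat, lon = pos$lon)
    transect <- build_transect(detections, pos)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    det_out <- detections
    det_out$diameter_mm <- round(det_out$diameter_mm, 2)
    utils::write.csv(det_out, file.path(outdir, "detections.csv"),
                     row.names = FALSE)
    if (!is.null(transect)) {
      write_transect_csv(transect, file.path(outdir, "transect.csv"))
      write_transect_geojson(transect, file.path(outdir, "transect.geojson"))
    }
  }
  list(detections = detections, transect = transect, n_frames = n - failed)
}

#' Score detections against synthetic ground truth
#'
#' Matches each detection to a ground-truth stem of the same frame when
#' their bottom-row spans overlap by at least half the narrower span
#' (greedy, in detection order). Unmatched detections are false positives
#' and are attributed to branch objects by the same overlap rule.
#' Reports the correctly / falsely detected rates, the undetected stem
#' count, the branch share of false positives, and the diameter RMSE
#' overall and per diameter class group (28.57-34.92 mm versus larger, the
#' two commercial class ranges).
#'
#' @param detections Detections data.frame from [run_pipeline()].
#' @param ground_truth Ground-truth data.frame from [generate_suite()]
#'   (needs `frame_id`, `kind`, `span_start`, `span_end`, `diameter_mm`).
#' @param min_overlap Minimum span-overlap fraction of the narrower span,
#'   default 0.5.
#' @return List of class `detection_metrics`: counts (`n_detected`,
#'   `n_correct`, `n_false`, `n_undetected`, `n_stems`), rates
#'   (`correct_rate`, `false_rate`, `recall`, `branch_fp_share`), diameter
#'   errors (`rmse_mm`, `rmse_low_mm`, `rmse_high_mm`) and the per-pair
#'   `matches` data.frame.
#' @export
evaluate_detections <- function(detections, ground_truth,
                                min_overlap = 0.5) {
  if (nrow(detections) > 0 && nrow(ground_truth) > 0 &&
      !all(detections$frame_id %in% ground_truth$frame_id))
    stop("detections reference frames absent from ground truth")
  span_overlap <- function(a1, a2, b1, b2) {
    ov <- min(a2, b2) - max(a1, b1) + 1L
    if (ov <= 0L) return(0)
    ov / min(a2 - a1 + 1L, b2 - b1 + 1L)
  }
  matches <- list()
  n_false <- 0L; n_branch_fp <- 0L
  stems <- ground_truth[ground_truth$kind == "stem", ]
  branches <- ground_truth[ground_truth$kind == "branch", ]
  if (!"col_min" %in% names(branches))
    branches <- branches[!is.na(branches$span_start), ]
  stems$matched <- FALSE
  for (i in seq_len(nrow(detections))) {
    d <- detections[i, ]
    cand <- which(stems$frame_id == d$frame_id & !stems$matched)
    ovs <- vapply(cand, function(j)
      span_overlap(d$span_start, d$span_end,
                   stems$span_start[j], stems$span_end[j]), numeric(1))
    hit <- cand[ovs >= min_overlap]
    if (length(hit) > 0L) {
      j <- hit[which.max(ovs[ovs >= min_overlap])]
      stems$matched[j] <- TRUE
      matches[[length(matches) + 1L]] <-
        data.frame(frame_id = d$frame_id, tree_id = d$tree_id,
                   est_mm = d$diameter_mm, true_mm = stems$diameter_mm[j])
    } else {
      n_false <- n_false + 1L
      # attribute the false positive to a branch when one lies inside the
      # detection's column footprint (the measured run can sit a few
      # pixels off a narrow branch foot, so the bbox is the fair test)
      f1 <- if ("bbox_left" %in% names(d)) d$bbox_left else d$span_start
      f2 <- if ("bbox_left" %in% names(d)) d$bbox_left + d$bbox_width - 1L
            else d$span_end
      b1 <- if ("col_min" %in% names(branches)) branches$col_min else
        branches$span_start
      b2 <- if ("col_max" %in% names(branches)) branches$col_max else
        branches$span_end
      bc <- which(branches$frame_id == d$frame_id)
      bov <- vapply(bc, function(j)
        span_overlap(f1, f2, b1[j], b2[j]), numeric(1))
      if (any(bov >= min_overlap)) n_branch_fp <- n_branch_fp + 1L
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(frame_id = integer(0), tree_id = integer(0),
               est_mm = numeric(0), true_mm = numeric(0))
  err <- matches$est_mm - matches$true_mm
  rmse <- function(e) if (length(e)) sqrt(mean(e^2)) else NA_real_
  low <- matches$true_mm <= 34.92
  n_correct <- nrow(matches)
  n_det <- nrow(detections)
  structure(list(
    n_detected = n_det, n_correct = n_correct, n_false = n_false,
    n_undetected = sum(!stems$matched), n_stems = nrow(stems),
    correct_rate = if (n_det) n_correct / n_det else NA_real_,
    false_rate = if (n_det) n_false / n_det else NA_real_,
    recall = if (nrow(stems)) n_correct / nrow(stems) else NA_real_,
    branch_fp_share = if (n_false) n_branch_fp / n_false else NA_real_,
    rmse_mm = rmse(err), rmse_low_mm = rmse(err[low]),
    rmse_high_mm = rmse(err[!low]), matches = matches),
    class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<detection_metrics> %d detections: %d correct (%.1f%%), ",
           "%d false, %d/%d stems undetected\n"),
    x$n_detected, x$n_correct, 100 * x$correct_rate,
    x$n_false, x$n_undetected, x$n_stems))
  cat(sprintf("  recall %.1f%%; branch share of FPs %s; RMSE %.2f mm\n",
              100 * x$recall,
              if (is.na(x$branch_fp_share)) "n/a" else
                sprintf("%.1f%%", 100 * x$branch_fp_share),
              x$rmse_mm))
  invisible(x)
}
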