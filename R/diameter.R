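#' Bottom-row pixel width and representative depth of a detected tree
#'
#' Extracts the filled contour's bottom image row together with the aligned
#' median-filtered depth row, trims leading and trailing empty columns, and
#' measures the stem width. If the trimmed run is solid its length is the
#' pixel width; if interior gaps remain (two objects sharing one contour,
#' e.g. a stem and a branch both reaching the bottom row), the row is split
#' at each gap and the widest solid run is assumed to belong to the true
#' tree (leftmost run on ties). The representative depth is the median of
#' the non-zero depths over the chosen span — zeros are invalid
#' measurements and never enter the median; for an even count the two
#' middle values are averaged and rounded to the nearest depth unit. When
#' every depth in the span is zero the depth is returned as `NA` so
#' [resolve_missing_depth()] can fill it from the frame's other trees.
#'
#' @param contour A `tree_contour` that touches the bottom row.
#' @param depth_median Median-filtered depth matrix of the frame.
#' @return List with `pixel_width`, `depth_value` (raw units or `NA`), and
#'   `span` (`c(start_col, end_col)`, inclusive).
#' @export
bottom_profile <- function(contour, depth_median) {
  if (!isTRUE(contour$touches_bottom))
    stop("contour does not reach the bottom image row")
  nr <- nrow(depth_median)
  row_vec <- integer(ncol(depth_median))
  row_vec[contour$bottom_cols] <- 1L
  runs <- solid_runs(row_vec)
  widths <- runs[, 2L] - runs[, 1L] + 1L
  best <- which.max(widths)                     # leftmost maximal run
  span <- c(start_col = runs[best, 1L], end_col = runs[best, 2L])
  d <- depth_median[nr, span[1L]:span[2L]]
  d <- d[d > 0L]
  depth_value <- if (length(d) == 0L) NA_real_ else median_depth(d)
  list(pixel_width = as.integer(widths[best]), depth_value = depth_value,
       span = span)
}

# maximal runs of 1s as a (start, end) matrix (equivalent to trimming the
# outer zeros and recursively splitting at interior zeros)
solid_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  cbind(starts[keep], ends[keep])
}

# median with even counts rounded to the nearest integer depth unit
median_depth <- function(d) round(stats::median(as.numeric(d)))

#' Fill missing per-tree depths from the frame's other trees
#'
#' Depth dropout can leave a detected tree with no valid depth anywhere in
#' its bottom-row span. Such trees are assigned the median depth of all
#' other trees in the same frame. If no tree in the frame has a valid
#' depth, all are assigned the camera's bottom-plane distance (the centre
#' of the row) converted to raw units.
#'
#' @param depths Numeric vector of raw depth values with `NA` for missing.
#' @param camera A [camera_model()], used only for the all-missing
#'   fallback.
#' @return Numeric vector with all depths filled.
#' @export
resolve_missing_depth <- function(depths, camera = camera_model()) {
  miss <- is.na(depths)
  if (!any(miss)) return(depths)
  if (all(miss))
    return(rep(camera$bottom_plane_distance / camera$depth_scale,
               length(depths)))
  # median of the *other* trees' depths; with one frame-wide pool this is
  # the median of all non-missing depths for every missing tree
  depths[miss] <- median_depth(depths[!miss])
  depths
}

#' Measure diameters of all detected trees in a frame
#'
#' For each detection: extract the bottom-row profile, resolve any missing
#' depths from the other trees of the frame, and convert pixel width and
#' depth to a diameter in millimetres via [diameter_from_width()].
#'
#' @param trees List of `detected_tree` objects from [detect_trees()].
#' @param depth_median Median-filtered depth matrix of the frame.
#' @param camera A [camera_model()].
#' @return The same list with each tree's `measurement` slot populated
#'   (a `tree_measurement` plus the bottom-row `span`).
#' @export
measure_trees <- function(trees, depth_median, camera = camera_model()) {
  if (length(trees) == 0L) return(trees)
  profiles <- lapply(trees, function(tr)
    bottom_profile(tr$contour, depth_median))
  depths <- vapply(profiles, function(p) as.numeric(p$depth_value),
                   numeric(1))
  depths <- resolve_missing_depth(depths, camera)
  for (i in seq_along(trees)) {
    m <- diameter_from_width(profiles[[i]]$pixel_width, depths[i], camera)
    m$span <- profiles[[i]]$span
    m$depth_was_missing <- is.na(profiles[[i]]$depth_value)
    trees[[i]]$measurement <- m
  }
  trees
}
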