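#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a solid rectangular kernel, used to
#' bridge small gaps left by the flood fill. The default kernel is 15 rows
#' x 2 columns — an upright rectangle matching the tall, narrow shape of a
#' stem. The kernel anchor sits at `floor(k / 2)` (0-based) in each
#' dimension; pixels outside the frame count as background for the
#' dilation and as foreground for the erosion, so closing never erodes the
#' mask at the frame border.
#'
#' @param mask Binary integer matrix.
#' @param kernel Integer vector `c(rows, cols)` of the solid kernel,
#'   default `c(15, 2)`.
#' @param iterations Number of dilations before the same number of
#'   erosions, default 1.
#' @return Binary integer matrix.
#' @export
morphological_close <- function(mask, kernel = c(15L, 2L), iterations = 1L) {
  mask <- as_int_matrix(mask)
  kernel <- as.integer(kernel)
  stopifnot(length(kernel) == 2L, all(kernel >= 1L), iterations >= 1L)
  out <- mask
  for (i in seq_len(iterations)) out <- rect_minmax(out, kernel, max)
  for (i in seq_len(iterations)) out <- rect_minmax(out, kernel, min)
  out
}

# Separable rectangular max/min filter; pad value is the identity of `op`
# (0 for max, 1 for min) so the border never flips under closing.
rect_minmax <- function(m, kernel, op) {
  pad <- if (identical(op, max)) 0L else 1L
  m <- axis_minmax(m, kernel[1L], pad, op, rows = TRUE)
  axis_minmax(m, kernel[2L], pad, op, rows = FALSE)
}

axis_minmax <- function(m, k, pad, op, rows) {
  if (k == 1L) return(m)
  a <- k %/% 2L                       # 0-based anchor
  offs <- seq.int(-(k - 1L - a), a)   # window covers x - a .. x + (k-1-a)
  acc <- NULL
  combine <- if (identical(op, max)) pmax else pmin
  for (o in offs) {
    s <- shift_matrix(m, o, pad, rows)
    acc <- if (is.null(acc)) s else combine(acc, s)
  }
  acc
}

shift_matrix <- function(m, o, pad, rows) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  if (rows) {
    if (o > 0) out[(o + 1L):nr, ] <- m[1L:(nr - o), , drop = FALSE]
    else if (o < 0) out[1L:(nr + o), ] <- m[(1L - o):nr, , drop = FALSE]
    else out <- m
  } else {
    if (o > 0) out[, (o + 1L):nc] <- m[, 1L:(nc - o), drop = FALSE]
    else if (o < 0) out[, 1L:(nc + o)] <- m[, (1L - o):nc, drop = FALSE]
    else out <- m
  }
  out
}

#' Find external contours of a binary mask
#'
#' Labels 8-connected components and returns one contour per component.
#' Area is the filled pixel count of the component (robust for 1-2 px wide
#' shapes, where a boundary-polygon area would underestimate); holes are
#' ignored. Contours are returned in left-to-right scan order of their
#' first pixel.
#'
#' @param mask Binary integer matrix.
#' @return List of `tree_contour` objects, each with `points` (boundary
#'   (row, col) coordinates in row-major order), `pixels` (linear indices
#'   of the filled component), `area`, `bbox` (`c(top, left, height,
#'   width)`), `touches_bottom`, and `bottom_cols` (columns occupied on the
#'   bottom image row).
#' @export
find_contours <- function(mask) {
  mask <- as_int_matrix(mask)
  lab <- .cpp_label_components(mask, 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  nr <- nrow(mask)
  idx <- which(lab != 0L)
  by_lab <- split(idx, lab[idx])
  lapply(seq_len(n), function(k) {
    px <- by_lab[[as.character(k)]]
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    # boundary: component pixel with any 4-neighbour outside the component
    inside <- matrix(FALSE, nr, ncol(mask))
    inside[px] <- TRUE
    on_edge <- rows == 1L | rows == nr | cols == 1L | cols == ncol(mask)
    interior <- !on_edge
    if (any(interior)) {
      p <- px[interior]
      interior[interior] <- inside[p - 1L] & inside[p + 1L] &
        inside[p - nr] & inside[p + nr]
    }
    b <- !interior
    pts <- cbind(row = rows[b], col = cols[b])
    pts <- pts[order(pts[, 1L], pts[, 2L]), , drop = FALSE]
    bottom_cols <- sort(cols[rows == nr])
    structure(list(points = pts, pixels = px, area = length(px),
                   bbox = c(top = min(rows), left = min(cols),
                            height = max(rows) - min(rows) + 1L,
                            width = max(cols) - min(cols) + 1L),
                   touches_bottom = length(bottom_cols) > 0L,
                   bottom_cols = bottom_cols),
              class = "tree_contour")
  })
}

#' Filter contours down to tree candidates
#'
#' Keeps exactly the contours whose filled area is at least `min_area`
#' squared pixels and which reach the bottom image row (stems enter the
#' frame from below; anything that "appears" mid-frame is not a tree).
#' Order is preserved.
#'
#' @param contours List of `tree_contour` objects.
#' @param min_area Minimum filled area in squared pixels, default 600.
#' @return Filtered list of contours.
#' @export
filter_contours <- function(contours, min_area = 600) {
  keep <- vapply(contours, function(ct)
    ct$area >= min_area && ct$touches_bottom, logical(1))
  contours[keep]
}

#' Detect trees in a segmented frame
#'
#' Applies morphological closing to the binary segmentation mask, extracts
#' contours, filters them by area and bottom-row presence, and assigns tree
#' IDs left to right by each contour's leftmost bottom-row column.
#'
#' @param seg A [segment_frame()] result (or any list with a `binary_mask`
#'   matrix).
#' @param min_area Minimum contour area, default 600.
#' @param close_kernel Closing kernel `c(rows, cols)`, default `c(15, 2)`.
#' @param iterations Closing iterations, default 1.
#' @return List of `detected_tree` objects: `tree_id`, `contour`, and a
#'   `measurement` slot filled later by [measure_trees()].
#' @export
detect_trees <- function(seg, min_area = 600, close_kernel = c(15L, 2L),
                         iterations = 1L) {
  closed <- morphological_close(seg$binary_mask, close_kernel, iterations)
  kept <- filter_contours(find_contours(closed), min_area)
  if (length(kept) == 0L) return(list())
  left <- vapply(kept, function(ct) min(ct$bottom_cols), integer(1))
  kept <- kept[order(left)]
  lapply(seq_along(kept), function(i)
    structure(list(tree_id = i, contour = kept[[i]], measurement = NULL),
              class = "detected_tree"))
}
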