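#' Aligned grayscale + depth frame pair
#'
#' Container for one frame from the row-facing camera: an 8-bit grayscale
#' image from the monochrome imager and the depth map computed from the same
#' viewpoint, so the two are pixel-aligned. Depth value 0 encodes "no
#' confident stereo match" and is treated as invalid everywhere downstream.
#'
#' @param gray Integer matrix of intensities in 0..255; rows are image rows
#'   (row 1 = top of the image).
#' @param depth Integer matrix of non-negative raw depth units, same shape.
#' @param timestamp Frame capture time, seconds.
#' @param frame_id Integer frame identifier.
#' @return Object of class `frame_pair`.
#' @export
frame_pair <- function(gray, depth, timestamp = 0, frame_id = 1L) {
  gray <- as_int_matrix(gray)
  depth <- as_int_matrix(depth)
  stopifnot(identical(dim(gray), dim(depth)))
  if (min(gray) < 0L || max(gray) > 255L)
    stop("gray intensities must lie in [0, 255]")
  if (min(depth) < 0L) stop("depth units must be non-negative")
  structure(list(gray = gray, depth = depth,
                 timestamp = as.numeric(timestamp),
                 frame_id = as.integer(frame_id)),
            class = "frame_pair")
}

as_int_matrix <- function(x) {
  stopifnot(is.matrix(x))
  if (!is.integer(x)) storage.mode(x) <- "integer"
  x
}

#' Dynamic histogram thresholding parameters
#'
#' @param peak_range Width (in bins) of the candidate intensity range
#'   centred on the histogram peak; applied as plus/minus
#'   `floor(peak_range / 2)`.
#' @param low_limit Lowest intensity bin ever admitted to the candidate
#'   range.
#' @param count_difference Maximum allowed drop (in normalized 0-255 count
#'   units) below the peak count for a bin to stay in the intensity list.
#' @return Object of class `histogram_params`.
#' @export
histogram_params <- function(peak_range = 50, low_limit = 10,
                             count_difference = 50) {
  stopifnot(peak_range >= 0, low_limit >= 0, low_limit <= 255,
            count_difference >= 0, count_difference <= 255)
  structure(list(peak_range = peak_range, low_limit = as.integer(low_limit),
                 count_difference = count_difference),
            class = "histogram_params")
}

#' Fixed-range flood-fill parameters
#'
#' @param lowdiff,updiff Maximal allowed brightness below / above the seed
#'   pixel's intensity for a pixel to join the seed's component.
#' @param connectivity Pixel adjacency, 4 or 8.
#' @return Object of class `flood_params`.
#' @export
flood_params <- function(lowdiff = 10, updiff = 30, connectivity = 4L) {
  stopifnot(lowdiff >= 0, updiff >= 0, connectivity %in% c(4L, 8L))
  structure(list(lowdiff = lowdiff, updiff = updiff,
                 connectivity = as.integer(connectivity)),
            class = "flood_params")
}

#' Median-filter a depth map
#'
#' Square-kernel median filter with replicated borders, used to remove
#' speckle noise from the raw depth map while keeping stem edges sharp.
#'
#' @param depth Integer matrix of raw depth units.
#' @param kernel Odd kernel side length in pixels (default 5).
#' @return Filtered integer matrix, same shape.
#' @export
median_filter_depth <- function(depth, kernel = 5L) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be odd and >= 1")
  .cpp_median_filter(as_int_matrix(depth), kernel)
}

#' Depth mask against the tilted threshold plane
#'
#' A pixel is foreground (1) when its filtered depth, converted to metres,
#' is strictly closer than the threshold plane at that image row, and its
#' depth is valid (non-zero). Invalid (zero) depth carries no information
#' and is masked out.
#'
#' @param depth_median Median-filtered depth matrix, raw units.
#' @param plane A [build_threshold_plane()] result.
#' @param camera A [camera_model()] (supplies `depth_scale`).
#' @return Binary integer matrix (0/1).
#' @export
depth_mask <- function(depth_median, plane, camera) {
  stopifnot(inherits(plane, "threshold_plane"),
            inherits(camera, "camera_model"),
            nrow(depth_median) == length(plane$per_row_threshold))
  depth_median <- as_int_matrix(depth_median)
  # per_row_threshold recycles down each column of the column-major matrix
  m <- (depth_median * camera$depth_scale < plane$per_row_threshold) &
    (depth_median > 0L)
  storage.mode(m) <- "integer"
  m
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Divides the image into a `tiles` x `tiles` grid, computes each tile's
#' 256-bin histogram, clips every bin at
#' `max(1, round(clip_limit * tile_pixels / 256))` and redistributes the
#' clipped excess uniformly (any remainder goes one count at a time to the
#' lowest bins), maps intensities through the clipped cumulative
#' distribution scaled to 0..255, and bilinearly interpolates between the
#' four nearest tile mappings at each pixel (clamped to the edge tiles
#' outside the grid of tile centres).
#'
#' @param gray Integer matrix of 8-bit intensities.
#' @param clip_limit Relative clip limit (default 40).
#' @param tiles Number of tiles per side (default 8).
#' @return Equalized integer matrix in 0..255.
#' @export
equalize_clahe <- function(gray, clip_limit = 40, tiles = 8L) {
  gray <- as_int_matrix(gray)
  nr <- nrow(gray); nc <- ncol(gray)
  tiles <- as.integer(tiles)
  stopifnot(tiles >= 1L, clip_limit > 0)
  if (tiles > nr || tiles > nc)
    stop("tile grid larger than frame: need at least one pixel per tile")
  rbreak <- round(seq(0L, nr, length.out = tiles + 1L))
  cbreak <- round(seq(0L, nc, length.out = tiles + 1L))
  ntile <- tiles * tiles
  luts <- matrix(0L, nrow = 256L, ncol = ntile)
  cy <- numeric(tiles); cx <- numeric(tiles)   # tile centres, 1-based px
  for (ty in seq_len(tiles)) {
    cy[ty] <- (rbreak[ty] + 1 + rbreak[ty + 1]) / 2
    for (tx in seq_len(tiles)) {
      cx[tx] <- (cbreak[tx] + 1 + cbreak[tx + 1]) / 2
      tile <- gray[(rbreak[ty] + 1L):rbreak[ty + 1L],
                   (cbreak[tx] + 1L):cbreak[tx + 1L], drop = FALSE]
      luts[, (tx - 1L) * tiles + ty] <- clahe_tile_lut(tile, clip_limit)
    }
  }
  # bilinear blend of the four nearest tile mappings
  iy <- findInterval(seq_len(nr), cy)          # 0..tiles
  y0 <- pmin(pmax(iy, 1L), tiles); y1 <- pmin(y0 + 1L, tiles)
  y1[iy == 0L] <- 1L
  wy <- ifelse(y1 == y0, 0, (seq_len(nr) - cy[y0]) / (cy[y1] - cy[y0]))
  ix <- findInterval(seq_len(nc), cx)
  x0 <- pmin(pmax(ix, 1L), tiles); x1 <- pmin(x0 + 1L, tiles)
  x1[ix == 0L] <- 1L
  wx <- ifelse(x1 == x0, 0, (seq_len(nc) - cx[x0]) / (cx[x1] - cx[x0]))

  g1 <- gray + 1L
  X0 <- matrix(x0, nr, nc, byrow = TRUE); X1 <- matrix(x1, nr, nc, byrow = TRUE)
  WX <- matrix(wx, nr, nc, byrow = TRUE)
  Y0 <- matrix(y0, nr, nc);  Y1 <- matrix(y1, nr, nc)
  WY <- matrix(wy, nr, nc)
  lut_at <- function(TY, TX) luts[g1 + ((TX - 1L) * tiles + TY - 1L) * 256L]
  out <- (1 - WY) * (1 - WX) * lut_at(Y0, X0) +
         (1 - WY) * WX       * lut_at(Y0, X1) +
         WY       * (1 - WX) * lut_at(Y1, X0) +
         WY       * WX       * lut_at(Y1, X1)
  out <- matrix(as.integer(pmin(pmax(round(out), 0), 255)), nr, nc)
  out
}

# Clipped-CDF lookup table for one tile (0-based intensity index + 1).
clahe_tile_lut <- function(tile, clip_limit) {
  npix <- length(tile)
  counts <- tabulate(as.vector(tile) + 1L, nbins = 256L)
  clip <- max(1, round(clip_limit * npix / 256))
  excess <- sum(pmax(counts - clip, 0))
  counts <- pmin(counts, clip)
  counts <- counts + excess %/% 256L
  rem <- excess %% 256L
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  cdf <- cumsum(counts)
  as.integer(pmin(pmax(round(cdf * 255 / npix), 0), 255))
}

#' Dynamic histogram thresholding
#'
#' Finds the list of intensity values that best represent stem pixels in
#' the equalized frame. The 256-bin histogram is computed over the pixels
#' selected by `mask` (or the whole frame when `mask` is `NULL`), min-max
#' normalized to 0..255, and the candidate range is the peak bin plus/minus
#' `floor(peak_range / 2)`, clipped to `[low_limit, 255]`. A candidate
#' intensity survives when its normalized count exceeds
#' `255 - count_difference`. Ties for the peak go to the lowest intensity.
#'
#' @param gray_eq Equalized 8-bit intensity matrix.
#' @param mask Binary matrix restricting the histogram, or `NULL` for the
#'   full frame.
#' @param params A [histogram_params()].
#' @return Sorted integer vector of intensities (possibly empty).
#' @export
dynamic_histogram_threshold <- function(gray_eq, mask = NULL,
                                        params = histogram_params()) {
  gray_eq <- as_int_matrix(gray_eq)
  vals <- if (is.null(mask)) as.vector(gray_eq) else {
    stopifnot(identical(dim(mask), dim(gray_eq)))
    gray_eq[mask != 0L]
  }
  if (length(vals) == 0L) return(integer(0))
  counts <- tabulate(vals + 1L, nbins = 256L)
  rng <- range(counts)
  norm <- if (rng[2] == rng[1]) rep(255, 256L) else
    (counts - rng[1]) * 255 / (rng[2] - rng[1])
  peak <- which.max(counts) - 1L                 # lowest intensity on ties
  half <- params$peak_range %/% 2
  lo <- max(params$low_limit, peak - half)
  hi <- min(255L, peak + half)
  if (lo > hi) return(integer(0))
  cand <- lo:hi
  cand[norm[cand + 1L] > 255 - params$count_difference]
}

#' Zero out pixels outside the depth mask
#'
#' @param gray_eq Equalized intensity matrix.
#' @param mask Binary depth mask.
#' @return Matrix equal to `gray_eq` where `mask != 0` and 0 elsewhere.
#' @export
background_removed <- function(gray_eq, mask) {
  gray_eq <- as_int_matrix(gray_eq)
  stopifnot(identical(dim(mask), dim(gray_eq)))
  out <- gray_eq
  out[mask == 0L] <- 0L
  out
}

#' Seed-point coordinates for flood fill
#'
#' Returns, in row-major order (top row first, left to right), the
#' coordinates of every pixel of the background-removed frame whose value
#' appears in `intensity_list`. Value 0 encodes removed background and is
#' never a seed even if listed.
#'
#' @param background Background-removed intensity matrix.
#' @param intensity_list Integer vector of admissible intensities.
#' @return Two-column integer matrix of 1-based (row, col) seed points.
#' @export
find_seed_points <- function(background, intensity_list) {
  background <- as_int_matrix(background)
  keep <- setdiff(as.integer(intensity_list), 0L)
  if (length(keep) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("row", "col"))))
  hits <- which(matrix(background %in% keep, nrow(background)),
                arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  dimnames(hits) <- list(NULL, c("row", "col"))
  hits
}

#' Fixed-range flood fill from a list of seed points
#'
#' Seeds are processed in order; a seed that already lies inside the
#' accumulated mask is skipped (no new flood). Otherwise its connected
#' component is grown: a pixel joins when its intensity lies within
#' `[seed - lowdiff, seed + updiff]` — the comparison always references the
#' original seed, not the neighbouring pixel — and it is
#' connectivity-adjacent to an already-joined pixel. All components are
#' unioned into one binary mask.
#'
#' @param gray_eq Equalized intensity matrix.
#' @param seeds Two-column matrix of 1-based (row, col) seed points.
#' @param params A [flood_params()].
#' @return List with `mask` (binary integer matrix) and `seeds_flooded`
#'   (number of seeds that started a flood).
#' @export
flood_fill_segment <- function(gray_eq, seeds, params = flood_params()) {
  gray_eq <- as_int_matrix(gray_eq)
  seeds <- matrix(as.integer(seeds), ncol = 2L)
  if (nrow(seeds) > 0L &&
      (min(seeds[, 1L]) < 1L || max(seeds[, 1L]) > nrow(gray_eq) ||
       min(seeds[, 2L]) < 1L || max(seeds[, 2L]) > ncol(gray_eq)))
    stop("seed out of bounds")
  .cpp_flood_fill(gray_eq, seeds, as.integer(params$lowdiff),
                  as.integer(params$updiff), params$connectivity)
}

#' Segment one frame pair into a binary stem-candidate mask
#'
#' Runs the full segmentation chain: median-filter the depth map, threshold
#' it against the tilted plane, CLAHE-equalize the grayscale image, select
#' the stem intensity band by dynamic histogram thresholding, locate seed
#' points in the background-removed frame, and flood-fill from the seeds.
#' All intermediates are returned for inspection.
#'
#' @param frame A [frame_pair()].
#' @param camera A [camera_model()] whose frame size matches the frame.
#' @param hist_params A [histogram_params()].
#' @param flood_params A [flood_params()].
#' @param median_kernel Median filter kernel (odd), default 5.
#' @param clip_limit,tiles CLAHE parameters, defaults 40 and 8.
#' @param histogram_scope `"masked"` restricts the histogram to depth-mask
#'   pixels; `"full"` uses the whole equalized frame.
#' @param plane Optional precomputed [build_threshold_plane()] result.
#' @return Object of class `segmentation_result`: list with `depth_mask`,
#'   `gray_eq`, `intensity_list`, `seed_points`, `seeds_flooded`,
#'   `binary_mask`.
#' @export
segment_frame <- function(frame, camera = camera_model(),
                          hist_params = histogram_params(),
                          flood_params = stemyield::flood_params(),
                          median_kernel = 5L, clip_limit = 40, tiles = 8L,
                          histogram_scope = c("masked", "full"),
                          plane = NULL) {
  stopifnot(inherits(frame, "frame_pair"), inherits(camera, "camera_model"),
            nrow(frame$gray) == camera$frame_height,
            ncol(frame$gray) == camera$frame_width)
  histogram_scope <- match.arg(histogram_scope)
  if (is.null(plane)) plane <- build_threshold_plane(camera)
  depth_med <- median_filter_depth(frame$depth, median_kernel)
  dmask <- depth_mask(depth_med, plane, camera)
  gray_eq <- equalize_clahe(frame$gray, clip_limit, tiles)
  ilist <- dynamic_histogram_threshold(
    gray_eq, mask = if (histogram_scope == "masked") dmask else NULL,
    params = hist_params)
  bg <- background_removed(gray_eq, dmask)
  seeds <- find_seed_points(bg, ilist)
  ff <- flood_fill_segment(gray_eq, seeds, flood_params)
  structure(list(depth_mask = dmask, gray_eq = gray_eq,
                 depth_median = depth_med,
                 intensity_list = ilist, seed_points = seeds,
                 seeds_flooded = ff$seeds_flooded,
                 binary_mask = ff$mask),
            class = "segmentation_result")
}
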