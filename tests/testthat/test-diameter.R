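# build a one-contour fixture whose bottom row is the given 0/1 vector
contour_from_row <- function(row_vec, depth_row, extra_rows = 3L) {
  W <- length(row_vec)
  idx <- which(row_vec == 1L)
  m <- matrix(0L, extra_rows + 1L, W)
  m[extra_rows + 1L, ] <- as.integer(row_vec)
  m[seq_len(extra_rows), idx] <- 1L
  m[1L, min(idx):max(idx)] <- 1L   # bridge, so all runs share one contour
  ct <- find_contours(m)
  depth <- matrix(0L, extra_rows + 1L, W)
  depth[extra_rows + 1L, ] <- as.integer(depth_row)
  list(contour = ct, depth = depth)
}

test_that("bottom profile measures solid runs and medians non-zero depth", {
  f <- contour_from_row(c(0, 1, 1, 1, 0), c(0, 9, 9, 9, 0))
  p <- bottom_profile(f$contour[[1]], f$depth)
  expect_equal(p$pixel_width, 3L)
  expect_equal(p$depth_value, 9)
  expect_equal(unname(p$span), c(2L, 4L))
})

test_that("split bottom rows keep the widest solid run", {
  f <- contour_from_row(c(1, 1, 0, 1, 1, 1), c(5, 5, 0, 7, 7, 7))
  # the 2-px and 3-px pieces are one 8-connected component via the upper
  # rows, so one contour carries both runs; the wider (right) run wins
  expect_length(f$contour, 1L)
  p <- bottom_profile(f$contour[[1]], f$depth)
  expect_equal(p$pixel_width, 3L)
  expect_equal(unname(p$span), c(4L, 6L))
  expect_equal(p$depth_value, 7)
})

test_that("run selection equals the exhaustive run-length oracle", {
  set.seed(14)
  for (i in 1:30) {
    v <- rbinom(16, 1, 0.55)
    if (sum(v) == 0) v[7] <- 1
    d <- ifelse(v == 1, sample(500:1500, 16, TRUE), 0)
    f <- contour_from_row(v, d)
    # all bottom runs belong to one contour: connect them at the top
    m <- matrix(0L, 4, 16)
    m[4, ] <- as.integer(v)
    m[1, ] <- 1L
    m[2:3, which(v == 1)] <- 1L
    ct <- find_contours(m)[[1]]
    depth <- matrix(0L, 4, 16); depth[4, ] <- as.integer(d)
    p <- bottom_profile(ct, depth)
    runs <- oracle_runs(v)
    widths <- runs[, 2] - runs[, 1] + 1
    expect_equal(p$pixel_width, as.integer(max(widths)))
    best <- runs[which.max(widths), ]       # leftmost maximal run
    expect_equal(unname(p$span), as.integer(best))
    dd <- d[best[1]:best[2]]; dd <- dd[dd > 0]
    expect_equal(p$depth_value,
                 if (length(dd) == 0) NA_real_ else
                   round(median(as.numeric(dd))))
  }
})

test_that("width ties between runs go to the leftmost run", {
  f <- contour_from_row(c(1, 1, 0, 1, 1), c(4, 4, 0, 9, 9))
  p <- bottom_profile(f$contour[[1]], f$depth)
  expect_equal(unname(p$span), c(1L, 2L))
  expect_equal(p$depth_value, 4)
})

test_that("all-zero depth spans defer to the frame fallback", {
  f <- contour_from_row(c(0, 1, 1, 0), c(0, 0, 0, 0))
  p <- bottom_profile(f$contour[[1]], f$depth)
  expect_true(is.na(p$depth_value))
})

test_that("missing depths resolve to the median of the other trees", {
  expect_equal(resolve_missing_depth(c(10, NA, 20)), c(10, 15, 20))
  expect_equal(resolve_missing_depth(c(5, 7, 9)), c(5, 7, 9))
  expect_equal(resolve_missing_depth(c(5, 7, 9, NA, NA)), c(5, 7, 9, 7, 7))
  cam <- camera_model()
  expect_equal(resolve_missing_depth(c(NA_real_, NA_real_), cam),
               rep(cam$bottom_plane_distance / cam$depth_scale, 2))
})

test_that("a contour absent from the bottom row cannot be profiled", {
  m <- matrix(0L, 5, 5); m[2:3, 2:3] <- 1L
  ct <- find_contours(m)[[1]]
  expect_error(bottom_profile(ct, matrix(0L, 5, 5)), "bottom")
})

test_that("measured diameters recover known stems to the quantization bound", {
  cam <- camera_model()
  expect_equal(measure_trees(list(), matrix(0L, 2, 2), cam), list())
  sc <- generate_scene(scene_spec(n_stems = 3, diameter_range_mm = c(35, 35),
                                  stem_depth_m = 1.23,
                                  stem_depth_jitter_m = 0, seed = 31), cam)
  # measure from the rendered stem mask itself: the chain from bottom-row
  # runs through the mm conversion must recover the projected diameter to
  # within one pixel-equivalent (quantization only)
  mask <- matrix(as.integer(sc$frame$depth == 1230L),
                 nrow(sc$frame$depth), ncol(sc$frame$depth))
  dmed <- median_filter_depth(sc$frame$depth, 5)
  trees <- measure_trees(detect_trees(list(binary_mask = mask)), dmed, cam)
  expect_length(trees, 3L)
  for (tr in trees) {
    expect_lt(abs(tr$measurement$diameter_mm - 35), 1.9)
    expect_equal(tr$measurement$depth_value, 1230)
  }
})

test_that("a depth-dropped stem falls back to the frame median depth", {
  cam <- camera_model()
  sc <- generate_scene(scene_spec(n_stems = 3, drop_stem_depth = 2L,
                                  stem_depth_jitter_m = 0, seed = 32), cam)
  seg <- segment_frame(sc$frame, cam)
  trees <- measure_trees(detect_trees(seg), seg$depth_median, cam)
  expect_length(trees, 3L)
  missing <- vapply(trees, function(t) t$measurement$depth_was_missing,
                    logical(1))
  expect_equal(sum(missing), 1L)
  others <- vapply(trees[!missing], function(t) t$measurement$depth_value,
                   numeric(1))
  expect_equal(trees[[which(missing)]]$measurement$depth_value,
               round(median(others)))
})

test_that("depth noise keeps the diameter RMSE within 5 mm", {
  cam <- camera_model()
  plane <- build_threshold_plane(cam)
  errs <- c()
  for (f in 1:25) {   # 25 frames x 8 stems = 200 stems
    sc <- generate_scene(scene_spec(depth_noise_sigma = 10,
                                    seed = 4000 + f), cam)
    seg <- segment_frame(sc$frame, cam, plane = plane)
    trees <- measure_trees(detect_trees(seg), seg$depth_median, cam)
    gt <- sc$ground_truth
    spans <- vapply(trees, function(t) t$measurement$span[[1]], numeric(1))
    ends <- vapply(trees, function(t) t$measurement$span[[2]], numeric(1))
    for (i in seq_len(nrow(gt))) {
      j <- which(spans <= gt$span_end[i] & ends >= gt$span_start[i])
      if (length(j) == 1)
        errs <- c(errs, trees[[j]]$measurement$diameter_mm -
                    gt$diameter_mm[i])
    }
  }
  expect_gt(length(errs), 180)
  expect_lte(sqrt(mean(errs^2)), 5)
})
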