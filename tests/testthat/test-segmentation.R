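test_that("median filter handles constants, impulses and matches the oracle", {
  const <- matrix(7L, 6, 6)
  expect_equal(median_filter_depth(const, 5), const)
  imp <- matrix(0L, 7, 7); imp[4, 4] <- 100L
  expect_equal(median_filter_depth(imp, 3), matrix(0L, 7, 7))
  expect_error(median_filter_depth(const, 4), "odd")
  set.seed(3)
  for (i in 1:5) {
    x <- rand_gray(9, 9, 0, 4000)
    expect_equal(median_filter_depth(x, 3), oracle_median(x, 3))
    expect_equal(median_filter_depth(x, 5), oracle_median(x, 5))
  }
})

test_that("depth mask thresholds against the plane and rejects zero depth", {
  cam <- camera_model(frame_width = 4, frame_height = 4)
  plane <- build_threshold_plane(cam)
  far <- matrix(5000L, 4, 4)
  expect_equal(depth_mask(far, plane, cam), matrix(0L, 4, 4))
  near <- matrix(round(1000 * cam$bottom_plane_distance / 2), 4, 4)
  expect_equal(depth_mask(near, plane, cam), matrix(1L, 4, 4))
  # mixed toy vs an explicit elementwise comparison
  d <- matrix(c(0L, 600L, 1300L, 5000L), 4, 4)
  got <- depth_mask(d, plane, cam)
  for (i in 1:4) for (j in 1:4) {
    want <- as.integer(d[i, j] * cam$depth_scale <
                         plane$per_row_threshold[i] && d[i, j] > 0)
    expect_identical(got[i, j], want)
  }
})

test_that("depth mask is anti-monotone in depth", {
  cam <- small_camera(16, 16)
  plane <- build_threshold_plane(cam)
  set.seed(4)
  d <- rand_gray(16, 16, 0, 3000)
  m1 <- depth_mask(d, plane, cam)
  bump <- d + rand_gray(16, 16, 0, 500)
  m2 <- depth_mask(bump, plane, cam)
  expect_true(all(m2 <= m1 | d == 0))   # raising depth never turns 0 into 1
})

test_that("CLAHE preserves constants and the 8-bit range", {
  const <- matrix(123L, 16, 16)
  out <- equalize_clahe(const, tiles = 2)
  expect_true(all(out == out[1, 1]))
  set.seed(5)
  x <- rand_gray(32, 32)
  out <- equalize_clahe(x, tiles = 4)
  expect_true(all(out >= 0 & out <= 255))
  expect_error(equalize_clahe(matrix(0L, 4, 4), tiles = 8), "tile")
})

test_that("CLAHE equals the clipped-CDF oracle where tiles are exact", {
  set.seed(6)
  # single tile: global clipped equalization
  x <- rand_gray(16, 16, 40, 200)
  expect_equal(equalize_clahe(x, clip_limit = 40, tiles = 1),
               oracle_clahe_one_tile(x, 40))
  # gradient image split into tiles: at each tile centre the bilinear
  # weights vanish, so the mapping is the tile's own clipped CDF
  g <- matrix(rep(seq(10L, 240L, length.out = 16), each = 16), 16, 16,
              byrow = TRUE)
  storage.mode(g) <- "integer"
  out <- equalize_clahe(g, clip_limit = 40, tiles = 2)
  # outside the grid of tile centres the blend clamps to the corner tile,
  # so the corner 4x4 blocks must equal that tile's own clipped-CDF map
  for (ty in 1:2) for (tx in 1:2) {
    rows <- if (ty == 1) 1:8 else 9:16
    cols <- if (tx == 1) 1:8 else 9:16
    lut <- oracle_clahe_one_tile(g[rows, cols], 40)
    pr <- if (ty == 1) 1:4 else 13:16
    pc <- if (tx == 1) 1:4 else 13:16
    expect_equal(out[pr, pc],
                 lut[match(pr, rows), match(pc, cols)])
  }
})

test_that("dynamic histogram threshold matches the exhaustive oracle", {
  p <- histogram_params(peak_range = 6, low_limit = 10,
                        count_difference = 50)
  # single spike
  img <- matrix(77L, 8, 8)
  expect_equal(dynamic_histogram_threshold(img, NULL, p), 77L)
  # empty mask
  expect_equal(dynamic_histogram_threshold(img, matrix(0L, 8, 8), p),
               integer(0))
  # vacuous count difference keeps the whole clipped candidate range
  # (every bin in the range must hold mass, or min-max kills it)
  img2 <- matrix(rep(c(100L, 101L, 102L), length.out = 64), 8, 8)
  got <- dynamic_histogram_threshold(img2, NULL,
                                     histogram_params(6, 10, 255))
  expect_equal(got, 100:102)
  # two populations vs brute force, masked and unmasked
  set.seed(7)
  for (i in 1:8) {
    img3 <- matrix(c(sample(58:70, 128, TRUE), sample(150:200, 128, TRUE)),
                   16, 16)
    mask <- matrix(rbinom(256, 1, 0.7), 16, 16)
    for (mk in list(NULL, mask)) {
      expect_equal(dynamic_histogram_threshold(img3, mk, p),
                   oracle_hist_threshold(img3, mk, 6, 10, 50))
    }
  }
})

test_that("histogram peak ties break to the lowest intensity", {
  img <- matrix(c(rep(40L, 30), rep(60L, 30), rep(200L, 4)), 8, 8)
  got <- dynamic_histogram_threshold(img, NULL,
                                     histogram_params(10, 10, 50))
  expect_true(40L %in% got)
  expect_false(60L %in% got)   # outside peak(40) +/- 5
})

test_that("background removal is an elementwise mask product", {
  set.seed(8)
  g <- rand_gray(6, 6)
  expect_equal(background_removed(g, matrix(1L, 6, 6)), g)
  expect_equal(background_removed(g, matrix(0L, 6, 6)), matrix(0L, 6, 6))
  chk <- matrix(rep_len(c(0L, 1L), 36), 6, 6)
  expect_equal(background_removed(g, chk), g * chk)
})

test_that("seed points enumerate matches in row-major order, never value 0", {
  expect_equal(nrow(find_seed_points(matrix(5L, 3, 3), integer(0))), 0L)
  u <- matrix(9L, 3, 4)
  s <- find_seed_points(u, 9L)
  expect_equal(nrow(s), 12L)
  expect_equal(s[1:4, ], cbind(row = rep(1L, 4), col = 1:4))
  # zero never seeds, even when listed
  z <- matrix(c(0L, 3L, 0L, 3L), 2, 2)
  expect_equal(nrow(find_seed_points(z, c(0L, 3L))), 2L)
  set.seed(9)
  img <- rand_gray(8, 8, 0, 9)
  lst <- c(2L, 5L, 7L)
  got <- find_seed_points(img, lst)
  want <- NULL
  for (i in 1:8) for (j in 1:8)
    if (img[i, j] %in% lst && img[i, j] != 0L)
      want <- rbind(want, c(i, j))
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(unname(got), unname(want))
})

test_that("flood fill equals breadth-first search and skips interior seeds", {
  fp <- flood_params(lowdiff = 10, updiff = 30)
  u <- matrix(100L, 5, 5)
  r <- flood_fill_segment(u, cbind(3L, 3L), fp)
  expect_equal(r$mask, matrix(1L, 5, 5))
  expect_equal(r$seeds_flooded, 1L)
  # isolated pixel differing beyond both bounds stays alone
  iso <- matrix(100L, 5, 5); iso[3, 3] <- 200L
  r2 <- flood_fill_segment(iso, cbind(3L, 3L), fp)
  expect_equal(sum(r2$mask), 1L)
  expect_equal(r2$mask[3, 3], 1L)
  # two-region image: BFS agreement and the skip rule
  two <- matrix(30L, 10, 10); two[, 6:10] <- 200L
  seeds <- rbind(c(2L, 2L), c(5L, 3L), c(2L, 8L), c(9L, 9L))
  r3 <- flood_fill_segment(two, seeds, fp)
  o3 <- oracle_flood(two, seeds, 10, 30, 4)
  expect_equal(r3$mask, o3$mask)
  expect_equal(r3$seeds_flooded, o3$seeds_flooded)
  expect_equal(r3$seeds_flooded, 2L)   # later in-region seeds are skipped
  expect_error(flood_fill_segment(u, cbind(9L, 1L), fp), "bounds")
})

test_that("flood fill output is seed-reachable under the brightness band", {
  set.seed(10)
  fp <- flood_params(10, 30, 4L)
  for (i in 1:6) {
    g <- rand_gray(12, 12, 0, 60)
    seeds <- cbind(sample(1:12, 5, TRUE), sample(1:12, 5, TRUE))
    r <- flood_fill_segment(g, seeds, fp)
    o <- oracle_flood(g, seeds, 10, 30, 4)
    expect_equal(r$mask, o$mask)
    expect_equal(r$seeds_flooded, o$seeds_flooded)
    # mask covers every seed
    expect_true(all(r$mask[seeds] == 1L))
  }
})

test_that("segmentation of a frame is deterministic and ordered correctly", {
  cam <- small_camera()
  sc <- generate_scene(scene_spec(n_stems = 2, seed = 77), cam)
  s1 <- segment_frame(sc$frame, cam)
  s2 <- segment_frame(sc$frame, cam)
  expect_identical(s1$binary_mask, s2$binary_mask)
  expect_identical(s1$intensity_list, s2$intensity_list)
  expect_lte(s1$seeds_flooded, nrow(s1$seed_points))
  # every seed lies inside the depth mask
  expect_true(all(s1$depth_mask[s1$seed_points] == 1L))
})

test_that("all-background frames segment to an empty mask", {
  cam <- small_camera()
  sc <- generate_scene(scene_spec(n_stems = 0, seed = 5), cam)
  seg <- segment_frame(sc$frame, cam)
  expect_equal(sum(seg$depth_mask), 0L)
  expect_equal(sum(seg$binary_mask), 0L)
})
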