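#' Specification for one synthetic row scene
#'
#' Describes a frame of a willow row as seen by the tilted depth camera:
#' near-vertical stems standing close to the vertical row plane, background
#' beyond the depth-threshold plane, optional slanted branch clutter (the
#' designated false-positive source), a horizontal illumination gradient,
#' optional saturated patches, Gaussian depth noise and depth dropout
#' (zeros). Stems are rendered darker than the background with mild texture
#' noise, so their intensities form the distinct histogram spike the
#' dynamic thresholding keys on.
#'
#' @param n_stems Number of stems in the frame.
#' @param diameter_range_mm `c(min, max)` of true stem diameters, mm.
#' @param stem_depth_m Nominal stem distance from the camera, metres
#'   (default 1.22, the camera-to-row distance).
#' @param stem_depth_jitter_m Half-width of the uniform per-stem depth
#'   jitter, metres.
#' @param branch_density Expected number of branch objects per frame.
#' @param branch_width_range_mm `c(min, max)` of branch widths, mm.
#' @param background_depth_m Background distance, metres (beyond the
#'   threshold plane).
#' @param stem_mean,background_mean Mean 8-bit intensities of stem and
#'   (lit) background pixels.
#' @param texture_amplitude Half-width of the uniform per-pixel bark
#'   texture: stem (and branch) intensities are drawn uniformly from
#'   `mean - texture_amplitude` to `mean + texture_amplitude`. A flat
#'   texture distribution keeps the equalized stem histogram flat, which is
#'   what makes bark read as one coherent population after CLAHE.
#' @param background_texture_sigma Std. dev. of the lit-background texture
#'   (foliage and ground are much more variable than bark).
#' @param shadow_fraction Fraction of background pixels in deep shadow
#'   (dappled shade darker than the stems), present in every image region.
#' @param shadow_mean Mean intensity of shadow pixels.
#' @param stem_shade_jitter Half-width of the uniform per-stem shade
#'   offset, intensity units. Stems of visibly different shade equalize to
#'   different bands and are the main cause of partial flood fills.
#' @param gradient_amplitude Peak-to-centre amplitude of the horizontal
#'   illumination gradient, intensity units.
#' @param saturation_probability Probability that the frame contains an
#'   oversaturated (255) patch.
#' @param depth_noise_sigma Std. dev. of Gaussian depth noise, raw units.
#' @param depth_dropout_rate Fraction of pixels whose depth is zeroed.
#' @param drop_stem_depth Index of a stem whose depth is zeroed over the
#'   bottom 80 image rows (stereo-matching failure at the measurement
#'   height: every depth in the stem's bottom-row span is invalid, so the
#'   frame-median fallback must supply its depth), or `NULL`. Seeds from
#'   the upper part of the stem keep it detectable, as in the field case.
#' @param seed Integer RNG seed; the scene is deterministic per seed.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(n_stems = 8L,
                       diameter_range_mm = c(28.57, 60),
                       stem_depth_m = 1.22,
                       stem_depth_jitter_m = 0.003,
                       branch_density = 0,
                       branch_width_range_mm = c(5, 15),
                       background_depth_m = 3.0,
                       stem_mean = 60,
                       background_mean = 170,
                       texture_amplitude = 20,
                       background_texture_sigma = 25,
                       shadow_fraction = 0.12,
                       shadow_mean = 25,
                       stem_shade_jitter = 1,
                       gradient_amplitude = 0,
                       saturation_probability = 0,
                       depth_noise_sigma = 0,
                       depth_dropout_rate = 0,
                       drop_stem_depth = NULL,
                       seed = 1L) {
  stopifnot(n_stems >= 0, all(diameter_range_mm > 0),
            diameter_range_mm[1] <= diameter_range_mm[2],
            stem_depth_m + stem_depth_jitter_m < background_depth_m,
            depth_dropout_rate >= 0, depth_dropout_rate <= 1,
            saturation_probability >= 0, saturation_probability <= 1)
  structure(as.list(environment()), class = "scene_spec")
}

#' Render a synthetic frame pair with exact ground truth
#'
#' Stems are vertical strips spanning the full frame height whose
#' bottom-row pixel width is the exact inverse of the measurement chain:
#' `round(diameter_mm / mm_per_pixel(depth_raw))`. Branches are slanted
#' strips at stem-like depth and intensity; when a branch reaches the
#' bottom row its bottom span is placed clear of every stem span. The depth
#' map holds the per-object depth on objects and the background depth
#' elsewhere, then Gaussian noise and dropout zeros are applied (dropout
#' last, so zeros stay exactly zero).
#'
#' @param spec A [scene_spec()].
#' @param camera A [camera_model()].
#' @param timestamp,frame_id Passed to the [frame_pair()].
#' @return List with `frame` (a `frame_pair`) and `ground_truth` (a
#'   data.frame: `object_id`, `kind` ("stem"/"branch"), `span_start`,
#'   `span_end` (bottom-row columns, `NA` when the object does not reach
#'   the bottom row), `col_min`, `col_max` (full column footprint),
#'   `diameter_mm`, `depth_raw`, and `meets_table3_width` — whether the
#'   object is at least 10 px wide at half frame height, the manual
#'   validation width criterion).
#' @export
generate_scene <- function(spec, camera = camera_model(),
                           timestamp = 0, frame_id = 1L) {
  stopifnot(inherits(spec, "scene_spec"), inherits(camera, "camera_model"))
  with_seed(spec$seed, {
    H <- camera$frame_height; W <- camera$frame_width
    bg_raw <- round(spec$background_depth_m / camera$depth_scale)

    # ---- stems: widths from the inverse projection, disjoint bottom spans
    n <- spec$n_stems
    depths_m <- spec$stem_depth_m +
      runif2(n, -spec$stem_depth_jitter_m, spec$stem_depth_jitter_m)
    depth_raw <- round(depths_m / camera$depth_scale)
    diam <- runif2(n, spec$diameter_range_mm[1], spec$diameter_range_mm[2])
    px_w <- pmax(1L, as.integer(round(diam / vapply(
      depth_raw, mm_per_pixel, numeric(1), camera = camera))))
    margin <- 12L
    if (n > 0 && sum(px_w) + (n + 1L) * margin > W)
      stop("infeasible packing: stems do not fit in the frame width")
    starts <- integer(n)
    if (n > 0) {
      slack <- W - sum(px_w) - (n + 1L) * margin
      cuts <- if (n > 1) sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
              else sample.int(slack + 1L, 1L) - 1L
      pos <- margin + cuts[1L]
      for (i in seq_len(n)) {
        starts[i] <- pos + 1L
        pos <- pos + px_w[i] + margin +
          (if (i < n) cuts[i + 1L] - cuts[i] else 0L)
      }
    }

    # lit background with dappled deep shadow; both present in every tile
    shadow <- matrix(stats::runif(H * W) < spec$shadow_fraction, H, W)
    gray <- matrix(stats::rnorm(H * W, spec$background_mean,
                                spec$background_texture_sigma), H, W)
    gray[shadow] <- stats::rnorm(sum(shadow), spec$shadow_mean, 10)
    if (spec$gradient_amplitude != 0)
      gray <- gray + matrix(spec$gradient_amplitude *
                              (2 * (seq_len(W) - 1) / (W - 1) - 1),
                            H, W, byrow = TRUE)
    depth <- matrix(bg_raw, H, W)

    stem_off <- runif2(n, -spec$stem_shade_jitter, spec$stem_shade_jitter)
    for (i in seq_len(n)) {
      cols <- starts[i]:(starts[i] + px_w[i] - 1L)
      gray[, cols] <- spec$stem_mean + stem_off[i] +
        runif2(H * px_w[i], -spec$texture_amplitude, spec$texture_amplitude)
      depth[, cols] <- depth_raw[i]
    }

    # ---- branches: slanted strips at stem-like depth
    n_br <- if (spec$branch_density > 0)
      stats::rpois(1, spec$branch_density) else 0L
    br <- vector("list", n_br)
    gaps <- bottom_gaps(starts, px_w, W, margin = 4L)
    for (b in seq_len(n_br)) {
      bd_raw <- round((spec$stem_depth_m +
                         runif2(1, -0.02, 0.02)) / camera$depth_scale)
      bw_mm <- runif2(1, spec$branch_width_range_mm[1],
                      spec$branch_width_range_mm[2])
      bw_px <- max(1L, as.integer(round(bw_mm / mm_per_pixel(bd_raw, camera))))
      touches <- stats::runif(1) < 0.5 && nrow(gaps) > 0
      # branches lean 10-25 degrees off vertical, one way or the other
      slope <- sample(c(-1, 1), 1) * runif2(1, 0.17, 0.45)
      if (touches) {
        g <- gaps[sample.int(nrow(gaps), 1L), ]
        c0 <- round(runif2(1, g[1], max(g[1], g[2] - bw_px)))
        r0 <- H                                # anchored at the bottom row
        len <- as.integer(round(runif2(1, H / 4, H / 2)))
      } else {
        c0 <- sample.int(W, 1L)
        r0 <- as.integer(round(runif2(1, H / 4, H - 30)))
        len <- as.integer(round(runif2(1, H / 5, H / 2)))
      }
      rows <- seq.int(r0, by = -1L, length.out = min(len, r0))
      centres <- round(c0 + slope * (r0 - rows))
      br_shade <- spec$stem_mean +
        runif2(1, -spec$stem_shade_jitter, spec$stem_shade_jitter)
      span_bottom <- c(NA_integer_, NA_integer_)
      col_ext <- c(NA_integer_, NA_integer_)
      for (k in seq_along(rows)) {
        cc <- centres[k]:(centres[k] + bw_px - 1L)
        cc <- cc[cc >= 1L & cc <= W]
        if (length(cc) == 0L) next
        if (rows[k] == H) {
          # never overwrite a stem's bottom span
          cc <- cc[!bottom_in_stem(cc, starts, px_w)]
          if (length(cc) == 0L) next
          span_bottom <- c(min(cc), max(cc))
        }
        col_ext <- c(min(col_ext[1], cc, na.rm = TRUE),
                     max(col_ext[2], cc, na.rm = TRUE))
        gray[rows[k], cc] <- br_shade +
          runif2(length(cc), -spec$texture_amplitude, spec$texture_amplitude)
        depth[rows[k], cc] <- bd_raw
      }
      br[[b]] <- data.frame(kind = "branch",
                            span_start = span_bottom[1],
                            span_end = span_bottom[2],
                            col_min = col_ext[1], col_max = col_ext[2],
                            diameter_mm = bw_mm, depth_raw = bd_raw,
                            meets_table3_width = bw_px >= 10L)
    }

    # ---- lighting artefacts, texture, depth noise, dropout
    if (stats::runif(1) < spec$saturation_probability) {
      pr <- sample.int(max(1L, H - 40L), 1L)
      pc <- sample.int(max(1L, W - 60L), 1L)
      gray[pr:min(H, pr + 39L), pc:min(W, pc + 59L)] <- 255
    }
    gray <- matrix(as.integer(pmin(pmax(round(gray), 0), 255)), H, W)

    if (spec$depth_noise_sigma > 0)
      depth <- depth + matrix(round(stats::rnorm(H * W, 0,
                                                 spec$depth_noise_sigma)),
                              H, W)
    depth <- pmax(depth, 0)
    if (spec$depth_dropout_rate > 0) {
      drop <- stats::runif(H * W) < spec$depth_dropout_rate
      depth[drop] <- 0
    }
    if (!is.null(spec$drop_stem_depth) && n >= spec$drop_stem_depth) {
      i <- spec$drop_stem_depth
      rows <- max(1L, H - 79L):H
      # dropout halos extend past the stem edge, as stereo matching fails
      # around occlusion boundaries
      cols <- max(1L, starts[i] - 3L):min(W, starts[i] + px_w[i] + 2L)
      depth[rows, cols] <- 0
    }
    depth <- matrix(as.integer(depth), H, W)

    gt_stems <- if (n > 0)
      data.frame(kind = "stem", span_start = starts,
                 span_end = starts + px_w - 1L, col_min = starts,
                 col_max = starts + px_w - 1L, diameter_mm = diam,
                 depth_raw = depth_raw, meets_table3_width = px_w >= 10L)
      else NULL
    gt <- rbind(gt_stems, do.call(rbind, br))
    if (is.null(gt))
      gt <- data.frame(kind = character(0), span_start = integer(0),
                       span_end = integer(0), col_min = integer(0),
                       col_max = integer(0), diameter_mm = numeric(0),
                       depth_raw = numeric(0),
                       meets_table3_width = logical(0))
    gt <- cbind(object_id = seq_len(nrow(gt)), gt)
    rownames(gt) <- NULL

    list(frame = frame_pair(gray, depth, timestamp, frame_id),
         ground_truth = gt)
  })
}

runif2 <- function(n, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (lo >= hi) rep(lo, n) else stats::runif(n, lo, hi)
}

bottom_in_stem <- function(cols, starts, widths) {
  if (length(starts) == 0L) return(rep(FALSE, length(cols)))
  hit <- rep(FALSE, length(cols))
  for (i in seq_along(starts))
    hit <- hit | (cols >= starts[i] - 2L & cols <= starts[i] + widths[i] + 1L)
  hit
}

# free intervals on the bottom row wide enough for a branch foot
bottom_gaps <- function(starts, widths, W, margin = 4L) {
  n <- length(starts)
  bounds <- rbind(c(1L, if (n) min(starts) - margin else W),
                  if (n) cbind((starts + widths - 1L)[order(starts)][-n] + margin,
                               sort(starts)[-1L] - margin),
                  if (n) c(max(starts + widths - 1L) + margin, W))
  bounds[bounds[, 2L] - bounds[, 1L] >= 6L, , drop = FALSE]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a suite of synthetic frames, ground truth and GPS log
#'
#' Presets describe three study conditions: `clean` (stems only — no
#' clutter, gradient, noise or dropout), `paper_like` (branch clutter,
#' illumination gradient, occasional saturation, depth noise sigma = 10 raw
#' units and 5% dropout), and `stress` (heavier clutter and artefacts; its
#' first frame additionally has one stem with fully dropped-out depth). All
#' presets target 8 stems per frame with diameters spanning the commercial
#' willow classes (28.57 mm up to about 60 mm). Frames sit 1 s apart along
#' a straight northbound track driven at harvest speed (0.64 m/s), and a
#' matching synthetic NMEA GGA log is produced.
#'
#' @param preset `"clean"`, `"paper_like"` or `"stress"`.
#' @param n_frames Number of frames.
#' @param seed Integer master seed; per-frame seeds are derived from it.
#' @param camera A [camera_model()].
#' @param outdir Optional directory: when given, writes per-frame images
#'   (grayscale PNG + 16-bit depth TIFF), `manifest.csv`,
#'   `ground_truth.csv` and `gps.nmea` there.
#' @return List with `scenes` (list of [generate_scene()] results),
#'   `manifest` (data.frame `frame_id`, `gray_path`, `depth_path`,
#'   `timestamp`), `ground_truth` (row-bound with `frame_id`), `nmea`
#'   (sentences), and `camera`.
#' @export
generate_suite <- function(preset = c("clean", "paper_like", "stress"),
                           n_frames = 10L, seed = 1L,
                           camera = camera_model(), outdir = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    clean = list(branch_density = 0, gradient_amplitude = 0,
                 saturation_probability = 0, depth_noise_sigma = 0,
                 depth_dropout_rate = 0, stem_shade_jitter = 1),
    paper_like = list(branch_density = 4, gradient_amplitude = 30,
                      saturation_probability = 0.3, depth_noise_sigma = 10,
                      depth_dropout_rate = 0.05, stem_shade_jitter = 5),
    stress = list(branch_density = 8, gradient_amplitude = 60,
                  saturation_probability = 0.6, depth_noise_sigma = 15,
                  depth_dropout_rate = 0.15, stem_shade_jitter = 8))
  scenes <- vector("list", n_frames)
  gt_all <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    args <- c(base, list(seed = (seed * 10007L + f) %% .Machine$integer.max))
    if (preset == "stress" && f == 1L) args$drop_stem_depth <- 1L
    sp <- do.call(scene_spec, args)
    scenes[[f]] <- generate_scene(sp, camera, timestamp = f - 1,
                                  frame_id = f)
    gt <- scenes[[f]]$ground_truth
    if (nrow(gt)) gt <- cbind(frame_id = f, gt)
    else gt <- cbind(frame_id = integer(0), gt)
    gt_all[[f]] <- gt
  }
  ground_truth <- do.call(rbind, gt_all)

  # straight northbound track at 0.64 m/s (~2.3 km/h), one fix per second
  t <- seq_len(n_frames) - 1
  lat0 <- 45.85; lon0 <- -73.45
  fixes <- data.frame(timestamp = t,
                      lat = lat0 + (0.64 * t) / 111320,
                      lon = rep(lon0, n_frames), quality = 1L)
  nmea <- write_nmea_log(fixes)

  manifest <- data.frame(frame_id = seq_len(n_frames),
                         gray_path = NA_character_,
                         depth_path = NA_character_,
                         timestamp = t)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_len(n_frames)) {
      gp <- file.path(outdir, sprintf("frame_%04d_gray.png", f))
      dp <- file.path(outdir, sprintf("frame_%04d_depth.tif", f))
      write_frame_pair(scenes[[f]]$frame, gp, dp)
      manifest$gray_path[f] <- gp
      manifest$depth_path[f] <- dp
    }
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(ground_truth, file.path(outdir, "ground_truth.csv"),
                     row.names = FALSE)
    writeLines(nmea, file.path(outdir, "gps.nmea"))
  }
  list(scenes = scenes, manifest = manifest, ground_truth = ground_truth,
       nmea = nmea, camera = camera)
}

#' Write / read an aligned frame pair on disk
#'
#' The grayscale image is stored as an 8-bit PNG and the depth map as a
#' single-channel 16-bit TIFF (raw depth units).
#'
#' @param frame A [frame_pair()].
#' @param gray_path,depth_path Output paths.
#' @return `gray_path`, invisibly.
#' @export
write_frame_pair <- function(frame, gray_path, depth_path) {
  png::writePNG(frame$gray / 255, gray_path)
  tiff::writeTIFF(frame$depth / 65535, depth_path, bits.per.sample = 16L)
  invisible(gray_path)
}

#' @rdname write_frame_pair
#' @param timestamp,frame_id Metadata for the reconstructed pair.
#' @export
read_frame_pair <- function(gray_path, depth_path, timestamp = 0,
                            frame_id = 1L) {
  g <- png::readPNG(gray_path)
  if (length(dim(g)) == 3L) g <- g[, , 1L]
  d <- tiff::readTIFF(depth_path, as.is = TRUE)
  if (length(dim(d)) == 3L) d <- d[, , 1L]
  frame_pair(matrix(as.integer(round(g * 255)), nrow(g), ncol(g)),
             matrix(as.integer(d), nrow(d), ncol(d)),
             timestamp, frame_id)
}
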