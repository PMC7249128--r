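# stemyield

Willow grown in short-rotation forestry (SRF) is harvested as whole rows of
stems, and unlike grain or cotton there is no commercial yield monitor for
it: growers who want a yield map must count and calliper stems by hand.
`stemyield` implements a machine-vision yield-mapping pipeline for this
setting. A stereo depth camera rides along the row on the harvester, tilted
upward at the stems; each frame is a pair of aligned images — an 8-bit
grayscale image from the monochrome imager and a 16-bit depth map (raw
units, zero meaning "no confident stereo match"). The package detects the
stems in every frame, estimates each stem's diameter in millimetres from
its bottom-row pixel width and depth, and geotags per-frame counts and
diameters into an along-row yield transect using a raw NMEA GPS log.

Because field recordings of this kind are not generally available, the
package ships a synthetic scene generator that renders frame pairs with
exact ground truth (stem positions, diameters, depths, branch clutter,
lighting artifacts, depth noise and dropout), so every stage of the
pipeline is testable end to end.

## The algorithm

Per frame, with defaults shown:

1. **Depth mask.** The depth map is median-filtered (5×5) and thresholded
   against a *tilted threshold plane*: a per-image-row distance cutoff that
   grows from 1.23 m at the bottom row to ≈2.29 m at the top row, matching
   the camera's 28.5° tilt so the cutoff tracks the vertical plane through
   the row. A pixel is kept iff `0 < depth × scale < plane(row)`.
2. **CLAHE.** Contrast-limited adaptive histogram equalization (clip
   limit 40, 8×8 tile grid) normalizes the grayscale image across
   illumination changes.
3. **Dynamic histogram thresholding.** The 256-bin histogram of the
   equalized image, restricted to depth-mask pixels, is min-max normalized
   to 0–255. Around the peak bin a candidate range of ±`peak_range/2`
   (peak range 50) is clipped to `[low_limit, 255]`, and every intensity
   whose normalized count exceeds `255 − count_difference` enters the stem
   intensity list.
4. **Seed points and flood fill.** Every pixel of the background-removed
   frame whose value is in the intensity list becomes a seed. Seeds are
   flood-filled with a *fixed-range* criterion: a pixel joins a component
   iff its intensity lies in `[seed − lowdiff, seed + updiff]`
   (10 and 30), always relative to the original seed. Seeds already inside
   the accumulated mask are skipped.
5. **Detection.** The binary mask is closed with an upright 15×2 kernel,
   contours are extracted, and a contour is a tree iff its filled area is
   ≥ 600 px **and** it reaches the bottom image row (stems enter the frame
   from below). IDs are assigned left to right.
6. **Diameter.** The contour's bottom row is trimmed and split at interior
   gaps; the widest solid run is the stem. Its width in pixels is converted
   to millimetres through the camera geometry:

   ```
   distance_mm = depth × depth_scale × 1000
   half_frame_width_mm = tan(FOVx / 2) × distance_mm
   ratio_mm_per_px = half_frame_width_mm / (frame_width / 2)
   diameter_mm = pixel_width × ratio_mm_per_px
   ```

   The representative depth is the median of the non-zero depths across the
   chosen span; if all are zero (stereo dropout) the median depth of the
   frame's other trees is substituted.
7. **Geotagging.** GGA sentences are parsed (checksum-validated) from the
   NMEA log, frame positions are interpolated between bracketing fixes, and
   the transect accumulates haversine distance along the row.

## Worked example

```r
library(stemyield)

suite <- generate_suite("paper_like", n_frames = 5, seed = 42)
res <- run_pipeline(lapply(suite$scenes, function(s) s$frame),
                    nmea = suite$nmea, verbose = FALSE)
head(res$detections[, c("frame_id","tree_id","pixel_width","depth_raw","diameter_mm")])
#>   frame_id tree_id pixel_width depth_raw diameter_mm
#> 1        1       1          19      1221       34.40
#> 2        1       2           8      1211       14.36
#> 3        1       3          26      1217       46.92
#> 4        1       4          18      1224       32.67
#> 5        1       5          26      1222       47.11
#> 6        1       6          20      1216       36.06

evaluate_detections(res$detections, suite$ground_truth)
#> <detection_metrics> 40 detections: 38 correct (95.0%), 2 false, 2/40 stems undetected
#>   recall 95.0%; branch share of FPs 100.0%; RMSE 1.43 mm

res$transect[, c("frame_id","tree_count","mean_diameter_mm","distance_m")]
#>   frame_id tree_count mean_diameter_mm distance_m
#> 1        1          9            35.57     0.0000
#> 2        2          8            42.52     0.6401
#> 3        3          6            43.11     1.2800
#> 4        4          8            45.43     1.9201
#> 5        5          9            40.65     2.5600
```

Each detection row is one tree: its bottom-row width in pixels, its raw
depth (here ≈1220, i.e. 1.22 m at the row plane, where one pixel ≈1.82 mm),
and the resulting diameter. The 8-px detection in frame 1 is a branch
object — the characteristic false-positive mode of this pipeline: branches
hang at row depth, share the bark intensity band, and when large enough and
present on the bottom row they pass both contour filters. The evaluation
confirms that every false positive in this run is attributable to a branch.
The transect gives the along-row yield: tree count and mean diameter per
frame against cumulative distance (0.64 m between frames at harvest speed).

A command-line front end covering the same pipeline
(`run`, `synth`, `eval`, `default-config`) is installed at
`system.file("cli", "stemyield.R", package = "stemyield")`.

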