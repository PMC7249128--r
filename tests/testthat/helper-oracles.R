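# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

small_camera <- function(w = 64L, h = 48L)
  camera_model(frame_width = w, frame_height = h)

rand_gray <- function(nr, nc, lo = 0L, hi = 255L)
  matrix(sample(lo:hi, nr * nc, replace = TRUE), nr, nc)

# median filter, per-pixel double loop, replicated borders
oracle_median <- function(x, k) {
  h <- k %/% 2
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (-h:h), 1L), nr)
    jj <- pmin(pmax(j + (-h:h), 1L), nc)
    v <- as.vector(x[ii, jj])
    out[i, j] <- sort(v)[(length(v) + 2L) %/% 2L]
  }
  out
}

# clipped-CDF global equalization: CLAHE restricted to a single tile
oracle_clahe_one_tile <- function(x, clip_limit) {
  npix <- length(x)
  counts <- tabulate(as.vector(x) + 1L, nbins = 256L)
  clip <- max(1, round(clip_limit * npix / 256))
  excess <- sum(pmax(counts - clip, 0))
  counts <- pmin(counts, clip)
  counts <- counts + excess %/% 256
  r <- excess %% 256
  if (r > 0) counts[seq_len(r)] <- counts[seq_len(r)] + 1
  lut <- pmin(pmax(round(cumsum(counts) * 255 / npix), 0), 255)
  matrix(lut[x + 1L], nrow(x), ncol(x))
}

# dynamic histogram threshold, direct per-bin scan over all 256 bins
oracle_hist_threshold <- function(gray, mask, peak_range, low_limit,
                                  count_difference) {
  vals <- if (is.null(mask)) as.vector(gray) else gray[mask != 0]
  if (length(vals) == 0) return(integer(0))
  counts <- sapply(0:255, function(v) sum(vals == v))
  norm <- if (max(counts) == min(counts)) rep(255, 256) else
    (counts - min(counts)) * 255 / (max(counts) - min(counts))
  peak <- min(which(counts == max(counts))) - 1L
  out <- integer(0)
  for (v in 0:255) {
    in_range <- v >= peak - peak_range %/% 2 && v <= peak + peak_range %/% 2
    in_clip <- v >= low_limit && v <= 255
    if (in_range && in_clip && norm[v + 1] > 255 - count_difference)
      out <- c(out, v)
  }
  out
}

# fixed-range flood fill by explicit breadth-first search
oracle_flood <- function(gray, seeds, lowdiff, updiff, connectivity = 4) {
  nr <- nrow(gray); nc <- ncol(gray)
  mask <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  flooded <- 0L
  for (s in seq_len(nrow(seeds))) {
    sr <- seeds[s, 1]; sc <- seeds[s, 2]
    if (mask[sr, sc] == 1L) next
    flooded <- flooded + 1L
    ref <- gray[sr, sc]
    queue <- list(c(sr, sc))
    mask[sr, sc] <- 1L
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        q <- p + o
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (mask[q[1], q[2]] == 1L) next
        v <- gray[q[1], q[2]]
        if (v >= ref - lowdiff && v <= ref + updiff) {
          mask[q[1], q[2]] <- 1L
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  list(mask = mask, seeds_flooded = flooded)
}

# dilation / erosion by direct window scan; anchor floor(k/2) 0-based,
# outside-the-frame counts as 0 for dilation and 1 for erosion
oracle_dilate <- function(m, kr, kc) {
  ar <- kr %/% 2; ac <- kc %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- (i - ar):(i + kr - 1 - ar)
    jj <- (j - ac):(j + kc - 1 - ac)
    ii <- ii[ii >= 1 & ii <= nr]; jj <- jj[jj >= 1 & jj <= nc]
    out[i, j] <- max(m[ii, jj])
  }
  out
}

oracle_erode <- function(m, kr, kc) {
  ar <- kr %/% 2; ac <- kc %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(1L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- (i - ar):(i + kr - 1 - ar)
    jj <- (j - ac):(j + kc - 1 - ac)
    ii <- ii[ii >= 1 & ii <= nr]; jj <- jj[jj >= 1 & jj <= nc]
    out[i, j] <- min(m[ii, jj])
  }
  out
}

oracle_close <- function(m, kr, kc) oracle_erode(oracle_dilate(m, kr, kc),
                                                 kr, kc)

# connected-component labelling by repeated BFS (8-connectivity)
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] == 0L || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        q <- p + o
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (mask[q[1], q[2]] == 0L || lab[q[1], q[2]] != 0L) next
        lab[q[1], q[2]] <- nxt
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  lab
}

# all maximal runs of 1s in a binary vector, scanned element by element
oracle_runs <- function(v) {
  runs <- NULL
  start <- NA
  for (i in seq_along(v)) {
    if (v[i] == 1 && is.na(start)) start <- i
    if ((v[i] == 0 || i == length(v)) && !is.na(start)) {
      end <- if (v[i] == 0) i - 1L else i
      runs <- rbind(runs, c(start, end))
      start <- NA
    }
  }
  runs
}
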