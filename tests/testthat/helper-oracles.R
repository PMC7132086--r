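# Independent brute-force reference implementations. Deliberately written
# as plain per-pixel loops, sharing no code with the package internals.

oracle_bg_neighbors <- function(mask, r, c) {
  h <- nrow(mask); w <- ncol(mask); n <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > h || cc < 1 || cc > w || !mask[rr, cc]) n <- n + 1L
  }
  n
}

oracle_erode <- function(mask, iterations, count = 1L) {
  for (it in seq_len(iterations)) {
    out <- mask
    for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
      if (mask[r, c] && oracle_bg_neighbors(mask, r, c) >= count) {
        out[r, c] <- FALSE
      }
    }
    mask <- out
  }
  mask
}

oracle_dilate <- function(mask, iterations, count = 1L) {
  for (it in seq_len(iterations)) {
    out <- mask
    for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
      if (!mask[r, c] && 8L - oracle_bg_neighbors(mask, r, c) >= count) {
        out[r, c] <- TRUE
      }
    }
    mask <- out
  }
  mask
}

oracle_open <- function(mask, iterations, count = 1L) {
  oracle_dilate(oracle_erode(mask, iterations, count), iterations, count)
}

# Exact Euclidean distance to the nearest background pixel, where pixels
# outside the raster count as background at unit spacing.
oracle_distmap <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  bg <- which(!mask, arr.ind = TRUE)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    d_edge <- min(r, c, h + 1 - r, w + 1 - c)
    d_bg <- if (nrow(bg) > 0) {
      sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
    } else Inf
    out[r, c] <- min(d_edge, d_bg)
  }
  out
}

# Minimum-method threshold by exhaustive valley search after iterative
# 3-bin smoothing with replicated edges.
oracle_min_threshold <- function(counts, max_iter = 10000L) {
  y <- as.numeric(counts)
  n <- length(y)
  for (it in 0:max_iter) {
    peaks <- integer(0)
    for (k in 2:(n - 1)) {
      if (y[k] > y[k - 1] && y[k] > y[k + 1]) peaks <- c(peaks, k)
    }
    if (length(peaks) == 2L) {
      for (t in (peaks[1] + 1):(peaks[2] - 1)) {
        if (y[t - 1] > y[t] && y[t + 1] >= y[t]) return(t - 1L)
      }
      return(NA_integer_)
    }
    if (it == max_iter) return(NA_integer_)
    y2 <- y
    for (k in 1:n) {
      lo <- max(1, k - 1); hi <- min(n, k + 1)
      y2[k] <- (y[lo] + y[k] + y[hi]) / 3
    }
    y <- y2
  }
  NA_integer_
}

# Random plausibly-bimodal 256-bin histogram: two Gaussian-shaped modes
# plus mild Poisson noise.
random_bimodal_hist <- function() {
  m1 <- runif(1, 40, 95); m2 <- runif(1, 150, 220)
  s1 <- runif(1, 6, 18); s2 <- runif(1, 6, 18)
  n1 <- runif(1, 2e3, 2e4); n2 <- runif(1, 2e3, 2e4)
  bins <- 0:255
  mu <- n1 * dnorm(bins, m1, s1) + n2 * dnorm(bins, m2, s2) + 0.2
  rpois(256, mu)
}

# Two-cone height map with a known saddle on the straight line between
# the apexes: v = max(0, h_i - slope * dist_to_apex_i).
two_peak_map <- function(h1, h2, saddle, nrow = 30L, ncol = 60L) {
  p1 <- c(15, 15); p2 <- c(15, 46)
  D <- sqrt(sum((p1 - p2)^2))
  slope <- (h1 + h2 - 2 * saddle) / D
  stopifnot(slope > 0)
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  d1 <- sqrt((rr - p1[1])^2 + (cc - p1[2])^2)
  d2 <- sqrt((rr - p2[1])^2 + (cc - p2[2])^2)
  list(map = pmax(h1 - slope * d1, h2 - slope * d2, 0), p1 = p1, p2 = p2)
}

# Saddle-prominence oracle for a two-peak map: the lower peak is a
# separate maximum iff no path between the apexes stays strictly above
# (lower peak height - tolerance). Connectivity is checked by a scanline
# relaxation over the thresholded map.
oracle_two_peak_count <- function(tp, tolerance) {
  v2 <- min(tp$map[tp$p1[1], tp$p1[2]], tp$map[tp$p2[1], tp$p2[2]])
  keep <- tp$map > (v2 - tolerance) & tp$map > 0
  lab <- matrix(0L, nrow(keep), ncol(keep))
  lab[tp$p1[1], tp$p1[2]] <- 1L
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(keep))) for (c in seq_len(ncol(keep))) {
      if (!keep[r, c] || lab[r, c] == 1L) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(keep) && cc >= 1 && cc <= ncol(keep) &&
            lab[rr, cc] == 1L) {
          lab[r, c] <- 1L; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (lab[tp$p2[1], tp$p2[2]] == 1L) 1L else 2L
}

random_mask <- function(h = 32L, w = 32L, p = 0.55) {
  matrix(runif(h * w) < p, h, w)
}

# Small synthetic scene for fast pipeline-level tests.
small_scene <- function(seed, n_cells = 12L, noise_sd = 8, shape = "round") {
  generate_scene(scene_spec(height_px = 320L, width_px = 320L, n_cells = n_cells,
                            shape = shape, noise_sd = noise_sd, seed = seed))
}
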