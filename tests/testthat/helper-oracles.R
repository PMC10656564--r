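# Shared fixtures and independent oracles used across the suite.

# --- scene fixtures ---------------------------------------------------------

small_scene <- function(seed = 1, extent = c(120, 120), intensity = 150,
                        relief = c(900, 1400), ...) {
  scene_config(extent_m = extent, intensity_ha = intensity,
               dtm_relief = relief, seed = seed, ...)
}

# One tree standing alone on flat ground; returns chm/labels plus the table.
single_tree_scene <- function(height = 20, crown_radius = 4,
                              shape = "cone", extent = 40) {
  sc <- scene_config(extent_m = c(extent, extent), intensity_ha = 0,
                     dtm_relief = c(1000, 1000), seed = 1)
  tr <- data.frame(tree_id = 1L, x = extent / 2, y = extent / 2,
                   height = height, crown_radius = crown_radius,
                   crown_base_height = 0.4 * height, genus = "Pinus",
                   crown_shape = shape, dead = FALSE, dead_fraction = 0,
                   predead = FALSE, stringsAsFactors = FALSE)
  c(render_chm(tr, sc), list(trees = tr, config = sc))
}

# --- voxel-marching ray oracle ---------------------------------------------

# Marches along the ray in small steps testing point membership with the
# closed-form inequality (independent of the quadratic-root ray test).
voxel_ray_hit <- function(origin, dir, solid, step = 0.05, max_t = 200) {
  dir <- dir / sqrt(sum(dir^2))
  t <- seq(step, max_t, by = step)
  pts <- cbind(origin[1] + t * dir[1], origin[2] + t * dir[2],
               origin[3] + t * dir[3])
  keep <- pts[, 3] <= solid$top + 1  # nothing above the crown matters
  any(canopymort:::point_in_solid(pts[keep, , drop = FALSE], solid))
}

# Inflate/deflate a crown solid's surfaces by d (m); used to flag grazing
# rays: a ray is non-grazing when the oracle answer is identical on the
# shrunk and grown solids.
resize_solid <- function(solid, d) {
  s <- solid
  if (solid$shape == "sphere") {
    s$sph_r <- max(solid$sph_r + d, 1e-3)
  } else {
    s$radius <- max(solid$radius + d, 1e-3)
    s$top <- solid$top + d
    s$base <- solid$base - d
  }
  s
}

# --- D8 routing oracle ------------------------------------------------------

# Raise interior pits by a hair until the surface drains everywhere, so that
# steepest-descent routing is unambiguous (no pits, no exact ties) and the
# implementation's pit/flat heuristics never engage.
make_pitless <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  repeat {
    changed <- FALSE
    for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
      nbrs <- z[(r - 1):(r + 1), (c - 1):(c + 1)][-5]
      if (z[r, c] <= min(nbrs)) {
        z[r, c] <- min(nbrs) + 1e-6
        changed <- TRUE
      }
    }
    if (!changed) return(z)
  }
}

# Independent steepest-descent routing: per-cell receiver by direct loops,
# then accumulation by walking the full path from every cell.
brute_force_accumulation <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  recv <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    best <- 0; bi <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      drop <- (z[r, c] - z[rr, cc]) / (sqrt(dr^2 + dc^2) * cell)
      if (drop > best) { best <- drop; bi <- (cc - 1L) * nr + rr }
    }
    recv[r, c] <- bi
  }
  acc <- matrix(1, nr, nc)
  for (i in seq_len(nr * nc)) {
    j <- recv[i]
    guard <- 0L
    while (j > 0L && guard < nr * nc) {
      acc[j] <- acc[j] + 1
      j <- recv[j]
      guard <- guard + 1L
    }
  }
  acc * cell^2
}

# --- piecewise brute-force oracle ------------------------------------------

# Weighted SSE of the best continuous 2-break model by naive enumeration
# with lm(); returns the minimising pair and its SSE.
brute_force_two_breaks <- function(x, y, w, min_seg = 3) {
  best <- list(sse = Inf, breaks = NULL)
  for (b1 in x) for (b2 in x) {
    if (b2 <= b1) next
    if (sum(x < b1) < min_seg || sum(x >= b1 & x < b2) < min_seg ||
        sum(x >= b2) < min_seg) next
    h1 <- pmax(x - b1, 0); h2 <- pmax(x - b2, 0)
    fit <- lm(y ~ x + h1 + h2, weights = w)
    sse <- sum(w * residuals(fit)^2)
    if (sse < best$sse) best <- list(sse = sse, breaks = c(b1, b2))
  }
  best
}

# --- simulated binned series with a known 2-break shape ---------------------

sim_piecewise_series <- function(seed, breaks = c(14, 39),
                                 slopes = c(-0.3, 0.25, -0.2),
                                 noise_sd = 0.12, x = seq(5, 59, 2)) {
  set.seed(seed)
  f <- slopes[1] * x + (slopes[2] - slopes[1]) * pmax(x - breaks[1], 0) +
    (slopes[3] - slopes[2]) * pmax(x - breaks[2], 0) + 10
  y <- f + rnorm(length(x), 0, noise_sd)
  w <- rpois(length(x), 40) + 5
  bin_weighted(x, y, w, bin_width = 2)
}
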