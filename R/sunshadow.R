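#' Crown solid of a tree
#'
#' Cone crowns have their apex at the stem top and base radius
#' `crown_radius` at `crown_base_height`; sphere crowns are centred midway
#' between crown base and top with radius
#' `min(crown_radius, (height - crown_base_height)/2)`.
#'
#' @param tree one-row tree table (or list) with `x`, `y`, `height`,
#'   `crown_radius`, `crown_base_height`, `crown_shape`.
#' @return list of class `crown_solid`.
#' @export
crown_solid <- function(tree) {
  shape <- tree$crown_shape %||% "cone"
  if (!shape %in% c("cone", "sphere")) stop("unknown crown shape: ", shape)
  s <- list(shape = shape, x = tree$x, y = tree$y,
            top = tree$height, base = tree$crown_base_height,
            radius = tree$crown_radius)
  if (shape == "sphere") {
    s$center_z <- (tree$height + tree$crown_base_height) / 2
    s$sph_r <- min(tree$crown_radius,
                   (tree$height - tree$crown_base_height) / 2)
  }
  structure(s, class = "crown_solid")
}

# Vectorized ray/solid intersection: origins is an n x 3 matrix, dir a unit
# 3-vector with positive z. Returns logical n-vector: does the ray from each
# origin (exclusive of its start point) pass through the solid?
ray_hits_solid <- function(origins, dir, solid) {
  eps <- 1e-9
  n <- nrow(origins)
  ox <- origins[, 1]; oy <- origins[, 2]; oz <- origins[, 3]
  dx <- dir[1]; dy <- dir[2]; dz <- dir[3]
  hit <- logical(n)
  if (solid$shape == "sphere") {
    ux <- ox - solid$x; uy <- oy - solid$y; uz <- oz - solid$center_z
    b <- ux * dx + uy * dy + uz * dz
    c0 <- ux^2 + uy^2 + uz^2 - solid$sph_r^2
    disc <- b^2 - c0
    t2 <- -b + sqrt(pmax(disc, 0))
    disc >= 0 & t2 > eps            # a forward intersection exists
  } else {
    # finite cone: apex (x, y, top), base radius at base height
    h_span <- solid$top - solid$base
    k <- solid$radius / h_span
    ux <- ox - solid$x; uy <- oy - solid$y
    w0 <- solid$top - oz              # apex height minus origin z
    a <- dx^2 + dy^2 - k^2 * dz^2
    b <- ux * dx + uy * dy + k^2 * w0 * dz
    c0 <- ux^2 + uy^2 - k^2 * w0^2
    hit <- logical(n)
    # quadratic roots
    if (abs(a) > eps) {
      disc <- b^2 - a * c0
      ok <- disc >= 0
      sq <- sqrt(pmax(disc, 0))
      for (t in list((-b - sq) / a, (-b + sq) / a)) {
        z <- oz + t * dz
        hit <- hit | (ok & t > eps & z >= solid$base - eps &
                        z <= solid$top + eps)
      }
    } else {
      t <- -c0 / (2 * b)
      z <- oz + t * dz
      hit <- hit | (is.finite(t) & t > eps & z >= solid$base - eps &
                      z <= solid$top + eps)
    }
    # base disk
    t <- (solid$base - oz) / dz
    px <- ox + t * dx - solid$x; py <- oy + t * dy - solid$y
    hit <- hit | (t > eps & px^2 + py^2 <= solid$radius^2)
    hit
  }
}

#' Does an upward ray intersect a crown solid?
#'
#' Closed-form quadratic intersection tests for sphere and finite cone
#' (lateral surface plus base disk). The ray starts at `origin_point` and
#' points toward the sun; `sun_direction` must have a positive vertical
#' component.
#'
#' @param origin_point numeric length 3 (x, y, z).
#' @param sun_direction numeric length 3, not all zero, `[3] > 0`.
#' @param solid a [crown_solid()].
#' @return logical.
#' @export
ray_intersects_solid <- function(origin_point, sun_direction, solid) {
  nrm <- sqrt(sum(sun_direction^2))
  if (nrm == 0) stop("zero-length sun direction")
  dir <- sun_direction / nrm
  if (dir[3] <= 0) stop("sun direction must point upward")
  as.logical(ray_hits_solid(matrix(origin_point, nrow = 1), dir, solid))
}

# Is a point inside the solid (closed-form inequality)? Vectorized over pts
# (n x 3). Independent of the ray test; used by the voxel-marching oracle.
point_in_solid <- function(pts, solid) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  r2 <- (x - solid$x)^2 + (y - solid$y)^2
  if (solid$shape == "sphere") {
    r2 + (z - solid$center_z)^2 <= solid$sph_r^2
  } else {
    k <- solid$radius / (solid$top - solid$base)
    z >= solid$base & z <= solid$top & r2 <= (k * (solid$top - z))^2
  }
}

# Seeded uniform sample of points on a crown solid's surface. Cones are
# sampled on the lateral surface (area element proportional to distance from
# the apex); spheres uniformly on the sphere.
sample_crown_surface <- function(solid, n, seed) {
  with_seed(seed, {
    if (solid$shape == "sphere") {
      v <- matrix(rnorm(3 * n), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      cbind(solid$x + solid$sph_r * v[, 1],
            solid$y + solid$sph_r * v[, 2],
            solid$center_z + solid$sph_r * v[, 3])
    } else {
      s <- sqrt(runif(n))                 # fraction of slant from apex
      th <- runif(n, 0, 2 * pi)
      r <- s * solid$radius
      z <- solid$top - s * (solid$top - solid$base)
      cbind(solid$x + r * cos(th), solid$y + r * sin(th), z)
    }
  })
}

#' Shadow configuration
#'
#' Defaults encode the reference simulation: a 15 m neighborhood, 23
#' half-hour time steps from 07:00 to 18:00 local solar time on 1 August
#' 2016 at the study latitude, 200 crown-surface sample points.
#'
#' @param neighborhood_radius neighbor eligibility radius (m).
#' @param time_steps decimal hours of the solar time steps.
#' @param date simulation day.
#' @param latitude_deg site latitude.
#' @param n_surface_samples crown-surface sample points (>= 50).
#' @param seed seed for sample-point placement.
#' @return list of class `shadow_config`.
#' @export
shadow_config <- function(neighborhood_radius = 15,
                          time_steps = seq(7, 18, by = 0.5),
                          date = "2016-08-01",
                          latitude_deg = 37.42,
                          n_surface_samples = 200,
                          seed = 1L) {
  if (n_surface_samples < 50) stop("n_surface_samples must be >= 50")
  if (any(time_steps < 0 | time_steps >= 24))
    stop("time steps must lie in [0, 24)")
  structure(list(neighborhood_radius = neighborhood_radius,
                 time_steps = time_steps, date = date,
                 latitude_deg = latitude_deg,
                 n_surface_samples = n_surface_samples,
                 seed = as.integer(seed)),
            class = "shadow_config")
}

#' Shaded crown fraction at one sun position
#'
#' Fraction of seeded uniform crown-surface sample points whose ray toward
#' the sun intersects at least one neighbor crown solid.
#'
#' @param tree central tree (row of a tree table).
#' @param neighbors tree table of neighbors (may be empty).
#' @param sun_elev,sun_azim solar elevation and azimuth (radians, azimuth
#'   clockwise from north).
#' @param n_samples number of surface sample points.
#' @param seed sampling seed.
#' @return shaded fraction in [0, 1].
#' @export
shadow_fraction_at_time <- function(tree, neighbors, sun_elev, sun_azim,
                                    n_samples = 200, seed = 1L) {
  if (sun_elev <= 0) stop("sun below horizon at requested time")
  if (nrow(neighbors) == 0) return(0)
  solid <- crown_solid(tree)
  pts <- sample_crown_surface(solid, n_samples, seed)
  dir <- c(sin(sun_azim) * cos(sun_elev),
           cos(sun_azim) * cos(sun_elev),
           sin(sun_elev))
  shaded <- logical(n_samples)
  for (j in seq_len(nrow(neighbors))) {
    if (all(shaded)) break
    ns <- crown_solid(neighbors[j, ])
    shaded <- shaded | ray_hits_solid(pts, dir, ns)
  }
  mean(shaded)
}

#' Daytime-averaged crown shadow ratio of one tree
#'
#' Per-time-step shaded fractions (sample points fixed across steps by the
#' config seed) averaged over the steps with the sun above the horizon,
#' times 100. Neighbors are the trees whose stems lie within
#' `neighborhood_radius` of the central tree, itself excluded.
#'
#' @param tree central tree (row of a tree table).
#' @param all_trees full tree table (central tree included or not).
#' @param config a [shadow_config()].
#' @return list of class `shadow_result`: `tree_id`, `step_hours`,
#'   `step_fraction` (NA where the sun is down), `crown_shadow_ratio` (%).
#' @export
crown_shadow_ratio <- function(tree, all_trees, config = shadow_config()) {
  stopifnot(inherits(config, "shadow_config"))
  d2 <- (all_trees$x - tree$x)^2 + (all_trees$y - tree$y)^2
  nb <- all_trees[d2 <= config$neighborhood_radius^2 &
                    all_trees$tree_id != tree$tree_id, , drop = FALSE]
  sp <- solar_position(config$latitude_deg, NULL, config$date,
                       config$time_steps)
  up <- sp$elevation_rad > 0
  if (!any(up)) stop("sun below horizon at every time step")
  frac <- rep(NA_real_, length(config$time_steps))
  pt_seed <- config$seed + tree$tree_id
  for (i in which(up)) {
    frac[i] <- shadow_fraction_at_time(
      tree, nb, sp$elevation_rad[i], sp$azimuth_rad[i],
      n_samples = config$n_surface_samples, seed = pt_seed)
  }
  structure(list(tree_id = tree$tree_id, step_hours = config$time_steps,
                 step_fraction = frac,
                 crown_shadow_ratio = 100 * mean(frac[up])),
            class = "shadow_result")
}

#' Crown shadow ratios for a whole tree table
#'
#' @param trees tree table.
#' @param config a [shadow_config()].
#' @return data.frame: `tree_id`, `crown_shadow_ratio`, `n_steps_lit`.
#' @export
compute_shadow_ratios <- function(trees, config = shadow_config()) {
  res <- lapply(seq_len(nrow(trees)), function(i)
    crown_shadow_ratio(trees[i, ], trees, config))
  data.frame(
    tree_id = vapply(res, `[[`, numeric(1), "tree_id"),
    crown_shadow_ratio = vapply(res, `[[`, numeric(1),
                                "crown_shadow_ratio"),
    n_steps_lit = vapply(res, function(r) sum(!is.na(r$step_fraction)),
                         numeric(1))
  )
}

#' Default mapping between crown shadow ratio and sunlit leaf fraction
#'
#' Reference grid: shadow ratio 73-91 % in steps of 3 paired with sunlit
#' fractions 0.17 down to 0.05 in steps of 0.02; extended linearly outside
#' the grid (slope -0.02/3 per percentage point of shadow).
#'
#' @return data.frame with `shadow_pct`, `f_sun`.
#' @export
sunlit_fraction_table <- function() {
  data.frame(shadow_pct = seq(73, 91, by = 3),
             f_sun = seq(0.17, 0.05, by = -0.02))
}

#' Relative evapotranspiration under crown shading (two-leaf reduction)
#'
#' Canopy ET is partitioned into sunlit and shaded leaf fractions with
#' different per-leaf rates driven by a saturating response to absorbed
#' radiation, `e(R) = 1 - exp(-R / R_half)`:
#' `ET_rel = (f e_sun + (1-f) e_shade) / (f0 e_sun + (1-f0) e_shade)`,
#' where `f` is the sunlit leaf fraction at the given shadow ratio (linear
#' mapping through `table`) and `f0` the unshaded reference. Because
#' `e_sun > e_shade`, ET declines monotonically as shading grows.
#'
#' @param shadow_ratio_pct crown shadow ratio (%), scalar or vector.
#' @param sunlit_to_total_leaf_ratio optional explicit sunlit fraction(s);
#'   overrides the table mapping.
#' @param table shadow-to-sunlit mapping (see [sunlit_fraction_table()]).
#' @param R_sun,R_shade absorbed radiation of sunlit / shaded leaves (W/m^2).
#' @param R_half half-saturation constant (W/m^2).
#' @return relative ET in (0, 1].
#' @export
relative_et_two_leaf <- function(shadow_ratio_pct = NULL,
                                 sunlit_to_total_leaf_ratio = NULL,
                                 table = sunlit_fraction_table(),
                                 R_sun = 1000, R_shade = 150,
                                 R_half = 400) {
  slope <- (table$f_sun[nrow(table)] - table$f_sun[1]) /
    (table$shadow_pct[nrow(table)] - table$shadow_pct[1])
  f0 <- table$f_sun[1] - slope * table$shadow_pct[1]   # shadow = 0 reference
  if (is.null(sunlit_to_total_leaf_ratio)) {
    if (is.null(shadow_ratio_pct))
      stop("give either shadow_ratio_pct or sunlit_to_total_leaf_ratio")
    f <- f0 + slope * shadow_ratio_pct
  } else {
    f <- sunlit_to_total_leaf_ratio
  }
  if (any(f <= 0 | f > 1))
    stop("sunlit leaf fraction outside (0, 1]")
  e <- function(R) 1 - exp(-R / R_half)
  e_sun <- e(R_sun); e_shade <- e(R_shade)
  (f * e_sun + (1 - f) * e_shade) / (f0 * e_sun + (1 - f0) * e_shade)
}
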