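#' @useDynLib canopymort, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rpois rweibull pweibull qweibull rbeta plogis
#'   quantile sd complete.cases
NULL

GENERA <- c("Abies", "Cedrus", "Pinus", "Quercus")

# Run `expr` under a fixed RNG stream without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Synthetic-scene configuration
#'
#' Bundles every parameter of the scene generator. Defaults emulate the
#' southern Sierra Nevada mixed-conifer setting the analysis is designed for:
#' relief spanning 730-2650 m, four genera stratified along the elevation
#' gradient (Abies highest, then Cedrus, Pinus, Quercus), a Quercus height
#' ceiling of 24 m, clustered stem positions, and a mortality process with a
#' piecewise height effect plus a negative neighborhood-competition effect.
#'
#' @param extent_m scene width/height in metres (length 2).
#' @param cell_size_m raster resolution (m).
#' @param dtm_relief min/max elevation (m).
#' @param intensity_ha expected stem density (trees/ha).
#' @param cluster use a Thomas cluster process (`TRUE`) or homogeneous Poisson.
#' @param parent_intensity_ha Thomas parent density (clusters/ha).
#' @param offspring_sd Gaussian scatter of offspring around parents (m).
#' @param genus_niches data.frame with columns genus, elev_mean, elev_sd,
#'   prior; niche weights are a prior-weighted Gaussian softmax in elevation.
#' @param height_model data.frame with columns genus, shape, scale, hmin, hmax
#'   (truncated Weibull above `hmin`).
#' @param allometry list: `a`, `b` in crown_radius = a * height^b, and
#'   `base_fraction` giving crown_base_height = base_fraction * height.
#' @param mortality a [mortality_params()] object.
#' @param classifier_noise spectral feature noise sd (class-mean units).
#' @param predead_prob probability a tree was already dead pre-drought.
#' @param stand_area_km2 mean stand size for the Voronoi tessellation (km^2).
#' @param seed integer; fully determines the generated scene.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(extent_m = c(500, 500),
                         cell_size_m = 1,
                         dtm_relief = c(730, 2650),
                         intensity_ha = 90,
                         cluster = TRUE,
                         parent_intensity_ha = 4,
                         offspring_sd = 12,
                         genus_niches = data.frame(
                           genus = GENERA,
                           elev_mean = c(2250, 1750, 1350, 950),
                           elev_sd = c(230, 210, 240, 190),
                           prior = c(0.3, 0.22, 0.28, 0.2)
                         ),
                         height_model = data.frame(
                           genus = GENERA,
                           shape = c(1.7, 1.7, 1.8, 2.0),
                           scale = c(18, 15, 17, 10),
                           hmin = c(2, 2, 2, 2),
                           hmax = c(62, 52, 56, 24)
                         ),
                         allometry = list(a = 0.6, b = 0.7,
                                          base_fraction = 0.4),
                         mortality = mortality_params(),
                         classifier_noise = 0.5,
                         predead_prob = 0.01,
                         stand_area_km2 = 0.144,
                         seed = 1L) {
  if (length(extent_m) == 1L) extent_m <- rep(extent_m, 2L)
  if (any(extent_m <= 0)) stop("scene extent must be positive")
  if (cell_size_m <= 0) stop("cell size must be positive")
  if (intensity_ha < 0) stop("tree intensity must be non-negative")
  if (dtm_relief[2] < dtm_relief[1]) stop("dtm_relief must be min <= max")
  stopifnot(all(GENERA %in% genus_niches$genus),
            all(GENERA %in% height_model$genus),
            all(genus_niches$prior > 0))
  cfg <- list(extent_m = extent_m, cell_size_m = cell_size_m,
              dtm_relief = dtm_relief, intensity_ha = intensity_ha,
              cluster = cluster, parent_intensity_ha = parent_intensity_ha,
              offspring_sd = offspring_sd, genus_niches = genus_niches,
              height_model = height_model, allometry = allometry,
              mortality = mortality, classifier_noise = classifier_noise,
              predead_prob = predead_prob, stand_area_km2 = stand_area_km2,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

#' Ground-truth mortality model parameters
#'
#' Logit-scale parameters of the generator's death process:
#' `logit P(dead) = beta0 + piecewise(height) + ccth_slope * CCTH +
#' elev_quad * ((elev - elev_center)/1000)^2 + noise`. The piecewise height
#' term is continuous with two knots and three per-segment slopes, defaulting
#' to the negative-positive-negative shape with knots at 14 m and 39 m; the
#' competition (CCTH) effect defaults negative. Dead-crown pixel fractions are
#' drawn from Beta mixtures above/below the 35 % calling threshold so that
#' threshold sweeps behave like real imagery.
#'
#' @param beta0 intercept (logit scale).
#' @param height_knots two strictly increasing breakpoints (m).
#' @param height_slopes three per-segment slopes (logit per m).
#' @param ccth_slope slope on CCTH (logit per percentage point).
#' @param elev_quad coefficient of the squared scaled-elevation term
#'   (U-shaped elevation effect); `elev_center` its vertex (m).
#' @param shadow_slope optional slope on crown shadow ratio (logit per
#'   percentage point); 0 disables the shadow pathway.
#' @param noise_sd logit-scale Gaussian noise sd.
#' @param dead_beta,live_beta length-2 Beta shape parameters for the crown
#'   dead-pixel fraction of dead and live trees.
#' @return list of class `mortality_params`.
#' @export
mortality_params <- function(beta0 = -0.35,
                             height_knots = c(14, 39),
                             height_slopes = c(-0.09, 0.05, -0.07),
                             ccth_slope = -0.02,
                             elev_quad = 1.2,
                             elev_center = 1650,
                             shadow_slope = 0,
                             noise_sd = 0.3,
                             dead_beta = c(6, 2.5),
                             live_beta = c(1.1, 9)) {
  if (length(height_knots) != 2L || diff(height_knots) <= 0)
    stop("height_knots must be two strictly increasing values")
  if (length(height_slopes) != 3L || any(!is.finite(height_slopes)))
    stop("height_slopes must be three finite values")
  structure(list(beta0 = beta0, height_knots = height_knots,
                 height_slopes = height_slopes, ccth_slope = ccth_slope,
                 elev_quad = elev_quad, elev_center = elev_center,
                 shadow_slope = shadow_slope, noise_sd = noise_sd,
                 dead_beta = dead_beta, live_beta = live_beta),
            class = "mortality_params")
}

# Continuous piecewise-linear height term used by the generator.
piecewise_height_term <- function(h, knots, slopes) {
  slopes[1] * h +
    (slopes[2] - slopes[1]) * pmax(h - knots[1], 0) +
    (slopes[3] - slopes[2]) * pmax(h - knots[2], 0)
}

#' Generate a smooth synthetic terrain model
#'
#' A broad cross-scene gradient plus a heavily smoothed Gaussian random field,
#' rescaled linearly to the configured relief bounds. Deterministic in the
#' config seed.
#'
#' @param config a [scene_config()].
#' @return elevation `grid_raster` (m), origin at (0, extent_y).
#' @export
generate_dtm <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nc <- max(1L, as.integer(round(config$extent_m[1] / config$cell_size_m)))
  nr <- max(1L, as.integer(round(config$extent_m[2] / config$cell_size_m)))
  rel <- config$dtm_relief
  with_seed(config$seed + 11L, {
    if (rel[2] == rel[1]) {
      m <- matrix(rel[1], nr, nc)
    } else {
      gx <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
      gy <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
      noise <- matrix(rnorm(nr * nc), nr, nc)
      sigma <- max(3, min(nr, nc) / 10)
      field <- gaussian_blur(noise, sigma)
      field <- (field - min(field)) / max(diff(range(field)), 1e-12)
      m <- 0.55 * gx + 0.15 * gy + 0.45 * field
      m <- rel[1] + (m - min(m)) / diff(range(m)) * (rel[2] - rel[1])
    }
    grid_raster(m, origin = c(0, nr * config$cell_size_m),
                cell_size = config$cell_size_m)
  })
}

#' Generate a synthetic tree list
#'
#' Stem positions from a Thomas cluster process (parents drawn in a window
#' buffered by 4 offspring sd so edge intensity is unbiased) or a homogeneous
#' Poisson process. Genus is sampled from a prior-weighted Gaussian softmax
#' over elevation; heights are truncated Weibull draws per genus (Quercus
#' capped at 24 m by default); crown radius follows the power allometry
#' `a * height^b` and crown base sits at `base_fraction * height`. Conifer
#' genera get cone crowns, Quercus spheres.
#'
#' @param config a [scene_config()].
#' @param dtm elevation raster covering the extent (from [generate_dtm()]).
#' @return data.frame of tree records (one row per tree).
#' @export
generate_trees <- function(config, dtm) {
  stopifnot(inherits(config, "scene_config"), inherits(dtm, "grid_raster"))
  W <- config$extent_m[1]; H <- config$extent_m[2]
  area_ha <- W * H / 1e4
  with_seed(config$seed + 23L, {
    if (config$intensity_ha == 0) {
      xy <- matrix(numeric(0), ncol = 2)
    } else if (config$cluster) {
      buf <- 4 * config$offspring_sd
      aw <- W + 2 * buf; ah <- H + 2 * buf
      n_par <- rpois(1, config$parent_intensity_ha * aw * ah / 1e4)
      mu <- config$intensity_ha / config$parent_intensity_ha
      if (n_par == 0) {
        xy <- matrix(numeric(0), ncol = 2)
      } else {
        px <- runif(n_par, -buf, W + buf)
        py <- runif(n_par, -buf, H + buf)
        n_off <- rpois(n_par, mu)
        cx <- rep(px, n_off) + rnorm(sum(n_off), 0, config$offspring_sd)
        cy <- rep(py, n_off) + rnorm(sum(n_off), 0, config$offspring_sd)
        keep <- cx >= 0 & cx < W & cy >= 0 & cy < H
        xy <- cbind(cx[keep], cy[keep])
      }
    } else {
      n <- rpois(1, config$intensity_ha * area_ha)
      xy <- cbind(runif(n, 0, W), runif(n, 0, H))
    }
    n <- nrow(xy)
    if (n == 0) return(empty_tree_table())

    elev <- extract_at(dtm, xy[, 1], xy[, 2])
    elev[is.na(elev)] <- mean(config$dtm_relief)

    # genus: prior-weighted Gaussian softmax over elevation
    gn <- config$genus_niches
    logw <- sapply(seq_len(nrow(gn)), function(i)
      log(gn$prior[i]) - (elev - gn$elev_mean[i])^2 / (2 * gn$elev_sd[i]^2))
    logw <- logw - apply(logw, 1L, max)
    w <- exp(logw); w <- w / rowSums(w)
    u <- runif(n)
    cum <- t(apply(w, 1L, cumsum))
    gidx <- rowSums(u > cum) + 1L
    genus <- gn$genus[gidx]

    hm <- config$height_model[match(genus, config$height_model$genus), ]
    # truncated Weibull on (0, hmax - hmin], shifted by hmin
    fmax <- pweibull(hm$hmax - hm$hmin, hm$shape, hm$scale)
    height <- hm$hmin + qweibull(runif(n) * fmax, hm$shape, hm$scale)
    height <- pmin(height, hm$hmax)

    crown_radius <- config$allometry$a * height^config$allometry$b
    crown_base <- config$allometry$base_fraction * height
    shape <- ifelse(genus == "Quercus", "sphere", "cone")

    data.frame(
      tree_id = seq_len(n), x = xy[, 1], y = xy[, 2],
      height = height, crown_radius = crown_radius,
      crown_base_height = crown_base,
      genus = genus, crown_shape = shape,
      dead = NA, dead_fraction = NA_real_, predead = FALSE,
      stringsAsFactors = FALSE
    )
  })
}

empty_tree_table <- function() {
  data.frame(tree_id = integer(0), x = numeric(0), y = numeric(0),
             height = numeric(0), crown_radius = numeric(0),
             crown_base_height = numeric(0), genus = character(0),
             crown_shape = character(0), dead = logical(0),
             dead_fraction = numeric(0), predead = logical(0),
             stringsAsFactors = FALSE)
}

#' Assign ground-truth mortality to a synthetic tree list
#'
#' Draws live/dead states from the logistic model described in
#' [mortality_params()] and crown dead-pixel fractions from the configured
#' Beta mixtures (dead trees above, live trees below the calling threshold,
#' with overlap set by the Beta shapes). Trees flagged `predead` are dead
#' before the drought and also show a dead crown.
#'
#' @param trees tree table from [generate_trees()].
#' @param competition data.frame with columns `tree_id` and `ccth` (one row
#'   per tree, e.g. the 15 m radius records from [compute_all_indices()]).
#' @param dtm elevation raster.
#' @param params a [mortality_params()] object.
#' @param seed RNG seed for the mortality draws.
#' @param shadow optional data.frame with `tree_id`, `crown_shadow_ratio`
#'   (percent), used when `params$shadow_slope != 0`.
#' @param predead_prob probability a tree was already dead before the drought.
#' @return `trees` with `dead`, `dead_fraction`, `predead` filled in, plus a
#'   `p_dead` column with the true death probability.
#' @export
assign_mortality <- function(trees, competition, dtm, params,
                             seed = 1L, shadow = NULL, predead_prob = 0.01) {
  stopifnot(inherits(params, "mortality_params"))
  if (nrow(trees) == 0) return(trees)
  m <- match(trees$tree_id, competition$tree_id)
  if (anyNA(m)) {
    missing_ids <- trees$tree_id[is.na(m)]
    stop("no competition record for tree_id ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  ccth <- competition$ccth[m]
  elev <- extract_at(dtm, trees$x, trees$y)
  elev[is.na(elev)] <- params$elev_center
  eta <- params$beta0 +
    piecewise_height_term(trees$height, params$height_knots,
                          params$height_slopes) +
    params$ccth_slope * ccth +
    params$elev_quad * ((elev - params$elev_center) / 1000)^2
  if (params$shadow_slope != 0) {
    if (is.null(shadow)) stop("shadow_slope != 0 but no shadow table given")
    sm <- match(trees$tree_id, shadow$tree_id)
    if (anyNA(sm)) stop("no shadow record for tree_id ",
                        paste(trees$tree_id[is.na(sm)][1], collapse = ", "))
    eta <- eta + params$shadow_slope * shadow$crown_shadow_ratio[sm]
  }
  with_seed(seed, {
    n <- nrow(trees)
    if (params$noise_sd > 0) eta <- eta + rnorm(n, 0, params$noise_sd)
    p <- plogis(eta)
    dead <- runif(n) < p
    predead <- runif(n) < predead_prob
    trees$predead <- predead
    trees$dead <- dead | predead
    showing_dead <- trees$dead
    df <- numeric(n)
    df[showing_dead] <- rbeta(sum(showing_dead),
                              params$dead_beta[1], params$dead_beta[2])
    df[!showing_dead] <- rbeta(sum(!showing_dead),
                               params$live_beta[1], params$live_beta[2])
    trees$dead_fraction <- df
    trees$p_dead <- p
    trees
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize crown surfaces to a canopy height model
#'
#' Each crown is a solid of revolution (cone with apex at the stem top, or
#' upper hemisphere of a sphere); the CHM value of a pixel is the maximum
#' crown-surface height over all crowns covering its centre, 0 on open ground.
#' A label raster recording which tree owns each canopy pixel (the ground
#' truth crown map) is returned alongside.
#'
#' @param trees tree table.
#' @param config a [scene_config()].
#' @return list with `chm` and `labels` (`grid_raster`s). Labels are
#'   `tree_id`; 0 = ground.
#' @export
render_chm <- function(trees, config) {
  nc <- max(1L, as.integer(round(config$extent_m[1] / config$cell_size_m)))
  nr <- max(1L, as.integer(round(config$extent_m[2] / config$cell_size_m)))
  cell <- config$cell_size_m
  chm <- matrix(0, nr, nc)
  lab <- matrix(0L, nr, nc)
  xs <- (seq_len(nc) - 0.5) * cell
  ys <- (nr - seq_len(nr) + 0.5) * cell  # row 1 = north
  for (i in seq_len(nrow(trees))) {
    tr <- trees[i, ]
    r <- tr$crown_radius
    c0 <- which(xs >= tr$x - r & xs <= tr$x + r)
    r0 <- which(ys >= tr$y - r & ys <= tr$y + r)
    if (!length(c0) || !length(r0)) next
    dx <- xs[c0] - tr$x
    dy <- ys[r0] - tr$y
    d2 <- outer(dy^2, dx^2, `+`)
    inside <- d2 <= r^2
    if (!any(inside)) next
    d <- sqrt(d2)
    if (tr$crown_shape == "cone") {
      z <- tr$height - (tr$height - tr$crown_base_height) * d / r
    } else {
      cz <- (tr$height + tr$crown_base_height) / 2
      sr <- min(r, (tr$height - tr$crown_base_height) / 2)
      z <- cz + suppressWarnings(sqrt(pmax(sr^2 - d2, 0)))
      inside <- inside & d <= sr
    }
    z[!inside] <- -Inf
    sub_chm <- chm[r0, c0, drop = FALSE]
    sub_lab <- lab[r0, c0, drop = FALSE]
    upd <- z > sub_chm
    sub_chm[upd] <- z[upd]
    sub_lab[upd] <- tr$tree_id
    chm[r0, c0] <- sub_chm
    lab[r0, c0] <- sub_lab
  }
  # the stem cell records the full tree height (apex may fall between pixel
  # centres otherwise); taller overlapping crowns still win
  if (nrow(trees)) {
    org_y <- nr * cell
    ci <- floor(trees$x / cell) + 1L
    ri <- floor((org_y - trees$y) / cell) + 1L
    ok <- ci >= 1L & ci <= nc & ri >= 1L & ri <= nr
    for (i in which(ok)) {
      if (trees$height[i] > chm[ri[i], ci[i]]) {
        chm[ri[i], ci[i]] <- trees$height[i]
        lab[ri[i], ci[i]] <- trees$tree_id[i]
      }
    }
  }
  chm <- round(chm / 0.01) * 0.01  # 1 cm vertical quantization
  org <- c(0, nr * cell)
  list(chm = grid_raster(chm, org, cell),
       labels = grid_raster(lab, org, cell))
}

# Fixed class-mean matrix for the six land-cover classes x five spectral
# features; separated by >> typical noise so the noiseless limit is separable.
CLASS_LEVELS <- c("dead_tree", "green_tree", "grass", "bare_ground",
                  "artificial", "water")
class_means <- function() {
  matrix(c(
    6, 2, 1, 4, 5,     # dead tree: high red, low NIR
    1, 6, 5, 2, 1,     # green tree: high NIR/greenness
    2, 5, 3, 3, 2,     # grass
    5, 3, 1, 6, 6,     # bare ground
    7, 4, 2, 7, 8,     # artificial
    0, 1, 6, 0, 0      # water
  ), nrow = 6, byrow = TRUE,
  dimnames = list(CLASS_LEVELS, paste0("f", 1:5)))
}

#' Render land-cover classes and spectral features
#'
#' Canopy pixels take class dead_tree / green_tree: each dead (or pre-dead)
#' tree has `round(dead_fraction * n_pixels)` of its crown pixels flagged
#' dead (a seeded random subset); live trees likewise show their (small)
#' dead fraction. Ground pixels are assigned grass / bare ground / artificial
#' / water with fixed probabilities. Five per-pixel spectral features are the
#' class means plus Gaussian noise of sd `classifier_noise`.
#'
#' @param trees tree table with `dead` and `dead_fraction` assigned.
#' @param chm,labels rasters from [render_chm()].
#' @param config a [scene_config()].
#' @param seed RNG seed for pixel assignment and feature noise.
#' @return list: `classes` (integer `grid_raster`, codes 1-6 in the order
#'   dead_tree, green_tree, grass, bare_ground, artificial, water) and
#'   `spectral` (data.frame row, col, class, f1..f5).
#' @export
render_classes <- function(trees, chm, labels, config, seed = 1L) {
  lab <- labels$values
  cls <- matrix(3L, nrow(lab), ncol(lab))  # default grass
  with_seed(seed + 41L, {
    ground <- lab == 0L
    n_g <- sum(ground)
    cls[ground] <- sample(c(3L, 4L, 5L, 6L), n_g, replace = TRUE,
                          prob = c(0.75, 0.19, 0.03, 0.03))
    cls[!ground] <- 2L  # green tree
    if (nrow(trees)) {
      frac <- trees$dead_fraction
      frac[is.na(frac)] <- 0
      for (i in seq_len(nrow(trees))) {
        px <- which(lab == trees$tree_id[i])
        np <- length(px)
        if (np == 0) next
        nd <- round(frac[i] * np)
        if (nd > 0) cls[px[sample.int(np, nd)]] <- 1L
      }
    }
    mu <- class_means()
    feat <- mu[cls, , drop = FALSE] +
      matrix(rnorm(length(cls) * 5, 0, config$classifier_noise),
             ncol = 5)
    idx <- arrayInd(seq_along(cls), dim(cls))
    spectral <- data.frame(row = idx[, 1], col = idx[, 2],
                           class = CLASS_LEVELS[as.vector(cls)],
                           feat, stringsAsFactors = FALSE)
    names(spectral)[4:8] <- paste0("f", 1:5)
    list(classes = grid_raster(cls, chm$origin, chm$cell_size),
         spectral = spectral)
  })
}

#' Render a full scene (CHM, class raster, spectral features)
#'
#' Convenience wrapper around [render_chm()] and [render_classes()].
#'
#' @inheritParams render_classes
#' @return list with `chm`, `labels`, `classes`, `spectral`.
#' @export
render_scene <- function(trees, config, seed = config$seed) {
  if (nrow(trees) && anyNA(trees$dead)) {
    trees$dead[is.na(trees$dead)] <- FALSE
    trees$dead_fraction[is.na(trees$dead_fraction)] <- 0
  }
  rc <- render_chm(trees, config)
  cl <- render_classes(trees, rc$chm, rc$labels, config, seed)
  c(rc, cl)
}

#' Tessellate the scene into synthetic forest stands
#'
#' Voronoi cells of seeded random points, clipped to the scene rectangle; the
#' number of seeds is chosen so the mean stand area matches
#' `config$stand_area_km2` (default 0.144 km^2).
#'
#' @param config a [scene_config()].
#' @param n_stands override the seed count directly.
#' @return list with `seeds` (data.frame stand_id, x, y) and `polygons`
#'   (list of two-column coordinate matrices, one ring per stand).
#' @export
generate_stands <- function(config, n_stands = NULL) {
  W <- config$extent_m[1]; H <- config$extent_m[2]
  if (is.null(n_stands))
    n_stands <- max(2L, as.integer(round(W * H / (config$stand_area_km2 * 1e6))))
  with_seed(config$seed + 57L, {
    seeds <- data.frame(stand_id = seq_len(n_stands),
                        x = runif(n_stands, 0, W),
                        y = runif(n_stands, 0, H))
    polys <- lapply(seq_len(n_stands), function(i)
      voronoi_cell(seeds$x, seeds$y, i, W, H))
    list(seeds = seeds, polygons = polys)
  })
}

# Voronoi cell of seed i clipped to [0,W]x[0,H]: intersect the rectangle with
# the half-plane nearer to i than to each other seed (Sutherland-Hodgman).
voronoi_cell <- function(sx, sy, i, W, H) {
  poly <- cbind(c(0, W, W, 0), c(0, 0, H, H))
  for (j in seq_along(sx)) {
    if (j == i) next
    # half-plane: a*x + b*y <= c  (points closer to i than j)
    a <- sx[j] - sx[i]; b <- sy[j] - sy[i]
    cc <- (sx[j]^2 - sx[i]^2 + sy[j]^2 - sy[i]^2) / 2
    poly <- clip_halfplane(poly, a, b, cc)
    if (nrow(poly) == 0) break
  }
  poly
}

clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n)) {
    p1 <- poly[k, ]; p2 <- poly[if (k == n) 1 else k + 1, ]
    d1 <- a * p1[1] + b * p1[2] - cc
    d2 <- a * p2[1] + b * p2[2] - cc
    if (d1 <= 0) out <- rbind(out, p1)
    if ((d1 < 0) != (d2 < 0) && d1 != d2) {
      t <- d1 / (d1 - d2)
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  out
}

#' Assign trees (or points) to stands by nearest seed
#'
#' Nearest-seed assignment is exactly membership in the Voronoi tessellation
#' of [generate_stands()].
#'
#' @param x,y point coordinates.
#' @param stands result of [generate_stands()].
#' @return integer vector of stand ids.
#' @export
assign_stand <- function(x, y, stands) {
  s <- stands$seeds
  vapply(seq_along(x), function(i)
    s$stand_id[which.min((s$x - x[i])^2 + (s$y - y[i])^2)], integer(1))
}

#' Write stand polygons as GeoJSON
#'
#' @param stands result of [generate_stands()].
#' @param path output file.
#' @export
write_stands_geojson <- function(stands, path) {
  features <- lapply(seq_along(stands$polygons), function(i) {
    ring <- stands$polygons[[i]]
    if (nrow(ring) == 0) return(NULL)
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close ring
    list(
      type = "Feature",
      properties = list(stand_id = stands$seeds$stand_id[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(k) as.numeric(ring[k, ])))
      )
    )
  })
  features <- Filter(Negate(is.null), features)
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

TREE_COLUMNS <- c("tree_id", "x", "y", "height", "crown_radius",
                  "crown_base_height", "genus", "crown_shape", "dead",
                  "dead_fraction", "predead")

#' Write / read a tree table as CSV
#'
#' Column order is fixed and validated on read; unknown genus values are
#' rejected with the offending row number.
#'
#' @param trees tree table.
#' @param path file path.
#' @export
write_trees_csv <- function(trees, path) {
  cols <- intersect(TREE_COLUMNS, names(trees))
  utils::write.csv(trees[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trees_csv
#' @export
read_trees_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "x", "y", "height", "genus")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("tree CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!tr$genus %in% GENERA)
  if (length(bad)) stop("invalid genus value in row ", bad[1], ": ",
                        tr$genus[bad[1]])
  if (any(tr$height <= 0)) stop("non-positive height in row ",
                                which(tr$height <= 0)[1])
  tr
}
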