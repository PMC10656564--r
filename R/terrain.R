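#' Slope and aspect from a terrain model
#'
#' Horn's 3x3 finite-difference kernel. Aspect is the azimuth of the steepest
#' descent direction, measured clockwise from north, in radians; flat cells
#' (zero gradient) receive the nodata value. Border cells are computed with
#' edge replication, so their gradients are one-sided approximations.
#'
#' @param dtm elevation `grid_raster`.
#' @return list with `slope` (radians) and `aspect` (radians) rasters.
#' @export
slope_aspect <- function(dtm) {
  stopifnot(inherits(dtm, "grid_raster"))
  z <- dtm$values
  if (all(z == dtm$nodata)) stop("all-nodata raster")
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("need at least a 3x3 raster")
  cell <- dtm$cell_size
  # edge-replicated padded matrix
  zp <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  sh <- function(dr, dc) zp[(1:nr) + 1 + dr, (1:nc) + 1 + dc]
  # Horn kernel; x east-positive, y north-positive (row 1 = north)
  gx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
         (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * cell)
  gy <- ((sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
         (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))) / (8 * cell)
  slope <- atan(sqrt(gx^2 + gy^2))
  aspect <- atan2(-gx, -gy) %% (2 * pi)   # downslope azimuth, cw from north
  aspect[gx == 0 & gy == 0] <- dtm$nodata
  list(slope = grid_raster(slope, dtm$origin, cell, nodata = dtm$nodata),
       aspect = grid_raster(aspect, dtm$origin, cell, nodata = dtm$nodata))
}

# Steepest-descent D8 receiver for every cell: returns integer vector of
# receiver linear indices (0 = outlet / no lower neighbor).
d8_receivers <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  recv <- integer(n)
  best <- rep(0, n)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  dist <- sqrt(offs[, 1]^2 + offs[, 2]^2) * cell
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  for (k in 1:8) {
    rr <- rows + offs[k, 1]; cc <- cols + offs[k, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    nb <- (cc - 1L) * nr + rr
    drop <- rep(-Inf, n)
    drop[ok] <- (as.vector(z)[ok] - as.vector(z)[nb[ok]]) / dist[k]
    upd <- drop > best & drop > 0
    recv[upd] <- nb[upd]
    best[upd] <- drop[upd]
  }
  recv
}

#' D8 flow accumulation
#'
#' Single-cell pits are filled (raised to the lowest neighbor) before routing;
#' each cell then drains to its steepest-descent neighbor of the eight
#' (distance-weighted drop). Remaining flat cells are routed toward their
#' nearest neighbor that already has a flow direction (breadth-first from the
#' flat edges, i.e. distance-to-lower-edge tie-break), with a warning.
#' Accumulation is the number of cells draining through a cell, itself
#' included, times the cell area (m^2).
#'
#' @param dtm elevation `grid_raster`.
#' @return accumulation `grid_raster` (m^2).
#' @export
flow_accumulation_d8 <- function(dtm) {
  stopifnot(inherits(dtm, "grid_raster"))
  z <- dtm$values
  nr <- nrow(z); nc <- ncol(z); n <- nr * nc
  cell <- dtm$cell_size
  if (n == 1)
    return(grid_raster(matrix(cell^2, 1, 1), dtm$origin, cell))

  # fill single-cell pits (interior cells strictly below all neighbors)
  zp <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  nmin <- matrix(Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nmin <- pmin(nmin, zp[(1:nr) + 1 + dr, (1:nc) + 1 + dc])
  }
  pit <- z < nmin
  z[pit] <- nmin[pit]

  recv <- d8_receivers(z, cell)
  # border cells with no lower neighbor are outlets (recv 0); interior flats
  # are routed toward the nearest already-routed neighbor
  rows <- rep(seq_len(nr), nc); cols <- rep(seq_len(nc), each = nr)
  border <- rows == 1 | rows == nr | cols == 1 | cols == nc
  flats <- which(recv == 0L & !border)
  if (length(flats)) {
    warning("unresolved flat cells routed by distance to drainage")
    offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1),
                  c(-1, 0, 1, -1, 1, -1, 0, 1))
    pending <- flats
    repeat {
      progressed <- FALSE
      still <- integer(0)
      for (i in pending) {
        r0 <- rows[i]; c0 <- cols[i]
        done <- FALSE
        for (k in 1:8) {
          rr <- r0 + offs[k, 1]; cc <- c0 + offs[k, 2]
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          j <- (cc - 1L) * nr + rr
          if ((recv[j] != 0L || border[j]) && z[j] <= z[i] && recv[j] != i) {
            recv[i] <- j; done <- TRUE; progressed <- TRUE; break
          }
        }
        if (!done) still <- c(still, i)
      }
      pending <- still
      if (!length(pending) || !progressed) break
    }
  }

  # Kahn topological accumulation over the (acyclic) flow forest
  indeg <- tabulate(recv[recv > 0L], nbins = n)
  acc <- rep(1, n)
  queue <- which(indeg == 0L)
  head <- 1L
  queue <- c(queue, integer(0))
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L
    j <- recv[i]
    if (j > 0L) {
      acc[j] <- acc[j] + acc[i]
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  grid_raster(matrix(acc * cell^2, nr, nc), dtm$origin, cell)
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan(slope))` with specific catchment area
#' `a = accumulation / cell_size` (m). `tan(slope)` is floored at 0.001 so
#' flat terrain stays finite.
#'
#' @param dtm elevation `grid_raster`.
#' @param tan_floor lower bound for tan(slope).
#' @return TWI `grid_raster` (dimensionless).
#' @export
twi <- function(dtm, tan_floor = 0.001) {
  sa <- slope_aspect(dtm)
  acc <- flow_accumulation_d8(dtm)
  a <- acc$values / dtm$cell_size
  tb <- pmax(tan(sa$slope$values), tan_floor)
  grid_raster(log(a / tb), dtm$origin, dtm$cell_size)
}

#' Solar position from latitude, day of year, and local solar time
#'
#' Declination by the 23.45 deg sine approximation, elevation from
#' `sin h = sin(lat) sin(dec) + cos(lat) cos(dec) cos(omega)` with hour angle
#' `omega = 15 deg * (t - 12)`, azimuth clockwise from north. Local solar
#' time is used directly (no longitude / equation-of-time correction).
#'
#' @param latitude_deg geographic latitude (deg, positive north).
#' @param longitude_deg kept for interface completeness; unused under the
#'   local-solar-time convention.
#' @param date a `Date` (or string coercible to one).
#' @param local_solar_time decimal hours in `[0, 24)`.
#' @return list with `elevation_rad` and `azimuth_rad` (vectors if `date` or
#'   `local_solar_time` are vectors).
#' @export
solar_position <- function(latitude_deg, longitude_deg = NULL, date,
                           local_solar_time) {
  if (abs(latitude_deg) > 90) stop("latitude outside [-90, 90]")
  if (any(local_solar_time < 0 | local_solar_time >= 24))
    stop("time must be in [0, 24)")
  n <- as.POSIXlt(as.Date(date))$yday + 1
  dec <- (23.45 * pi / 180) * sin(2 * pi * (284 + n) / 365)
  phi <- latitude_deg * pi / 180
  omega <- (15 * (local_solar_time - 12)) * pi / 180
  sinh_ <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(omega)
  h <- asin(pmin(pmax(sinh_, -1), 1))
  cosaz <- (sin(dec) - sinh_ * sin(phi)) / (cos(h) * cos(phi))
  cosaz[!is.finite(cosaz)] <- 1
  az <- acos(pmin(pmax(cosaz, -1), 1))
  az <- ifelse(omega > 0, 2 * pi - az, az)
  list(elevation_rad = h, azimuth_rad = az %% (2 * pi))
}

#' Clear-sky solar radiation on terrain
#'
#' Per-cell sum over the requested hours of direct-beam irradiance on the
#' tilted surface, `S0 * tau^(1/sin h) * cos(incidence)` (negative incidence
#' clamped to zero), plus an isotropic diffuse term
#' `d * S0 * tau^(1/sin h) * sin h * (1 + cos slope)/2`. Units Wh/m^2 (one
#' value per listed hour). Hours with the sun below the horizon contribute
#' nothing; if all hours are dark a zero raster is returned with a warning.
#'
#' @param dtm elevation raster (used for grid geometry).
#' @param slope,aspect rasters from [slope_aspect()] (radians).
#' @param date day to simulate (default the study's reference summer day,
#'   2016-08-01).
#' @param hours vector of local solar hours (default 10:14, endpoints
#'   inclusive).
#' @param latitude_deg site latitude (deg).
#' @param solar_constant extraterrestrial irradiance (W/m^2).
#' @param transmittance broadband atmospheric transmittance per unit air mass.
#' @param diffuse_fraction isotropic diffuse fraction.
#' @return radiation `grid_raster` (Wh/m^2).
#' @export
clear_sky_radiation <- function(dtm, slope = NULL, aspect = NULL,
                                date = "2016-08-01", hours = 10:14,
                                latitude_deg = 37.42,
                                solar_constant = 1367,
                                transmittance = 0.7,
                                diffuse_fraction = 0.15) {
  stopifnot(inherits(dtm, "grid_raster"))
  if (is.null(slope) || is.null(aspect)) {
    sa <- slope_aspect(dtm)
    slope <- sa$slope; aspect <- sa$aspect
  }
  beta <- slope$values
  asp <- aspect$values
  flat <- asp == aspect$nodata
  asp[flat] <- 0; beta[flat] <- 0
  rad <- matrix(0, nrow(beta), ncol(beta))
  if (length(hours)) {
    any_sun <- FALSE
    for (t in hours) {
      sp <- solar_position(latitude_deg, NULL, date, t)
      h <- sp$elevation_rad
      if (h <= 0) next
      any_sun <- TRUE
      dni <- solar_constant * transmittance^(1 / sin(h))
      cosi <- cos(beta) * sin(h) +
        sin(beta) * cos(h) * cos(sp$azimuth_rad - asp)
      rad <- rad + dni * pmax(cosi, 0) +
        diffuse_fraction * dni * sin(h) * (1 + cos(beta)) / 2
    }
    if (!any_sun) warning("sun below horizon for all requested hours")
  }
  grid_raster(rad, dtm$origin, dtm$cell_size)
}
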