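plane_raster <- function(gx = 0, gy = 0, n = 9, cell = 1, z0 = 100) {
  xs <- (seq_len(n) - 0.5) * cell
  ys <- (n - seq_len(n) + 0.5) * cell
  grid_raster(outer(ys, xs, function(y, x) z0 + gx * x + gy * y),
              origin = c(0, n * cell), cell_size = cell)
}

test_that("slope and aspect recover analytic planes and flag flat cells", {
  flat <- plane_raster()
  sa <- slope_aspect(flat)
  expect_true(all(sa$slope$values == 0))
  expect_true(all(sa$aspect$values == sa$aspect$nodata))

  east <- plane_raster(gx = 0.1)     # z rises eastward
  sa_e <- slope_aspect(east)
  interior <- sa_e$slope$values[2:8, 2:8]
  expect_equal(as.vector(interior), rep(atan(0.1), 49), tolerance = 1e-10)
  # downslope points west: azimuth 270 deg
  expect_equal(as.vector(sa_e$aspect$values[2:8, 2:8]),
               rep(3 * pi / 2, 49), tolerance = 1e-10)

  south <- plane_raster(gy = 0.2)    # z rises northward, dips due south
  sa_s <- slope_aspect(south)
  expect_equal(as.vector(sa_s$aspect$values[2:8, 2:8]), rep(pi, 49),
               tolerance = 1e-10)

  expect_error(slope_aspect(grid_raster(matrix(-9999, 4, 4))), "nodata")
})

test_that("D8 accumulation matches hand-traced plane and the brute-force oracle", {
  # uniform plane dipping west: row-independent accumulation growing eastward
  pl <- plane_raster(gx = 0.1, n = 5)
  acc <- flow_accumulation_d8(pl)
  # westernmost column is most downstream; column k from the east edge
  # accumulates k+1 cells
  expect_equal(acc$values[3, ], c(5, 4, 3, 2, 1))

  # single cell
  single <- grid_raster(matrix(5, 1, 1), cell_size = 2)
  expect_equal(flow_accumulation_d8(single)$values[1, 1], 4)

  # V-shaped valley drains both flanks into the axis
  n <- 7
  xs <- (seq_len(n) - 0.5)
  v <- outer(rep(1, n), abs(xs - 3.5) * 0.5) +
    outer((n:1) * 0.2, rep(1, n))   # valley axis at column 4, draining south
  vr <- grid_raster(v, origin = c(0, n), cell_size = 1)
  acc_v <- flow_accumulation_d8(vr)
  oracle_v <- brute_force_accumulation(vr$values, 1)
  expect_equal(acc_v$values, oracle_v)
  expect_gt(acc_v$values[n, 4], acc_v$values[n, 2])

  # random smooth surfaces, grids up to 10x10: exact oracle agreement
  set.seed(31)
  for (rep in 1:5) {
    nn <- sample(4:10, 1)
    z <- matrix(rnorm(nn * nn), nn, nn)
    z <- canopymort:::gaussian_blur(z, 1) + 0.001 * matrix(rnorm(nn * nn), nn)
    zr <- grid_raster(
      make_pitless(z * 10 + outer(seq_len(nn), seq_len(nn)) * 0.5),
      origin = c(0, nn), cell_size = 1)
    expect_equal(flow_accumulation_d8(zr)$values,
                 brute_force_accumulation(zr$values, 1))
  }

  # every cell carries at least its own area
  expect_true(all(acc_v$values >= 1))
})

test_that("TWI follows its closed form on planes and stays finite on flats", {
  pl <- plane_raster(gx = 0.1, n = 7)
  t1 <- twi(pl)
  # interior cell one step in from the upstream (east) edge: two cells drain
  # through it, so a = 2 * cell and tan(slope) = 0.1 exactly (Horn interior)
  expect_equal(t1$values[4, 6], log(2 / 0.1), tolerance = 1e-9)

  # doubling cell size shifts TWI by log(2) at corresponding cells
  pl2 <- plane_raster(gx = 0.1, n = 7, cell = 2)
  t2 <- twi(pl2)
  expect_equal(t2$values[4, 6] - t1$values[4, 6], log(2), tolerance = 1e-9)

  flat <- plane_raster(n = 6)
  tf <- suppressWarnings(twi(flat))
  expect_true(all(is.finite(tf$values)))

  # monotone in accumulation at fixed slope / in slope at fixed accumulation
  expect_gt(t1$values[4, 1], t1$values[4, 7])   # downstream col accumulates more
  st <- plane_raster(gx = 0.4, n = 7)
  expect_lt(twi(st)$values[4, 7], t1$values[4, 7])
})

test_that("solar position behaves like the textbook geometry", {
  # equator at equinox, solar noon: sun overhead
  sp <- solar_position(0, NULL, as.Date("2024-03-21"), 12)
  expect_gt(sp$elevation_rad * 180 / pi, 89.5)

  # study latitude: noon elevation equals 90 - |lat - declination|
  n <- as.POSIXlt(as.Date("2016-08-01"))$yday + 1
  dec <- 23.45 * sin(2 * pi * (284 + n) / 365)
  noon <- solar_position(37.42, NULL, "2016-08-01", 12)
  expect_equal(noon$elevation_rad * 180 / pi, 90 - abs(37.42 - dec),
               tolerance = 1e-6)
  expect_equal(noon$azimuth_rad, pi, tolerance = 1e-6)

  # hour-angle symmetry around solar noon
  e10 <- solar_position(37.42, NULL, "2016-08-01", 10)$elevation_rad
  e14 <- solar_position(37.42, NULL, "2016-08-01", 14)$elevation_rad
  expect_equal(e10, e14, tolerance = 1e-12)

  # elevation peaks at noon over a fine grid and is continuous
  ts <- seq(5, 19, 0.25)
  el <- solar_position(37.42, NULL, "2016-08-01", ts)$elevation_rad
  expect_equal(ts[which.max(el)], 12)
  expect_lt(max(abs(diff(el))), 0.1)

  expect_error(solar_position(95, NULL, "2016-08-01", 12), "latitude")
  expect_error(solar_position(37, NULL, "2016-08-01", 24), "time")
})

test_that("clear-sky radiation matches a scalar closed form and incidence geometry", {
  flat <- plane_raster(n = 5)
  sa <- slope_aspect(flat)
  hours <- 10:14
  r <- clear_sky_radiation(flat, sa$slope, sa$aspect, hours = hours,
                           latitude_deg = 37.42)
  # independent scalar integration of the same formula on a flat cell
  expected <- 0
  for (t in hours) {
    sp <- solar_position(37.42, NULL, "2016-08-01", t)
    h <- sp$elevation_rad
    dni <- 1367 * 0.7^(1 / sin(h))
    expected <- expected + dni * sin(h) + 0.15 * dni * sin(h)
  }
  expect_equal(r$values[3, 3], expected, tolerance = 1e-9)

  # north-facing 30 deg slope receives less than flat ground in August
  # (z falls toward the north edge, i.e. rises southward)
  north <- plane_raster(gy = -tan(30 * pi / 180), n = 5)
  sa_n <- slope_aspect(north)
  rn <- clear_sky_radiation(north, sa_n$slope, sa_n$aspect,
                            latitude_deg = 37.42)
  expect_gt(r$values[3, 3], rn$values[3, 3])

  # empty hour list -> zero raster; all-dark hours -> zero with warning
  r0 <- clear_sky_radiation(flat, sa$slope, sa$aspect, hours = numeric(0))
  expect_true(all(r0$values == 0))
  expect_warning(
    rd <- clear_sky_radiation(flat, sa$slope, sa$aspect, hours = c(1, 2)),
    "horizon")
  expect_true(all(rd$values == 0))
})
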