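test_that("terrain generator respects relief bounds, degenerate relief, and seed determinism", {
  sc <- small_scene(seed = 42)
  d1 <- generate_dtm(sc)
  d2 <- generate_dtm(sc)
  expect_identical(d1$values, d2$values)
  expect_gte(min(d1$values), sc$dtm_relief[1])
  expect_lte(max(d1$values), sc$dtm_relief[2])

  flat <- scene_config(extent_m = c(30, 30), dtm_relief = c(1000, 1000))
  df <- generate_dtm(flat)
  expect_true(all(df$values == 1000))

  expect_error(scene_config(extent_m = c(-10, 10)), "positive")
  expect_error(scene_config(cell_size_m = 0), "positive")
})

test_that("tree counts match the intensity and zero intensity gives an empty list", {
  sc <- scene_config(extent_m = c(100, 100), intensity_ha = 100,
                     dtm_relief = c(1000, 1200), seed = 1)
  dtm <- generate_dtm(sc)
  counts <- vapply(1:200, function(s) {
    sci <- sc; sci$seed <- s
    nrow(generate_trees(sci, dtm))
  }, numeric(1))
  expected <- 100 * 1  # 100/ha on 1 ha
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)

  sc0 <- scene_config(extent_m = c(100, 100), intensity_ha = 0)
  expect_equal(nrow(generate_trees(sc0, generate_dtm(sc0))), 0)
})

test_that("genus niches order with elevation and Quercus respects its height cap", {
  sc <- scene_config(extent_m = c(400, 400), intensity_ha = 120, seed = 5)
  dtm <- generate_dtm(sc)
  tr <- generate_trees(sc, dtm)
  elev <- extract_at(dtm, tr$x, tr$y)
  med <- tapply(elev, tr$genus, median)
  expect_true(med["Abies"] > med["Cedrus"])
  expect_true(med["Cedrus"] > med["Pinus"])
  expect_true(med["Pinus"] > med["Quercus"])
  expect_lte(max(tr$height[tr$genus == "Quercus"]), 24)
  expect_true(all(tr$height > 0))
  expect_true(all(tr$crown_base_height < tr$height))
  expect_true(all(tr$crown_radius > 0))

  # disjoint niches pin genus to elevation bands
  scd <- scene_config(extent_m = c(200, 200), intensity_ha = 80, seed = 2,
                      genus_niches = data.frame(
                        genus = c("Abies", "Cedrus", "Pinus", "Quercus"),
                        elev_mean = c(2400, 1800, 1200, 800),
                        elev_sd = rep(5, 4), prior = rep(0.25, 4)))
  dtm2 <- generate_dtm(scd)
  tr2 <- generate_trees(scd, dtm2)
  e2 <- extract_at(dtm2, tr2$x, tr2$y)
  nearest <- c("Abies", "Cedrus", "Pinus", "Quercus")[
    apply(abs(outer(e2, c(2400, 1800, 1200, 800), "-")), 1, which.min)]
  expect_identical(tr2$genus, nearest)
})

test_that("mortality assignment follows the logistic ground truth", {
  sc <- scene_config(extent_m = c(250, 250), intensity_ha = 150,
                     dtm_relief = c(1000, 1000), seed = 3)
  dtm <- generate_dtm(sc)
  tr <- generate_trees(sc, dtm)
  comp <- data.frame(tree_id = tr$tree_id,
                     ccth = runif(nrow(tr), 0, 60))

  # all slopes zero, beta0 = 0 -> dead fraction near 0.5
  p0 <- mortality_params(beta0 = 0, height_slopes = c(0, 0, 0),
                         ccth_slope = 0, elev_quad = 0, noise_sd = 0)
  t0 <- assign_mortality(tr, comp, dtm, p0, seed = 9, predead_prob = 0)
  expect_lt(abs(mean(t0$dead) - 0.5), 3 * sqrt(0.25 / nrow(tr)))

  # saturated logit with no noise -> nobody dies
  pneg <- mortality_params(beta0 = -20, height_slopes = c(0, 0, 0),
                           ccth_slope = 0, elev_quad = 0, noise_sd = 0)
  tneg <- assign_mortality(tr, comp, dtm, pneg, seed = 9, predead_prob = 0)
  expect_equal(sum(tneg$dead), 0)

  # negative competition effect -> mortality decreasing across CCTH deciles
  pc <- mortality_params(beta0 = 1, height_slopes = c(0, 0, 0),
                         ccth_slope = -0.06, elev_quad = 0, noise_sd = 0)
  tc <- assign_mortality(tr, comp, dtm, pc, seed = 9, predead_prob = 0)
  dec <- cut(comp$ccth, quantile(comp$ccth, 0:10 / 10),
             include.lowest = TRUE)
  rates <- tapply(tc$dead, dec, mean)
  expect_lt(cor(seq_along(rates), rates, method = "spearman"), -0.8)

  # missing competition record errors with the tree id
  expect_error(assign_mortality(tr, comp[-1, ], dtm, p0),
               as.character(tr$tree_id[1]))

  # dead trees carry large dead fractions, live trees small ones
  expect_gt(mean(tc$dead_fraction[tc$dead]), 0.5)
  expect_lt(mean(tc$dead_fraction[!tc$dead]), 0.25)
})

test_that("rendered CHM has apex fidelity and per-pixel max compositing", {
  one <- single_tree_scene(height = 20, crown_radius = 4)
  apex <- extract_at(one$chm, one$trees$x, one$trees$y)
  expect_equal(apex, 20, tolerance = 0.006)  # within half the quantization

  # two overlapping crowns: overlap pixels take the taller surface
  sc <- scene_config(extent_m = c(40, 40), intensity_ha = 0,
                     dtm_relief = c(1000, 1000))
  tr <- data.frame(tree_id = 1:2, x = c(18, 23), y = c(20, 20),
                   height = c(12, 25), crown_radius = c(5, 5),
                   crown_base_height = c(4.8, 10), genus = "Pinus",
                   crown_shape = "cone", dead = FALSE, dead_fraction = 0,
                   predead = FALSE)
  rc <- render_chm(tr, sc)
  # per-pixel oracle: compute both cone surfaces directly at every pixel
  cen <- cell_centers(rc$chm)
  for (px in list(c(20, 20), c(21, 20), c(19, 20))) {
    x <- px[1] + 0.5; y <- px[2] + 0.5
    z <- vapply(1:2, function(i) {
      d <- sqrt((x - tr$x[i])^2 + (y - tr$y[i])^2)
      if (d > tr$crown_radius[i]) return(0)
      tr$height[i] - (tr$height[i] - tr$crown_base_height[i]) *
        d / tr$crown_radius[i]
    }, numeric(1))
    expect_equal(extract_at(rc$chm, x, y), max(z), tolerance = 0.006)
  }
  # label of an overlap pixel belongs to the taller surface
  lab_mid <- extract_at(rc$labels, 20.5, 20.5)
  expect_equal(lab_mid, 2)
})

test_that("noiseless spectral features are perfectly separable", {
  one <- single_tree_scene()
  sc <- one$config
  sc$classifier_noise <- 0
  tr <- one$trees
  tr$dead <- TRUE; tr$dead_fraction <- 0.6
  cl <- render_classes(tr, one$chm, one$labels, sc, seed = 4)
  res <- classify_cover_pixels(cl$spectral, seed = 1, ntree = 50)
  expect_equal(res$accuracy, 1)
})

test_that("scene generation is bit-identical under a fixed seed", {
  sc <- small_scene(seed = 77, extent = c(80, 80))
  s1 <- render_scene(generate_trees(sc, generate_dtm(sc)), sc)
  s2 <- render_scene(generate_trees(sc, generate_dtm(sc)), sc)
  expect_identical(s1$chm$values, s2$chm$values)
  expect_identical(s1$classes$values, s2$classes$values)
  expect_identical(s1$spectral, s2$spectral)
})

test_that("tree CSV round-trips and rejects malformed genus", {
  sc <- small_scene(seed = 8, extent = c(60, 60))
  tr <- generate_trees(sc, generate_dtm(sc))
  f <- tempfile(fileext = ".csv")
  write_trees_csv(tr, f)
  back <- read_trees_csv(f)
  expect_equal(back$x, tr$x, tolerance = 1e-6)
  expect_equal(back$height, tr$height, tolerance = 1e-6)
  bad <- tr; bad$genus[3] <- "Sequoia"
  f2 <- tempfile(fileext = ".csv")
  write_trees_csv(bad, f2)
  expect_error(read_trees_csv(f2), "row 3")
})

test_that("stand tessellation covers the scene and assigns by nearest seed", {
  sc <- small_scene(seed = 10, extent = c(200, 200))
  st <- generate_stands(sc, n_stands = 12)
  areas <- vapply(st$polygons, function(p) {
    if (nrow(p) < 3) return(0)
    abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) -
              p[, 2] * c(p[-1, 1], p[1, 1]))) / 2
  }, numeric(1))
  expect_equal(sum(areas), 200 * 200, tolerance = 1e-6)
  pts_x <- runif(50, 0, 200); pts_y <- runif(50, 0, 200)
  sid <- assign_stand(pts_x, pts_y, st)
  expect_true(all(sid %in% st$seeds$stand_id))
  f <- tempfile(fileext = ".geojson")
  write_stands_geojson(st, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 12)
})
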