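two_cone_scene <- function(sep = 20, heights = c(20, 20), extent = 50) {
  sc <- scene_config(extent_m = c(extent, extent), intensity_ha = 0,
                     dtm_relief = c(1000, 1000))
  x0 <- extent / 2 - sep / 2
  tr <- data.frame(tree_id = 1:2, x = c(x0, x0 + sep),
                   y = extent / 2 + 0.5, height = heights,
                   crown_radius = 5, crown_base_height = 0.4 * heights,
                   genus = "Pinus", crown_shape = "cone", dead = FALSE,
                   dead_fraction = 0, predead = FALSE)
  c(render_chm(tr, sc), list(trees = tr))
}

test_that("marker detection finds isolated apexes and obeys the height threshold", {
  one <- single_tree_scene(height = 20, crown_radius = 4)
  mk <- detect_markers(one$chm)
  expect_equal(nrow(mk), 1)
  expect_lt((mk$x - one$trees$x)^2 + (mk$y - one$trees$y)^2, 2^2)

  two <- two_cone_scene(sep = 20)
  mk2 <- detect_markers(two$chm, min_distance = 5)
  expect_equal(nrow(mk2), 2)
  # exhaustive maxima scan agrees: exactly two 8-neighborhood maxima > 5 m
  z <- two$chm$values
  nmax <- 0
  for (r in 2:(nrow(z) - 1)) for (c in 2:(ncol(z) - 1)) {
    if (z[r, c] > 5 && all(z[r, c] >= z[(r - 1):(r + 1), (c - 1):(c + 1)]))
      nmax <- nmax + 1
  }
  expect_equal(nmax, 2)

  short <- single_tree_scene(height = 4.5)
  expect_equal(nrow(detect_markers(short$chm, min_height = 5)), 0)
})

test_that("watershed floods one basin per marker and splits equals on the ridge", {
  one <- single_tree_scene(height = 20, crown_radius = 4)
  mk <- detect_markers(one$chm)
  seg <- watershed_segment(one$chm, mk)
  expect_equal(seg$n_segments, 1)
  # the single segment is exactly the above-threshold connected pixels
  expect_equal(sum(seg$labels$values > 0), sum(one$chm$values > 5))

  # two separated crowns: segments match connected components
  two <- two_cone_scene(sep = 24)
  mk2 <- detect_markers(two$chm, min_distance = 5)
  seg2 <- watershed_segment(two$chm, mk2)
  expect_equal(seg2$n_segments, 2)
  z <- two$chm$values > 5
  # connected-component oracle by flood fill
  comp <- matrix(0L, nrow(z), ncol(z)); nextid <- 0L
  for (start in which(z)) {
    if (comp[start] != 0L) next
    nextid <- nextid + 1L
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[i] != 0L || !z[i]) next
      comp[i] <- nextid
      r <- ((i - 1L) %% nrow(z)) + 1L; c <- ((i - 1L) %/% nrow(z)) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nrow(z) && cc >= 1 && cc <= ncol(z))
          stack <- c(stack, (cc - 1L) * nrow(z) + rr)
      }
    }
  }
  expect_equal(nextid, 2L)
  for (k in 1:2) {
    lab_of_comp <- unique(seg2$labels$values[comp == k])
    expect_length(lab_of_comp, 1)
  }

  # touching equal crowns split along the equidistant ridge, areas +- 1 px
  touch <- two_cone_scene(sep = 8, heights = c(18, 18))
  mkt <- detect_markers(touch$chm, min_distance = 4)
  segt <- watershed_segment(touch$chm, mkt)
  expect_equal(segt$n_segments, 2)
  areas <- segt$apex$n_pixels
  expect_lte(abs(areas[1] - areas[2]), 1)

  # marker on background dropped with warning
  mk_bad <- rbind(mk2[, ], data.frame(marker_id = 3, row = 2, col = 2,
                                      x = 1.5, y = 48.5, height = 0))
  expect_warning(seg_b <- watershed_segment(two$chm, mk_bad), "dropped")
  expect_equal(seg_b$n_segments, 2)
})

test_that("small-tree filter removes below 5 m strictly and relabels", {
  sc <- scene_config(extent_m = c(60, 60), intensity_ha = 0,
                     dtm_relief = c(1000, 1000))
  tr <- data.frame(tree_id = 1:3, x = c(10, 30, 50), y = 30,
                   height = c(4.9, 5.0, 12), crown_radius = 3,
                   crown_base_height = 0.4 * c(4.9, 5, 12), genus = "Pinus",
                   crown_shape = "cone", dead = FALSE, dead_fraction = 0,
                   predead = FALSE)
  rc <- render_chm(tr, sc)
  seg <- watershed_segment(rc$chm, detect_markers(rc$chm, min_height = 2),
                           min_height = 2)
  expect_equal(seg$n_segments, 3)
  filt <- filter_small_trees(seg, rc$chm, min_tree_height = 5)
  expect_equal(filt$n_segments, 2)               # 4.9 removed, 5.0 retained
  expect_equal(sort(round(filt$apex$height, 1)), c(5.0, 12.0))
  expect_equal(filt$apex$label, 1:2)             # contiguous relabeling

  empty <- filter_small_trees(seg, rc$chm, min_tree_height = 99)
  expect_equal(empty$n_segments, 0)
})

test_that("segments partition the canopy and truth matching scores detections", {
  sc <- small_scene(seed = 21, extent = c(100, 100), intensity = 80)
  tr <- generate_trees(sc, generate_dtm(sc))
  rc <- render_chm(tr, sc)
  mk <- detect_markers(rc$chm)
  seg <- watershed_segment(rc$chm, mk)
  expect_equal(seg$n_segments, nrow(mk))
  # union of segments = above-threshold mask reachable from markers;
  # segments disjoint by construction (single label raster)
  expect_true(all(seg$labels$values[rc$chm$values <= 5] == 0))
  # apex heights bound their segment pixels
  for (k in seg$apex$label) {
    expect_lte(max(rc$chm$values[seg$labels$values == k]),
               seg$apex$height[seg$apex$label == k] + 1e-9)
  }

  # scoring arithmetic on an idealized cohort
  iso <- lapply(1:10, function(i)
    data.frame(tree_id = i, x = 10 * i - 5, y = 50, height = 15))
  truth <- do.call(rbind, iso)
  sc2 <- scene_config(extent_m = c(100, 100), intensity_ha = 0,
                      dtm_relief = c(1000, 1000))
  tr2 <- data.frame(truth, crown_radius = 3, crown_base_height = 6,
                    genus = "Pinus", crown_shape = "cone", dead = FALSE,
                    dead_fraction = 0, predead = FALSE)
  rc2 <- render_chm(tr2, sc2)
  seg2 <- watershed_segment(rc2$chm, detect_markers(rc2$chm))
  perfect <- match_to_truth(seg2, truth)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f_score, 1)

  # 9 of 10 detected, no false positives: render only 9 of the 10 trees
  rc9 <- render_chm(tr2[1:9, ], sc2)
  seg9 <- watershed_segment(rc9$chm, detect_markers(rc9$chm))
  nine <- match_to_truth(seg9, truth)
  expect_equal(nine$recall, 0.9)
  expect_equal(nine$precision, 1)
  expect_equal(nine$f_score, 2 * 0.9 / 1.9)

  # no segments at all
  empty_map <- filter_small_trees(seg2, rc2$chm, min_tree_height = 99)
  none <- match_to_truth(empty_map, truth)
  expect_equal(none$recall, 0)
  expect_equal(none$f_score, 0)
})
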