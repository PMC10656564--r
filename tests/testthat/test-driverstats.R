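test_that("weighted binning computes weighted means, quartiles and bin counts", {
  # single bin: weighted mean of rates {0, 4} with weights {1, 3} is 3
  b <- bin_weighted(c(1, 1.5), c(0, 4), c(1, 3), bin_width = 2)
  expect_equal(nrow(b), 1)
  expect_equal(b$mean_rate, 3)
  expect_equal(b$weight, 4)

  # constant response: every bin mean equals it
  bc <- bin_weighted(runif(50, 0, 10), rep(2.5, 50), bin_width = 2)
  expect_true(all(bc$mean_rate == 2.5))

  # bin_width 2 on x in [0, 10) gives 5 bins
  b5 <- bin_weighted(seq(0, 9.9, 0.1), seq(0, 9.9, 0.1), bin_width = 2)
  expect_equal(nrow(b5), 5)
  expect_true(all(b5$q1 <= b5$q3))

  empty <- bin_weighted(numeric(0), numeric(0), bin_width = 1)
  expect_equal(nrow(empty), 0)
})

test_that("weighted least squares honors weight semantics and recovers slopes", {
  x <- 1:10
  y <- 2 * x + 1
  f <- suppressWarnings(wls_fit(x = x, y = y, w = runif(10, 1, 5)))
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  # duplicating a point with weight 2 = listing it twice with weight 1
  set.seed(3)
  y2 <- 2 * x + rnorm(10)
  fa <- wls_fit(x = c(x, 5), y = c(y2, 99), w = c(rep(1, 10), 2))
  fb <- wls_fit(x = c(x, 5, 5), y = c(y2, 99, 99), w = rep(1, 12))
  expect_equal(fa$slope, fb$slope, tolerance = 1e-12)
  expect_equal(fa$intercept, fb$intercept, tolerance = 1e-12)

  # slope on the CCTH scale recovered within 2 se
  set.seed(7)
  cx <- seq(0, 98, 2)
  cy <- -0.017 * cx + 2 + rnorm(length(cx), 0, 0.05)
  fr <- wls_fit(x = cx, y = cy, w = rpois(length(cx), 30) + 1)
  expect_lt(abs(fr$slope - (-0.017)), 2 * fr$slope_se)

  expect_error(wls_fit(x = 1:2, y = 1:2), "3 bins")
})

test_that("piecewise search selects parsimonious models and matches brute force", {
  # an exact line (one point per bin centre) selects zero breakpoints
  ser_line <- bin_weighted(seq(1, 39, 2), 0.5 * seq(1, 39, 2) + 3,
                           bin_width = 2)
  pf0 <- suppressWarnings(piecewise_fit(ser_line))  # perfect-fit summary note
  expect_equal(pf0$n_breaks, 0)
  expect_equal(pf0$r_squared, 1, tolerance = 1e-9)

  # max_breaks = 0 equals wls_fit exactly
  ser <- sim_piecewise_series(5)
  p0 <- piecewise_fit(ser, max_breaks = 0)
  w0 <- wls_fit(ser)
  expect_equal(p0$slopes[1], w0$slope, tolerance = 1e-12)
  expect_equal(p0$intercept, w0$intercept, tolerance = 1e-12)
  expect_equal(p0$r_squared, w0$r_squared, tolerance = 1e-12)

  # 2-break recovery with the reference negative-positive-negative shape
  pf <- piecewise_fit(ser)
  expect_equal(pf$n_breaks, 2)
  expect_equal(sign(pf$slopes), c(-1, 1, -1))
  expect_lt(abs(pf$breakpoints[1] - 14), 4)
  expect_lt(abs(pf$breakpoints[2] - 39), 4)

  # grid search equals brute-force enumeration of all pairs (<= 20 bins)
  ser20 <- sim_piecewise_series(11, x = seq(5, 43, 2))
  pf20 <- piecewise_fit(ser20)
  bf <- brute_force_two_breaks(ser20$bin_center, ser20$mean_rate,
                               ser20$weight)
  expect_equal(sort(pf20$breakpoints), sort(bf$breaks))
  sse_pf <- sum(ser20$weight *
                  (ser20$mean_rate - predict(pf20, ser20$bin_center))^2)
  expect_equal(sse_pf, bf$sse, tolerance = 1e-8)

  # continuity of the fitted function at the breakpoints
  for (bp in pf$breakpoints) {
    expect_equal(predict(pf, bp - 1e-9), predict(pf, bp + 1e-9),
                 tolerance = 1e-6)
  }

  expect_warning(piecewise_fit(sim_piecewise_series(1, x = seq(5, 11, 2))),
                 "single line")
})

test_that("beta regression recovers parameters and matches the WLS slope sign", {
  # mean-only model: intercept near logit of the constant rate
  set.seed(21)
  y <- rbeta(400, 0.2 * 60, 0.8 * 60)
  bf <- beta_fit(y, rep(0, 400) + rnorm(400, 0, 1e-8))
  expect_equal(plogis(bf$coefficients[1]), 0.2, tolerance = 0.02,
               ignore_attr = TRUE)

  # parameter recovery at n = 500 within 2 se
  set.seed(22)
  x <- runif(500, 0, 50)
  mu <- plogis(-1 + 0.04 * x)
  y2 <- rbeta(500, mu * 40, (1 - mu) * 40)
  b2 <- beta_fit(y2, x)
  expect_lt(abs(b2$coefficients[2] - 0.04), 2 * b2$se[2])
  expect_equal(unname(b2$phi), 40, tolerance = 0.2)

  # boundary rates are shrunk, not fatal
  yb <- c(0, y2[1:50], 1)
  expect_silent(beta_fit(yb, c(0, x[1:50], 50)))

  # sign agreement with the weighted linear fit on a declining series
  set.seed(23)
  cx <- seq(1, 99, 2)
  rate <- plogis(-1.2 - 0.02 * cx) + rnorm(50, 0, 0.002)
  w <- rpois(50, 40) + 1
  expect_lt(beta_fit(rate, cx, w)$coefficients[2], 0)
  expect_lt(wls_fit(x = cx, y = rate, w = w)$slope, 0)
})

test_that("mixed model flags real group structure and not its absence", {
  set.seed(31)
  n <- 90
  x <- runif(n, 0, 50)
  g <- rep(1:3, each = n / 3)

  # strong group offsets: LRT significant, fixed slope keeps its sign
  y1 <- -0.03 * x + c(0, 3, 6)[g] + rnorm(n, 0, 0.5)
  m1 <- mixed_fit(y1, x, g)
  expect_lt(m1$lrt_p, 0.05)
  expect_lt(m1$slope, 0)

  # no group structure: LRT non-significant in >= 90 % of null simulations
  hits <- 0
  for (s in 1:60) {
    set.seed(s + 500)
    y0 <- -0.03 * x + rnorm(n, 0, 0.5)
    m0 <- suppressWarnings(mixed_fit(y0, x, g))
    if (m0$lrt_p > 0.05) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)

  expect_error(mixed_fit(y1, x, rep(1, n)), "2 height groups")
})

test_that("mediation decomposes exactly and brackets known effects", {
  set.seed(41)
  n <- 300
  e <- rnorm(n)
  m <- 0.7 * e + rnorm(n)
  o <- 0.6 * m + 0 * e + rnorm(n)  # fully mediated truth
  w <- runif(n, 0.5, 2)
  md <- mediation(e, m, o, w, n_boot = 499, seed = 9)
  expect_equal(md$total, md$c_prime + md$indirect, tolerance = 1e-8)
  expect_gt(md$ci[1], 0)  # indirect clearly positive
  se_c <- sd(o) / sqrt(n)
  expect_lt(abs(md$c_prime), 4 * se_c)

  expect_error(mediation(e[1:10], m[1:10], o[1:10]), "n >= 30")
  # determinism under seed
  md2 <- mediation(e, m, o, w, n_boot = 499, seed = 9)
  expect_identical(md$ci, md2$ci)
})

test_that("random-forest drivers rank the true signal and respect nesting", {
  set.seed(51)
  n <- 220
  feats <- data.frame(height = runif(n, 5, 55), ccth = runif(n, 0, 60),
                      elevation = runif(n, 700, 2600),
                      twi = rnorm(n, 5, 1), radiation = rnorm(n, 4000, 400))
  rate <- 5 - 0.06 * feats$ccth + rnorm(n, 0, 0.3)
  rf <- rf_importance_pdp(feats, rate, ntree = 300, seed = 4)
  expect_equal(names(which.max(rf$importance)), "ccth")
  # PDP of the monotone-truth feature is monotone up to one inversion
  pd <- rf$pdp$ccth
  expect_lte(sum(diff(pd$yhat) > 0), 1)
  # structure+environment never loses to environment-only in-sample
  cmp <- rf$env_comparison
  expect_gte(cmp$r2_insample_w[2], cmp$r2_insample_w[1])
  # determinism
  rf2 <- rf_importance_pdp(feats, rate, ntree = 300, seed = 4)
  expect_identical(rf$importance, rf2$importance)
  expect_warning(rf_importance_pdp(feats, rep(1, n), ntree = 20, seed = 1),
                 "degenerate")
})
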