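#' Weighted binning of a response along a covariate
#'
#' Bins span the data range in steps of `bin_width` (edges anchored at
#' `floor(min/width) * width`); each bin carries the weighted mean response,
#' the unweighted first/third response quartiles, and the total weight (tree
#' count). Empty bins are dropped.
#'
#' @param x covariate (e.g. tree height, CCTH).
#' @param rate response (e.g. mortality rate of the unit the tree sits in).
#' @param weight non-negative weights (tree counts); default 1.
#' @param bin_width bin width in covariate units.
#' @return data.frame of class `binned_series`: `bin_center`, `bin_lo`,
#'   `bin_hi`, `mean_rate`, `q1`, `q3`, `weight`, `n`.
#' @export
bin_weighted <- function(x, rate, weight = 1, bin_width) {
  stopifnot(bin_width > 0)
  if (length(weight) == 1L) weight <- rep(weight, length(x))
  if (length(x) != length(rate) || length(x) != length(weight))
    stop("x, rate and weight must have equal length")
  if (any(weight < 0)) stop("weights must be non-negative")
  keep <- is.finite(x) & is.finite(rate)
  x <- x[keep]; rate <- rate[keep]; weight <- weight[keep]
  if (!length(x)) {
    out <- data.frame(bin_center = numeric(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), mean_rate = numeric(0),
                      q1 = numeric(0), q3 = numeric(0), weight = numeric(0),
                      n = integer(0))
    class(out) <- c("binned_series", "data.frame")
    return(out)
  }
  lo <- floor(min(x) / bin_width) * bin_width
  idx <- floor((x - lo) / bin_width)
  out <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    w <- weight[sel]; r <- rate[sel]
    if (sum(w) == 0) return(NULL)
    q <- stats::quantile(r, c(0.25, 0.75), names = FALSE)
    data.frame(bin_center = lo + (b + 0.5) * bin_width,
               bin_lo = lo + b * bin_width,
               bin_hi = lo + (b + 1) * bin_width,
               mean_rate = sum(w * r) / sum(w),
               q1 = q[1], q3 = q[2], weight = sum(w), n = sum(sel))
  }))
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Weighted linear regression of a binned series
#'
#' Weighted least squares of the bin means on the bin centres, weighted by
#' bin tree counts. Reports the slope with its two-tailed t-test p-value and
#' the weighted R^2 (`1 - SSE_w / SST_w`).
#'
#' @param series a `binned_series`, or any data.frame with columns
#'   `bin_center`, `mean_rate`, `weight` (alternatively supply `x`, `y`, `w`).
#' @param x,y,w raw vectors, used when `series` is missing.
#' @return object of class `wls_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `slope_se`, `n`, and the underlying `lm`.
#' @export
wls_fit <- function(series = NULL, x = NULL, y = NULL, w = NULL) {
  if (!is.null(series)) {
    x <- series$bin_center; y <- series$mean_rate; w <- series$weight
  }
  if (is.null(w)) w <- rep(1, length(x))
  if (length(x) < 3) stop("need at least 3 bins for a weighted fit")
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  yhat <- stats::fitted(fit)
  wmean <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - wmean)^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 p_value = sm$coefficients[2, 4],
                 r_squared = r2, n = length(x), lm = fit),
            class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted linear fit: slope %.4g (se %.3g, p %.3g), intercept %.4g, weighted R2 %.3f, n = %d\n",
    x$slope, x$slope_se, x$p_value, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.wls_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

# Continuous piecewise-linear design matrix for given breakpoints.
pw_design <- function(x, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  X
}

pw_wls <- function(x, y, w, breaks) {
  X <- pw_design(x, breaks)
  fit <- stats::lm.wfit(X, y, w)
  sse <- sum(w * fit$residuals^2)
  list(coef = fit$coefficients, sse = sse, rank = fit$rank)
}

#' Weighted piecewise-linear (segmented) regression with breakpoint search
#'
#' Fits continuous piecewise-linear models with 0, 1, ..., `max_breaks`
#' breakpoints by exhaustive grid search over the interior bin centres,
#' minimising the weighted SSE for each breakpoint count, and selects the
#' count by weighted BIC. Candidate breakpoints that would leave a segment
#' with fewer than `min_seg_bins` bins are refused. With `max_breaks = 0`
#' this reduces exactly to [wls_fit()].
#'
#' @param series a `binned_series` (columns `bin_center`, `mean_rate`,
#'   `weight`).
#' @param max_breaks maximum number of breakpoints (0-2).
#' @param min_seg_bins minimum bins per segment.
#' @return object of class `piecewise_fit`: `n_breaks`, `breakpoints`,
#'   `slopes` (per segment), `intercept`, `slope_p` (two-tailed t per
#'   segment slope), `r_squared` (weighted), `bic` (per candidate count),
#'   `coef` (basis coefficients), `series`.
#' @export
piecewise_fit <- function(series, max_breaks = 2, min_seg_bins = 3) {
  x <- series$bin_center; y <- series$mean_rate; w <- series$weight
  n <- length(x)
  if (n < 2 * min_seg_bins && max_breaks > 0) {
    warning("too few bins for breakpoints; fitting a single line")
    max_breaks <- 0
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; w <- w[ord]
  cand_breaks <- function(k) {
    if (k == 0) return(list(numeric(0)))
    # breakpoints at interior bin centres, keeping min_seg_bins per segment
    pos <- seq_len(n)
    res <- list()
    if (k == 1) {
      for (i in pos) {
        b <- x[i]
        if (sum(x < b) >= min_seg_bins && sum(x >= b) >= min_seg_bins)
          res[[length(res) + 1L]] <- b
      }
    } else if (k == 2) {
      for (i in pos) for (j in pos) {
        if (x[j] <= x[i]) next
        b <- c(x[i], x[j])
        if (sum(x < b[1]) >= min_seg_bins &&
            sum(x >= b[1] & x < b[2]) >= min_seg_bins &&
            sum(x >= b[2]) >= min_seg_bins)
          res[[length(res) + 1L]] <- b
      }
    } else stop("max_breaks > 2 not supported")
    res
  }
  best <- list(); bics <- numeric(0)
  # floor the SSE at a relative tolerance so numerically exact fits compare
  # on the parameter penalty alone
  wmean_all <- sum(w * y) / sum(w)
  sse_floor <- 1e-10 * sum(w * (y - wmean_all)^2) + 1e-300
  for (k in 0:max_breaks) {
    cands <- cand_breaks(k)
    if (!length(cands)) {
      if (k > 0) warning("no admissible breakpoints for ", k,
                         " break(s); skipping")
      next
    }
    fits <- lapply(cands, function(b) pw_wls(x, y, w, b))
    sses <- vapply(fits, `[[`, numeric(1), "sse")
    i <- which.min(sses)
    npar <- 2 + 2 * k   # intercept + base slope + (slope change, position)/bp
    bic <- n * log(max(sses[i], sse_floor) / n) + npar * log(n)
    best[[as.character(k)]] <- list(breaks = cands[[i]],
                                    fit = fits[[i]], bic = bic)
    bics[as.character(k)] <- bic
  }
  kbest <- names(bics)[which.min(bics)]
  sel <- best[[kbest]]
  breaks <- sel$breaks
  # refit with lm for slope inference
  df <- as.data.frame(pw_design(x, breaks)[, -1, drop = FALSE])
  names(df) <- paste0("b", seq_along(df))
  df$y <- y
  fit <- stats::lm(y ~ ., data = df, weights = w)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  nseg <- length(breaks) + 1
  slopes <- numeric(nseg); slope_se <- numeric(nseg)
  for (s in seq_len(nseg)) {
    contrast <- c(0, rep(1, s), rep(0, nseg - s))  # cumulative basis slopes
    slopes[s] <- sum(contrast * cf)
    slope_se[s] <- sqrt(drop(t(contrast) %*% V %*% contrast))
  }
  dfree <- fit$df.residual
  slope_p <- 2 * stats::pt(abs(slopes / slope_se), dfree, lower.tail = FALSE)
  yhat <- stats::fitted(fit)
  wmean <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - wmean)^2)
  structure(list(n_breaks = length(breaks), breakpoints = breaks,
                 slopes = slopes, slope_se = slope_se, slope_p = slope_p,
                 intercept = unname(cf[1]), r_squared = r2, bic = bics,
                 coef = cf, series = data.frame(x = x, y = y, w = w)),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Piecewise weighted fit: %d breakpoint(s)", x$n_breaks))
  if (x$n_breaks) cat(" at ", paste(signif(x$breakpoints, 4),
                                    collapse = ", "))
  cat(sprintf("\n  segment slopes: %s\n  weighted R2 %.3f\n",
              paste(signif(x$slopes, 3), collapse = ", "), x$r_squared))
  invisible(x)
}

#' @export
coef.piecewise_fit <- function(object, ...) object$coef

#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$series$x else newdata
  drop(pw_design(x, object$breakpoints) %*% object$coef)
}

#' @export
plot.piecewise_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$x, s$y, cex = 0.5 + 1.5 * s$w / max(s$w),
                 xlab = "bin centre", ylab = "rate", ...)
  xs <- seq(min(s$x), max(s$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "steelblue", lwd = 2)
  if (x$n_breaks) graphics::abline(v = x$breakpoints, lty = 3)
  invisible(x)
}

#' Beta regression of a proportion on a covariate
#'
#' Maximum-likelihood fit of `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = b0 + b1 * x` and constant precision `phi`, with optional
#' observation weights. Responses on the boundary are first shrunk by the
#' standard `(y * (n - 1) + 0.5) / n` adjustment. Standard errors come from
#' the numerical Hessian at the optimum; p-values are two-tailed Wald tests.
#'
#' @param rate responses in \[0, 1\].
#' @param covariate regressor.
#' @param weight observation weights (default 1).
#' @return object of class `beta_fit`: `coefficients` (b0, b1), `phi`,
#'   `se`, `p_values`, `log_lik`, `converged`.
#' @export
beta_fit <- function(rate, covariate, weight = 1) {
  if (length(weight) == 1L) weight <- rep(weight, length(rate))
  keep <- is.finite(rate) & is.finite(covariate) & weight > 0
  y <- rate[keep]; x <- covariate[keep]; w <- weight[keep]
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  if (any(y < 0 | y > 1)) stop("rates must lie in [0, 1]")
  if (any(y == 0 | y == 1)) y <- (y * (n - 1) + 0.5) / n
  nll <- function(par) {
    mu <- stats::plogis(par[1] + par[2] * x)
    phi <- exp(par[3])
    -sum(w * stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  # starts: logit-scale least squares + method-of-moments precision
  z <- stats::qlogis(pmin(pmax(y, 1e-6), 1 - 1e-6))
  st <- stats::lm.wfit(cbind(1, x), z, w)$coefficients
  v <- stats::var(y)
  phi0 <- max(mean(y) * (1 - mean(y)) / max(v, 1e-6) - 1, 1)
  opt <- stats::optim(c(st[1], st[2], log(phi0)), nll, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  if (opt$convergence != 0)
    stop("beta regression did not converge (optim code ", opt$convergence,
         "); value trace: ", paste(signif(opt$value, 6), collapse = " "))
  H <- opt$hessian
  se <- rep(NA_real_, 3)
  ih <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(ih)) se <- sqrt(pmax(diag(ih), 0))
  z_stat <- opt$par[1:2] / se[1:2]
  structure(list(coefficients = c(intercept = unname(opt$par[1]),
                                  slope = unname(opt$par[2])),
                 phi = exp(opt$par[3]), se = se[1:2],
                 p_values = 2 * stats::pnorm(-abs(z_stat)),
                 log_lik = -opt$value, converged = TRUE, n = n),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf(
    "Beta regression (logit link): intercept %.4g, slope %.4g (p %.3g), phi %.3g, n = %d\n",
    x$coefficients[1], x$coefficients[2], x$p_values[2], x$phi, x$n))
  invisible(x)
}

#' @export
coef.beta_fit <- function(object, ...) object$coefficients

#' Mixed model of mortality rate on CCTH with height random effects
#'
#' Random-intercept model `rate ~ ccth + (1 | height_group)` fitted by
#' maximum likelihood (lme4), compared to the weighted linear model without
#' the random effect by a likelihood-ratio test (p from the 50:50
#' chi-squared 0/1 boundary mixture). The fixed CCTH slope carries a Wald
#' normal-approximation p-value.
#'
#' @param rate response.
#' @param ccth fixed-effect covariate.
#' @param height_group grouping factor (e.g. height terciles); must have at
#'   least 2 levels.
#' @param weight optional observation weights.
#' @return list of class `mixed_fit`: `slope`, `slope_se`, `slope_p`,
#'   `ranef_var`, `lrt_stat`, `lrt_p`, `singular`, plus both fitted models.
#' @export
mixed_fit <- function(rate, ccth, height_group, weight = NULL) {
  height_group <- factor(height_group)
  if (nlevels(height_group) < 2) stop("need at least 2 height groups")
  if (is.null(weight)) weight <- rep(1, length(rate))
  dat <- data.frame(rate = rate, ccth = ccth, g = height_group, w = weight)
  mm <- lme4::lmer(rate ~ ccth + (1 | g), data = dat, weights = w,
                   REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4)))
  m0 <- stats::lm(rate ~ ccth, data = dat, weights = w)
  ll1 <- as.numeric(stats::logLik(mm)); ll0 <- as.numeric(stats::logLik(m0))
  lrt <- max(0, 2 * (ll1 - ll0))
  lrt_p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE) +
    0.5 * (lrt <= 0)
  singular <- lme4::isSingular(mm, tol = 1e-4)
  if (singular) warning("singular mixed fit: random-effect variance ~ 0")
  cf <- summary(mm)$coefficients
  vc <- as.data.frame(lme4::VarCorr(mm))
  structure(list(slope = cf["ccth", "Estimate"],
                 slope_se = cf["ccth", "Std. Error"],
                 slope_p = 2 * stats::pnorm(-abs(cf["ccth", "t value"])),
                 ranef_var = vc$vcov[vc$grp == "g"],
                 lrt_stat = lrt, lrt_p = lrt_p, singular = singular,
                 model = mm, null_model = m0),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "Mixed fit: CCTH slope %.4g (p %.3g); random-intercept var %.3g; LRT p %.3g\n",
    x$slope, x$slope_p, x$ranef_var, x$lrt_p))
  invisible(x)
}

# Weighted simple / two-covariate OLS via normal equations (fast path for
# the bootstrap).
wols <- function(X, y, w) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)[, 1]
}

#' Mediation (path) analysis with bootstrap confidence interval
#'
#' Linear path model for the exposure -> mediator -> outcome chain:
#' path `a` from the weighted regression of the mediator on the exposure,
#' path `b` and direct effect `c'` from the weighted regression of the
#' outcome on exposure and mediator. Indirect effect `a * b`; for weighted
#' OLS the total effect decomposes exactly as `c = c' + a * b`. The CI is a
#' seeded percentile bootstrap over units.
#'
#' @param exposure,mediator,outcome aligned numeric vectors.
#' @param weight observation weights (default 1).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param conf_level CI level (default 0.95).
#' @return list of class `mediation_result`: `a`, `b`, `c_prime`, `total`,
#'   `indirect`, `ci` (percentile), `n_boot`, `seed`.
#' @export
mediation <- function(exposure, mediator, outcome, weight = 1,
                      n_boot = 999, seed = 1L, conf_level = 0.95) {
  n <- length(exposure)
  if (n < 30) stop("mediation needs n >= 30 units")
  if (length(weight) == 1L) weight <- rep(weight, n)
  paths <- function(idx) {
    e <- exposure[idx]; m <- mediator[idx]; o <- outcome[idx]
    w <- weight[idx]
    ca <- wols(cbind(1, e), m, w)
    cb <- wols(cbind(1, e, m), o, w)
    c(a = unname(ca[2]), b = unname(cb[3]), c_prime = unname(cb[2]))
  }
  est <- paths(seq_len(n))
  indirect <- est["a"] * est["b"]
  total <- unname(wols(cbind(1, exposure), outcome, weight)[2])
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      p <- tryCatch(paths(idx), error = function(e) c(a = NA, b = NA,
                                                      c_prime = NA))
      p["a"] * p["b"]
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c_prime = unname(est["c_prime"]), total = total,
                 indirect = unname(indirect), ci = ci,
                 boot = boots, n_boot = n_boot, seed = seed,
                 conf_level = conf_level),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Mediation: a = %.4g, b = %.4g, indirect a*b = %.4g [%.4g, %.4g], direct c' = %.4g, total = %.4g\n",
    x$a, x$b, x$indirect, x$ci[1], x$ci[2], x$c_prime, x$total))
  invisible(x)
}

#' Random-forest driver analysis: importance and partial dependence
#'
#' Seeded random-forest regression of unit mortality rate on canopy
#' structure (height, CCTH) and environment (elevation, TWI, radiation),
#' with permutation importance (% increase in MSE), partial-dependence
#' curves on fixed per-feature grids, and a comparison against the
#' environment-only model (weighted in-sample R^2 and out-of-bag R^2 for
#' both). Bin weights enter the R^2 comparison; the forest itself is
#' unweighted.
#'
#' @param features data.frame of predictors (any subset of height, ccth,
#'   elevation, twi, radiation or other numeric columns).
#' @param rate response vector.
#' @param weight weights for the weighted R^2 report (default 1).
#' @param env_features names of the environment-only columns (default
#'   intersect with elevation/twi/radiation).
#' @param ntree,mtry forest parameters (defaults 500 and 3, the reference
#'   configuration).
#' @param n_grid partial-dependence grid size per feature.
#' @param seed RNG seed.
#' @return list of class `rf_drivers`: `importance` (%IncMSE), `pdp` (named
#'   list of data.frames x/yhat), `r2_oob`, `r2_insample_w`,
#'   `env_comparison` (both models' R^2), `model`.
#' @export
rf_importance_pdp <- function(features, rate, weight = 1,
                              env_features = intersect(
                                c("elevation", "twi", "radiation"),
                                names(features)),
                              ntree = 500, mtry = 3, n_grid = 20,
                              seed = 1L) {
  stopifnot(is.data.frame(features), nrow(features) == length(rate))
  if (length(weight) == 1L) weight <- rep(weight, length(rate))
  if (stats::var(rate) == 0) warning("constant outcome: degenerate model")
  with_seed(seed + 131L, {
    fit <- randomForest::randomForest(features, rate, ntree = ntree,
                                      mtry = min(mtry, ncol(features)),
                                      importance = TRUE)
    imp <- randomForest::importance(fit, type = 1)[, 1]
    pdp <- lapply(names(features), function(f) {
      xs <- seq(min(features[[f]]), max(features[[f]]),
                length.out = n_grid)
      yhat <- vapply(xs, function(v) {
        nd <- features
        nd[[f]] <- v
        mean(predict(fit, nd))
      }, numeric(1))
      data.frame(x = xs, yhat = yhat)
    })
    names(pdp) <- names(features)
    wr2 <- function(model, X) {
      yhat <- predict(model, X)
      wmean <- sum(weight * rate) / sum(weight)
      1 - sum(weight * (rate - yhat)^2) / sum(weight * (rate - wmean)^2)
    }
    r2_full <- wr2(fit, features)
    env_cmp <- NULL
    if (length(env_features) >= 1 &&
        length(env_features) < ncol(features)) {
      env_fit <- randomForest::randomForest(
        features[, env_features, drop = FALSE], rate, ntree = ntree,
        mtry = min(mtry, length(env_features)))
      env_cmp <- data.frame(
        model = c("environment_only", "environment_plus_structure"),
        r2_insample_w = c(wr2(env_fit, features[, env_features,
                                                drop = FALSE]), r2_full),
        r2_oob = c(utils::tail(env_fit$rsq, 1), utils::tail(fit$rsq, 1)))
    }
    structure(list(importance = imp, pdp = pdp,
                   r2_oob = utils::tail(fit$rsq, 1),
                   r2_insample_w = r2_full,
                   env_comparison = env_cmp, model = fit),
              class = "rf_drivers")
  })
}

#' @export
print.rf_drivers <- function(x, ...) {
  cat("Random-forest drivers (%IncMSE):\n")
  print(round(sort(x$importance, decreasing = TRUE), 2))
  cat(sprintf("OOB R2 %.3f, weighted in-sample R2 %.3f\n",
              x$r2_oob, x$r2_insample_w))
  if (!is.null(x$env_comparison)) print(x$env_comparison)
  invisible(x)
}
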