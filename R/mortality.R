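#' Crown dead-pixel fraction per segment
#'
#' Overlay of the land-cover classification on the crown segments: fraction
#' of each segment's pixels carrying the dead-tree class. Empty segments get
#' NA.
#'
#' @param class_raster integer `grid_raster` of land-cover codes.
#' @param segments a `segment_map` aligned with it.
#' @param dead_class code of the dead-tree class (default 1).
#' @return data.frame: `label`, `n_pixels`, `n_dead_pixels`, `dead_fraction`.
#' @export
crown_dead_fraction <- function(class_raster, segments, dead_class = 1L) {
  stopifnot(inherits(class_raster, "grid_raster"),
            inherits(segments, "segment_map"))
  lab <- segments$labels$values
  if (!all(dim(lab) == dim(class_raster$values)))
    stop("class raster and segment map are not aligned")
  ids <- segments$apex$label
  inside <- lab > 0
  lv <- factor(lab[inside], levels = ids)
  tot <- as.integer(table(lv))
  dead <- tabulate(match(lab[inside & class_raster$values == dead_class],
                         ids), nbins = length(ids))
  frac <- ifelse(tot > 0, dead / tot, NA_real_)
  data.frame(label = ids, n_pixels = tot, n_dead_pixels = dead,
             dead_fraction = frac)
}

#' Call dead trees from crown dead fractions
#'
#' A tree is dead when *over* `threshold` of its crown is classified dead
#' (strict inequality: a fraction exactly at the threshold stays alive).
#'
#' @param fractions numeric vector of crown dead fractions in [0, 1].
#' @param threshold calling threshold (default 0.35).
#' @return logical vector (NA preserved).
#' @export
flag_dead <- function(fractions, threshold = 0.35) {
  if (any(fractions < 0 | fractions > 1, na.rm = TRUE))
    stop("dead fractions must lie in [0, 1]")
  fractions > threshold
}

#' Threshold sweep of the dead-tree call
#'
#' Repeats the dead call across a grid of thresholds (default 30 % to 50 % in
#' 5 % steps) and reports the resulting counts and annual mortality rates.
#' Counts are non-increasing in the threshold by construction.
#'
#' @param fractions crown dead fractions in [0, 1].
#' @param thresholds vector of thresholds (proportions).
#' @param years drought span in years (default 4).
#' @return data.frame: `threshold`, `n_trees`, `n_dead`, `rate_pct_per_year`.
#' @export
threshold_sweep <- function(fractions, thresholds = seq(0.30, 0.50, 0.05),
                            years = 4) {
  fractions <- fractions[!is.na(fractions)]
  n <- length(fractions)
  do.call(rbind, lapply(thresholds, function(th) {
    nd <- sum(flag_dead(fractions, th))
    data.frame(threshold = th, n_trees = n, n_dead = nd,
               rate_pct_per_year = if (n > 0) 100 * nd / n / years
                                   else NA_real_)
  }))
}

#' Exclude trees that were dead before the drought
#'
#' Pre-drought dead trees are neither counted as drought mortality nor kept
#' in the denominator cohort.
#'
#' @param dead_flags logical vector from [flag_dead()].
#' @param predead_flags logical vector, dead in pre-drought imagery.
#' @return list: `drought_dead` (dead now and not pre-dead) and `keep`
#'   (cohort membership, `!predead`).
#' @export
exclude_predead <- function(dead_flags, predead_flags) {
  if (length(dead_flags) != length(predead_flags))
    stop("flag vectors must be aligned")
  list(drought_dead = dead_flags & !predead_flags,
       keep = !predead_flags)
}

#' Mortality rates per statistical unit and genus
#'
#' Annual mortality rate of a cohort: `100 * n_dead / n_trees / years`
#' (percent of trees dying per year over the drought span). Rates are
#' reported per (unit, genus), per unit pooled over genera (genus `"All"`),
#' and pooled over everything (unit `"All"`).
#'
#' @param dead_flags logical vector (drought deaths).
#' @param unit_assignment unit id per tree (stand id or grid-cell id); a
#'   single value is recycled.
#' @param genus genus per tree; a single value is recycled.
#' @param years drought span in years (default 4, the 2012-2016 window).
#' @return data.frame of class `mortality_table`: `unit_id`, `genus`,
#'   `n_trees`, `n_dead`, `years`, `rate_pct_per_year`.
#' @export
mortality_rate <- function(dead_flags, unit_assignment = "All",
                           genus = "All", years = 4) {
  n <- length(dead_flags)
  if (length(unit_assignment) == 1L) unit_assignment <- rep(unit_assignment, n)
  if (length(genus) == 1L) genus <- rep(genus, n)
  if (length(unit_assignment) != n || length(genus) != n)
    stop("every tree needs a unit and genus assignment")
  df <- data.frame(dead = dead_flags, unit = as.character(unit_assignment),
                   genus = as.character(genus))
  if (n == 0) {
    out <- data.frame(unit_id = "All", genus = "All", n_trees = 0L,
                      n_dead = 0L, years = years,
                      rate_pct_per_year = NA_real_)
    class(out) <- c("mortality_table", "data.frame")
    return(out)
  }
  one <- function(d, uid, g) {
    nt <- length(d); nd <- sum(d)
    data.frame(unit_id = uid, genus = g, n_trees = nt, n_dead = nd,
               years = years,
               rate_pct_per_year = if (nt > 0) 100 * nd / nt / years
                                   else NA_real_)
  }
  rows <- list()
  for (u in unique(df$unit)) {
    du <- df[df$unit == u, ]
    for (g in unique(du$genus))
      rows[[length(rows) + 1L]] <- one(du$dead[du$genus == g], u, g)
    if (length(unique(du$genus)) > 1L)
      rows[[length(rows) + 1L]] <- one(du$dead, u, "All")
  }
  if (length(unique(df$unit)) > 1L) {
    rows[[length(rows) + 1L]] <- one(df$dead, "All", "All")
    for (g in unique(df$genus))
      rows[[length(rows) + 1L]] <- one(df$dead[df$genus == g], "All", g)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mortality_table", "data.frame")
  out
}

#' Assign trees to regular grid cells
#'
#' Axis-aligned square cells anchored at the scene origin (0, 0); trees are
#' assigned by stem coordinate.
#'
#' @param x,y stem coordinates (m).
#' @param grid_size cell edge (m), default 500.
#' @return character vector of cell ids `"gx_gy"`.
#' @export
assign_grid_cell <- function(x, y, grid_size = 500) {
  gx <- floor(x / grid_size); gy <- floor(y / grid_size)
  paste0("g", gx, "_", gy)
}

#' Land-cover classification of spectral pixels
#'
#' Random-forest classifier over the per-pixel spectral features: a seeded
#' stratified 50/50 split of the labeled pixels trains the forest, the
#' held-out half scores it, and the model is applied to all pixels. Errors if
#' any class is absent from the training half.
#'
#' @param spectral data.frame with a `class` column and feature columns
#'   `f1..fk` (plus optional `row`/`col` pixel indices).
#' @param seed RNG seed for the split and the forest.
#' @param ntree forest size.
#' @return list: `predicted` (factor per pixel), `accuracy` (held-out),
#'   `confusion` (held-out table), `per_class` (precision/recall/F per
#'   class), `model`.
#' @export
classify_cover_pixels <- function(spectral, seed = 1L, ntree = 100) {
  feat_cols <- grep("^f[0-9]+$", names(spectral), value = TRUE)
  if (length(feat_cols) < 1) stop("no feature columns f1..fk found")
  cls <- factor(spectral$class)
  if (nlevels(cls) < 2) stop("need at least two classes")
  with_seed(seed + 97L, {
    train <- logical(nrow(spectral))
    for (lev in levels(cls)) {
      idx <- which(cls == lev)
      train[sample(idx, ceiling(length(idx) / 2))] <- TRUE
    }
    miss <- setdiff(levels(cls), unique(as.character(cls[train])))
    if (length(miss))
      stop("class(es) absent from training split: ",
           paste(miss, collapse = ", "))
    x <- spectral[, feat_cols, drop = FALSE]
    fit <- randomForest::randomForest(x[train, , drop = FALSE],
                                      droplevels(cls[train]),
                                      ntree = ntree)
    pred_all <- predict(fit, x)
    held <- !train
    conf <- table(truth = cls[held], predicted = pred_all[held])
    acc <- sum(diag(conf)) / sum(conf)
    per_class <- do.call(rbind, lapply(levels(cls), function(lev) {
      tp <- sum(cls[held] == lev & pred_all[held] == lev)
      fp <- sum(cls[held] != lev & pred_all[held] == lev)
      fn <- sum(cls[held] == lev & pred_all[held] != lev)
      p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else 0
      data.frame(class = lev, precision = p, recall = r, f_score = f)
    }))
    list(predicted = pred_all, accuracy = acc, confusion = conf,
         per_class = per_class, model = fit)
  })
}

#' Detection recall, precision and F-score
#'
#' @param predicted_dead,true_dead aligned logical vectors.
#' @return list with `recall`, `precision`, `f_score`, `tp`, `fp`, `fn`.
#' @export
detection_scores <- function(predicted_dead, true_dead) {
  if (length(predicted_dead) != length(true_dead))
    stop("cohorts must be aligned")
  tp <- sum(predicted_dead & true_dead)
  fp <- sum(predicted_dead & !true_dead)
  fn <- sum(!predicted_dead & true_dead)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(recall = r, precision = p, f_score = f, tp = tp, fp = fp, fn = fn)
}
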