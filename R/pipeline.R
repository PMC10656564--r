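#' Pipeline run configuration
#'
#' Bundles the scene (or real input paths), dead-call thresholds,
#' neighborhood radii, shadow settings, statistical settings, output
#' directory and the single global seed from which all stage seeds are
#' derived.
#'
#' @param scene a [scene_config()] for synthetic runs.
#' @param real_inputs optional named list of file paths (`dtm`, `chm`,
#'   `trees`) for a real-data run; every named path must exist.
#' @param thresholds dead-call threshold sweep (proportions).
#' @param call_threshold the headline dead-call threshold (default 0.35).
#' @param radii neighborhood radii for the competition indices; the first is
#'   used by the mortality model and the statistics.
#' @param shadow a [shadow_config()].
#' @param stats list of statistical settings: `height_bin` (m), `ccth_bin`
#'   (%), `shadow_bin` (%), `n_boot`, `years`.
#' @param out_dir output directory (created on run); `NULL` disables writing.
#' @param seed global integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(scene = scene_config(),
                       real_inputs = NULL,
                       thresholds = seq(0.30, 0.50, 0.05),
                       call_threshold = 0.35,
                       radii = 15,
                       shadow = shadow_config(),
                       stats = list(height_bin = 2, ccth_bin = 2,
                                    shadow_bin = 2, n_boot = 499,
                                    years = 4),
                       out_dir = NULL,
                       seed = 1L) {
  if (!is.null(real_inputs)) {
    if (is.null(real_inputs$dtm))
      stop("real-data mode requires a `dtm` path")
    for (nm in names(real_inputs)) {
      if (!file.exists(real_inputs[[nm]]))
        stop("real input `", nm, "` not found: ", real_inputs[[nm]])
    }
  } else {
    stopifnot(inherits(scene, "scene_config"))
  }
  stopifnot(inherits(shadow, "shadow_config"),
            all(thresholds > 0 & thresholds < 1),
            all(radii > 0))
  structure(list(scene = scene, real_inputs = real_inputs,
                 thresholds = thresholds, call_threshold = call_threshold,
                 radii = radii, shadow = shadow, stats = stats,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# Documented seed-splitting scheme: stage k of a run with global seed s uses
# (s + 7919 * k) mod 2^31-1. 7919 is just a fixed odd prime spacing the
# streams; every source of randomness in run_all draws from one of these.
stage_seed <- function(seed, k) as.integer((as.numeric(seed) + 7919 * k) %%
                                             2147483647)

#' Run the full synthetic analysis pipeline
#'
#' Executes scene generation, canopy rendering, competition indices, crown
#' shadow ray tracing, ground-truth mortality, land-cover rendering,
#' watershed segmentation, dead-tree calling with threshold sweep, stand
#' tessellation, per-stand mortality rates, and the statistical layer
#' (piecewise height fit, CCTH fits, shadow fits, mediation, random-forest
#' drivers). With `out_dir` set, every artifact is written (CSV / ASCII grid
#' / GeoJSON / JSON) along with a provenance manifest; reruns under the same
#' config are byte-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return list of class `run_report` with all stage outputs.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$real_inputs))
    stop("real-data mode supports input validation only in this release; ",
         "supply a scene_config for a full run")
  say <- function(...) if (!quiet) message(sprintf(...))
  sc <- config$scene
  seed <- config$seed
  t0 <- proc.time()[3]

  say("[1/9] terrain")
  dtm <- generate_dtm(sc)
  terr <- slope_aspect(dtm)
  twi_r <- twi(dtm)
  rad_r <- clear_sky_radiation(dtm, terr$slope, terr$aspect,
                               date = config$shadow$date,
                               latitude_deg = config$shadow$latitude_deg)

  say("[2/9] trees")
  trees <- generate_trees(sc, dtm)
  if (nrow(trees) == 0) stop("scene generated no trees")

  say("[3/9] canopy rendering")
  rc <- render_chm(trees, sc)
  truth_segments <- make_segment_map(rc$labels$values, rc$chm)

  say("[4/9] competition indices (%d trees x %d radii)", nrow(trees),
      length(config$radii))
  comp <- compute_all_indices(rc$chm, truth_segments, trees,
                              radii = config$radii,
                              own_labels = trees$tree_id)
  comp0 <- comp[comp$radius == config$radii[1], ]

  say("[5/9] crown shadow ray tracing")
  shadow_cfg <- config$shadow
  shadow_cfg$seed <- stage_seed(seed, 5L)
  shadow <- compute_shadow_ratios(trees, shadow_cfg)

  say("[6/9] ground-truth mortality + land cover")
  trees <- assign_mortality(trees, comp0, dtm, sc$mortality,
                            seed = stage_seed(seed, 6L), shadow = shadow,
                            predead_prob = sc$predead_prob)
  cls <- render_classes(trees, rc$chm, rc$labels, sc,
                        seed = stage_seed(seed, 6L))

  say("[7/9] watershed segmentation + dead-tree calling")
  markers <- detect_markers(rc$chm)
  segments <- filter_small_trees(watershed_segment(rc$chm, markers), rc$chm)
  seg_match <- match_to_truth(segments,
                              trees[trees$height >= 5, , drop = FALSE])
  cdf_truth <- crown_dead_fraction(cls$classes, truth_segments)
  mcd <- match(trees$tree_id, cdf_truth$label)
  called_frac <- cdf_truth$dead_fraction[mcd]
  called_dead <- flag_dead(called_frac, config$call_threshold)
  called_dead[is.na(called_dead)] <- FALSE
  sweep <- threshold_sweep(called_frac, config$thresholds,
                           years = config$stats$years)
  det <- detection_scores(called_dead[!trees$predead],
                          trees$dead[!trees$predead])

  say("[8/9] stands + mortality rates")
  stands <- generate_stands(sc)
  unit <- assign_stand(trees$x, trees$y, stands)
  ex <- exclude_predead(called_dead, trees$predead)
  cohort <- ex$keep & trees$height >= 5
  rates <- mortality_rate(ex$drought_dead[cohort], unit[cohort],
                          trees$genus[cohort], years = config$stats$years)

  say("[9/9] statistical layer")
  srate <- rates[rates$genus == "All" & rates$unit_id != "All", ]
  rate_of_unit <- srate$rate_pct_per_year[match(unit, srate$unit_id)]
  co <- comp0[match(trees$tree_id, comp0$tree_id), ]
  sh <- shadow$crown_shadow_ratio[match(trees$tree_id, shadow$tree_id)]
  ok <- cohort & !is.na(rate_of_unit)
  hser <- bin_weighted(trees$height[ok], rate_of_unit[ok],
                       bin_width = config$stats$height_bin)
  cser <- bin_weighted(co$ccth[ok], rate_of_unit[ok],
                       bin_width = config$stats$ccth_bin)
  sser <- bin_weighted(sh[ok], rate_of_unit[ok],
                       bin_width = config$stats$shadow_bin)
  csser <- bin_weighted(co$ccth[ok], sh[ok],
                        bin_width = config$stats$ccth_bin)
  fits <- list(
    height_piecewise = piecewise_fit(hser),
    ccth_wls = wls_fit(cser),
    ccth_beta = beta_fit(cser$mean_rate / 100 * config$stats$years,
                         cser$bin_center, cser$weight),
    ccth_shadow_wls = wls_fit(csser),
    shadow_rate_wls = wls_fit(sser)
  )
  # stand-level mediation: CCTH -> shadow -> mortality rate
  ag <- stats::aggregate(cbind(ccth = co$ccth[ok], shadow = sh[ok]),
                         by = list(unit = unit[ok]), FUN = mean)
  ag$rate <- srate$rate_pct_per_year[match(ag$unit, srate$unit_id)]
  ag$w <- srate$n_trees[match(ag$unit, srate$unit_id)]
  med <- if (nrow(ag) >= 30)
    mediation(ag$ccth, ag$shadow, ag$rate, ag$w,
              n_boot = config$stats$n_boot, seed = stage_seed(seed, 9L))
  else NULL
  elev <- extract_at(dtm, trees$x, trees$y)
  twi_v <- extract_at(twi_r, trees$x, trees$y)
  rad_v <- extract_at(rad_r, trees$x, trees$y)
  fdat <- stats::aggregate(
    cbind(height = trees$height[ok], ccth = co$ccth[ok],
          elevation = elev[ok], twi = twi_v[ok], radiation = rad_v[ok]),
    by = list(unit = unit[ok]), FUN = mean)
  fdat$rate <- srate$rate_pct_per_year[match(fdat$unit, srate$unit_id)]
  fdat$w <- srate$n_trees[match(fdat$unit, srate$unit_id)]
  rf <- if (nrow(fdat) >= 15)
    rf_importance_pdp(fdat[, c("height", "ccth", "elevation", "twi",
                               "radiation")],
                      fdat$rate, fdat$w, seed = stage_seed(seed, 10L))
  else NULL

  report <- structure(list(
    config = config, dtm = dtm, twi = twi_r, radiation = rad_r,
    trees = trees, chm = rc$chm, truth_labels = rc$labels,
    classes = cls$classes, competition = comp, shadow = shadow,
    segments = segments, segmentation_score = seg_match[c(
      "recall", "precision", "f_score")],
    crown_dead = cdf_truth, called_dead = called_dead, sweep = sweep,
    detection = det, stands = stands, unit = unit, rates = rates,
    series = list(height = hser, ccth = cser, shadow = sser,
                  ccth_shadow = csser),
    fits = fits, mediation = med, rf_drivers = rf,
    elapsed_s = proc.time()[3] - t0
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_run_outputs(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  overall <- x$rates[x$rates$unit_id == "All" & x$rates$genus == "All", ]
  cat(sprintf(
    paste0("<run_report> %d trees, %d segments; overall called mortality ",
           "%.2f %%/yr; segmentation F %.3f; elapsed %.1f s\n"),
    nrow(x$trees), x$segments$n_segments,
    if (nrow(overall)) overall$rate_pct_per_year else NA,
    x$segmentation_score$f_score, x$elapsed_s))
  invisible(x)
}

# Serialize every pipeline artifact as text files plus a manifest whose hash
# covers the config and seed (no timestamps: reruns are byte-identical).
write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_ascii_grid(report$dtm, p("dtm.asc"))
  write_ascii_grid(report$chm, p("chm.asc"))
  write_ascii_grid(report$classes, p("classes.asc"), digits = 1)
  write_ascii_grid(report$segments$labels, p("segments.asc"), digits = 8)
  write_trees_csv(report$trees, p("trees.csv"))
  utils::write.csv(report$competition, p("competition.csv"),
                   row.names = FALSE)
  utils::write.csv(report$shadow, p("shadow.csv"), row.names = FALSE)
  utils::write.csv(report$rates, p("mortality_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$sweep, p("threshold_sweep.csv"),
                   row.names = FALSE)
  write_stands_geojson(report$stands, p("stands.geojson"))
  fits <- report$fits
  fit_json <- list(
    height_piecewise = list(
      n_breaks = fits$height_piecewise$n_breaks,
      breakpoints = fits$height_piecewise$breakpoints,
      slopes = fits$height_piecewise$slopes,
      r_squared = fits$height_piecewise$r_squared),
    ccth_wls = fits$ccth_wls[c("slope", "intercept", "r_squared",
                               "p_value")],
    ccth_beta = list(coefficients = fits$ccth_beta$coefficients,
                     phi = fits$ccth_beta$phi),
    ccth_shadow_wls = fits$ccth_shadow_wls[c("slope", "r_squared",
                                             "p_value")],
    shadow_rate_wls = fits$shadow_rate_wls[c("slope", "r_squared",
                                             "p_value")],
    mediation = if (!is.null(report$mediation))
      report$mediation[c("a", "b", "c_prime", "indirect", "ci")],
    detection = report$detection,
    segmentation = report$segmentation_score
  )
  jsonlite::write_json(fit_json, p("fits.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  cfg_file <- p("config.json")
  jsonlite::write_json(serialize_config(report$config), cfg_file,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  manifest <- list(
    package = "canopymort",
    version = as.character(utils::packageVersion("canopymort")),
    seed = report$config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_trees = nrow(report$trees),
    n_segments = report$segments$n_segments,
    files = sort(setdiff(list.files(out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

serialize_config <- function(config) {
  config$out_dir <- NULL  # not part of the scientific configuration
  drop_class <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_class)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  drop_class(unclass(config))
}

#' Read a run configuration from YAML
#'
#' Scalar fields of [run_config()], [scene_config()], [shadow_config()] and
#' [mortality_params()] can be overridden from a YAML file with top-level
#' keys `scene`, `mortality`, `shadow`, and the run-level scalars.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  merge_into <- function(fun, overrides) {
    args <- overrides[intersect(names(overrides), names(formals(fun)))]
    do.call(fun, args)
  }
  mort <- if (!is.null(y$mortality)) merge_into(mortality_params,
                                                y$mortality)
  else mortality_params()
  scene_over <- y$scene %||% list()
  scene_over$mortality <- mort
  scene <- merge_into(scene_config, scene_over)
  shadow <- if (!is.null(y$shadow)) merge_into(shadow_config, y$shadow)
  else shadow_config()
  top <- y[intersect(names(y), names(formals(run_config)))]
  top$scene <- scene
  top$shadow <- shadow
  do.call(run_config, top)
}
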