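#' Detect tree-top markers in a canopy height model
#'
#' Local maxima of the Gaussian-smoothed CHM above `min_height`, followed by
#' non-maximum suppression within `min_distance` (taller marker wins; ties
#' resolved toward the earlier cell in row-major order). Marker heights are
#' read from the raw (unsmoothed) CHM.
#'
#' @param chm canopy height `grid_raster`.
#' @param min_height minimum apex height (m) for a marker (default 5, the
#'   small-tree removal rule applied throughout the analysis).
#' @param smooth_sigma Gaussian sd in pixels (0 disables smoothing).
#' @param min_distance suppression radius in metres.
#' @return data.frame: `marker_id`, `row`, `col`, `x`, `y`, `height`.
#' @export
detect_markers <- function(chm, min_height = 5, smooth_sigma = 1,
                           min_distance = 2) {
  stopifnot(inherits(chm, "grid_raster"))
  z <- chm$values
  nr <- nrow(z); nc <- ncol(z)
  s <- if (smooth_sigma > 0) gaussian_blur(z, smooth_sigma) else z
  if (nr < 1 || nc < 1 || all(z <= min_height)) return(empty_marker_table())
  sp <- matrix(-Inf, nr + 2, nc + 2)
  sp[2:(nr + 1), 2:(nc + 1)] <- s
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (s >= sp[(1:nr) + 1 + dr, (1:nc) + 1 + dc])
  }
  cand <- which(is_max & z > min_height)
  if (!length(cand)) return(empty_marker_table())
  rows <- ((cand - 1L) %% nr) + 1L
  cols <- ((cand - 1L) %/% nr) + 1L
  h <- z[cand]
  ord <- order(-h, cand)
  rows <- rows[ord]; cols <- cols[ord]; h <- h[ord]
  cen <- cell_centers(chm)
  x <- cen$x[cols]; y <- cen$y[rows]
  keep <- logical(length(h))
  for (i in seq_along(h)) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- which(keep)
    d2 <- (x[kept] - x[i])^2 + (y[kept] - y[i])^2
    keep[i] <- all(d2 > min_distance^2)
  }
  out <- data.frame(marker_id = seq_len(sum(keep)),
                    row = rows[keep], col = cols[keep],
                    x = x[keep], y = y[keep], height = h[keep])
  out
}

empty_marker_table <- function() {
  data.frame(marker_id = integer(0), row = integer(0), col = integer(0),
             x = numeric(0), y = numeric(0), height = numeric(0))
}

#' Marker-controlled watershed segmentation of a CHM
#'
#' Floods downhill from the markers (watershed of the inverted CHM with
#' imposed minima); pixels below `min_height` are background. Markers falling
#' on background pixels are dropped with a warning.
#'
#' @param chm canopy height `grid_raster`.
#' @param markers data.frame from [detect_markers()] (needs `row`, `col`).
#' @param min_height canopy/background threshold (m).
#' @return object of class `segment_map`: list with `labels` (integer
#'   `grid_raster`, 0 = background), `apex` (data.frame label, row, col, x, y,
#'   height, n_pixels), and `n_segments`.
#' @export
watershed_segment <- function(chm, markers, min_height = 5) {
  stopifnot(inherits(chm, "grid_raster"))
  if (nrow(markers) < 1) stop("at least one marker required")
  z <- chm$values
  nr <- nrow(z)
  mask <- z > min_height
  idx <- (markers$col - 1L) * nr + markers$row
  on_bg <- !mask[idx]
  if (any(on_bg)) {
    warning(sum(on_bg), " marker(s) on background pixels dropped")
  }
  lab <- .watershed_flood(z, as.integer(idx), mask)
  # relabel contiguously in marker order
  used <- sort(unique(lab[lab > 0]))
  remap <- integer(max(used, 0))
  remap[used] <- seq_along(used)
  lab[lab > 0] <- remap[lab[lab > 0]]
  make_segment_map(lab, chm)
}

make_segment_map <- function(lab, chm) {
  labels <- grid_raster(lab, chm$origin, chm$cell_size, nodata = -1)
  apex <- segment_apexes(lab, chm)
  structure(list(labels = labels, apex = apex,
                 n_segments = nrow(apex)),
            class = "segment_map")
}

segment_apexes <- function(lab, chm) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) {
    return(data.frame(label = integer(0), row = integer(0), col = integer(0),
                      x = numeric(0), y = numeric(0), height = numeric(0),
                      n_pixels = integer(0)))
  }
  z <- chm$values
  nr <- nrow(z)
  cen <- cell_centers(chm)
  px <- which(lab > 0)
  lv <- lab[px]
  hv <- z[px]
  ord <- order(lv, -hv, px)
  first <- !duplicated(lv[ord])
  apex_px <- px[ord][first]
  counts <- as.integer(table(factor(lv, levels = ids)))
  rows <- ((apex_px - 1L) %% nr) + 1L
  cols <- ((apex_px - 1L) %/% nr) + 1L
  data.frame(label = ids, row = rows, col = cols,
             x = cen$x[cols], y = cen$y[rows],
             height = z[apex_px], n_pixels = counts)
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d segments, %d labeled pixels\n",
              x$n_segments, sum(x$apex$n_pixels)))
  invisible(x)
}

#' Remove segments of small trees
#'
#' Drops segments whose apex height is strictly below `min_tree_height`
#' (trees of exactly the threshold height are retained) and relabels the
#' remainder contiguously.
#'
#' @param segments a `segment_map`.
#' @param chm the CHM the map was built from.
#' @param min_tree_height removal threshold (m), default 5.
#' @return filtered `segment_map`.
#' @export
filter_small_trees <- function(segments, chm, min_tree_height = 5) {
  stopifnot(inherits(segments, "segment_map"))
  keep <- segments$apex$label[segments$apex$height >= min_tree_height]
  lab <- segments$labels$values
  lab[!(lab %in% keep)] <- 0L
  if (length(keep)) {
    remap <- integer(max(keep))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  make_segment_map(lab, chm)
}

#' Match segments to ground-truth trees
#'
#' Greedy one-to-one matching: candidate pairs are (segment apex, true tree)
#' within `max_dist` of each other whose heights agree within
#' `height_tol_frac` of the true height (plus 1 m absolute floor); pairs are
#' accepted in order of a combined distance + height-difference score.
#' Reports detection recall, precision, and F-score.
#'
#' @param segments a `segment_map`.
#' @param true_trees data.frame with `tree_id`, `x`, `y`, `height`.
#' @param max_dist maximum apex-to-stem distance (m).
#' @param height_tol_frac relative height tolerance.
#' @return list with `matches` (data.frame label, tree_id, dist, dheight),
#'   `recall`, `precision`, `f_score`.
#' @export
match_to_truth <- function(segments, true_trees, max_dist = 3,
                           height_tol_frac = 0.3) {
  stopifnot(inherits(segments, "segment_map"))
  ap <- segments$apex
  n_seg <- nrow(ap); n_true <- nrow(true_trees)
  matches <- data.frame(label = integer(0), tree_id = integer(0),
                        dist = numeric(0), dheight = numeric(0))
  if (n_seg && n_true) {
    cand <- list()
    for (i in seq_len(n_seg)) {
      d <- sqrt((true_trees$x - ap$x[i])^2 + (true_trees$y - ap$y[i])^2)
      dh <- abs(true_trees$height - ap$height[i])
      tol <- pmax(1, height_tol_frac * true_trees$height)
      ok <- which(d <= max_dist & dh <= tol)
      if (length(ok))
        cand[[length(cand) + 1L]] <- data.frame(
          seg = i, true = ok, dist = d[ok], dheight = dh[ok])
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$dist + 0.5 * cand$dheight), ]
      seg_used <- logical(n_seg); true_used <- logical(n_true)
      for (k in seq_len(nrow(cand))) {
        s <- cand$seg[k]; t <- cand$true[k]
        if (seg_used[s] || true_used[t]) next
        seg_used[s] <- TRUE; true_used[t] <- TRUE
        matches <- rbind(matches, data.frame(
          label = ap$label[s], tree_id = true_trees$tree_id[t],
          dist = cand$dist[k], dheight = cand$dheight[k]))
      }
    }
  }
  tp <- nrow(matches)
  recall <- if (n_true) tp / n_true else NA_real_
  precision <- if (n_seg) tp / n_seg else NA_real_
  f <- if (!is.na(recall) && !is.na(precision) && (recall + precision) > 0)
    2 * recall * precision / (recall + precision) else 0
  list(matches = matches, recall = recall, precision = precision,
       f_score = f)
}

#' Tree table from a segment map
#'
#' One row per segment: apex position, apex height (the tree height
#' definition used throughout: maximum CHM value within the segment), crown
#' pixel count, and an equivalent crown radius from the segment area.
#'
#' @param segments a `segment_map`.
#' @param base_fraction crown base height as a fraction of tree height, used
#'   to complete the crown geometry for downstream ray tracing.
#' @return data.frame compatible with the synthetic tree-table schema.
#' @export
segments_to_trees <- function(segments, base_fraction = 0.4) {
  ap <- segments$apex
  cell <- segments$labels$cell_size
  data.frame(
    tree_id = ap$label, x = ap$x, y = ap$y, height = ap$height,
    crown_radius = sqrt(ap$n_pixels * cell^2 / pi),
    crown_base_height = base_fraction * ap$height,
    genus = NA_character_, crown_shape = "cone",
    n_pixels = ap$n_pixels, stringsAsFactors = FALSE
  )
}
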