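#' Canopy cover taller than a fraction of the central tree's height
#'
#' Percentage of the circular neighborhood (pixel centres within `radius` of
#' the tree stem, clipped to the raster) covered by canopy strictly taller
#' than `fraction * height` of the central tree. The central tree's own
#' segment pixels are excluded from the numerator but kept in the denominator
#' (the index measures cover of *other* canopy over total neighborhood area);
#' set `exclude_own = FALSE` for the alternative reading.
#'
#' @param chm canopy height `grid_raster`.
#' @param segments a `segment_map` (or `NULL`: no own-crown exclusion).
#' @param tree one-row data.frame (or list) with `x`, `y`, `height` and
#'   optionally `tree_id`.
#' @param radius neighborhood radius (m).
#' @param fraction height fraction in (0, 1]; 1 gives CCTH, 0.66 gives CC66.
#' @param own_label segment label of the central tree; defaults to the label
#'   under the stem coordinate.
#' @param exclude_own exclude the central tree's pixels from the numerator.
#' @return cover percentage in [0, 100].
#' @export
canopy_cover_taller <- function(chm, segments, tree, radius, fraction = 1,
                                own_label = NULL, exclude_own = TRUE) {
  stopifnot(inherits(chm, "grid_raster"), fraction > 0, fraction <= 1)
  cen <- cell_centers(chm)
  ci <- which(abs(cen$x - tree$x) <= radius)
  ri <- which(abs(cen$y - tree$y) <= radius)
  if (!length(ci) || !length(ri)) stop("neighborhood entirely outside raster")
  d2 <- outer((cen$y[ri] - tree$y)^2, (cen$x[ci] - tree$x)^2, `+`)
  inb <- d2 <= radius^2
  n_buf <- sum(inb)
  if (n_buf == 0) stop("neighborhood entirely outside raster")
  zz <- chm$values[ri, ci, drop = FALSE]
  taller <- inb & zz > fraction * tree$height
  if (exclude_own && !is.null(segments)) {
    lab <- segments$labels$values[ri, ci, drop = FALSE]
    if (is.null(own_label)) {
      idx <- cell_index(chm, tree$x, tree$y)
      own_label <- if (!is.na(idx$row[1]))
        segments$labels$values[idx$row[1], idx$col[1]] else 0L
    }
    if (length(own_label) && own_label > 0)
      taller <- taller & lab != own_label
  }
  100 * sum(taller) / n_buf
}

#' Coefficient of variation of neighbor heights (CVTH)
#'
#' `100 * sd(neighbor heights) / mean(neighbor heights)` over all trees whose
#' stems lie within `radius` of the central tree, the central tree excluded.
#' Sample standard deviation. Undefined (NA) with fewer than two neighbors.
#'
#' @param trees tree table with `tree_id`, `x`, `y`, `height`.
#' @param center_tree one-row data.frame or list with `tree_id`, `x`, `y`.
#' @param radius neighborhood radius (m).
#' @return list with `cvth` (percent or NA) and `n_neighbors`.
#' @export
cvth_index <- function(trees, center_tree, radius) {
  d2 <- (trees$x - center_tree$x)^2 + (trees$y - center_tree$y)^2
  nb <- d2 <= radius^2 & trees$tree_id != center_tree$tree_id
  h <- trees$height[nb]
  if (length(h) < 2) return(list(cvth = NA_real_, n_neighbors = length(h)))
  list(cvth = 100 * stats::sd(h) / mean(h), n_neighbors = length(h))
}

#' Neighborhood competition indices for every tree
#'
#' CCTH (cover taller than the tree), CC66 (cover taller than 66 % of its
#' height) and CVTH at each requested radius. Trees whose neighborhood circle
#' is clipped by more than half (by area of pixel centres) are flagged
#' `edge`.
#'
#' @param chm canopy height `grid_raster`.
#' @param segments `segment_map` aligning crowns to trees (may be `NULL`).
#' @param trees tree table (`tree_id`, `x`, `y`, `height`).
#' @param radii neighborhood radii in metres (default the analysis set
#'   15/30/50/100).
#' @param own_labels optional integer vector mapping each tree to its segment
#'   label (defaults to lookup under the stem).
#' @return data.frame with one row per tree per radius: `tree_id`, `radius`,
#'   `ccth`, `cc66`, `cvth`, `n_neighbors`, `edge`.
#' @export
compute_all_indices <- function(chm, segments, trees,
                                radii = c(15, 30, 50, 100),
                                own_labels = NULL) {
  cen <- cell_centers(chm)
  cell <- chm$cell_size
  out <- vector("list", length(radii) * nrow(trees))
  k <- 0L
  for (radius in radii) {
    full_area <- pi * radius^2 / cell^2  # expected pixel count, uncut
    for (i in seq_len(nrow(trees))) {
      tr <- trees[i, ]
      ci <- which(abs(cen$x - tr$x) <= radius)
      ri <- which(abs(cen$y - tr$y) <= radius)
      if (!length(ci) || !length(ri)) {
        k <- k + 1L
        out[[k]] <- data.frame(tree_id = tr$tree_id, radius = radius,
                               ccth = NA_real_, cc66 = NA_real_,
                               cvth = NA_real_, n_neighbors = 0L,
                               edge = TRUE)
        next
      }
      d2 <- outer((cen$y[ri] - tr$y)^2, (cen$x[ci] - tr$x)^2, `+`)
      inb <- d2 <= radius^2
      n_buf <- sum(inb)
      zz <- chm$values[ri, ci, drop = FALSE]
      own <- if (!is.null(own_labels)) own_labels[i] else NULL
      excl <- !inb
      if (!is.null(segments)) {
        if (is.null(own)) {
          idx <- cell_index(chm, tr$x, tr$y)
          own <- if (!is.na(idx$row[1]))
            segments$labels$values[idx$row[1], idx$col[1]] else 0L
        }
        if (length(own) && !is.na(own) && own > 0)
          excl <- excl | segments$labels$values[ri, ci, drop = FALSE] == own
      }
      ccth <- 100 * sum(!excl & zz > tr$height) / n_buf
      cc66 <- 100 * sum(!excl & zz > 0.66 * tr$height) / n_buf
      cv <- cvth_index(trees, tr, radius)
      k <- k + 1L
      out[[k]] <- data.frame(tree_id = tr$tree_id, radius = radius,
                             ccth = ccth, cc66 = cc66, cvth = cv$cvth,
                             n_neighbors = cv$n_neighbors,
                             edge = n_buf < 0.5 * full_area)
    }
  }
  do.call(rbind, out)
}
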