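#' Georeferenced single-band raster
#'
#' Light container for the gridded surfaces used throughout the pipeline
#' (terrain model, canopy height model, land-cover classes, segment labels,
#' derived covariates). Values are stored north-up: row 1 is the northern edge,
#' column 1 the western edge. `origin` is the upper-left *corner* of the grid
#' in map units (metres in the local scene frame); pixel centres sit at
#' half-cell offsets from it.
#'
#' @param values numeric or integer matrix (rows = north to south).
#' @param origin length-2 numeric, x/y of the upper-left corner.
#' @param cell_size cell edge length in metres (> 0).
#' @param nodata sentinel for missing cells (default -9999).
#' @param crs free-text coordinate-system label.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin = c(0, 0), cell_size = 1,
                        nodata = -9999, crs = "local") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be length-2 numeric")
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata, crs = crs),
    class = "grid_raster"
  )
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[x$values != x$nodata]
  cat(sprintf("<grid_raster> %d x %d cells, cell %.3g m, origin (%.6g, %.6g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  if (length(v)) {
    cat(sprintf("  values: [%.6g, %.6g], nodata = %s (%d cells)\n",
                min(v), max(v), format(x$nodata),
                sum(x$values == x$nodata)))
  } else {
    cat("  all nodata\n")
  }
  invisible(x)
}

#' Pixel-centre coordinates of raster cells
#'
#' @param r a `grid_raster`.
#' @return list with `x` (length ncol) and `y` (length nrow) centre coordinates.
#' @export
cell_centers <- function(r) {
  stopifnot(inherits(r, "grid_raster"))
  list(
    x = r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * r$cell_size,
    y = r$origin[2] - (seq_len(nrow(r$values)) - 0.5) * r$cell_size
  )
}

#' Map coordinates to row/column indices
#'
#' Points on the grid boundary are assigned to the adjacent interior cell, so
#' any coordinate inside the extent maps to a valid cell.
#'
#' @param r a `grid_raster`.
#' @param x,y coordinate vectors (m).
#' @return data.frame with integer columns `row`, `col`; NA outside the raster.
#' @export
cell_index <- function(r, x, y) {
  stopifnot(inherits(r, "grid_raster"))
  col <- floor((x - r$origin[1]) / r$cell_size) + 1L
  row <- floor((r$origin[2] - y) / r$cell_size) + 1L
  nr <- nrow(r$values); nc <- ncol(r$values)
  col[x == r$origin[1] + nc * r$cell_size] <- nc
  row[y == r$origin[2] - nr * r$cell_size] <- nr
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @inheritParams cell_index
#' @return numeric vector; NA outside the raster or at nodata cells.
#' @export
extract_at <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out[!is.na(out) & out == r$nodata] <- NA_real_
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by rows north to south); readable by any GIS.
#'
#' @param r a `grid_raster`.
#' @param path output file path.
#' @param digits significant digits written per cell.
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  stopifnot(inherits(r, "grid_raster"))
  nr <- nrow(r$values); nc <- ncol(r$values)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - nr * r$cell_size),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", r$nodata)
  )
  body <- apply(r$values, 1L, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any conforming grid.
#' @return a `grid_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1]); vals <- as.numeric(kv[, 2])
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  g <- function(k) vals[match(k, keys)]
  nc <- as.integer(g("ncols")); nr <- as.integer(g("nrows"))
  cell <- g("cellsize")
  vals_txt <- paste(lines[-(1:6)], collapse = " ")
  v <- as.numeric(strsplit(trimws(vals_txt), "\\s+")[[1]])
  if (length(v) != nr * nc) stop("ASCII grid body has wrong cell count")
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  grid_raster(m, origin = c(g("xllcorner"), g("yllcorner") + nr * cell),
              cell_size = cell, nodata = g("nodata_value"))
}

# Separable Gaussian smoothing of a matrix (reflected edges). Used for the
# synthetic terrain field and watershed marker detection.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    # reflect-pad so the kernel never runs off the data
    padded <- c(v[pmin(half:1, n)], v, v[pmax(n - (1:half) + 1, 1)])
    stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
  }
  m1 <- apply(m, 2L, smooth_vec)
  t(apply(t(m1), 2L, smooth_vec))
}
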