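#' Regular-grid raster container
#'
#' Minimal in-memory raster used for digital elevation (DEM), surface (DSM)
#' and canopy height (CHM) grids. Values are stored as a matrix whose row
#' index increases with the y coordinate (south to north): `values[i, j]` is
#' the cell centred at `x0 + (j - 0.5) * cell_size`,
#' `y0 + (i - 0.5) * cell_size`. ESRI ASCII files store rows north-first;
#' the reader/writer handle the flip.
#'
#' @param values numeric matrix of cell values (may contain `NA` for nodata).
#' @param x0,y0 coordinates (m) of the lower-left corner of the grid.
#' @param cell_size cell edge length in m; must be > 0.
#' @return an object of class `ls_raster`.
#' @export
ls_raster <- function(values, x0 = 0, y0 = 0, cell_size = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (nrow(values) == 0 || ncol(values) == 0)
    stop("raster has zero area")
  structure(
    list(values = values, x0 = as.numeric(x0), y0 = as.numeric(y0),
         cell_size = as.numeric(cell_size)),
    class = "ls_raster"
  )
}

#' @export
print.ls_raster <- function(x, ...) {
  cat(sprintf("<ls_raster> %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$x0, x$y0))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: [%.3f, %.3f], %d nodata cells\n",
                min(v), max(v), sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
dim.ls_raster <- function(x) dim(x$values)

#' Read an ESRI ASCII grid
#'
#' @param path file path to a `.asc` grid.
#' @return an [ls_raster] with nodata cells as `NA`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  # file rows run north to south; flip to south-first internal convention
  m <- m[hdr$nrows:1, , drop = FALSE]
  ls_raster(m, x0 = hdr$xllcorner, y0 = hdr$yllcorner, cell_size = hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param r an [ls_raster].
#' @param path output file path.
#' @param nodata value used to encode `NA` cells.
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999, digits = 6) {
  stopifnot(inherits(r, "ls_raster"))
  m <- r$values[nrow(r$values):1, , drop = FALSE] # north-first on disk
  m[!is.finite(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", r$x0),
    sprintf("yllcorner %.10g", r$y0),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  write.table(signif(m, digits), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cell centre coordinates of a raster
#' @param r an [ls_raster].
#' @return list with numeric vectors `x` (per column) and `y` (per row).
#' @export
raster_coords <- function(r) {
  list(x = r$x0 + (seq_len(ncol(r$values)) - 0.5) * r$cell_size,
       y = r$y0 + (seq_len(nrow(r$values)) - 0.5) * r$cell_size)
}

#' Extract raster values inside a rectangular window
#'
#' Cells belong to the window when their centre lies in
#' `[xmin, xmax) x [ymin, ymax)` (half-open, matching quadrat membership).
#'
#' @param r an [ls_raster].
#' @param xmin,xmax,ymin,ymax window bounds in map units.
#' @return numeric vector of cell values (possibly with `NA`).
#' @export
raster_window_values <- function(r, xmin, xmax, ymin, ymax) {
  cc <- raster_coords(r)
  jx <- which(cc$x >= xmin & cc$x < xmax)
  iy <- which(cc$y >= ymin & cc$y < ymax)
  as.vector(r$values[iy, jx])
}
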