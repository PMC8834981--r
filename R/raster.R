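#' Elevation / value raster
#'
#' A minimal in-memory raster: a numeric matrix whose first row is the
#' northernmost (top) row, plus the grid header of the Esri ASCII (.asc)
#' convention — lower-left corner coordinates, square cell size in meters.
#' Missing cells are `NA` internally; the nodata sentinel only appears on
#' disk.
#'
#' @param values numeric matrix, row 1 = top (north) row.
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param cellsize cell edge length in meters (> 0).
#' @param nodata nodata sentinel used when writing to disk.
#' @return an object of class `elev_raster`.
#' @export
elev_raster <- function(values, xll = 0, yll = 0, cellsize = 25, nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1 || !is.finite(cellsize) || cellsize <= 0)
    stop("cellsize must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), nodata = nodata),
    class = "elev_raster"
  )
}

#' @export
print.elev_raster <- function(x, ...) {
  cat(sprintf("<elev_raster> %d x %d cells, %.6g m cells, origin (%.6g, %.6g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.6g, %.6g], %d NA\n", rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.elev_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  c(xmin = r$xll, ymin = r$yll,
    xmax = r$xll + ncol(r$values) * r$cellsize,
    ymax = r$yll + nrow(r$values) * r$cellsize)
}

#' Cell-center coordinates of a raster or analysis grid
#'
#' @param r an `elev_raster` or `analysis_grid`.
#' @return list with vectors `x` (per column, west to east) and `y` (per row,
#'   north to south, matching matrix row order).
#' @export
cell_centers <- function(r) {
  nr <- grid_nrow(r); nc <- grid_ncol(r)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

grid_nrow <- function(r) if (inherits(r, "elev_raster")) nrow(r$values) else r$nrow
grid_ncol <- function(r) if (inherits(r, "elev_raster")) ncol(r$values) else r$ncol

same_grid_header <- function(a, b, tol = 1e-9) {
  abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    grid_nrow(a) == grid_nrow(b) && grid_ncol(a) == grid_ncol(b)
}

#' Bilinear sampling from a raster
#'
#' Samples values at arbitrary planar coordinates by bilinear interpolation
#' between the four surrounding cell centers. Points inside the raster extent
#' but beyond the outermost cell centers are clamped to the edge value.
#'
#' @param r an `elev_raster`.
#' @param x,y coordinate vectors (m, same CRS as the raster).
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(r, x, y) {
  ext <- raster_extent(r)
  eps <- 1e-9 * max(1, r$cellsize)
  out <- x < ext["xmin"] - eps | x > ext["xmax"] + eps |
         y < ext["ymin"] - eps | y > ext["ymax"] + eps
  if (any(out))
    stop(sprintf("%d point(s) outside the raster extent (first at x=%.3f, y=%.3f)",
                 sum(out), x[which(out)[1]], y[which(out)[1]]), call. = FALSE)
  nr <- nrow(r$values); nc <- ncol(r$values)
  # fractional column / row-from-top indices in cell-center units
  j <- (x - r$xll) / r$cellsize + 0.5
  i <- (r$yll + nr * r$cellsize - y) / r$cellsize + 0.5
  j <- pmin(pmax(j, 1), nc)
  i <- pmin(pmax(i, 1), nr)
  j0 <- pmin(floor(j), nc - 1L); j1 <- j0 + 1
  i0 <- pmin(floor(i), nr - 1L); i1 <- i0 + 1
  if (nc == 1) { j0 <- j1 <- 1 }
  if (nr == 1) { i0 <- i1 <- 1 }
  fx <- j - j0; fy <- i - i0
  v00 <- r$values[cbind(i0, j0)]; v01 <- r$values[cbind(i0, j1)]
  v10 <- r$values[cbind(i1, j0)]; v11 <- r$values[cbind(i1, j1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Read an Esri ASCII grid
#'
#' Parses the NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_VALUE header
#' followed by whitespace-separated values, top row first. XLLCENTER /
#' YLLCENTER headers are converted to corner coordinates.
#'
#' @param path file path to a `.asc` grid.
#' @return an `elev_raster`; nodata cells become `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- toupper(parts[1])
    if (!key %in% c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "XLLCENTER",
                    "YLLCENTER", "CELLSIZE", "NODATA_VALUE")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (k in c("NCOLS", "NROWS", "CELLSIZE"))
    if (is.null(hdr[[k]])) stop("missing ", k, " in ASCII grid header", call. = FALSE)
  cs <- hdr$CELLSIZE
  xll <- if (!is.null(hdr$XLLCORNER)) hdr$XLLCORNER else hdr$XLLCENTER - cs / 2
  yll <- if (!is.null(hdr$YLLCORNER)) hdr$YLLCORNER else hdr$YLLCENTER - cs / 2
  nodata <- if (is.null(hdr$NODATA_VALUE)) -9999 else hdr$NODATA_VALUE
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  nr <- hdr$NROWS; nc <- hdr$NCOLS
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d", length(vals), nr * nc),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  elev_raster(m, xll = xll, yll = yll, cellsize = cs, nodata = nodata)
}

#' Write an Esri ASCII grid
#'
#' @param r an `elev_raster` (or any object with the same fields).
#' @param path output path.
#' @param digits significant digits used for the body values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, digits = 10) {
  m <- r$values
  m[is.na(m)] <- r$nodata
  hdr <- c(
    sprintf("NCOLS %d", ncol(m)),
    sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.10g", r$xll),
    sprintf("YLLCORNER %.10g", r$yll),
    sprintf("CELLSIZE %.10g", r$cellsize),
    sprintf("NODATA_VALUE %.10g", as.numeric(r$nodata))
  )
  body <- apply(m, 1, function(row) paste(formatC(row, digits = digits, format = "g"),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Analysis grid for the accessibility overlay
#'
#' The common grid every layer is rasterized onto before reclassification and
#' the weighted sum. Default cell size is 5 m. An optional logical mask
#' restricts the zone over which areas are summarized (`TRUE` = inside).
#'
#' @param xll,yll lower-left corner (m).
#' @param nrow,ncol grid dimensions.
#' @param cellsize cell edge length (m), default 5.
#' @param mask optional logical matrix of the same dimensions.
#' @return an object of class `analysis_grid`.
#' @export
analysis_grid <- function(xll, yll, nrow, ncol, cellsize = 5, mask = NULL) {
  if (cellsize <= 0) stop("cellsize must be > 0", call. = FALSE)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), c(as.integer(nrow), as.integer(ncol))))
      stop("mask dimensions must match the grid", call. = FALSE)
    storage.mode(mask) <- "logical"
  }
  structure(list(xll = as.numeric(xll), yll = as.numeric(yll),
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = as.numeric(cellsize), mask = mask),
            class = "analysis_grid")
}

#' Build an analysis grid covering a rectangular extent
#'
#' @param xmin,ymin,xmax,ymax extent in meters.
#' @param cellsize cell size (m), default 5.
#' @return an `analysis_grid` whose cells tile the extent (rounded up).
#' @export
grid_from_extent <- function(xmin, ymin, xmax, ymax, cellsize = 5) {
  analysis_grid(xll = xmin, yll = ymin,
                nrow = ceiling((ymax - ymin) / cellsize),
                ncol = ceiling((xmax - xmin) / cellsize),
                cellsize = cellsize)
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("<analysis_grid> %d x %d cells of %.6g m, origin (%.6g, %.6g)%s\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll,
              if (is.null(x$mask)) "" else sprintf(", %d masked cells", sum(!x$mask))))
  invisible(x)
}

grid_raster <- function(grid, values, nodata = -9999) {
  elev_raster(values, xll = grid$xll, yll = grid$yll, cellsize = grid$cellsize,
              nodata = nodata)
}

#' Resample a raster onto an analysis grid
#'
#' Samples the source raster bilinearly at every cell center of the target
#' grid. Used to carry the coarse-DTM slope raster onto the fine analysis
#' grid without re-differentiating interpolated elevations.
#'
#' @param r source `elev_raster`.
#' @param grid target `analysis_grid`.
#' @return an `elev_raster` on the target grid header.
#' @export
resample_to_grid <- function(r, grid) {
  xy <- expand_centers(grid)
  v <- bilinear_sample(r, xy$x, xy$y)
  grid_raster(grid, matrix(v, nrow = grid$nrow, ncol = grid$ncol))
}

# all cell centers in column-major matrix order
expand_centers <- function(grid) {
  cc <- cell_centers(grid)
  list(x = rep(cc$x, each = grid_nrow(grid)),
       y = rep(cc$y, times = grid_ncol(grid)))
}
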