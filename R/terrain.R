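#' Percent slope from a digital terrain model
#'
#' Computes the slope magnitude of a DTM with the Horn 3x3 finite-difference
#' operator and reports it as percent (rise over run x 100). Border cells are
#' handled by edge replication, so small rasters keep full coverage; any 3x3
#' window containing a nodata cell propagates `NA`.
#'
#' On an inclined plane the Horn kernel is exact at interior cells, so a 4%
#' ramp yields exactly 4% slope away from the border.
#'
#' @param dtm an [elev_raster()] of elevations (m); at least 3 x 3 cells.
#' @return an `elev_raster` of percent slope on the same grid header.
#' @export
slope_percent <- function(dtm) {
  stopifnot(inherits(dtm, "elev_raster"))
  m <- dtm$values
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3)
    stop("DTM must be at least 3 x 3 cells to compute slope", call. = FALSE)
  P <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]  # edge-replicated pad
  z1 <- P[1:nr, 1:nc];           z2 <- P[1:nr, 2:(nc + 1)];           z3 <- P[1:nr, 3:(nc + 2)]
  z4 <- P[2:(nr + 1), 1:nc];                                          z6 <- P[2:(nr + 1), 3:(nc + 2)]
  z7 <- P[3:(nr + 2), 1:nc];     z8 <- P[3:(nr + 2), 2:(nc + 1)];     z9 <- P[3:(nr + 2), 3:(nc + 2)]
  cs <- dtm$cellsize
  gx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * cs)
  gy <- ((z7 + 2 * z8 + z9) - (z1 + 2 * z2 + z3)) / (8 * cs)
  s <- sqrt(gx^2 + gy^2) * 100
  # the kernel never reads the window center, so propagate its nodata too
  s[is.na(m)] <- NA_real_
  elev_raster(s, xll = dtm$xll, yll = dtm$yll,
              cellsize = dtm$cellsize, nodata = dtm$nodata)
}

#' Statutory accessibility of a gradient
#'
#' French accessibility law (Law No. 2005-102) deems a path obstacle-free
#' when its gradient does not exceed 5%. This predicate applies that rule.
#'
#' @param gradient percent slope, `>= 0` (vectorized).
#' @return logical: `TRUE` where `gradient <= 5`.
#' @export
is_statutory <- function(gradient) {
  if (any(gradient < 0, na.rm = TRUE))
    stop("gradient must be >= 0 (pass percent slope magnitudes)", call. = FALSE)
  gradient <= 5.0
}
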