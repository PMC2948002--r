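# Minimal single-band geographic raster container and plain-text I/O.
#
# Rasters are stored row-major with row 1 the NORTHERNMOST row, matching the
# on-disk convention of the ESRI ASCII grid format used for import/export.
# Values are percent tree cover in [0, 100]; the nodata sentinel is -1.

#' Construct a tree-cover raster
#'
#' A lightweight georeferenced grid of percent tree cover, the substrate of
#' the gradient analysis. Coordinates are geographic degrees; `xll`/`yll`
#' give the lower-left corner of the grid and `cellsize` the (square) pixel
#' size in degrees. Row 1 of `values` is the northernmost row.
#'
#' @param values numeric matrix of percent cover; non-nodata values must lie
#'   in `[0, 100]`.
#' @param xll,yll lower-left corner, degrees.
#' @param cellsize pixel size in degrees, `> 0`.
#' @param nodata nodata sentinel (default `-1`).
#' @param region,epoch optional labels carried through the analysis.
#' @param check_range validate the `[0, 100]` bound (disabled for derived
#'   rasters such as trait projections or masks).
#' @return An object of class `eco_raster` (and `tree_cover_raster` when
#'   range-checked).
#' @export
tree_cover_raster <- function(values, xll, yll, cellsize, nodata = -1,
                              region = NA_character_, epoch = NA_character_,
                              check_range = TRUE) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a positive scalar (degrees)", call. = FALSE)
  v <- values[values != nodata & !is.na(values)]
  if (check_range && length(v) && (min(v) < 0 || max(v) > 100))
    stop("non-nodata cover values must lie in [0, 100]", call. = FALSE)
  r <- structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         nodata = nodata, region = region, epoch = epoch),
    class = c(if (check_range) "tree_cover_raster", "eco_raster"))
  r
}

#' @export
print.eco_raster <- function(x, ...) {
  v <- x$values[x$values != x$nodata & !is.na(x$values)]
  cat(sprintf("<%s> %d x %d pixels, cellsize %.6g deg\n",
              class(x)[1L], nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  extent: lon [%.4g, %.4g], lat [%.4g, %.4g]\n",
              x$xll, x$xll + ncol(x$values) * x$cellsize,
              x$yll, x$yll + nrow(x$values) * x$cellsize))
  if (!is.na(x$region)) cat("  region:", x$region, "\n")
  if (length(v)) cat(sprintf("  values: [%.4g, %.4g], %d nodata\n",
                             min(v), max(v), sum(x$values == x$nodata)))
  invisible(x)
}

#' Latitudes of raster row centers (north to south, matching row order)
#' @param raster an `eco_raster`.
#' @return numeric vector of length `nrow(raster$values)`.
#' @export
raster_lat_centers <- function(raster) {
  nr <- nrow(raster$values)
  raster$yll + raster$cellsize * (nr - seq_len(nr) + 0.5)
}

#' Longitudes of raster column centers (west to east)
#' @param raster an `eco_raster`.
#' @export
raster_lon_centers <- function(raster) {
  raster$xll + raster$cellsize * (seq_len(ncol(raster$values)) - 0.5)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange (readable by GDAL, QGIS, terra).
#' Used in place of GeoTIFF so that artifacts stay text-only.
#'
#' @param raster an `eco_raster`.
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- raster$values
  writeLines(c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    sprintf("XLLCORNER %.10g", raster$xll),
    sprintf("YLLCORNER %.10g", raster$yll),
    sprintf("CELLSIZE %.10g", raster$cellsize),
    sprintf("NODATA_VALUE %.10g", raster$nodata)), con)
  writeLines(apply(v, 1L, function(row) paste(format(row, trim = TRUE,
                                                     digits = 10),
                                              collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path file path.
#' @param region,epoch optional labels to attach.
#' @param check_range enforce the `[0, 100]` tree-cover bound.
#' @return an `eco_raster`.
#' @export
read_ascii_grid <- function(path, region = NA_character_,
                            epoch = NA_character_, check_range = TRUE) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[toupper(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  needed <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(needed %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$NROWS, ncol = hdr$NCOLS, byrow = TRUE)
  tree_cover_raster(m, hdr$XLLCORNER, hdr$YLLCORNER, hdr$CELLSIZE,
                    nodata = hdr$NODATA_VALUE %||% -1,
                    region = region, epoch = epoch,
                    check_range = check_range)
}
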