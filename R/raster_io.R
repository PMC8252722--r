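#' Read a raster from ESRI ASCII grid file(s)
#'
#' Reads one or more plain-text ESRI ASCII grids (.asc). The format's
#' NODATA_value tag is honoured (those cells become `NA`) and the
#' xllcorner/yllcorner/cellsize georeference is preserved. Multi-band
#' input is expressed as a vector of single-band files; `band` selects
#' one of them, `band = NULL` stacks them all.
#'
#' @param path character vector of .asc file path(s)
#' @param band 1-based band to select among the paths, or `NULL` to stack
#' @return a `raster_grid`
#' @export
read_raster <- function(path, band = 1L) {
  if (!is.null(band)) {
    if (band < 1L || band > length(path))
      stop(sprintf("band out of range: requested %d of %d", band, length(path)))
    path <- path[band]
  }
  grids <- lapply(path, read_asc_one)
  if (length(grids) == 1L) return(grids[[1L]])
  geo <- grids[[1L]]$geo
  nodata <- grids[[1L]]$nodata
  raster_grid(lapply(grids, function(g) g$data), nodata = nodata, geo = geo)
}

read_asc_one <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(nodata_value = NA_real_, xllcorner = 0, yllcorner = 0,
              cellsize = 1)
  i <- 0L
  repeat {
    i <- i + 1L
    if (i > length(lines)) stop("unreadable format: no data rows in ", path)
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    key <- tolower(tok[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(tok[2L])
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows))
    stop("unreadable format: missing ncols/nrows header in ", path)
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1L]])
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("unreadable format: cell count does not match header in ", path)
  data <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  raster_grid(data, nodata = hdr$nodata_value,
              geo = list(xll = hdr$xllcorner, yll = hdr$yllcorner,
                         cellsize = hdr$cellsize))
}

#' Write a raster layer to an ESRI ASCII grid file
#'
#' Writes one layer in the plain-text ESRI ASCII grid format with the
#' grid's georeference and the given nodata sentinel; `NA` cells are
#' encoded as the sentinel. Warns if the sentinel also occurs as a data
#' value (such cells would read back as nodata).
#'
#' @param map a `raster_grid` (single layer, or use `layer`)
#' @param path output file path
#' @param nodata sentinel written for invalid cells
#' @param layer layer to write when `map` is a stack
#' @return `path`, invisibly
#' @export
write_raster <- function(map, path, nodata = -9999, layer = 1L) {
  stopifnot(inherits(map, "raster_grid"))
  m <- grid_layer(map, layer)
  if (any(m == nodata, na.rm = TRUE))
    warning("nodata sentinel ", nodata, " occurs as a data value")
  geo <- map$geo
  if (is.null(geo)) geo <- list(xll = 0, yll = 0, cellsize = 1)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(geo$xll, digits = 15)),
    paste("yllcorner", format(geo$yll, digits = 15)),
    paste("cellsize", format(geo$cellsize, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))
  ), con)
  writeLines(apply(m, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - red) / (NIR + red), per cell, in [-1, 1]. Cells where
#' either band is nodata, or where NIR + red = 0 (no reflectance
#' information), are nodata in the result.
#'
#' @param red,nir aligned single-layer `raster_grid`s of reflectance
#' @return a `raster_grid` of NDVI values
#' @export
compute_ndvi <- function(red, nir) {
  stopifnot(inherits(red, "raster_grid"), inherits(nir, "raster_grid"))
  if (!identical(dim(red$data), dim(nir$data)))
    stop("misaligned bands: red and nir shapes differ")
  r <- red$data; n <- nir$data
  denom <- n + r
  ndvi <- (n - r) / denom
  ndvi[!is.na(denom) & denom == 0] <- NA_real_
  raster_grid(ndvi, nodata = NA_real_, geo = red$geo)
}

#' Rescale a raster to 8-bit radiometric resolution
#'
#' Linearly maps a value range onto the integers 0..255, the granularity
#' recommended for heterogeneity indices (256 classes avoids the spurious
#' neighbour heterogeneity of float binning). The range is either the
#' observed min/max of valid cells (`mode = "observed"`) or a fixed
#' interval (`mode = "fixed"`, e.g. `range = c(-1, 1)` for NDVI
#' comparability across scenes). Values are rounded half-away-from-zero
#' and clipped to [0, 255]; nodata is preserved; a constant input maps to
#' 0 under the observed-range rule.
#'
#' @param raster a single-layer `raster_grid` with at least one valid cell
#' @param mode `"observed"` or `"fixed"`
#' @param range length-2 numeric `c(lo, hi)`, required for `"fixed"`
#' @return a `raster_grid` of integers 0..255
#' @export
rescale_to_8bit <- function(raster, mode = c("observed", "fixed"),
                            range = NULL) {
  stopifnot(inherits(raster, "raster_grid"))
  mode <- match.arg(mode)
  x <- grid_layer(raster, 1L)
  if (all(is.na(x))) stop("all-nodata input: nothing to rescale")
  if (mode == "observed") {
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
  } else {
    if (is.null(range) || length(range) != 2L)
      stop("invalid parameter: fixed mode requires range = c(lo, hi)")
    lo <- range[1L]; hi <- range[2L]
    if (!(lo < hi)) stop("invalid parameter: lo must be < hi")
  }
  y <- if (hi > lo) (x - lo) / (hi - lo) * 255 else x * 0
  y <- trunc(y + 0.5 * sign(y))              # round half away from zero
  y <- pmin(pmax(y, 0), 255)
  out <- matrix(y, nrow(x), ncol(x))
  raster_grid(out, nodata = NA_real_, geo = raster$geo)
}
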