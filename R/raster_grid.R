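#' Raster grid container
#'
#' A minimal in-memory raster: a numeric matrix (single layer) or a
#' rows x cols x layers array (stack), with invalid cells stored as `NA`
#' and an optional georeference carried through unchanged.
#'
#' Invalid cells are normalised to `NA` at construction: any cell equal to
#' the `nodata` sentinel becomes `NA`, and `nodata` is kept only as the
#' sentinel to use when the grid is written to disk. All layers of a stack
#' share shape, nodata semantics and georeference.
#'
#' @param data numeric matrix, or 3-d array (rows x cols x layers), or a
#'   list of conforming matrices (stacked).
#' @param nodata numeric sentinel marking invalid cells in `data` and used
#'   when writing; `NA` cells in `data` are always treated as invalid.
#' @param geo optional georeference: a list with elements `xll`, `yll`
#'   (lower-left corner) and `cellsize`; passed through all operations.
#' @return an object of class `raster_grid`.
#' @examples
#' r <- raster_grid(matrix(1:12, 3, 4))
#' dim(r$data)
#' @export
raster_grid <- function(data, nodata = NA_real_, geo = NULL) {
  if (is.list(data) && !is.data.frame(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L)
      stop("shape mismatch: all layers of a stack must share rows and cols")
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dims[[1L]], length(data)))
  }
  if (!(is.matrix(data) || (is.array(data) && length(dim(data)) == 3L)))
    stop("data must be a matrix, a rows x cols x layers array, or a list of matrices")
  storage.mode(data) <- "double"
  if (!is.na(nodata)) data[data == nodata] <- NA_real_
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("raster must have at least one row and one column")
  if (!is.null(geo)) {
    need <- c("xll", "yll", "cellsize")
    if (!all(need %in% names(geo)))
      stop("geo must contain xll, yll and cellsize")
  }
  structure(list(data = data, nodata = nodata, geo = geo),
            class = "raster_grid")
}

#' Number of layers in a raster grid
#' @param r a `raster_grid`
#' @return integer layer count (1 for a plain matrix)
#' @export
n_layers <- function(r) {
  stopifnot(inherits(r, "raster_grid"))
  if (is.matrix(r$data)) 1L else dim(r$data)[3L]
}

#' Extract one layer of a raster grid as a matrix
#' @param r a `raster_grid`
#' @param layer 1-based layer index
#' @return numeric matrix
#' @export
grid_layer <- function(r, layer = 1L) {
  nl <- n_layers(r)
  if (layer < 1L || layer > nl)
    stop(sprintf("band out of range: requested %d of %d", layer, nl))
  if (is.matrix(r$data)) r$data else r$data[, , layer]
}

#' @export
dim.raster_grid <- function(x) dim(x$data)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("raster_grid: %d x %d, %d layer(s), %d NA cell(s)\n",
              d[1L], d[2L], n_layers(x), sum(is.na(x$data))))
  invisible(x)
}

# validity mask of a single layer (TRUE = observation)
valid_mask <- function(r) {
  if (is.matrix(r$data)) !is.na(r$data)
  else apply(!is.na(r$data), c(1L, 2L), all)
}
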