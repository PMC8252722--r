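#' Window specification
#'
#' A square focal window of odd side length, as used by the moving-window
#' traversal: the window's central entry sits on the focal cell and the
#' index is computed from whatever valid cells the window covers.
#'
#' @param side odd integer >= 1, the window edge length in pixels
#' @return a `window_spec` with `side` and `center_offset` = (side+1)/2
#' @export
window_spec <- function(side) {
  side <- as.integer(side)
  if (length(side) != 1L || is.na(side) || side < 1L || side %% 2L == 0L)
    stop("invalid window spec: side must be an odd integer >= 1")
  structure(list(side = side, center_offset = (side + 1L) %/% 2L),
            class = "window_spec")
}

as_window_spec <- function(spec) {
  if (inherits(spec, "window_spec")) spec else window_spec(spec)
}

#' Extract the valid values under one window placement
#'
#' Returns the multiset of in-bounds, non-nodata values in the
#' side x side neighbourhood centred at (row, col). Positions falling
#' outside the raster are simply absent (clipped window, no padding), so
#' edge and corner windows are smaller. For a stack, each pixel yields a
#' tuple (row of the returned matrix) and is kept only if valid in every
#' layer.
#'
#' @param raster a `raster_grid`
#' @param spec a `window_spec` or odd integer side
#' @param row,col 1-based focal position
#' @return numeric vector (single layer) or matrix with one row per pixel
#'   and one column per layer; may have zero observations
#' @export
extract_window <- function(raster, spec, row, col) {
  stopifnot(inherits(raster, "raster_grid"))
  spec <- as_window_spec(spec)
  d <- dim(raster$data)
  if (row < 1L || row > d[1L] || col < 1L || col > d[2L])
    stop("invalid position: focal cell outside the raster")
  h <- spec$side %/% 2L
  rows <- max(1L, row - h):min(d[1L], row + h)
  cols <- max(1L, col - h):min(d[2L], col + h)
  if (is.matrix(raster$data)) {
    v <- as.vector(raster$data[rows, cols])
    v[!is.na(v)]
  } else {
    nl <- d[3L]
    m <- matrix(raster$data[rows, cols, ], ncol = nl)
    m[stats::complete.cases(m), , drop = FALSE]
  }
}

# resolve an index name + parameters into a function(sample) -> value
index_function <- function(index, alpha = NULL, q = NULL, metric = NULL) {
  index <- match.arg(index, c("shannon", "renyi", "hill", "simpson", "rao"))
  switch(index,
    shannon = function(s) shannon(relative_abundances(s)),
    simpson = function(s) simpson_dominance(relative_abundances(s)),
    renyi = {
      if (is.null(alpha)) stop("invalid parameter: renyi requires alpha")
      a <- alpha
      function(s) renyi(relative_abundances(s), a)
    },
    hill = {
      if (is.null(q)) stop("invalid parameter: hill requires q")
      qq <- q
      function(s) hill(relative_abundances(s), qq)
    },
    rao = function(s) rao_q_multilayer(s, metric = if (is.null(metric))
      "euclidean" else metric)
  )
}

#' Apply an index over a moving window
#'
#' Slides a square window of odd side over the raster and writes, at each
#' focal position, the index evaluated on the valid values the window
#' covers. Edge windows are clipped (out-of-bounds cells do not
#' contribute); a focal cell that is itself nodata yields nodata, as does
#' a window with no valid observations. The output has exactly the input
#' shape and georeference, in double precision, and is deterministic in
#' the traversal order.
#'
#' Only `"rao"` accepts a multi-layer stack (each pixel becomes a tuple
#' across layers); the abundance-only indices are single-layer.
#'
#' @param raster a `raster_grid`
#' @param spec a `window_spec` or odd integer side
#' @param index one of `"shannon"`, `"renyi"`, `"hill"`, `"simpson"`,
#'   `"rao"`
#' @param alpha Renyi order (required for `index = "renyi"`)
#' @param q Hill order (required for `index = "hill"`)
#' @param metric distance metric for `"rao"`: `"absolute"` (single
#'   layer), `"euclidean"` or `"manhattan"` (stacks); default chosen from
#'   the layer count
#' @return a `raster_grid` heterogeneity map, same shape as the input
#' @examples
#' r <- raster_grid(matrix(rep(1:3, each = 12), 6, 6))
#' m <- apply_moving_window(r, 3, "shannon")
#' dim(m)
#' @export
apply_moving_window <- function(raster, spec, index,
                                alpha = NULL, q = NULL, metric = NULL) {
  stopifnot(inherits(raster, "raster_grid"))
  spec <- as_window_spec(spec)
  index <- match.arg(index, c("shannon", "renyi", "hill", "simpson", "rao"))
  if (n_layers(raster) > 1L && index != "rao")
    stop("invalid parameter: only rao supports multi-layer stacks")
  fn <- index_function(index, alpha = alpha, q = q, metric = metric)
  d <- dim(raster$data)
  out <- matrix(NA_real_, d[1L], d[2L])
  focal_ok <- valid_mask(raster)
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      if (!focal_ok[i, j]) next
      s <- extract_window(raster, spec, i, j)
      n <- if (is.matrix(s)) nrow(s) else length(s)
      if (n == 0L) next
      out[i, j] <- fn(s)
    }
  }
  raster_grid(out, nodata = NA_real_, geo = raster$geo)
}

#' Renyi entropy profile over a moving window
#'
#' Computes one heterogeneity map per Renyi order alpha, reusing a single
#' window-extraction and abundance pass per focal cell across all orders
#' (the maps are identical to calling [apply_moving_window()] once per
#' alpha, just cheaper). Per-cell values are non-increasing in alpha.
#'
#' @param raster a single-layer `raster_grid`
#' @param spec a `window_spec` or odd integer side
#' @param alphas non-empty vector of orders, each >= 0
#' @return named list of `raster_grid` maps, one per alpha (names
#'   `"alpha=<a>"`)
#' @export
renyi_profile <- function(raster, spec, alphas) {
  stopifnot(inherits(raster, "raster_grid"))
  if (n_layers(raster) > 1L)
    stop("invalid parameter: renyi profile is single-layer")
  spec <- as_window_spec(spec)
  if (length(alphas) == 0L) stop("invalid parameter: alphas must be non-empty")
  if (any(!is.finite(alphas)) || any(alphas < 0))
    stop("invalid parameter: every alpha must be >= 0")
  d <- dim(raster$data)
  maps <- lapply(alphas, function(a) matrix(NA_real_, d[1L], d[2L]))
  focal_ok <- valid_mask(raster)
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      if (!focal_ok[i, j]) next
      s <- extract_window(raster, spec, i, j)
      if (length(s) == 0L) next
      dist <- relative_abundances(s)
      for (k in seq_along(alphas))
        maps[[k]][i, j] <- renyi(dist, alphas[k])
    }
  }
  out <- lapply(maps, raster_grid, nodata = NA_real_, geo = raster$geo)
  names(out) <- paste0("alpha=", format(alphas, trim = TRUE))
  out
}
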