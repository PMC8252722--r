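# run expr with a locally seeded Mersenne-Twister RNG, restoring any
# pre-existing RNG state so fixture generation never perturbs user code
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a deterministic synthetic raster fixture
#'
#' Seeded generators of small rasters emulating 8-bit landscape imagery,
#' so indices and the full pipeline are testable without downloads. The
#' same arguments always yield a bit-identical grid (Mersenne-Twister,
#' locally seeded).
#'
#' Kinds:
#' \describe{
#'   \item{constant}{every cell equals `value`.}
#'   \item{checkerboard}{alternating square tiles of `values[1]` and
#'     `values[2]` with edge `tile`.}
#'   \item{gradient}{column-wise linear ramp from `from` (first column)
#'     to `to` (last column), constant within a column.}
#'   \item{categorical}{i.i.d. uniform draws from the classes
#'     `0 .. n_classes-1`.}
#'   \item{fractal}{midpoint-displacement surface with roughness `h` in
#'     (0, 1) (displacement amplitude halves as 2^-h per level), linearly
#'     rescaled to [0, 255]; a heterogeneity-rich fixture, with no claim
#'     of ecological realism.}
#' }
#'
#' @param kind one of `"constant"`, `"checkerboard"`, `"gradient"`,
#'   `"categorical"`, `"fractal"`
#' @param rows,cols grid size, each >= 1
#' @param value constant value (kind `"constant"`)
#' @param values length-2 vector of tile values (kind `"checkerboard"`)
#' @param tile tile edge length in pixels (kind `"checkerboard"`)
#' @param from,to ramp endpoints (kind `"gradient"`)
#' @param n_classes number of classes (kind `"categorical"`)
#' @param h roughness in (0, 1) (kind `"fractal"`)
#' @param seed integer seed for the random kinds and the nodata mask
#' @param nodata_fraction fraction of cells masked as nodata (seeded)
#' @return a `raster_grid`
#' @examples
#' generate_raster("checkerboard", 8, 8, values = c(0, 255), tile = 1)
#' @export
generate_raster <- function(kind = c("constant", "checkerboard", "gradient",
                                     "categorical", "fractal"),
                            rows, cols,
                            value = 0, values = c(0, 255), tile = 1L,
                            from = 0, to = cols - 1,
                            n_classes = 8L, h = 0.7,
                            seed = 1L, nodata_fraction = 0) {
  kind <- match.arg(kind)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("invalid parameter: rows and cols must be >= 1")
  if (nodata_fraction < 0 || nodata_fraction >= 1)
    stop("invalid parameter: nodata_fraction must be in [0, 1)")
  m <- switch(kind,
    constant = matrix(value, rows, cols),
    checkerboard = {
      if (length(values) != 2L) stop("invalid parameter: need two tile values")
      if (tile < 1L) stop("invalid parameter: tile must be >= 1")
      ri <- (seq_len(rows) - 1L) %/% tile
      ci <- (seq_len(cols) - 1L) %/% tile
      values[(outer(ri, ci, "+") %% 2L) + 1L]
    },
    gradient = {
      ramp <- if (cols == 1L) from else
        from + (seq_len(cols) - 1L) * (to - from) / (cols - 1L)
      matrix(ramp, rows, cols, byrow = TRUE)
    },
    categorical = {
      if (n_classes < 1L) stop("invalid parameter: n_classes must be >= 1")
      with_local_seed(seed,
        matrix(sample.int(n_classes, rows * cols, replace = TRUE) - 1L,
               rows, cols))
    },
    fractal = {
      if (h <= 0 || h >= 1) stop("invalid parameter: h must be in (0, 1)")
      with_local_seed(seed, fractal_surface(rows, cols, h))
    })
  m <- matrix(as.double(m), rows, cols)
  if (nodata_fraction > 0) {
    mask <- with_local_seed(seed + 1000003L,
      sample.int(rows * cols, round(nodata_fraction * rows * cols)))
    m[mask] <- NA_real_
  }
  raster_grid(m, nodata = NA_real_,
              geo = list(xll = 0, yll = 0, cellsize = 1))
}

# diamond-square midpoint displacement on a (2^k+1)^2 grid, cropped,
# rescaled to [0, 255]
fractal_surface <- function(rows, cols, h) {
  k <- ceiling(log2(max(rows, cols, 2L) - 1L))
  n <- 2L^k + 1L
  g <- matrix(0, n, n)
  g[c(1L, n), c(1L, n)] <- stats::rnorm(4L)
  step <- n - 1L
  amp <- 1
  while (step > 1L) {
    half <- step %/% 2L
    amp <- amp * 2^(-h)
    # diamond step
    for (i in seq(1L, n - step, by = step)) {
      for (j in seq(1L, n - step, by = step)) {
        g[i + half, j + half] <-
          mean(g[c(i, i + step), c(j, j + step)]) + amp * stats::rnorm(1L)
      }
    }
    # square step
    for (i in seq(1L, n, by = half)) {
      off <- if (((i - 1L) %/% half) %% 2L == 0L) half + 1L else 1L
      for (j in seq(off, n, by = step)) {
        nb <- c(if (i > half) g[i - half, j],
                if (i + half <= n) g[i + half, j],
                if (j > half) g[i, j - half],
                if (j + half <= n) g[i, j + half])
        g[i, j] <- mean(nb) + amp * stats::rnorm(1L)
      }
    }
    step <- half
  }
  g <- g[seq_len(rows), seq_len(cols), drop = FALSE]
  lo <- min(g); hi <- max(g)
  if (hi > lo) round((g - lo) / (hi - lo) * 255) else g * 0
}

#' Generate an aligned red/near-infrared band pair
#'
#' Builds two aligned reflectance grids emulating a landscape with a
#' vegetated region and a bare region, so the NDVI pipeline has
#' meaningful input. Vegetation pixels have NIR well above red (NDVI
#' strongly positive); bare pixels have NIR exactly equal to red (NDVI
#' exactly 0), with seeded per-pixel brightness variation in both
#' regions. The default split layout puts vegetation in the left
#' `veg_fraction` of the columns, creating a sharp vertical ecotone where
#' distance-aware heterogeneity should peak.
#'
#' @param rows,cols grid size
#' @param veg_fraction fraction of columns that are vegetation, in
#'   [0, 1]; 0 = all bare, 1 = all vegetation
#' @param seed integer seed for the reflectance noise
#' @return list with `red` and `nir` (`raster_grid`s) and `veg_mask`
#'   (logical matrix, TRUE where vegetated)
#' @export
generate_band_pair <- function(rows, cols, veg_fraction = 0.5, seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("invalid parameter: rows and cols must be >= 1")
  if (veg_fraction < 0 || veg_fraction > 1)
    stop("invalid parameter: veg_fraction must be in [0, 1]")
  n_veg <- round(veg_fraction * cols)
  veg <- matrix(FALSE, rows, cols)
  if (n_veg > 0L) veg[, seq_len(n_veg)] <- TRUE
  with_local_seed(seed, {
    # bare soil: one brightness draw per pixel, used for both bands so
    # NDVI is exactly 0 there
    bare <- matrix(0.25 + 0.03 * stats::rnorm(rows * cols), rows, cols)
    red <- matrix(0.08 + 0.01 * stats::rnorm(rows * cols), rows, cols)
    nir <- matrix(0.55 + 0.04 * stats::rnorm(rows * cols), rows, cols)
    red[!veg] <- bare[!veg]
    nir[!veg] <- bare[!veg]
    red <- pmax(red, 0.01); nir <- pmax(nir, 0.01)
  })
  geo <- list(xll = 0, yll = 0, cellsize = 1)
  list(red = raster_grid(red, geo = geo),
       nir = raster_grid(nir, geo = geo),
       veg_mask = veg)
}
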