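#' Relative abundance distribution of a window sample
#'
#' Turns the multiset of valid values under one window placement into the
#' distinct values and their relative abundances p_i (counts / n_obs).
#' Observations are scalars (numeric vector) or fixed-length tuples (a
#' matrix with one row per observation, e.g. one column per layer).
#' Distinct values are returned in ascending order (tuples:
#' lexicographic), so every downstream index is independent of pixel
#' traversal order.
#'
#' @param sample numeric vector of scalar observations, or a numeric
#'   matrix whose rows are tuple observations. `NA` entries (any `NA`
#'   within a tuple row) are dropped as nodata.
#' @return an `abundance_distribution`: list with `values` (sorted vector,
#'   or matrix of sorted distinct rows), `p` (relative abundances summing
#'   to 1) and `n_obs` (number of valid observations).
#' @examples
#' d <- relative_abundances(c(2, 2, 7))
#' d$p   # 2/3, 1/3
#' @export
relative_abundances <- function(sample) {
  if (is.matrix(sample)) {
    keep <- stats::complete.cases(sample)
    sample <- sample[keep, , drop = FALSE]
    n <- nrow(sample)
    if (n == 0L) stop("no valid observations")
    df <- as.data.frame(sample)
    ord <- do.call(order, df)
    sample <- sample[ord, , drop = FALSE]
    first <- !duplicated(sample)
    grp <- cumsum(first)
    cnt <- tabulate(grp)
    values <- sample[first, , drop = FALSE]
    dimnames(values) <- NULL
  } else {
    sample <- sample[!is.na(sample)]
    n <- length(sample)
    if (n == 0L) stop("no valid observations")
    values <- sort(unique(sample))
    cnt <- tabulate(match(sample, values))
  }
  structure(list(values = values, p = cnt / n, n_obs = n),
            class = "abundance_distribution")
}

#' Number of distinct values in an abundance distribution
#' @param dist an `abundance_distribution`
#' @return integer richness
#' @export
richness <- function(dist) {
  stopifnot(inherits(dist, "abundance_distribution"))
  length(dist$p)
}

#' @export
print.abundance_distribution <- function(x, ...) {
  cat(sprintf("abundance_distribution: richness %d, n_obs %d\n",
              richness(x), x$n_obs))
  invisible(x)
}

check_dist <- function(dist) {
  if (!inherits(dist, "abundance_distribution"))
    stop("expected an abundance_distribution")
  dist
}
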