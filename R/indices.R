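#' Shannon entropy
#'
#' H = -sum(p_i * ln p_i) over the relative abundances of distinct values,
#' in nats. Maximal (ln richness) when abundances are uniform; 0 for a
#' single class. Depends only on abundances, not on how far apart the
#' values are numerically.
#'
#' @param dist an `abundance_distribution`
#' @return entropy in nats
#' @examples
#' shannon(relative_abundances(1:9))  # ln(9) = 2.197225
#' @export
shannon <- function(dist) {
  dist <- check_dist(dist)
  -sum(dist$p * log(dist$p))
}

#' Renyi generalized entropy
#'
#' H_alpha = ln(sum(p_i^alpha)) / (1 - alpha), in nats. alpha = 0 gives
#' log-richness, alpha -> 1 the Shannon limit (routed analytically when
#' |alpha - 1| <= 1e-9 to avoid catastrophic cancellation in 1/(1-alpha)),
#' alpha = 2 equals ln(1/D) with D the Simpson dominance. Non-increasing
#' in alpha.
#'
#' @param dist an `abundance_distribution`
#' @param alpha order of the entropy, a single real >= 0
#' @return entropy in nats
#' @export
renyi <- function(dist, alpha) {
  dist <- check_dist(dist)
  stopifnot(length(alpha) == 1L, is.finite(alpha))
  if (alpha < 0) stop("invalid parameter: alpha must be >= 0")
  if (abs(alpha - 1) <= 1e-9) return(shannon(dist))
  if (alpha == 0) return(log(richness(dist)))
  log(sum(dist$p^alpha)) / (1 - alpha)
}

#' Simpson dominance
#'
#' D = sum(p_i^2): the probability that two observations drawn at random
#' with replacement belong to the same class. Related to the order-2
#' Renyi entropy by H_2 = ln(1/D).
#'
#' @param dist an `abundance_distribution`
#' @return dominance in [1/richness, 1]
#' @export
simpson_dominance <- function(dist) {
  dist <- check_dist(dist)
  sum(dist$p^2)
}

#' Hill number (effective number of classes)
#'
#' N_q = (sum(p_i^q))^(1/(1-q)), with the q -> 1 case routed to
#' exp(shannon). Equals exp(renyi(dist, q)) for every q, turning entropies
#' into intuitive "effective class counts".
#'
#' @param dist an `abundance_distribution`
#' @param q order, a single real >= 0
#' @return effective number of classes (>= 1)
#' @export
hill <- function(dist, q) {
  dist <- check_dist(dist)
  stopifnot(length(q) == 1L, is.finite(q))
  if (q < 0) stop("invalid parameter: q must be >= 0")
  if (abs(q - 1) <= 1e-9) return(exp(shannon(dist)))
  sum(dist$p^q)^(1 / (1 - q))
}

#' Pairwise distance matrix between distinct values
#'
#' Builds the symmetric matrix d_ij of pairwise distances between the
#' distinct values of an abundance distribution, indexed consistently
#' with `dist$values`. Scalar values use absolute difference; tuple
#' (multi-layer) values use Euclidean or Manhattan distance.
#'
#' @param dist an `abundance_distribution`
#' @param metric `"absolute"` (scalar values, default), `"euclidean"` or
#'   `"manhattan"` (tuple values)
#' @return a `distance_matrix`: list with `entries` (symmetric, zero
#'   diagonal) and `metric`
#' @export
build_distance_matrix <- function(dist, metric = NULL) {
  dist <- check_dist(dist)
  tuples <- is.matrix(dist$values)
  if (is.null(metric)) metric <- if (tuples) "euclidean" else "absolute"
  metric <- match.arg(metric, c("absolute", "euclidean", "manhattan"))
  if (!tuples && metric != "absolute")
    stop("metric/value mismatch: ", metric, " metric requires tuple values")
  if (tuples && metric == "absolute")
    stop("metric/value mismatch: absolute-difference metric requires scalar values")
  entries <- if (tuples) {
    as.matrix(stats::dist(dist$values,
                          method = if (metric == "euclidean") "euclidean"
                                   else "manhattan"))
  } else {
    abs(outer(dist$values, dist$values, "-"))
  }
  dimnames(entries) <- NULL
  structure(list(entries = entries, metric = metric),
            class = "distance_matrix")
}

#' Rao's quadratic entropy
#'
#' Q = sum_i sum_j d_ij p_i p_j: the expected distance between two
#' observations drawn at random with replacement. Unlike Shannon or
#' Renyi entropy it is sensitive to how far apart values are, not only to
#' how many distinct values occur. Computed over distinct values with
#' abundance weights, which is algebraically identical to averaging the
#' distance over all n_obs^2 ordered pixel pairs.
#'
#' @param dist an `abundance_distribution`
#' @param dmat a `distance_matrix` indexed consistently with `dist`
#'   (as produced by [build_distance_matrix()]); built automatically with
#'   the default metric when omitted
#' @return expected pairwise distance, in the units of the values
#' @examples
#' d <- relative_abundances(c(0, 255))
#' rao_q(d)  # 127.5
#' @export
rao_q <- function(dist, dmat = NULL) {
  dist <- check_dist(dist)
  if (is.null(dmat)) dmat <- build_distance_matrix(dist)
  if (!inherits(dmat, "distance_matrix"))
    stop("expected a distance_matrix")
  if (nrow(dmat$entries) != richness(dist))
    stop("inconsistent inputs: distance matrix dimension != richness")
  drop(crossprod(dist$p, dmat$entries %*% dist$p))
}

#' Multi-layer Rao's quadratic entropy
#'
#' Treats each pixel position as a tuple of values across aligned layers,
#' then computes Rao's Q with a tuple metric. A pixel is a valid
#' observation only if it is valid in every layer. With a single layer
#' the result reduces exactly to the single-layer [rao_q()] with the
#' absolute-difference metric.
#'
#' @param samples a list of equal-length numeric vectors (one per layer,
#'   aligned by pixel position), or a matrix with one column per layer
#' @param metric `"euclidean"` (default) or `"manhattan"`
#' @return expected pairwise tuple distance
#' @export
rao_q_multilayer <- function(samples, metric = "euclidean") {
  if (is.list(samples)) {
    lens <- lengths(samples)
    if (length(unique(lens)) != 1L)
      stop("shape mismatch: layers contribute different pixel counts")
    samples <- do.call(cbind, samples)
  }
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  if (ncol(samples) == 1L) {
    dist <- relative_abundances(drop(samples[, 1L]))
    return(rao_q(dist, build_distance_matrix(dist, "absolute")))
  }
  dist <- relative_abundances(samples)
  rao_q(dist, build_distance_matrix(dist, metric))
}
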