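# Independent reference implementations used as oracles. They work
# straight from the raw multiset of window values (table() counts,
# brute-force pixel-pair sums) and never touch the package's
# abundance/distance machinery.

oracle_shannon <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log(p))
}

oracle_renyi <- function(v, a) {
  if (abs(a - 1) < 1e-12) return(oracle_shannon(v))
  p <- as.numeric(table(v)) / length(v)
  log(sum(p^a)) / (1 - a)
}

oracle_simpson <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  sum(p^2)
}

oracle_hill <- function(v, q) {
  if (abs(q - 1) < 1e-12) return(exp(oracle_shannon(v)))
  p <- as.numeric(table(v)) / length(v)
  sum(p^q)^(1 / (1 - q))
}

# expected |difference| over all n^2 ordered pixel pairs, with replacement
oracle_rao <- function(v) {
  n <- length(v)
  sum(abs(outer(v, v, "-"))) / n^2
}

# naive moving-window reference: explicit bounds arithmetic, no reuse of
# the package's extract_window
naive_moving_window <- function(mat, side, fn) {
  h <- side %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(mat[i, j])) next
    w <- mat[max(1L, i - h):min(nr, i + h),
             max(1L, j - h):min(nc, j + h)]
    w <- w[!is.na(w)]
    if (length(w)) out[i, j] <- fn(w)
  }
  out
}

# random abundance distribution with arbitrary (irrational) weights,
# built directly so property tests cover more than count/n ratios
random_dist <- function(seed, max_k = 12L) {
  set.seed(seed)
  k <- sample(2:max_k, 1L)
  w <- stats::rexp(k)
  structure(list(values = sort(stats::runif(k)), p = w / sum(w),
                 n_obs = 10L * k),
            class = "abundance_distribution")
}
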