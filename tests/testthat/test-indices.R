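A <- relative_abundances(1:9)
B <- relative_abundances(c(1, 102:109))

test_that("relative abundances count, normalise and order correctly", {
  expect_equal(A$values, as.numeric(1:9))
  expect_equal(A$p, rep(1 / 9, 9))
  expect_equal(A$n_obs, 9L)

  d <- relative_abundances(c(5, 5, 5, 5))
  expect_equal(d$values, 5)
  expect_equal(d$p, 1)

  d <- relative_abundances(c(7, 2, 2))
  expect_equal(d$values, c(2, 7))          # ascending regardless of input order
  expect_equal(d$p, c(2 / 3, 1 / 3))

  d <- relative_abundances(c(3, NA, 3, 1))
  expect_equal(d$n_obs, 3L)

  expect_error(relative_abundances(c(NA_real_, NA_real_)),
               "no valid observations")
  expect_error(relative_abundances(numeric(0)), "no valid observations")
})

test_that("tuple observations are deduplicated in lexicographic order", {
  m <- rbind(c(1, 5), c(0, 9), c(1, 5), c(0, 2), c(NA, 1))
  d <- relative_abundances(m)
  expect_equal(d$values, rbind(c(0, 2), c(0, 9), c(1, 5)))
  expect_equal(d$p, c(1, 1, 2) / 4)
  expect_equal(d$n_obs, 4L)
})

test_that("Shannon entropy matches the distinct-array worked example", {
  expect_equal(shannon(A), log(9), tolerance = 1e-12)
  expect_equal(shannon(B), log(9), tolerance = 1e-12)
  expect_equal(shannon(relative_abundances(rep(4, 6))), 0)
})

test_that("Renyi entropy: limits, routing and parameter domain", {
  expect_equal(renyi(A, 0), log(9))
  half <- relative_abundances(c(0, 0, 1, 1))
  expect_equal(renyi(half, 2), log(2), tolerance = 1e-12)
  for (d in list(A, B, half))
    expect_identical(renyi(d, 1), shannon(d))
  expect_error(renyi(A, -0.5), "alpha")
})

test_that("Renyi is non-increasing in alpha and continuous at 1", {
  alphas <- c(0, 0.3, 0.9, 1, 1.5, 2, 5, 20)
  for (s in 1:100) {
    d <- random_dist(s)
    h <- vapply(alphas, function(a) renyi(d, a), 0)
    expect_true(all(diff(h) <= 1e-12))
    expect_lt(abs(renyi(d, 1 + 1e-6) - shannon(d)), 1e-4)
    expect_lt(abs(renyi(d, 1 - 1e-6) - shannon(d)), 1e-4)
  }
})

test_that("Simpson dominance and its Renyi-2 identity", {
  expect_equal(simpson_dominance(relative_abundances(rep(1, 3))), 1)
  expect_equal(simpson_dominance(A), 1 / 9)
  expect_equal(simpson_dominance(relative_abundances(c(0, 1))), 0.5)
  for (s in 1:50) {
    d <- random_dist(s)
    expect_equal(renyi(d, 2), log(1 / simpson_dominance(d)),
                 tolerance = 1e-12)
  }
})

test_that("Hill numbers: examples and exp(Renyi) identity", {
  expect_equal(hill(A, 0), 9)
  half <- relative_abundances(c(0, 0, 1, 1))
  expect_equal(hill(half, 2), 2)
  const <- relative_abundances(rep(3, 5))
  for (q in c(0, 0.5, 1, 2, 7)) expect_equal(hill(const, q), 1)
  for (s in 1:50) {
    d <- random_dist(s)
    for (q in c(0, 0.5, 1, 2, 5))
      expect_equal(hill(d, q), exp(renyi(d, q)), tolerance = 1e-9)
  }
  expect_error(hill(A, -1), "q")
})

test_that("distance matrices: metrics, symmetry and mismatch errors", {
  d2 <- relative_abundances(c(0, 255))
  dm <- build_distance_matrix(d2)
  expect_equal(dm$entries, rbind(c(0, 255), c(255, 0)))

  d3 <- relative_abundances(1:3)
  dm3 <- build_distance_matrix(d3, "absolute")
  expect_equal(dm3$entries, rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))

  tup <- relative_abundances(rbind(c(0, 0), c(3, 4)))
  expect_equal(build_distance_matrix(tup, "euclidean")$entries[1, 2], 5)
  expect_equal(build_distance_matrix(tup, "manhattan")$entries[1, 2], 7)

  expect_error(build_distance_matrix(d2, "euclidean"), "mismatch")
  expect_error(build_distance_matrix(tup, "absolute"), "mismatch")
})

test_that("Rao's Q: worked examples and input checks", {
  expect_equal(rao_q(relative_abundances(rep(9, 4))), 0)
  expect_equal(rao_q(relative_abundances(c(0, 255))), 127.5)
  expect_equal(rao_q(A), 240 / 81, tolerance = 1e-12)
  wrong <- build_distance_matrix(relative_abundances(c(0, 1)))
  expect_error(rao_q(A, wrong), "inconsistent")
})

test_that("Rao's Q equals brute-force enumeration over ordered pixel pairs", {
  for (s in 1:30) {
    set.seed(s)
    v <- sample(0:255, sample(2:81, 1L), replace = TRUE)
    d <- relative_abundances(v)
    expect_equal(rao_q(d), oracle_rao(v), tolerance = 1e-10)
  }
})

test_that("Rao's Q is translation-invariant and scales linearly", {
  set.seed(42)
  v <- sample(0:255, 40, replace = TRUE)
  q0 <- rao_q(relative_abundances(v))
  expect_equal(rao_q(relative_abundances(v + 17.5)), q0, tolerance = 1e-10)
  expect_equal(rao_q(relative_abundances(v * 3.25)), 3.25 * q0,
               tolerance = 1e-10)
})

test_that("spectrally distant values raise Rao's Q at equal Shannon", {
  expect_equal(shannon(A), shannon(B))
  expect_gt(rao_q(B), rao_q(A))
})

test_that("multi-layer Rao: reduction, tuples and alignment checks", {
  expect_equal(rao_q_multilayer(list(rep(2, 5), rep(2, 5))), 0)
  v <- c(0, 255, 13, 13, 200)
  expect_identical(rao_q_multilayer(list(v)),
                   rao_q(relative_abundances(v)))
  expect_equal(rao_q_multilayer(list(c(0, 3), c(0, 4))), 2.5)
  expect_equal(rao_q_multilayer(list(c(0, 3), c(0, 4)), "manhattan"), 3.5)
  expect_error(rao_q_multilayer(list(1:4, 1:5)), "mismatch")
})
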