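test_that("pooled standardization gives scale-free Euclidean distances", {
  set.seed(2)
  p0 <- matrix(rnorm(10), 5, 2)
  p1 <- matrix(rnorm(8, 1), 4, 2)
  D <- pooled_distance_matrix(p0, p1)
  # brute-force double loop on hand-standardized coordinates
  pooled <- rbind(p0, p1)
  z <- sweep(sweep(pooled, 2, colMeans(pooled)), 2,
             apply(pooled, 2, sd), "/")
  for (i in 1:9) for (j in 1:9)
    expect_equal(D[i, j], sqrt(sum((z[i, ] - z[j, ])^2)), tolerance = 1e-12)
  expect_true(all(diag(D) == 0))
  # identical points at zero distance
  expect_equal(pooled_distance_matrix(rbind(c(1, 2), c(1, 2)),
                                      rbind(c(3, 1), c(0, 0)))[1, 2], 0)
  # affine rescaling of all inputs leaves the matrix unchanged
  resc <- function(p) sweep(sweep(p, 2, c(3, -0.2), "*"), 2, c(-7, 11), "+")
  expect_equal(pooled_distance_matrix(resc(p0), resc(p1)), D,
               tolerance = 1e-9)
  expect_warning(
    pooled_distance_matrix(cbind(1, rnorm(3)), cbind(1, rnorm(3))),
    "constant")
  expect_error(pooled_distance_matrix(cbind(1, 1), cbind(1, 1)),
               class = "ceusperf_invalid")
})

test_that("matching is optimal: forced cases and brute-force enumeration", {
  D <- matrix(10, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 1
  pairs <- optimal_nonbipartite_matching(D)
  expect_identical(pairs, cbind(i = c(1L, 3L), j = c(2L, 4L)))
  # all even/odd sizes 4-8 against exhaustive enumeration, many seeds
  for (s in 1:50) {
    set.seed(s)
    n <- sample(4:8, 1)
    D <- as.matrix(dist(matrix(runif(2 * n), n, 2)))
    pairs <- optimal_nonbipartite_matching(D)
    cost <- sum(D[pairs])
    if (n %% 2 == 0) {
      expect_equal(cost, brute_force_matching(D)$cost, tolerance = 1e-12)
      expect_identical(nrow(pairs), n %/% 2L)
    } else {
      # odd: best over every choice of left-out point
      best <- min(vapply(seq_len(n), function(drop)
        brute_force_matching(D[-drop, -drop, drop = FALSE])$cost, 0))
      expect_equal(cost, best, tolerance = 1e-12)
      expect_identical(nrow(pairs), (n - 1L) %/% 2L)
    }
    expect_true(all(pairs[, 1L] < pairs[, 2L]))
    expect_false(any(duplicated(as.vector(pairs))))
  }
})

test_that("multi-start local search matches the exact optimum", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(c(12L, 16L, 20L), 1)
    D <- as.matrix(dist(matrix(rnorm(2 * n), n, 2)))
    exact <- ceusperf:::min_weight_matching_cpp(D)
    heur <- ceusperf:::min_weight_matching_cpp(D, TRUE)
    expect_equal(sum(D[cbind(seq_len(n), heur)]),
                 sum(D[cbind(seq_len(n), exact)]), tolerance = 1e-9)
  }
})

test_that("crossmatch null pmf matches enumeration, normalizes, has the known mean", {
  for (n0 in 1:6) for (n1 in 1:6) {
    pmf <- crossmatch_null_pmf(n0, n1)
    enum <- enum_crossmatch_pmf(n0, n1)
    expect_equal(pmf$a1, enum$a1)
    expect_equal(pmf$prob, enum$prob, tolerance = 1e-12)
  }
  for (n0 in 1:15) for (n1 in 1:(30 - n0)) {
    if (n1 > 15) next
    pmf <- crossmatch_null_pmf(n0, n1)
    N <- n0 + n1
    expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
    mean_a1 <- sum(pmf$a1 * pmf$prob)
    if (N %% 2 == 0) {
      expect_equal(mean_a1, n0 * n1 / (N - 1), tolerance = 1e-12)
    } else {
      expect_equal(mean_a1, n0 * n1 / N, tolerance = 1e-12)
    }
    # parity of the support when N is even
    if (N %% 2 == 0) expect_true(all((pmf$a1 - n1) %% 2 == 0))
  }
})

test_that("separated groups yield the minimal crossmatch count and p", {
  # two tight clusters far apart along both coordinates: within-group
  # pairing is forced even after pooled standardization
  r <- crossmatch_test(rbind(c(0, 0), c(0, 1)), rbind(c(10, 10), c(10, 11)))
  expect_identical(r$a1, 0L)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)  # P(A1 = 0), N = 4
  expect_equal(r$expected_a1, 4 / 3, tolerance = 1e-12)  # n0 n1 / (N - 1)
  # larger separated groups: a1 at its parity minimum, p at the pmf floor
  set.seed(9)
  p0 <- cbind(rnorm(7, 0, 0.05), rnorm(7, 0, 0.05))
  p1 <- cbind(rnorm(9, 50, 0.05), rnorm(9, 50, 0.05))
  r2 <- crossmatch_test(p0, p1)
  expect_identical(r2$a1, 1L)   # N = 16 even, n1 = 9 odd -> min feasible 1
  expect_equal(r2$p_value, min(cumsum(r2$null_pmf$prob)), tolerance = 1e-12)
})

test_that("crossmatch p is invariant to joint affine maps of the points", {
  set.seed(14)
  p0 <- matrix(rnorm(20), 10, 2)
  p1 <- matrix(rnorm(16, 0.8), 8, 2)
  base <- crossmatch_test(p0, p1)
  tf <- function(p) sweep(sweep(p, 2, c(0.01, 40), "*"), 2, c(5, -3), "+")
  mapped <- crossmatch_test(tf(p0), tf(p1))
  expect_identical(mapped$a1, base$a1)
  expect_equal(mapped$p_value, base$p_value, tolerance = 1e-12)
  expect_error(crossmatch_test(p0[1, , drop = FALSE], p1),
               class = "ceusperf_invalid")
})

test_that("parabolic regression recovers coefficients and matches normal equations", {
  V <- seq(0.2, 2, length.out = 9)
  TT <- 2 - V + 0.5 * V^2
  fit <- fit_parabola(V, TT)
  expect_equal(unname(fit$coefficients), c(2, -1, 0.5), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant response: curvature and slope vanish
  flat <- fit_parabola(V, rep(3, 9))
  expect_equal(unname(flat$coefficients), c(3, 0, 0), tolerance = 1e-10)
  # noisy data against an independent normal-equations solve
  set.seed(8)
  TTn <- TT + rnorm(9, 0, 0.1)
  fitn <- fit_parabola(V, TTn)
  X <- cbind(1, V, V^2)
  beta <- solve(t(X) %*% X, t(X) %*% TTn)
  expect_equal(unname(fitn$coefficients), as.numeric(beta),
               tolerance = 1e-8)
  expect_error(fit_parabola(c(1, 1, 2, 2), 1:4), class = "ceusperf_invalid")
  expect_error(fit_parabola(1:3, 1:3), class = "ceusperf_invalid")
})
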