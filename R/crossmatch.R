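#' Pooled standardized distance matrix
#'
#' Standardizes each coordinate of the pooled two-group point cloud to zero
#' mean and unit variance, then returns the Euclidean distance matrix. A
#' coordinate with zero pooled variance carries no information and is
#' dropped with a warning; if every coordinate is degenerate an error is
#' raised.
#'
#' @param points0,points1 numeric matrices (or data.frames) with one row per
#'   observation and matching columns, e.g. `(MFV, transit_time)`.
#' @return Symmetric `N x N` matrix, zero diagonal; rows of `points0` come
#'   first.
#' @export
pooled_distance_matrix <- function(points0, points1) {
  p0 <- as.matrix(points0); p1 <- as.matrix(points1)
  if (ncol(p0) != ncol(p1)) stop_invalid("point sets differ in dimension")
  pooled <- rbind(p0, p1)
  if (nrow(pooled) < 2L) stop_invalid("need at least 2 points in total")
  sds <- apply(pooled, 2L, sd)
  keep <- sds > 0
  if (!any(keep))
    stop_invalid("all coordinates have zero pooled variance")
  if (!all(keep))
    warning("dropping constant coordinate(s): ",
            paste(which(!keep), collapse = ", "))
  z <- scale(pooled[, keep, drop = FALSE])
  as.matrix(dist(z))
}

#' Minimum-weight non-bipartite matching
#'
#' Finds the perfect matching of minimum total distance over all points
#' (groups ignored). An odd point count is handled by a ghost point at zero
#' distance to everything; the ghost's partner is left unmatched. Exact
#' (dynamic programming) for up to 22 points; larger problems use a
#' deterministic greedy + exchange local search.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return Two-column integer matrix of matched index pairs (`i < j`); with
#'   an odd input one point is absent.
#' @export
optimal_nonbipartite_matching <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop_invalid("need at least 2 points")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop_invalid("distance matrix must be symmetric")
  odd <- n %% 2L == 1L
  if (odd) {
    D <- rbind(cbind(D, 0), 0)
  }
  mate <- min_weight_matching_cpp(D)
  pairs <- cbind(seq_along(mate), mate)
  pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
  if (odd) pairs <- pairs[pairs[, 2L] != n + 1L, , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  pairs
}

#' Exact null distribution of the crossmatch count
#'
#' Probability mass function of `A1`, the number of cross-group pairs, when
#' group labels (`n1` of one kind among `N = n0 + n1`) are assigned at
#' random to the vertices of a fixed perfect matching. For even `N`,
#' `P(A1 = a) = 2^a (N/2)! / ( C(N, n1) ((n0-a)/2)! a! ((n1-a)/2)! )` over
#' the parity-feasible support. For odd `N` one point is unmatched and the
#' pmf is the mixture over that point's label of the even-`N` pmfs with
#' `n0 - 1` or `n1 - 1`.
#'
#' @param n0,n1 group sizes (>= 1).
#' @return `data.frame` with columns `a1` and `prob`; probabilities sum
#'   to 1. The null mean is `n0 n1 / (N - 1)` for even `N` and `n0 n1 / N`
#'   for odd `N`.
#' @export
crossmatch_null_pmf <- function(n0, n1) {
  check_scalar(n0, "n0", nonneg = TRUE, integerish = TRUE)
  check_scalar(n1, "n1", nonneg = TRUE, integerish = TRUE)
  N <- n0 + n1
  if (N < 1) stop_invalid("empty pooled sample")
  if (n0 == 0L || n1 == 0L)
    return(data.frame(a1 = 0L, prob = 1))
  if (N %% 2L == 0L) {
    a <- 0:min(n0, n1)
    a <- a[(n1 - a) %% 2L == 0L]
    lp <- a * log(2) + lfactorial(N / 2) -
      (lchoose(N, n1) + lfactorial((n0 - a) / 2) + lfactorial(a) +
         lfactorial((n1 - a) / 2))
    data.frame(a1 = a, prob = exp(lp))
  } else {
    # ghost-point construction: the unmatched vertex is equally likely to be
    # any point, so mix the even-N pmfs over its group
    p0 <- crossmatch_null_pmf(n0 - 1L, n1); p0$prob <- p0$prob * n0 / N
    p1 <- crossmatch_null_pmf(n0, n1 - 1L); p1$prob <- p1$prob * n1 / N
    all <- rbind(p0, p1)
    agg <- stats::aggregate(prob ~ a1, data = all, FUN = sum)
    agg[order(agg$a1), c("a1", "prob")]
  }
}

#' Crossmatch multivariate two-sample test
#'
#' Rosenbaum's distribution-free comparison of two multivariate samples:
#' pool the points, find the minimum-distance non-bipartite matching, count
#' the pairs containing one point from each group (`a1`), and compare the
#' count to its exact randomization null. Well-separated groups produce few
#' cross-group pairs, so the reported p value is the lower tail
#' `P(A1 <= a1)`.
#'
#' Used here to compare the joint (MFV, transit time) relationship between
#' hypoxic and normoxic animals; coordinates are standardized over the
#' pooled sample before distances are taken, which makes the test invariant
#' to affine changes of units.
#'
#' @param points0,points1 per-group point matrices, `n0, n1 >= 2` rows.
#' @return Object of class `crossmatch_result`: `n0`, `n1`, `a1`,
#'   `matching` (index pairs into the pooled order, group 0 first),
#'   `null_pmf`, `p_value` (exact lower tail), `z` and `p_approx` (normal
#'   deviate from the exact null moments with continuity correction, the
#'   usual large-sample report), `expected_a1`.
#' @export
crossmatch_test <- function(points0, points1) {
  p0 <- as.matrix(points0); p1 <- as.matrix(points1)
  n0 <- nrow(p0); n1 <- nrow(p1)
  if (n0 < 2L || n1 < 2L) stop_invalid("each group needs at least 2 points")
  D <- pooled_distance_matrix(p0, p1)
  pairs <- optimal_nonbipartite_matching(D)
  cross <- (pairs[, 1L] <= n0) != (pairs[, 2L] <= n0)
  a1 <- sum(cross)
  pmf <- crossmatch_null_pmf(n0, n1)
  p <- sum(pmf$prob[pmf$a1 <= a1])
  mu <- sum(pmf$a1 * pmf$prob)
  v <- sum((pmf$a1 - mu)^2 * pmf$prob)
  z <- if (v > 0) (a1 + 0.5 - mu) / sqrt(v) else 0
  structure(list(n0 = n0, n1 = n1, a1 = a1, matching = pairs,
                 null_pmf = pmf, p_value = min(p, 1),
                 z = z, p_approx = pnorm(z),
                 expected_a1 = mu),
            class = "crossmatch_result")
}

#' @export
print.crossmatch_result <- function(x, ...) {
  cat(sprintf(
    "<crossmatch> n0=%d n1=%d  a1=%d (null mean %.3f)  p=%.4g\n",
    x$n0, x$n1, x$a1, x$expected_a1, x$p_value))
  invisible(x)
}

#' Parabolic regression of transit time on flow velocity
#'
#' Ordinary least squares of `TT = c0 + c1 V + c2 V^2`, the empiric
#' nonlinear summary of how transit time rises as microvascular flow
#' velocity falls within a group.
#'
#' @param V microvascular flow velocities (au/s), >= 4 points.
#' @param TT transit times (s), same length.
#' @param group optional group label.
#' @return Object of class `parabola_fit` with `coefficients`
#'   (`c0`, `c1`, `c2`) and `r_squared`.
#' @export
fit_parabola <- function(V, TT, group = NA_character_) {
  if (length(V) != length(TT)) stop_invalid("V and TT lengths differ")
  keep <- !(is.na(V) | is.na(TT))
  V <- V[keep]; TT <- TT[keep]
  if (length(V) < 4L) stop_invalid("parabola fit needs at least 4 points")
  if (length(unique(V)) < 3L)
    stop_invalid("parabola fit needs at least 3 distinct V values")
  fit <- lm(TT ~ V + I(V^2))
  ss_tot <- sum((TT - mean(TT))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(list(group = group,
                 coefficients = setNames(unname(coef(fit)),
                                         c("c0", "c1", "c2")),
                 r_squared = r2, n = length(V)),
            class = "parabola_fit")
}

#' @importFrom stats residuals dist aggregate
NULL
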