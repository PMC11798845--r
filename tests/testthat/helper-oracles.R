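# Shared fixtures and independent oracles used across the suite.

# Analytic flash-replenishment TIC sampled like a cine acquisition:
# destruction floor O on [0, t_f), then O + A(1 - exp(-beta (t - t_f))).
make_synthetic_tic <- function(A, beta, O = 0, t_f = 3, frame_rate = 15,
                               imaging = 15, noise_sigma = 0, seed = NULL) {
  dt <- 1 / frame_rate
  times <- seq(0, t_f + imaging, by = dt)
  y <- ifelse(times < t_f, O, O + A * (1 - exp(-beta * (times - t_f))))
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y * exp(rnorm(length(y), -noise_sigma^2 / 2, noise_sigma))
  }
  tic(times, y, flash_end_index = which(times >= t_f - 1e-12)[1L])
}

small_cine <- function(...) {
  args <- list(height_px = 12L, width_px = 12L, pixel_spacing_mm = 0.5,
               frame_rate_hz = 15, baseline_duration_s = 1,
               noise_sigma = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cine_config, args)
}

# exhaustive minimum-weight perfect matching (even n), independent of the
# compiled implementation
brute_force_matching <- function(D) {
  n <- nrow(D)
  stopifnot(n %% 2 == 0)
  best <- list(cost = Inf, pairs = NULL)
  rec <- function(unmatched, cost, pairs) {
    if (length(unmatched) == 0L) {
      if (cost < best$cost) best <<- list(cost = cost, pairs = pairs)
      return(invisible())
    }
    i <- unmatched[1L]
    for (j in unmatched[-1L]) {
      rec(setdiff(unmatched, c(i, j)), cost + D[i, j],
          rbind(pairs, c(i, j)))
    }
  }
  rec(seq_len(n), 0, NULL)
  best
}

# exact two-sided Mann-Whitney p by enumerating all group-label assignments
# (tie-free samples)
enum_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  combos <- utils::combn(N, n1)
  us <- apply(combos, 2L, u_of)
  mean(abs(us - mu) >= obs - 1e-12)
}

# crossmatch null pmf by enumerating label assignments over a fixed
# matching structure on N points (one unmatched when N is odd)
enum_crossmatch_pmf <- function(n0, n1) {
  N <- n0 + n1
  n_pairs <- N %/% 2L
  pairs <- matrix(seq_len(2L * n_pairs), ncol = 2L, byrow = TRUE)
  combos <- utils::combn(N, n1)
  a1 <- apply(combos, 2L, function(g1) {
    lab <- rep(0L, N); lab[g1] <- 1L
    sum(lab[pairs[, 1L]] != lab[pairs[, 2L]])
  })
  tab <- table(a1) / ncol(combos)
  data.frame(a1 = as.integer(names(tab)), prob = as.numeric(tab))
}

# grid search + Nelder-Mead refinement for the replenishment model,
# independent of the package's nonlinear least squares
grid_fit_oracle <- function(t, y) {
  sse_beta <- function(beta) {
    x <- 1 - exp(-beta * t)
    fit <- lm(y ~ x)
    sum(residuals(fit)^2)
  }
  betas <- exp(seq(log(1e-3), log(50), length.out = 400))
  b0 <- betas[which.min(vapply(betas, sse_beta, 0))]
  x0 <- 1 - exp(-b0 * t)
  cf <- coef(lm(y ~ x0))
  obj <- function(p) {
    if (any(p < 0)) return(1e12)
    sum((y - (p[1L] + p[2L] * (1 - exp(-p[3L] * t))))^2)
  }
  opt <- optim(c(max(cf[1L], 0), max(cf[2L], 1e-8), b0), obj,
               control = list(maxit = 5000, reltol = 1e-14))
  opt <- optim(opt$par, obj, control = list(maxit = 5000, reltol = 1e-14))
  setNames(opt$par, c("O", "A", "beta"))
}
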