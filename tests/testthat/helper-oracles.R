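# Independent oracles used across the suite. These reimplement the checks
# from first principles (quadrature, exhaustive enumeration) and never call
# the code paths they verify.

# Penalty by direct numerical quadrature of the inverse-integral
# construction: P(theta) = int_0^|theta| [Theta^{-1}(u) - u] du, with the
# sup-inverse obtained by bisection (vectorized over the quadrature grid;
# independent of the package's fallback machinery). Composite trapezoid on
# a dense grid keeps the kink error of piecewise-smooth integrands around
# 1e-10, well inside the 1e-8 comparison tolerance.
oracle_penalty <- function(theta_fun, th, lam, n_grid = 80001L) {
  a <- abs(th)
  if (a == 0) return(0)
  u <- seq(0, a, length.out = n_grid)
  hi <- rep(a + lam + 2, n_grid)
  bad <- theta_fun(hi, lam) <= u
  while (any(bad)) {               # ensure the upper bracket exceeds u
    hi[bad] <- hi[bad] * 2
    bad <- theta_fun(hi, lam) <= u
  }
  lo <- rep(0, n_grid)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    inside <- theta_fun(mid, lam) <= u
    lo[inside] <- mid[inside]
    hi[!inside] <- mid[!inside]
  }
  s <- (lo + hi) / 2 - u
  h <- a / (n_grid - 1)
  h * (sum(s) - (s[1] + s[n_grid]) / 2)
}

# Exhaustive modified-BIC enumeration over mean-shift supports up to
# max_size, scored by the OLS refit on the complement rows.
oracle_enum_bic <- function(X, y, max_size) {
  n <- nrow(X); p <- ncol(X); m <- n - p
  best <- integer(0); best_bic <- Inf
  idx_all <- seq_len(n)
  for (size in 0:max_size) {
    combs <- if (size == 0) matrix(integer(0), 0, 1)
             else utils::combn(idx_all, size)
    for (j in seq_len(ncol(combs))) {
      A <- combs[, j]
      keep <- setdiff(idx_all, A)
      if (length(keep) <= p) next
      f <- qr(X[keep, , drop = FALSE])
      rss <- sum(qr.resid(f, y[keep])^2)
      if (rss <= 1e-12) next
      bic <- m * log(rss / m) + (length(A) + 1) * (log(m) + 1)
      if (bic < best_bic - 1e-9) { best_bic <- bic; best <- A }
    }
  }
  sort(as.integer(best))
}

# Location-model fixture: intercept-only design with well-separated
# planted shifts, the minimal mean-shift testbed (uniform leverage 1/n).
location_fixture <- function(n, n_shift, seed, shift = 8, sigma = 0.1) {
  set.seed(seed)
  y <- 3 + stats::rnorm(n, 0, sigma)
  shifts <- if (n_shift > 0) sample.int(n, n_shift) else integer(0)
  y[shifts] <- y[shifts] + shift
  list(X = matrix(1, n, 1), y = y, shifts = sort(shifts))
}
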