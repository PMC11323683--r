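test_that("hat matrix is the projection onto the column space", {
  d1 <- hat_matrix(matrix(1, 4, 1))
  expect_equal(hat_H(d1), matrix(0.25, 4, 4))
  expect_equal(d1$h, rep(0.25, 4))

  expect_error(hat_matrix(diag(5)), "n > p")
  expect_error(regression_problem(diag(5), rnorm(5)), "n > p")

  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  d <- hat_matrix(X)
  expect_equal(sum(d$h), 3, tolerance = 1e-10)          # trace = rank
  H <- hat_H(d)
  expect_lt(max(abs(H %*% H - H)), 1e-8)                # idempotent
  expect_equal(H, t(H))                                 # symmetric
  expect_true(all(d$h >= 0 & d$h <= 1))

  Xdef <- cbind(1, 1:10, 2 * (1:10))
  expect_error(hat_matrix(Xdef), "singular design: column\\(s\\) 3")
})

test_that("exact data and large thresholds give the null fit (OLS)", {
  set.seed(3)
  X <- cbind(1, rnorm(12))
  beta <- c(2, -1)
  prob0 <- regression_problem(X, drop(X %*% beta))      # no noise
  f0 <- ipod_fit(prob0, lam = 0.5, rule = "soft")
  expect_equal(f0$gamma_hat, numeric(12))
  expect_equal(unname(f0$beta_hat), beta)

  y <- drop(X %*% beta) + rnorm(12, 0, 0.3)
  prob <- regression_problem(X, y)
  dec <- hat_matrix(X)
  Py <- drop(y - dec$Q %*% crossprod(dec$Q, y))
  lam_max <- max(abs(Py) / sqrt(1 - dec$h))
  f <- ipod_fit(prob, lam_max * 1.0000001, "hard")
  expect_equal(f$gamma_hat, numeric(12))
  expect_equal(f$beta_hat, qr.coef(qr(X), y))
})

test_that("a single gross shift is flagged at mid-range thresholds", {
  fx <- location_fixture(10, 1, seed = 71)
  prob <- regression_problem(fx$X, fx$y)
  # exhaustive single-shift oracle: the hypothesis with the smallest
  # refit RSS is the planted index
  rss1 <- vapply(1:10, function(i)
    sum((fx$y[-i] - mean(fx$y[-i]))^2), numeric(1))
  expect_equal(which.min(rss1), fx$shifts)
  for (lam in c(2, 4, 6)) {
    for (rn in c("soft", "hard")) {
      f <- ipod_fit(prob, lam, rn)
      expect_equal(f$outlier_idx, fx$shifts)
    }
  }
})

test_that("soft-rule objective decreases monotonically along iterations", {
  set.seed(9)
  X <- cbind(1, rnorm(40))
  y <- drop(X %*% c(1, 2)) + rnorm(40, 0, 0.5)
  y[c(5, 20)] <- y[c(5, 20)] + 6
  prob <- regression_problem(X, y)
  dec <- hat_matrix(X)
  rule <- threshold_rule("soft")
  lam <- 2
  lam_i <- lam * sqrt(1 - dec$h)
  gamma <- numeric(40)
  Py <- drop(y - dec$Q %*% crossprod(dec$Q, y))
  obj <- function(g) {
    r <- (y - g) - dec$Q %*% crossprod(dec$Q, y - g)
    0.5 * sum(r^2) + sum(rule$penalty(g, lam_i))
  }
  prev <- obj(gamma)
  for (it in 1:60) {
    gamma <- rule$theta(Py + drop(dec$Q %*% crossprod(dec$Q, gamma)), lam_i)
    cur <- obj(gamma)
    expect_lte(cur, prev + 1e-10)
    prev <- cur
  }
})

test_that("the converged shift vector is a fixed point of the update", {
  set.seed(11)
  X <- cbind(1, rnorm(30))
  y <- drop(X %*% c(0, 1)) + rnorm(30, 0, 0.4)
  y[7] <- y[7] + 5
  prob <- regression_problem(X, y)
  dec <- hat_matrix(X)
  for (rn in c("soft", "hard")) {
    f <- ipod_fit(prob, 1.5, rn, dec = dec)
    expect_true(f$converged)
    lam_i <- 1.5 * sqrt(1 - dec$h)
    z <- drop(y - dec$Q %*% crossprod(dec$Q, y - f$gamma_hat))
    expect_equal(apply_threshold(z, lam_i, rn), f$gamma_hat,
                 tolerance = 1e-6)
  }
})

test_that("at lambda = 0 the residual projection of y - gamma vanishes", {
  set.seed(13)
  X <- cbind(1, rnorm(15))
  y <- rnorm(15)
  prob <- regression_problem(X, y)
  dec <- hat_matrix(X)
  f <- ipod_fit(prob, 0, "soft", dec = dec, max_iter = 5000L)
  r <- (y - f$gamma_hat) - dec$Q %*% crossprod(dec$Q, y - f$gamma_hat)
  expect_lt(max(abs(r)), 1e-6)
})

test_that("modified BIC matches hand computation and flags saturation", {
  X <- matrix(1, 6, 1)
  y <- c(0, 0, 0, 0, 0, 6)
  dec <- hat_matrix(X)
  # null support: RSS = sum((y - ybar)^2) = 30, m = 5, k = 1
  expect_equal(bic_star(dec, y, numeric(6)),
               5 * log(6) + (log(5) + 1))
  # shift absorbing the sixth point: exact interpolation -> sentinel
  g <- c(0, 0, 0, 0, 0, 6)
  expect_warning(b <- bic_star(dec, y, g), class = "sipod_degenerate_fit")
  expect_identical(b, -Inf)
  # support cap: sets beyond the identifiable bound are degenerate
  expect_warning(b2 <- bic_star(dec, y, c(1, 1, 1, 1, 0, 0)),
                 class = "sipod_degenerate_fit")
  expect_identical(b2, -Inf)
})

test_that("two-point path degenerates to OLS vs saturated, OLS wins on clean data", {
  set.seed(17)
  X <- cbind(1, rnorm(25))
  y <- drop(X %*% c(1, 1)) + rnorm(25, 0, 0.3)
  f <- ipod_select(regression_problem(X, y), "hard", n_lambda = 2L)
  expect_identical(f$outlier_idx, integer(0))
  expect_equal(f$beta_hat, qr.coef(qr(X), y))
})

test_that("path selection agrees with bounded exhaustive enumeration on a fixture", {
  fx <- location_fixture(12, 2, seed = 31)
  prob <- regression_problem(fx$X, fx$y)
  f <- ipod_select(prob, "hard", n_lambda = 2000L, max_support = 2L)
  expect_identical(sort(f$outlier_idx),
                   oracle_enum_bic(fx$X, fx$y, 2L))
  expect_identical(sort(f$outlier_idx), fx$shifts)
})
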