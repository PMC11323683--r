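test_that("AR-decay kernel matches the printed form and standardizes", {
  w_raw <- make_weights(3, 0.5, row_standardize = FALSE)
  expect_equal(w_raw$W, rbind(c(0, .5, .25), c(.5, 0, .5), c(.25, .5, 0)))
  w <- make_weights(3, 0.5)
  expect_equal(rowSums(w$W), rep(1, 3))
  expect_true(w$row_standardized)
  # decay limit: far entries vanish as r -> 0
  w_small <- make_weights(3, 1e-6, row_standardize = FALSE)
  expect_lt(w_small$W[1, 3], 1e-11)
  expect_error(make_weights(1), "n must be >= 2")
  expect_error(make_weights(5, 1.2), "r_decay")
})

test_that("design has the declared variance, correlation and leverage rows", {
  X0 <- make_design(p = 4, rho = 0, seed = 8, n = 500)
  expect_equal(mean(apply(X0, 2, var)), 100 / 12, tolerance = 0.05)
  X1 <- make_design(p = 15, rho = 0.5, seed = 8, n = 500)
  cc <- cor(X1)
  expect_equal(mean(cc[upper.tri(cc)]), 0.5, tolerance = 0.05)
  XL <- make_design(p = 5, rho = 0.5, L = 15, O = 10, seed = 8, n = 500)
  expect_true(all(XL[1:10, ] == 15))
  expect_equal(XL[11:500, ], X1 <- make_design(p = 5, rho = 0.5, seed = 8,
                                               n = 500)[11:500, ])
  expect_error(make_design(p = 5, rho = -0.5), "positive definite")
})

test_that("datasets are reproducible and carry the planted truth", {
  sc <- scenario(n = 40, p = 3, O = 4, seed = 123)
  d1 <- make_dataset(sc)
  d2 <- make_dataset(sc)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$truth, 1:4)
  expect_equal(d1$gamma[1:4], rep(8, 4))
  expect_equal(d1$gamma[5:40], rep(0, 36))
  d3 <- make_dataset(scenario(n = 40, p = 3, O = 4, seed = 124))
  expect_false(identical(d1$y, d3$y))
  # clean scenario: empty truth
  d0 <- make_dataset(scenario(n = 40, p = 3, O = 0, seed = 1))
  expect_identical(d0$truth, integer(0))
})

test_that("the noiseless zero-mu limit recovers truth by plain thresholding", {
  sc <- scenario(n = 50, p = 2, O = 5, mu = 0, sigma2 = 1e-12, seed = 6)
  d <- make_dataset(sc)
  expect_equal(d$y - drop(d$X %*% rep(1, 2)), d$gamma, tolerance = 1e-4)
  # any threshold below the shift isolates exactly the planted set
  prob <- regression_problem(d$X, d$y)
  for (lam in c(1, 4, 7.5)) {
    f <- ipod_fit(prob, lam, "hard")
    expect_identical(f$outlier_idx, 1:5)
  }
})

test_that("the spatial error field has the analytic covariance and positive autocorrelation", {
  n <- 30
  w <- make_weights(n)
  A <- diag(n) - 0.7 * w$W
  target <- 0.2 * solve(A) %*% t(solve(A))
  xs <- sapply(1:400, function(k)
    make_dataset(scenario(n = n, p = 2, O = 0,
                          seed = derive_seed(9, 3L, k)), w = w)$xi)
  emp <- tcrossprod(xs - rowMeans(xs)) / (ncol(xs) - 1)
  # entrywise Monte-Carlo agreement: elements are O(1), 400 replicates
  expect_lt(max(abs(emp - target)), 6 * max(diag(target)) / sqrt(400))
  expect_gt(mean(diag(emp)), 0.2)          # spatial inflation above sigma2
  d <- make_dataset(scenario(O = 50, seed = 2), w = make_weights(500))
  expect_gt(cor(d$xi, drop(make_weights(500)$W %*% d$xi)), 0)
  expect_gt(var(d$xi), 0.2)
})

test_that("derived seeds are deterministic, distinct and 31-bit", {
  sc <- scenario(seed = 1)
  s1 <- derive_seed(42, sc, 7)
  expect_identical(s1, derive_seed(42, sc, 7))
  expect_false(s1 == derive_seed(42, sc, 8))
  expect_false(s1 == derive_seed(43, sc, 7))
  ss <- vapply(1:500, function(k) derive_seed(1, sc, k), integer(1))
  expect_true(all(ss >= 1 & ss < 2^31))
  expect_equal(length(unique(ss)), 500)
})
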