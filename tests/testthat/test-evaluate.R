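test_that("masking, swamping and joint detection follow their definitions", {
  expect_equal(masking(1:10, 1:10), 0)
  expect_equal(masking(integer(0), 1:10), 1)
  expect_equal(masking(c(1, 2, 99), 1:4), 0.5)
  expect_error(masking(1:3, integer(0)), "nonempty truth")

  expect_equal(swamping(1:5, 1:10, 100), 0)
  expect_equal(swamping(c(1:10, 11, 12), 1:10, 100), 2 / 90)
  expect_equal(swamping(1:100, 1:10, 100), 1)
  expect_error(swamping(1:5, 1:10, 10), "must exceed")

  oc <- function(det, tr) replicate_outcome(det, tr, 1, 1)
  all_perfect <- replicate(10, oc(1:3, 1:3), simplify = FALSE)
  expect_equal(joint_detection(all_perfect), 100)
  none <- replicate(10, oc(1:2, 1:3), simplify = FALSE)
  expect_equal(joint_detection(none), 0)
  mixed <- c(replicate(87, oc(1:3, 1:3), simplify = FALSE),
             replicate(13, oc(1:2, 1:3), simplify = FALSE))
  expect_equal(joint_detection(mixed), 87)
  expect_error(joint_detection(list()), "at least one replicate")
})

test_that("coefficient MSE uses the per-coordinate convention", {
  o1 <- replicate_outcome(integer(0), 1L, c(1.001, 1.003), c(1, 1))
  expect_equal(mse_beta(list(o1)), 5e-6)
  o2 <- replicate_outcome(integer(0), 1L, c(1, 1), c(1, 1))
  expect_equal(mse_beta(list(o2)), 0)
  # mean of per-replicate values
  expect_equal(mse_beta(list(o1, o2)), 2.5e-6)
  o3 <- replicate_outcome(integer(0), 1L, 1, 1)
  expect_error(mse_beta(list(o1, o3)), "dimension mismatch")
})

test_that("per-replicate masking decreases weakly along the soft path", {
  d <- make_dataset(scenario(n = 80, p = 3, O = 8, seed = 5))
  prob <- regression_problem(d$X, d$y)
  dec <- hat_matrix(d$X)
  Py <- drop(d$y - dec$Q %*% crossprod(dec$Q, d$y))
  lam_max <- max(abs(Py) / sqrt(1 - dec$h))
  gamma <- numeric(80)
  masks <- c()
  for (lam in seq(lam_max, 0.5, length.out = 40)) {
    f <- ipod_fit(prob, lam, "soft", gamma_init = gamma, dec = dec)
    gamma <- f$gamma_hat
    masks <- c(masks, masking(f$outlier_idx, d$truth))
  }
  expect_true(all(diff(masks) <= 0))
})

test_that("benchmark rows are seed-stable and independent of the method set", {
  sc <- scenario(n = 60, p = 2, O = 5, seed = 1)
  r1 <- run_benchmark(sc, methods = c("hard-ipod", "spatial-hard-ipod"),
                      n_reps = 3, seed = 7)
  r2 <- run_benchmark(sc, methods = c("spatial-hard-ipod"),
                      n_reps = 3, seed = 7)
  a <- as.data.frame(r1)
  b <- as.data.frame(r2)
  expect_equal(a[a$method == "spatial-hard-ipod",
                 c("M", "S", "JD", "mse_beta")],
               b[, c("M", "S", "JD", "mse_beta")],
               ignore_attr = TRUE)
  expect_true(all(a$M >= 0 & a$M <= 1))
  expect_true(all(a$S >= 0 & a$S <= 1))
  expect_true(all(a$JD >= 0 & a$JD <= 100))
  # JD = 100 implies masking 0 in every audited replicate
  oc <- attr(r2, "outcomes")[["1:spatial-hard-ipod"]]
  if (b$JD == 100)
    expect_true(all(vapply(oc, function(o) masking(o$detected, o$truth),
                           numeric(1)) == 0))
  # single replicate: degenerate JD
  r3 <- run_benchmark(sc, methods = "hard-ipod", n_reps = 1, seed = 7)
  expect_true(as.data.frame(r3)$JD %in% c(0, 100))
  expect_error(run_benchmark(sc, methods = "mm-estimator", n_reps = 1),
               "unknown method")
})
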