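# Non-spatial Theta-IPOD: mean-shift outlier model y = X beta + gamma + eps,
# solved by iterating gamma <- Theta(H gamma + (I - H) y; lambda_i) with
# leverage-adjusted thresholds lambda_i = lambda * sqrt(1 - h_i), then
# back-solving beta by least squares on (X, y - gamma). The regularization
# parameter is tuned by a modified BIC over a decreasing lambda path.

#' Regression problem container
#'
#' Validates and bundles a design matrix and response for the mean-shift
#' outlier model. The design must be full column rank with more rows than
#' columns (the underdetermined case p >= n is out of scope).
#'
#' @param X Numeric matrix (n x p), full column rank.
#' @param y Numeric response vector of length n.
#' @return An object of class `regression_problem` with fields `X`, `y`,
#'   `n`, `p`.
#' @export
regression_problem <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop(sprintf("dimension error: nrow(X) = %d but length(y) = %d",
                 nrow(X), length(y)), call. = FALSE)
  if (anyNA(X) || anyNA(y))
    stop("X and y must not contain missing values", call. = FALSE)
  if (nrow(X) <= ncol(X))
    stop(sprintf("n > p required (got n = %d, p = %d); p >= n is not supported",
                 nrow(X), ncol(X)), call. = FALSE)
  structure(list(X = X, y = y, n = nrow(X), p = ncol(X)),
            class = "regression_problem")
}

#' Hat matrix decomposition
#'
#' Computes the projection onto the column space of `X` through a QR
#' factorization (no explicit inverse of X'X). The full n x n matrix is
#' never needed by the solvers; products with H use the thin orthonormal
#' factor `Q` (H = Q Q'), available explicitly via [hat_H()].
#'
#' @param X Numeric matrix, full column rank, n > p.
#' @return Object of class `hat_decomposition` with fields `Q` (n x p
#'   orthonormal basis, the unit-eigenvalue eigenvectors of H), `h`
#'   (leverages, the diagonal of H), `n`, `p`, `m = n - p`, `X` and the
#'   QR object used for back-solves.
#' @examples
#' d <- hat_matrix(cbind(1, rnorm(10)))
#' sum(d$h)  # trace(H) = p = 2
#' @export
hat_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop(sprintf("n > p required (got n = %d, p = %d)", n, p), call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- qrX$pivot[(qrX$rank + 1L):p]
    stop(sprintf("singular design: column(s) %s linearly dependent",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  Q <- qr.Q(qrX)
  h <- pmin(pmax(rowSums(Q^2), 0), 1)
  structure(list(Q = Q, h = h, n = n, p = p, m = n - p, X = X, qr = qrX),
            class = "hat_decomposition")
}

#' Dense hat matrix
#'
#' @param dec A `hat_decomposition`.
#' @return The n x n projection matrix `H = X (X'X)^{-1} X'`.
#' @export
hat_H <- function(dec) tcrossprod(dec$Q)

#' @export
print.hat_decomposition <- function(x, ...) {
  cat(sprintf("Hat decomposition: n = %d, p = %d, leverage in [%.3f, %.3f]\n",
              x$n, x$p, min(x$h), max(x$h)))
  invisible(x)
}

# Penalized objective with beta implicitly profiled out: since beta enters
# only through the projection, f(gamma) = ||(I-H)(y-gamma)||^2 / 2 + penalty.
.ipod_objective <- function(dec, y, gamma, rule, lam_i) {
  r <- y - gamma
  r <- r - dec$Q %*% crossprod(dec$Q, r)
  0.5 * sum(r^2) + sum(rule$penalty(gamma, lam_i))
}

# OLS mean-shift refit on a fixed support A: equivalent to OLS on the
# complement rows, with gamma_A the raw residuals of the deleted rows.
.refit_support <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  if (length(A) == 0L) {
    f <- qr(X)
    return(list(beta = qr.coef(f, y), gamma = numeric(n),
                rss = sum(qr.resid(f, y)^2), ok = TRUE))
  }
  keep <- setdiff(seq_len(n), A)
  if (length(keep) <= p) return(list(ok = FALSE))
  f <- qr(X[keep, , drop = FALSE])
  if (f$rank < p) return(list(ok = FALSE))
  beta <- qr.coef(f, y[keep])
  gamma <- numeric(n)
  gamma[A] <- y[A] - drop(X[A, , drop = FALSE] %*% beta)
  list(beta = beta, gamma = gamma, rss = sum(qr.resid(f, y[keep])^2), ok = TRUE)
}

#' Fit the mean-shift model at a fixed threshold level
#'
#' Iterates the thresholded update of the shift vector until the sup-norm
#' change drops below `tol`. Per-coordinate thresholds are
#' `lam * sqrt(1 - h_i)`; coordinates with leverage numerically equal to 1
#' are excluded from thresholding (their shift is pinned at zero) and
#' reported in the fit. For the non-convex hard rule the iteration can
#' enter a 2-cycle; cycles are detected against the iterate two steps back
#' and the lower-objective member is returned.
#'
#' @param prob A [regression_problem()].
#' @param lam Nonnegative threshold level.
#' @param rule Threshold rule name or object (`"soft"`, `"hard"`).
#' @param gamma_init Starting shift vector (default zero, the cold start).
#' @param tol Convergence tolerance on the sup-norm change of gamma.
#' @param max_iter Iteration cap; hitting it flags `converged = FALSE`
#'   rather than raising an error.
#' @param dec Optional precomputed [hat_matrix()] of `prob$X`.
#' @return Object of class `ipod_fit`: `beta_hat` (least squares on
#'   `(X, y - gamma_hat)`), `gamma_hat` (fixed point of the update),
#'   `outlier_idx`, `lam`, `n_iter`, `converged`, `cycled`, `objective`,
#'   `excluded` (unit-leverage indices), `bic_star` (filled by
#'   [ipod_select()]).
#' @export
ipod_fit <- function(prob, lam, rule, gamma_init = NULL, tol = 1e-8,
                     max_iter = 500L, dec = NULL) {
  stopifnot(inherits(prob, "regression_problem"))
  .check_lambda(lam)
  rule <- threshold_rule(rule)
  if (is.null(dec)) dec <- hat_matrix(prob$X)
  n <- prob$n
  y <- prob$y
  if (is.null(gamma_init)) gamma_init <- numeric(n)
  if (length(gamma_init) != n)
    stop(sprintf("dimension error: gamma_init has length %d, expected %d",
                 length(gamma_init), n), call. = FALSE)

  Q <- dec$Q
  Py <- y - Q %*% crossprod(Q, y)          # (I - H) y
  free <- dec$h < 1 - 1e-10
  lam_i <- lam * sqrt(pmax(1 - dec$h, 0))

  gamma <- gamma_init
  gamma[!free] <- 0
  g_prev2 <- NULL
  converged <- FALSE; cycled <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    z <- Py + Q %*% crossprod(Q, gamma)    # H gamma + (I - H) y
    g_new <- rule$theta(drop(z), lam_i)
    g_new[!free] <- 0
    if (max(abs(g_new - gamma)) < tol) {
      gamma <- g_new; converged <- TRUE; break
    }
    if (!is.null(g_prev2) && max(abs(g_new - g_prev2)) < tol) {
      # 2-cycle: keep the lower-objective member
      f_new <- .ipod_objective(dec, y, g_new, rule, lam_i)
      f_old <- .ipod_objective(dec, y, gamma, rule, lam_i)
      if (f_old < f_new) g_new <- gamma
      gamma <- g_new; cycled <- TRUE; converged <- TRUE; break
    }
    g_prev2 <- gamma
    gamma <- g_new
  }
  gamma <- drop(gamma)
  beta <- qr.coef(dec$qr, y - gamma)
  structure(list(
    beta_hat = beta,
    gamma_hat = gamma,
    lam = lam,
    outlier_idx = which(gamma != 0),
    n_iter = iter,
    converged = converged,
    cycled = cycled,
    objective = .ipod_objective(dec, y, gamma, rule, lam_i),
    excluded = which(!free),
    rule = rule$name,
    bic_star = NA_real_
  ), class = "ipod_fit")
}

#' Modified BIC for a mean-shift fit
#'
#' `BIC*(lambda) = m log(RSS/m) + k (log m + 1)` with `m = n - p` and
#' `k` = number of flagged shifts + 1. The residual sum of squares is taken
#' from the ordinary least squares refit with one free shift parameter per
#' flagged observation (for the hard rule this coincides with the fixed
#' point of the iteration; for the soft rule it undoes the shrinkage).
#' A saturated fit (RSS numerically zero, or too few clean rows left to
#' identify beta) returns `-Inf` with a degenerate-fit warning; such
#' lambdas are excluded from model selection.
#'
#' @param dec A [hat_matrix()] decomposition of the design.
#' @param y Response vector.
#' @param gamma_hat Estimated shift vector; only its support is used.
#' @param refit If `FALSE`, uses `RSS = ||(I - H)(y - gamma_hat)||^2`
#'   with `gamma_hat` as given instead of the refit.
#' @param max_support Largest admissible outlier set; defaults to half the
#'   sample. Mean-shift contamination beyond 50 percent is not
#'   identifiable (no detector has a breakdown point above 1/2), and for
#'   such supports the RSS loses the degrees of freedom the BIC* formula
#'   assumes, so larger sets are scored as degenerate.
#' @return The BIC* value, or `-Inf` for a degenerate fit.
#' @export
bic_star <- function(dec, y, gamma_hat, refit = TRUE,
                     max_support = floor(dec$n / 2)) {
  stopifnot(inherits(dec, "hat_decomposition"))
  m <- dec$m
  if (m <= 0) stop("m = n - p must be positive", call. = FALSE)
  A <- which(gamma_hat != 0)
  k <- length(A) + 1
  if (length(A) > max_support) {
    warning(.degenerate_warning(sprintf(
      "candidate outlier set of size %d exceeds the identifiable bound %d",
      length(A), max_support)))
    return(-Inf)
  }
  if (refit) {
    rf <- .refit_support(dec$X, y, A)
    if (!rf$ok) {
      warning(.degenerate_warning("too few clean rows to refit"))
      return(-Inf)
    }
    rss <- rf$rss
  } else {
    r <- y - gamma_hat
    r <- r - dec$Q %*% crossprod(dec$Q, r)
    rss <- sum(r^2)
  }
  scale <- max(sum(y^2), 1)
  if (rss <= scale * .Machine$double.eps^0.75) {
    warning(.degenerate_warning("residual sum of squares is numerically zero"))
    return(-Inf)
  }
  m * log(rss / m) + k * (log(m) + 1)
}

.degenerate_warning <- function(msg) {
  structure(class = c("sipod_degenerate_fit", "warning", "condition"),
            list(message = paste0("degenerate fit: ", msg), call = NULL))
}

#' Tune the threshold level by modified BIC over a lambda path
#'
#' Builds a linearly spaced path of `n_lambda` threshold levels from
#' `lambda_max = max_i |((I-H)y)_i| / sqrt(1 - h_i)` (the smallest level at
#' which no observation is flagged) down to 0, fits each level with warm
#' starts from the previous (larger) level, scores each visited support by
#' [bic_star()], and returns the minimizing fit. Ties are broken toward the
#' larger lambda, i.e. fewer flagged outliers. Degenerate (saturated) fits
#' are excluded from the selection.
#'
#' @inheritParams ipod_fit
#' @param n_lambda Number of path points (>= 2).
#' @param max_support Assumed upper bound on the number of outliers;
#'   candidate sets larger than this are excluded from selection (see
#'   [bic_star()]). Defaults to half the sample, the identifiability
#'   limit.
#' @return The selected `ipod_fit`, augmented with `beta_refit` and
#'   `gamma_refit` (the OLS mean-shift refit on the flagged support, the
#'   recommended robust coefficient estimate), the path diagnostics
#'   `lambda_path`, `bic_path`, `nz_path`, and `selected` (path index).
#' @export
ipod_select <- function(prob, rule, n_lambda = 100L, tol = 1e-8,
                        max_iter = 500L, max_support = floor(prob$n / 2)) {
  stopifnot(inherits(prob, "regression_problem"))
  if (n_lambda < 2L) stop("n_lambda must be >= 2", call. = FALSE)
  rule <- threshold_rule(rule)
  dec <- hat_matrix(prob$X)
  y <- prob$y
  Py <- drop(y - dec$Q %*% crossprod(dec$Q, y))
  free <- dec$h < 1 - 1e-10
  lam_max <- max(abs(Py[free]) / sqrt(1 - dec$h[free]))
  lams <- seq(lam_max, 0, length.out = n_lambda)

  fits <- vector("list", n_lambda)
  bics <- numeric(n_lambda)
  nz <- integer(n_lambda)
  gamma <- numeric(prob$n)
  bic_cache <- new.env(parent = emptyenv())
  for (j in seq_len(n_lambda)) {
    fit <- ipod_fit(prob, lams[j], rule, gamma_init = gamma,
                    tol = tol, max_iter = max_iter, dec = dec)
    gamma <- fit$gamma_hat
    key <- paste0("s", paste(fit$outlier_idx, collapse = ","))
    if (is.null(bic_cache[[key]])) {
      bic_cache[[key]] <- withCallingHandlers(
        bic_star(dec, y, fit$gamma_hat, max_support = max_support),
        sipod_degenerate_fit = function(w) invokeRestart("muffleWarning"))
    }
    fit$bic_star <- bic_cache[[key]]
    fits[[j]] <- fit
    bics[j] <- fit$bic_star
    nz[j] <- length(fit$outlier_idx)
  }
  ok <- is.finite(bics)
  if (!any(ok)) stop("all lambda values gave degenerate fits", call. = FALSE)
  sel <- which(ok)[which.min(bics[ok])]   # which.min keeps the first (larger lambda) on ties
  best <- fits[[sel]]
  rf <- .refit_support(prob$X, y, best$outlier_idx)
  best$beta_refit <- rf$beta
  best$gamma_refit <- rf$gamma
  best$lambda_path <- lams
  best$bic_path <- bics
  best$nz_path <- nz
  best$selected <- sel
  best
}

#' @export
print.ipod_fit <- function(x, ...) {
  cat(sprintf("Theta-IPOD fit (%s rule), lambda = %.4g\n", x$rule, x$lam))
  cat(sprintf("  flagged outliers: %d%s\n", length(x$outlier_idx),
              if (length(x$outlier_idx) > 0 && length(x$outlier_idx) <= 20)
                paste0(" (", paste(x$outlier_idx, collapse = ", "), ")")
              else ""))
  cat(sprintf("  iterations: %d, converged: %s%s\n", x$n_iter, x$converged,
              if (isTRUE(x$cycled)) " (2-cycle resolved)" else ""))
  if (is.finite(x$bic_star)) cat(sprintf("  BIC*: %.4f\n", x$bic_star))
  invisible(x)
}
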