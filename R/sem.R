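# Spatial error model (SEM) machinery: weight matrices, the GLS whitening
# transform, Gaussian maximum likelihood, and robustified-likelihood
# scoring (bounded psi influence functions) for the spatial autoregressive
# parameter mu.
#
# Model: y = X beta + xi,  xi = mu W xi + eps,  eps ~ N(0, sigma^2 I),
# so Cov(xi) = sigma^2 [(I - mu W)'(I - mu W)]^{-1} and left-multiplying by
# (I - mu W) whitens the errors.

#' Spatial weights container
#'
#' @param W Square numeric matrix with zero diagonal and nonnegative
#'   entries.
#' @param row_standardized Whether rows of `W` already sum to one.
#' @param source Provenance note (e.g. `"file"`, `"generated"`, `"user"`).
#' @return Object of class `spatial_weights` with fields `W`, `n`,
#'   `row_standardized`, `source`, `zero_rows` (indices of isolated units)
#'   and an internal cache environment for the spectrum of `W`.
#' @export
spatial_weights <- function(W, row_standardized = FALSE, source = "user") {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  n <- nrow(W)
  if (n != ncol(W))
    stop("invalid weights: W must be square", call. = FALSE)
  if (anyNA(W) || any(W < 0))
    stop("invalid weights: entries must be nonnegative and non-missing",
         call. = FALSE)
  if (any(abs(diag(W)) > 0))
    stop("invalid weights: diagonal must be zero", call. = FALSE)
  rs <- rowSums(W)
  if (row_standardized && any(rs > 0 & abs(rs - 1) > 1e-10))
    stop("invalid weights: declared row-standardized but rows do not sum to 1",
         call. = FALSE)
  structure(list(W = W, n = n, row_standardized = row_standardized,
                 source = source, zero_rows = which(rs == 0),
                 cache = new.env(parent = emptyenv())),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial weights: %d x %d, %srow-standardized, source: %s\n",
              x$n, x$n, if (x$row_standardized) "" else "not ", x$source))
  if (length(x$zero_rows) > 0)
    cat(sprintf("  isolated units (zero rows): %s\n",
                paste(x$zero_rows, collapse = ", ")))
  invisible(x)
}

#' Row-standardize a weight matrix
#'
#' Divides every nonzero row by its sum so that `mu` is interpretable on
#' (-1, 1). Zero rows (isolated units) are left as zero and reported in
#' the `zero_rows` field of the result.
#'
#' @param W Square nonnegative matrix with zero diagonal, or a
#'   `spatial_weights` object.
#' @param source Provenance note stored in the result.
#' @return A row-standardized `spatial_weights` object.
#' @export
row_standardize <- function(W, source = NULL) {
  if (inherits(W, "spatial_weights")) {
    if (is.null(source)) source <- W$source
    W <- W$W
  }
  if (is.null(source)) source <- "user"
  w0 <- spatial_weights(W, row_standardized = FALSE, source = source)
  rs <- rowSums(w0$W)
  nz <- rs > 0
  W2 <- w0$W
  W2[nz, ] <- W2[nz, ] / rs[nz]
  spatial_weights(W2, row_standardized = TRUE, source = source)
}

# Real spectrum of W (cached). Row-standardized decay kernels are similar
# to symmetric matrices, so the eigenvalues are real up to rounding.
weights_eigenvalues <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (is.null(w$cache$ev)) {
    ev <- eigen(w$W, only.values = TRUE)$values
    if (max(abs(Im(ev))) > 1e-8 * max(1, max(abs(Re(ev)))))
      warning("weight matrix has non-negligible complex eigenvalues; using real parts")
    w$cache$ev <- Re(ev)
  }
  w$cache$ev
}

#' Admissible interval for the spatial parameter
#'
#' The open interval of `mu` values keeping `I - mu W` invertible with
#' positive determinant terms, `(1/min(eig W), 1/max(eig W))`, intersected
#' with (-1, 1) for row-standardized weights. A zero weight matrix yields
#' (-1, 1).
#'
#' @param w A `spatial_weights` object.
#' @return Length-2 numeric vector (lower, upper).
#' @export
mu_interval <- function(w) {
  ev <- weights_eigenvalues(w)
  lo <- -Inf; hi <- Inf
  if (any(ev < 0)) lo <- 1 / min(ev)
  if (any(ev > 0)) hi <- 1 / max(ev)
  if (w$row_standardized) { lo <- max(lo, -1); hi <- min(hi, 1) }
  if (!is.finite(lo)) lo <- -1
  if (!is.finite(hi)) hi <- 1
  c(lo, hi)
}

.check_mu <- function(w, mu) {
  ev <- weights_eigenvalues(w)
  if (length(ev) && min(abs(1 - mu * ev)) < 1e-10)
    stop(sprintf("spatial parameter out of range: I - mu W is singular at mu = %g", mu),
         call. = FALSE)
  invisible(mu)
}

#' GLS whitening transform
#'
#' Left-multiplies the design and response by `(I - mu W)`, which whitens
#' the SEM errors back to an independent-error regression. `mu = 0` returns
#' the inputs untouched.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param w `spatial_weights`.
#' @param mu Spatial autoregressive parameter; `I - mu W` must be
#'   invertible.
#' @return List with `X`, `y` (transformed), `mu`, and `transform`
#'   (the matrix `I - mu W`, retained for back-transforming shift vectors;
#'   `NULL` when `mu = 0`).
#' @export
gls_transform <- function(X, y, w, mu) {
  stopifnot(inherits(w, "spatial_weights"))
  X <- as.matrix(X)
  if (nrow(X) != w$n || length(y) != w$n)
    stop("dimension error: X, y and W must agree on n", call. = FALSE)
  if (mu == 0)
    return(list(X = X, y = as.numeric(y), mu = 0, transform = NULL))
  .check_mu(w, mu)
  A <- diag(w$n) - mu * w$W
  list(X = X - mu * (w$W %*% X), y = drop(y - mu * (w$W %*% y)),
       mu = mu, transform = A)
}

.sem_estimate <- function(mu_hat, beta_hat, sigma_hat, method, psi_kind,
                          converged, n_iter, ...) {
  structure(c(list(mu_hat = mu_hat, beta_hat = beta_hat,
                   sigma_hat = sigma_hat, method = method,
                   psi_kind = psi_kind, converged = converged,
                   n_iter = n_iter), list(...)),
            class = "sem_estimate")
}

#' @export
print.sem_estimate <- function(x, ...) {
  cat(sprintf("SEM estimate (%s%s): mu = %.4f, sigma = %.4f, converged: %s\n",
              x$method,
              if (x$psi_kind != "none") paste0(", psi = ", x$psi_kind) else "",
              x$mu_hat, x$sigma_hat, x$converged))
  cat("  beta:", format(x$beta_hat, digits = 4), "\n")
  invisible(x)
}

# Profile Gaussian log-likelihood of mu (beta, sigma^2 profiled out);
# WX / Wy are precomputed so each evaluation is O(np).
.sem_profile <- function(mu, X, y, WX, Wy, ev, n) {
  Xt <- X - mu * WX
  yt <- y - mu * Wy
  f <- qr(Xt)
  s2 <- sum(qr.resid(f, yt)^2) / n
  sum(log(pmax(1 - mu * ev, 1e-300))) - n / 2 * log(s2)
}

#' Maximum likelihood estimation of the spatial error model
#'
#' Profiles beta and sigma^2 out of the Gaussian SEM log-likelihood and
#' line-searches mu over its admissible interval. Serves both as the
#' non-robust comparator and as a fallback/initializer for
#' [romle_fit()].
#'
#' @inheritParams gls_transform
#' @return A `sem_estimate` with `method = "mle"`; `converged = FALSE`
#'   flags a boundary hit of the mu search. Carries `loglik`, the profile
#'   log-likelihood at the optimum (up to the usual constant).
#' @export
sem_mle <- function(X, y, w) {
  stopifnot(inherits(w, "spatial_weights"))
  X <- as.matrix(X); y <- as.numeric(y)
  n <- w$n
  if (nrow(X) != n || length(y) != n)
    stop("dimension error: X, y and W must agree on n", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("n > p required", call. = FALSE)
  ev <- weights_eigenvalues(w)
  WX <- w$W %*% X
  Wy <- drop(w$W %*% y)
  iv <- mu_interval(w)
  eps <- 1e-6 * (iv[2] - iv[1])
  opt <- stats::optimize(.sem_profile, interval = c(iv[1] + eps, iv[2] - eps),
                         X = X, y = y, WX = WX, Wy = Wy, ev = ev, n = n,
                         maximum = TRUE, tol = 1e-9)
  mu <- opt$maximum
  boundary <- (mu - iv[1] < 10 * eps) || (iv[2] - mu < 10 * eps)
  Xt <- X - mu * WX
  yt <- y - mu * Wy
  f <- qr(Xt)
  beta <- qr.coef(f, yt)
  s2 <- sum(qr.resid(f, yt)^2) / n
  .sem_estimate(mu, beta, sqrt(s2), "mle", "none", !boundary, NA_integer_,
                loglik = opt$objective - n / 2 * (log(2 * pi) + 1))
}

# --- psi influence functions ----------------------------------------------

.psi_registry <- new.env(parent = emptyenv())

.register_psi <- function(kind, psi, dpsi, tuning) {
  assign(kind, list(psi = psi, dpsi = dpsi, tuning = tuning),
         envir = .psi_registry)
}

# Conventional bounded-influence families; tuning constants are the
# customary high-efficiency values for each family (the identity kind is
# the unbounded Gaussian score, for which scoring reduces to MLE).
.register_psi("cauchy",
  function(r, c) r / (1 + (r / c)^2),
  function(r, c) { u <- (r / c)^2; (1 - u) / (1 + u)^2 },
  2.385)
.register_psi("welsch",
  function(r, c) r * exp(-(r / c)^2),
  function(r, c) { u <- (r / c)^2; exp(-u) * (1 - 2 * u) },
  2.985)
.register_psi("insha",
  function(r, c) r * (1 + (r / c)^4)^(-2),
  function(r, c) { u <- (r / c)^4; (1 - 7 * u) / (1 + u)^3 },
  5.0)
.register_psi("logistic",
  function(r, c) c * tanh(r / c),
  function(r, c) 1 / cosh(r / c)^2,
  1.205)
.register_psi("identity",
  function(r, c) r,
  function(r, c) rep(1, length(r)),
  1)

.psi_info <- function(kind) {
  stopifnot(is.character(kind), length(kind) == 1L)
  if (!exists(kind, envir = .psi_registry, inherits = FALSE))
    stop(sprintf("invalid parameter: unknown psi kind '%s'; available: %s",
                 kind, paste(ls(.psi_registry), collapse = ", ")),
         call. = FALSE)
  get(kind, envir = .psi_registry, inherits = FALSE)
}

#' Bounded influence functions
#'
#' Evaluates the named psi function at standardized residuals `r`. All
#' non-identity kinds are odd, continuous and bounded; the tuning constant
#' of each family defaults to its conventional high-efficiency value.
#'
#' @param r Numeric vector of standardized residuals.
#' @param kind One of `"cauchy"`, `"welsch"`, `"insha"`, `"logistic"`
#'   (or `"identity"`, the unbounded Gaussian score).
#' @param tuning Optional override of the family tuning constant.
#' @return `psi(r)` evaluated coordinate-wise.
#' @export
psi <- function(r, kind, tuning = NULL) {
  info <- .psi_info(kind)
  if (is.null(tuning)) tuning <- info$tuning
  info$psi(r, tuning)
}

#' @rdname psi
#' @export
psi_deriv <- function(r, kind, tuning = NULL) {
  info <- .psi_info(kind)
  if (is.null(tuning)) tuning <- info$tuning
  info$dpsi(r, tuning)
}

# E[psi^2(r)] and E[psi'(r)] under the standard normal reference density,
# by Gauss-Hermite quadrature (cached per kind).
.psi_moments <- function(kind) {
  key <- paste0("mom_", kind)
  if (is.null(.psi_registry[[key]])) {
    gh <- pracma::gaussHermite(60)
    r <- sqrt(2) * gh$x
    wts <- gh$w / sqrt(pi)
    info <- .psi_info(kind)
    .psi_registry[[key]] <- list(
      K = sum(wts * info$psi(r, info$tuning)^2),
      Edpsi = sum(wts * info$dpsi(r, info$tuning)))
  }
  .psi_registry[[key]]
}

#' Symmetric inverse square root of the SEM error correlation
#'
#' Computes the unique symmetric positive-definite `S` with
#' `S Omega S = I`, where
#' `Omega = (I - mu W)^{-1} (I - mu W')^{-1}` is the SEM error correlation
#' structure. Provided as a verification utility; the estimation routines
#' whiten residuals with the equivalent triangular-type factor `I - mu W`
#' itself, which is exact and cheaper.
#'
#' @inheritParams gls_transform
#' @return The n x n symmetric matrix `Omega^{-1/2}`.
#' @export
omega_inv_sqrt <- function(w, mu) {
  stopifnot(inherits(w, "spatial_weights"))
  .check_mu(w, mu)
  A <- diag(w$n) - mu * w$W
  Oinv <- crossprod(A)                       # (I - mu W')(I - mu W), SPD
  e <- eigen(Oinv, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("Omega^{-1} not positive definite; mu outside admissible range",
         call. = FALSE)
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

#' Robustified-likelihood scoring for the spatial error model
#'
#' Alternates Fisher-scoring updates of beta and mu in which the
#' standardized whitened residuals enter only through a bounded psi
#' function, with the consistency constant `K = E[psi^2]` (standard normal
#' reference, Gauss-Hermite quadrature) correcting the mu score. The scale
#' is re-estimated each sweep by the normalized median absolute deviation
#' of the whitened residuals (for `kind = "identity"` the Gaussian
#' root-mean-square is used instead, so the iteration is exactly
#' likelihood scoring). If the step norms grow for 5 consecutive sweeps
#' the routine falls back to [sem_mle()] with `converged = FALSE`.
#'
#' @inheritParams gls_transform
#' @param psi_kind Influence function family, see [psi()].
#' @param init `"ols"` (beta from OLS, mu from a coarse profile-likelihood
#'   grid). A `"gmm"` moment-based start is reserved as an extension point
#'   and currently errors.
#' @param tol Convergence tolerance on the sup-norm of the parameter
#'   updates.
#' @param max_iter Maximum number of scoring sweeps.
#' @return A `sem_estimate` with `method = "romle"` (or the `sem_mle`
#'   fallback result flagged `converged = FALSE`, `fallback = TRUE`).
#' @export
romle_fit <- function(X, y, w, psi_kind = "cauchy", init = "ols",
                      tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(w, "spatial_weights"))
  X <- as.matrix(X); y <- as.numeric(y)
  n <- w$n; p <- ncol(X)
  if (nrow(X) != n || length(y) != n)
    stop("dimension error: X, y and W must agree on n", call. = FALSE)
  if (n <= p) stop("n > p required", call. = FALSE)
  init <- match.arg(init, c("ols", "gmm"))
  if (init == "gmm")
    stop("init = 'gmm' is an extension point and not implemented; use 'ols'",
         call. = FALSE)
  info <- .psi_info(psi_kind)
  mom <- .psi_moments(psi_kind)
  K <- mom$K; Edpsi <- mom$Edpsi

  ev <- weights_eigenvalues(w)
  WX <- w$W %*% X
  Wy <- drop(w$W %*% y)
  iv <- mu_interval(w)
  margin <- 1e-4 * (iv[2] - iv[1])

  # initial values: OLS beta, coarse grid profile for mu
  beta <- qr.coef(qr(X), y)
  grid <- seq(iv[1] + margin, iv[2] - margin, length.out = 41L)
  prof <- vapply(grid, function(m) .sem_profile(m, X, y, WX, Wy, ev, n),
                 numeric(1))
  mu <- grid[which.max(prof)]

  scale_est <- if (psi_kind == "identity") {
    function(u) sqrt(mean(u^2))
  } else {
    function(u) 1.4826 * stats::median(abs(u))
  }

  grow <- 0L; last_step <- Inf
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Xt <- X - mu * WX
    yt <- y - mu * Wy
    u <- yt - drop(Xt %*% beta)
    sigma <- scale_est(u)
    r <- u / sigma
    # (iii) beta scoring step: s_beta = X~' psi(r) / sigma,
    # I(beta) = E[psi'] X~'X~ / sigma^2
    pr <- info$psi(r, info$tuning)
    delta_b <- drop(solve(crossprod(Xt), crossprod(Xt, pr))) * sigma / Edpsi
    beta <- beta + delta_b
    # (iv) residual update with the new beta
    u <- yt - drop(Xt %*% beta)
    sigma <- scale_est(u)
    r <- u / sigma
    pr <- info$psi(r, info$tuning)
    # (v) mu scoring step: s_mu = -K tr(G) + psi(r)' W (I - mu W)^{-1} psi(r)
    trG <- sum(ev / (1 - mu * ev))
    z <- solve(diag(n) - mu * w$W, pr)
    smu <- -K * trG + sum(pr * drop(w$W %*% z))
    Imu <- K * 2 * sum((ev / (1 - mu * ev))^2)
    delta_m <- if (Imu > 0) smu / Imu else 0
    mu_new <- min(max(mu + delta_m, iv[1] + margin), iv[2] - margin)
    delta_m <- mu_new - mu
    mu <- mu_new
    step <- max(max(abs(delta_b)), abs(delta_m))
    if (step < tol) { converged <- TRUE; break }
    if (step > last_step) grow <- grow + 1L else grow <- 0L
    if (grow >= 5L) break
    last_step <- step
  }
  if (grow >= 5L) {
    fb <- sem_mle(X, y, w)
    fb$converged <- FALSE
    fb$fallback <- TRUE
    fb$psi_kind <- psi_kind
    return(fb)
  }
  at_boundary <- (mu - iv[1] <= 2 * margin) || (iv[2] - mu <= 2 * margin)
  .sem_estimate(mu, beta, sigma, "romle", psi_kind,
                converged && !at_boundary, iter, K = K, fallback = FALSE)
}
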