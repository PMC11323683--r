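# Benchmark data generator: correlated uniform design, optional
# leverage-row contamination, mean-shift outliers on the first O rows,
# AR-decay spatial weights arranged on a line graph, and spatially
# autocorrelated SEM errors.

#' Benchmark scenario description
#'
#' Bundles the generative parameters of one simulation condition:
#' n observations, p predictors drawn as `X = U Sigma^{1/2}` with
#' `U_ij ~ U(-5, 5)` and equicorrelation `Sigma` (unit diagonal, `rho`
#' off-diagonal), the first `O` rows optionally replaced by the constant
#' leverage vector `L * [1, ..., 1]`, mean shifts of size `shift` on those
#' same first `O` rows, and SEM errors
#' `xi = (I - mu W)^{-1} eps`, `eps ~ N(0, sigma2 I)` with AR-decay
#' weights `w_ij = r_decay^{|i - j|}`.
#'
#' @param n Sample size.
#' @param p Number of predictors.
#' @param O Number of contaminated (shifted) observations; 0 gives clean
#'   data.
#' @param L Leverage value replacing the first `O` design rows, or `NULL`
#'   for no leverage contamination.
#' @param mu Spatial autoregressive parameter of the error process.
#' @param sigma2 Innovation variance.
#' @param rho Equicorrelation of the design columns (`rho > -1/(p-1)`).
#' @param r_decay Decay rate of the weight kernel, in (0, 1).
#' @param shift Size of the mean shift marking an outlier.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return Object of class `sipod_scenario`.
#' @export
scenario <- function(n = 500L, p = 15L, O = 50L, L = NULL, mu = 0.7,
                     sigma2 = 0.2, rho = 0.5, r_decay = 0.5, shift = 8,
                     seed = 1L) {
  stopifnot(n >= 2, p >= 1, O >= 0, O < n, sigma2 > 0,
            r_decay > 0, r_decay < 1, n > p)
  if (p > 1 && rho <= -1 / (p - 1))
    stop("invalid parameter: equicorrelation matrix not positive definite",
         call. = FALSE)
  if (!is.null(L)) stopifnot(is.numeric(L), length(L) == 1L)
  structure(list(n = as.integer(n), p = as.integer(p), O = as.integer(O),
                 L = L, mu = mu, sigma2 = sigma2, rho = rho,
                 r_decay = r_decay, shift = shift, seed = as.integer(seed)),
            class = "sipod_scenario")
}

#' @export
print.sipod_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: n = %d, p = %d, O = %d, leverage = %s, mu = %g, sigma2 = %g, shift = %g, seed = %d\n",
    x$n, x$p, x$O, if (is.null(x$L)) "none" else format(x$L),
    x$mu, x$sigma2, x$shift, x$seed))
  invisible(x)
}

#' AR-decay spatial weights on a line graph
#'
#' Builds the dense kernel `w_ij = r_decay^{|i - j|}` (zero diagonal) for
#' observations arranged in a linear sequence, then row-standardizes it by
#' default. The raw kernel is available with `row_standardize = FALSE` for
#' sensitivity checks.
#'
#' @param n Number of units (>= 2).
#' @param r_decay Decay rate in (0, 1).
#' @param row_standardize Whether to row-standardize the kernel.
#' @return A `spatial_weights` object with `source = "generated"`.
#' @export
make_weights <- function(n, r_decay = 0.5, row_standardize = TRUE) {
  if (n < 2) stop("invalid parameter: n must be >= 2", call. = FALSE)
  if (r_decay <= 0 || r_decay >= 1)
    stop("invalid parameter: r_decay must be in (0, 1)", call. = FALSE)
  W <- r_decay^abs(outer(seq_len(n), seq_len(n), "-"))
  diag(W) <- 0
  if (row_standardize) {
    row_standardize(W, source = "generated")
  } else {
    spatial_weights(W, row_standardized = FALSE, source = "generated")
  }
}

# Symmetric square root of the equicorrelation matrix in closed form:
# Sigma = (1 - rho) I + rho J has sqrt a I + b J.
.equicorr_sqrt <- function(p, rho) {
  a <- sqrt(1 - rho)
  b <- (sqrt(1 + (p - 1) * rho) - a) / p
  m <- matrix(b, p, p)
  diag(m) <- diag(m) + a
  m
}

#' Correlated uniform design with optional leverage rows
#'
#' Draws `U_ij ~ U(-5, 5)` iid, right-multiplies by the symmetric square
#' root of the equicorrelation matrix, and (if `L` is given) overwrites
#' rows `1..O` with the constant vector `L * [1, ..., 1]`. The uniform
#' draws are made before the overwrite so the random stream is identical
#' across leverage settings.
#'
#' @inheritParams scenario
#' @return An `n x p` numeric design matrix.
#' @export
make_design <- function(p, rho = 0.5, L = NULL, O = 0L, seed = 1L, n = 500L) {
  if (p > 1 && rho <= -1 / (p - 1))
    stop("invalid parameter: equicorrelation matrix not positive definite",
         call. = FALSE)
  set.seed(seed)
  U <- matrix(stats::runif(n * p, -5, 5), n, p)
  X <- U %*% .equicorr_sqrt(p, rho)
  if (!is.null(L) && O > 0) X[seq_len(O), ] <- L
  X
}

#' Generate one benchmark dataset
#'
#' Simulates `y = X 1_p + gamma + xi` with `gamma_i = shift` for
#' `i <= O` (else 0) and `xi` solving `(I - mu W) xi = eps`,
#' `eps ~ N(0, sigma2 I)` (exact, one dense solve). All randomness comes
#' from `sc$seed`; the draw order (design first, then innovations) is
#' fixed so leverage settings share design streams.
#'
#' @param sc A [scenario()].
#' @param w Optional precomputed `spatial_weights` (as from
#'   [make_weights()]); supplying it avoids rebuilding the kernel across
#'   replicates.
#' @return Object of class `sipod_dataset`: list with `X`, `y`, `w`,
#'   `truth` (indices `1..O`), `gamma`, `xi`, `scenario`.
#' @export
make_dataset <- function(sc, w = NULL) {
  stopifnot(inherits(sc, "sipod_scenario"))
  if (is.null(w)) w <- make_weights(sc$n, sc$r_decay)
  stopifnot(inherits(w, "spatial_weights"), w$n == sc$n)
  .check_mu(w, sc$mu)
  set.seed(sc$seed)
  U <- matrix(stats::runif(sc$n * sc$p, -5, 5), sc$n, sc$p)
  X <- U %*% .equicorr_sqrt(sc$p, sc$rho)
  if (!is.null(sc$L) && sc$O > 0) X[seq_len(sc$O), ] <- sc$L
  gamma <- numeric(sc$n)
  if (sc$O > 0) gamma[seq_len(sc$O)] <- sc$shift
  eps <- stats::rnorm(sc$n, 0, sqrt(sc$sigma2))
  xi <- if (sc$mu == 0) eps else drop(solve(diag(sc$n) - sc$mu * w$W, eps))
  y <- drop(X %*% rep(1, sc$p)) + gamma + xi
  structure(list(X = X, y = y, w = w, truth = seq_len(sc$O),
                 gamma = gamma, xi = xi, scenario = sc),
            class = "sipod_dataset")
}

#' @export
print.sipod_dataset <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  dataset: %d x %d design, %d planted outliers\n",
              nrow(x$X), ncol(x$X), length(x$truth)))
  invisible(x)
}

#' Derive a replicate seed from a master seed
#'
#' Deterministic 31-bit mixing of the master seed, a scenario key and the
#' replicate index, so that adding methods or reordering scenarios never
#' perturbs the data streams of other replicates.
#'
#' @param master Master integer seed.
#' @param key Scenario key (integer, or a `sipod_scenario` which is
#'   hashed from its parameters).
#' @param k Replicate index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key, k) {
  if (inherits(key, "sipod_scenario"))
    key <- .hash31(c(key$n, key$p, key$O, if (is.null(key$L)) -1 else key$L,
                     key$mu * 1e4, key$sigma2 * 1e4, key$rho * 1e4,
                     key$r_decay * 1e4, key$shift * 1e4))
  M <- 2147483647
  h <- (as.numeric(master) %% M)
  h <- (h * 69069 + as.numeric(key) %% M + 1) %% M
  h <- (h * 69069 + as.numeric(k) + 1) %% M
  h <- (h * 69069 + 7) %% M
  as.integer(h %% (M - 2) + 1)
}

.hash31 <- function(v) {
  M <- 2147483647
  h <- 17
  for (x in v) h <- (h * 69069 + (abs(as.numeric(x)) %% M) + 1) %% M
  h
}
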