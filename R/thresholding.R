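# Threshold (shrinkage) rules and their induced penalties.
#
# A threshold rule Theta(.; lambda) is an odd, monotone, unbounded shrinkage
# operator on the real line. Each rule induces a minimum-curvature penalty
# P_Theta through the inverse-integral construction
#   Theta^{-1}(u; lambda) = sup{ t : Theta(t; lambda) <= u }
#   s(u; lambda)          = Theta^{-1}(u; lambda) - u
#   P_Theta(theta;lambda) = int_0^{|theta|} s(u; lambda) du
# Rules live in a small registry so further rules satisfying the axioms can
# be added without touching the solvers; the built-in soft and hard rules
# carry closed-form penalties and the registry falls back to numerical
# construction when none is supplied.

.threshold_registry <- new.env(parent = emptyenv())

.check_lambda <- function(lam) {
  if (!is.numeric(lam) || anyNA(lam) || any(lam < 0))
    stop("invalid parameter: `lam` must be nonnegative", call. = FALSE)
  invisible(lam)
}

#' Soft-thresholding rule
#'
#' Shrinks `x` toward zero by `lam`, mapping the whole dead zone
#' `|x| <= lam` (boundary included) to zero.
#'
#' @param x Numeric vector of values to shrink.
#' @param lam Nonnegative threshold(s), scalar or the length of `x`.
#' @return Numeric vector, `0` where `|x| <= lam`, else `x - sign(x) * lam`.
#' @seealso [theta_hard()], [threshold_rule()]
#' @examples
#' theta_soft(c(2, 0.5, -2), 1)
#' @export
theta_soft <- function(x, lam) {
  .check_lambda(lam)
  sign(x) * pmax(abs(x) - lam, 0)
}

#' Hard-thresholding rule
#'
#' Keeps `x` untouched outside the dead zone and zeroes it inside;
#' the boundary `|x| = lam` belongs to the zero branch.
#'
#' @inheritParams theta_soft
#' @return Numeric vector, `0` where `|x| <= lam`, else `x`.
#' @export
theta_hard <- function(x, lam) {
  .check_lambda(lam)
  x * (abs(x) > lam)
}

.penalty_soft <- function(theta, lam) lam * abs(theta)

.penalty_hard <- function(theta, lam) {
  a <- abs(theta)
  ifelse(a < lam, lam * a - a^2 / 2, lam^2 / 2)
}

#' Register a threshold rule
#'
#' Adds a shrinkage rule to the package registry. `theta` must satisfy the
#' four axioms (odd, monotone on the nonnegatives, `0 <= Theta(t) <= t`,
#' unbounded). When `penalty` is `NULL` the induced penalty is evaluated by
#' numerical quadrature of the inverse-integral construction, which is exact
#' but slower than a closed form.
#'
#' @param name Character name under which the rule is stored.
#' @param theta Function `(x, lam)`, vectorized in both arguments.
#' @param penalty Optional function `(theta, lam)` giving the induced
#'   penalty in closed form.
#' @return The registered `threshold_rule` object, invisibly.
#' @export
register_threshold_rule <- function(name, theta, penalty = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(theta))
  if (is.null(penalty)) {
    force(theta)
    penalty <- function(th, lam) .numeric_penalty(theta, th, lam)
  }
  rule <- structure(list(name = name, theta = theta, penalty = penalty),
                    class = "threshold_rule")
  assign(name, rule, envir = .threshold_registry)
  invisible(rule)
}

#' Look up a threshold rule
#'
#' @param rule A `threshold_rule` object or the name of a registered rule
#'   (`"soft"` and `"hard"` are built in).
#' @return A `threshold_rule` object with fields `name`, `theta`, `penalty`.
#' @export
threshold_rule <- function(rule) {
  if (inherits(rule, "threshold_rule")) return(rule)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (!exists(rule, envir = .threshold_registry, inherits = FALSE))
    stop(sprintf("unknown threshold rule '%s'; registered: %s", rule,
                 paste(ls(.threshold_registry), collapse = ", ")),
         call. = FALSE)
  get(rule, envir = .threshold_registry, inherits = FALSE)
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("Threshold rule '%s' (odd monotone unbounded shrinkage)\n",
              x$name))
  invisible(x)
}

#' Induced penalty of a threshold rule
#'
#' Evaluates the minimum-curvature penalty `P_Theta(theta; lam)` whose
#' penalized least-squares stationary condition reproduces the rule:
#' `lam * |theta|` for the soft rule and
#' `lam * |theta| - theta^2 / 2` (capped at `lam^2 / 2`) for the hard rule.
#'
#' @param theta Numeric vector of shift values.
#' @param lam Nonnegative threshold(s).
#' @param rule Rule name or `threshold_rule` object.
#' @return Nonnegative numeric vector of penalty values.
#' @examples
#' induced_penalty(2, 1, "soft")   # 2
#' induced_penalty(0.5, 1, "hard") # 0.375
#' @export
induced_penalty <- function(theta, lam, rule) {
  .check_lambda(lam)
  rule <- threshold_rule(rule)
  rule$penalty(theta, lam)
}

#' Apply a threshold rule coordinate-wise
#'
#' @param v Numeric vector.
#' @param lams Nonnegative thresholds, one per coordinate of `v`.
#' @param rule Rule name or `threshold_rule` object.
#' @return `Theta(v_i; lams_i)` coordinate-wise.
#' @export
apply_threshold <- function(v, lams, rule) {
  if (length(v) != length(lams))
    stop(sprintf("dimension error: length(v) = %d but length(lams) = %d",
                 length(v), length(lams)), call. = FALSE)
  .check_lambda(lams)
  if (length(v) == 0L) return(numeric(0))
  rule <- threshold_rule(rule)
  rule$theta(v, lams)
}

# --- numerical inverse-integral construction (fallback path) ---------------

# sup{ t : theta(t) <= u } by bisection; relies on monotonicity on [0, Inf).
.theta_inverse <- function(theta_fun, u, lam) {
  if (u < 0) stop("theta inverse defined for u >= 0")
  hi <- max(u + lam + 1, 1)
  while (theta_fun(hi, lam) <= u) hi <- hi * 2
  lo <- 0
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (theta_fun(mid, lam) <= u) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.numeric_penalty <- function(theta_fun, th, lam) {
  n <- max(length(th), length(lam))
  th <- rep_len(th, n); lam <- rep_len(lam, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- abs(th[i])
    if (a == 0) { out[i] <- 0; next }
    s <- Vectorize(function(u) .theta_inverse(theta_fun, u, lam[i]) - u)
    out[i] <- stats::integrate(s, 0, a, subdivisions = 400L,
                               rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  out
}

register_threshold_rule("soft", theta_soft, .penalty_soft)
register_threshold_rule("hard", theta_hard, .penalty_hard)
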