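# File I/O, run configuration, and the command surface (detect, simulate,
# benchmark) tying the estimators together. Numeric output uses %.17g so
# write-then-read round-trips are exact.

#' Run configuration
#'
#' Validated bundle of the tunable options of a detection run;
#' round-trips through a plain-text YAML file via [write_config()] /
#' [read_config()].
#'
#' @param rule Threshold rule, `"soft"` or `"hard"`.
#' @param psi_kind Influence function family for spatial-parameter
#'   estimation.
#' @param mu Optional known spatial parameter (`NULL` = estimate).
#' @param n_lambda Threshold-path length (>= 2).
#' @param tol Convergence tolerance.
#' @param max_iter Iteration cap.
#' @param max_support Optional contamination budget: the largest outlier
#'   set the selection may return (`NULL` = half the sample, the
#'   identifiability limit).
#' @param report_scale `"transformed"` or `"original"`.
#' @param seed Integer seed.
#' @param log_level `"debug"`, `"info"` or `"quiet"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(rule = "soft", psi_kind = "cauchy", mu = NULL,
                       n_lambda = 100L, tol = 1e-8, max_iter = 500L,
                       max_support = NULL, report_scale = "transformed",
                       seed = 1L, log_level = "info") {
  rule <- match.arg(rule, c("soft", "hard"))
  .psi_info(psi_kind)
  report_scale <- match.arg(report_scale, c("transformed", "original"))
  log_level <- match.arg(log_level, c("debug", "info", "quiet"))
  stopifnot(n_lambda >= 2, tol > 0, max_iter >= 1)
  if (!is.null(mu)) stopifnot(is.numeric(mu), length(mu) == 1L)
  if (!is.null(max_support))
    stopifnot(is.numeric(max_support), length(max_support) == 1L,
              max_support >= 0)
  structure(list(rule = rule, psi_kind = psi_kind, mu = mu,
                 n_lambda = as.integer(n_lambda), tol = tol,
                 max_iter = as.integer(max_iter),
                 max_support = if (is.null(max_support)) NULL
                               else as.integer(max_support),
                 report_scale = report_scale, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(run_config, v[!vapply(v, is.null, logical(1))])
}

.log <- function(config, level, fmt, ...) {
  ranks <- c(debug = 1, info = 2, quiet = 3)
  if (ranks[[level]] >= ranks[[config$log_level]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

# Reads a CSV of numbers; tolerates an optional header row; errors name
# the offending cells. Returns a matrix plus the NA-row indices.
.read_numeric_csv <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(raw) == 0) stop(sprintf("parse error: %s is empty", path),
                           call. = FALSE)
  first <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  has_header <- anyNA(first) && !any(toupper(unlist(raw[1, ])) %in%
                                       c("NA", "NAN", ""))
  if (has_header) raw <- raw[-1, , drop = FALSE]
  m <- matrix(NA_real_, nrow(raw), ncol(raw))
  na_rows <- integer(0)
  for (j in seq_len(ncol(raw))) {
    col <- raw[[j]]
    miss <- is.na(col) | toupper(col) %in% c("NA", "NAN", "")
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !miss)
    if (length(bad) > 0)
      stop(sprintf("parse error in %s: non-numeric cell at row %d, column %d ('%s')",
                   path, bad[1] + has_header, j, col[bad[1]]), call. = FALSE)
    v[miss] <- NA_real_
    m[, j] <- v
  }
  list(m = m, na_rows = which(apply(m, 1, anyNA)))
}

#' Read a regression dataset from CSV files
#'
#' Reads a numeric design matrix and single-column response. Rows with
#' any missing value (in either file) are rejected: they are dropped from
#' the returned problem, reported in a message, and listed in
#' `attr(, "dropped_rows")`.
#'
#' @param x_path CSV of the design matrix.
#' @param y_path CSV of the response (one column).
#' @return A [regression_problem()].
#' @export
read_dataset <- function(x_path, y_path) {
  xr <- .read_numeric_csv(x_path)
  yr <- .read_numeric_csv(y_path)
  if (ncol(yr$m) != 1L)
    stop(sprintf("parse error: %s must have a single column (found %d)",
                 y_path, ncol(yr$m)), call. = FALSE)
  if (nrow(xr$m) != nrow(yr$m))
    stop(sprintf("parse error: row count mismatch, %s has %d rows but %s has %d",
                 x_path, nrow(xr$m), y_path, nrow(yr$m)), call. = FALSE)
  drop_rows <- sort(union(xr$na_rows, yr$na_rows))
  if (length(drop_rows) > 0) {
    message(sprintf("rejected %d row(s) with missing values: %s",
                    length(drop_rows), paste(drop_rows, collapse = ", ")))
    keep <- setdiff(seq_len(nrow(xr$m)), drop_rows)
    xr$m <- xr$m[keep, , drop = FALSE]
    yr$m <- yr$m[keep, , drop = FALSE]
  }
  prob <- regression_problem(xr$m, drop(yr$m))
  attr(prob, "dropped_rows") <- drop_rows
  prob
}

.read_gal <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  # GeoDa convention: "0 n shapefile key" or plain "n"
  n <- as.integer(if (length(hdr) >= 2) hdr[2] else hdr[1])
  ids <- character(n); nbrs <- vector("list", n)
  i <- 2L
  for (u in seq_len(n)) {
    if (i > length(lines))
      stop(sprintf("format error in %s: truncated GAL record for unit %d",
                   path, u), call. = FALSE)
    rec <- strsplit(lines[i], "\\s+")[[1]]
    ids[u] <- rec[1]
    k <- as.integer(rec[2])
    nb <- if (k > 0) strsplit(lines[i + 1L], "\\s+")[[1]] else character(0)
    if (length(nb) != k)
      stop(sprintf("format error in %s: unit %s declares %d neighbors but lists %d",
                   path, ids[u], k, length(nb)), call. = FALSE)
    nbrs[[u]] <- nb
    i <- i + (if (k > 0) 2L else 1L)
  }
  idx <- stats::setNames(seq_len(n), ids)
  W <- matrix(0, n, n)
  for (u in seq_len(n)) for (v in nbrs[[u]]) {
    if (is.na(idx[v]))
      stop(sprintf("format error in %s: unknown neighbor ID '%s'", path, v),
           call. = FALSE)
    W[u, idx[[v]]] <- 1
  }
  if (!isTRUE(all.equal(W, t(W))))
    stop(sprintf("format error in %s: GAL adjacency is not symmetric", path),
         call. = FALSE)
  list(W = W, ids = ids)
}

.read_gwt <- function(path, gwt_values) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  n <- as.integer(if (length(hdr) >= 2) hdr[2] else hdr[1])
  recs <- strsplit(lines[-1], "\\s+")
  ids <- unique(unlist(lapply(recs, function(r) r[1:2])))
  if (length(ids) > n)
    stop(sprintf("format error in %s: %d distinct IDs but header declares n = %d",
                 path, length(ids), n), call. = FALSE)
  # honor the 1-based numeric ID convention when present
  num_ids <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num_ids)) {
    if (any(num_ids < 1 | num_ids > n))
      stop(sprintf("format error in %s: unknown ID %s (declared n = %d)",
                   path, ids[which(num_ids < 1 | num_ids > n)[1]], n),
           call. = FALSE)
    ids <- as.character(seq_len(n))
  } else if (length(ids) < n) {
    ids <- as.character(seq_len(n))
  }
  idx <- stats::setNames(seq_len(n), ids)
  W <- matrix(0, n, n)
  for (r in recs) {
    i <- idx[r[1]]; j <- idx[r[2]]
    if (anyNA(c(i, j)))
      stop(sprintf("format error in %s: unknown ID in triple '%s'",
                   path, paste(r, collapse = " ")), call. = FALSE)
    v <- as.numeric(r[3])
    W[i, j] <- if (gwt_values == "distance") 1 / v else v
  }
  list(W = W, ids = ids)
}

#' Read a spatial weight matrix
#'
#' Supports a header-free dense CSV, the GeoDa GAL contiguity dialect
#' (header line, then per-unit neighbor lists; produces symmetric binary
#' weights) and the GeoDa GWT dialect (header line, then directed
#' `(i, j, value)` triples; the reverse entry is only set if listed).
#' IDs are mapped to matrix rows and the mapping is attached as
#' `attr(, "id_map")`.
#'
#' @param path File path.
#' @param format `"csv"`, `"gal"` or `"gwt"`.
#' @param row_standardize Row-standardize after reading.
#' @param gwt_values `"weight"` (use the third column as the weight,
#'   default) or `"distance"` (store the reciprocal, inverse-distance
#'   weights).
#' @return A `spatial_weights` object with `source = "file"`.
#' @export
read_weights <- function(path, format = c("csv", "gal", "gwt"),
                         row_standardize = TRUE,
                         gwt_values = c("weight", "distance")) {
  format <- match.arg(format)
  gwt_values <- match.arg(gwt_values)
  parsed <- switch(format,
    csv = {
      m <- .read_numeric_csv(path)$m
      list(W = m, ids = as.character(seq_len(nrow(m))))
    },
    gal = .read_gal(path),
    gwt = .read_gwt(path, gwt_values))
  w <- if (row_standardize) row_standardize(parsed$W, source = "file")
       else spatial_weights(parsed$W, row_standardized = FALSE,
                            source = "file")
  attr(w, "id_map") <- data.frame(id = parsed$ids,
                                  row = seq_along(parsed$ids),
                                  stringsAsFactors = FALSE)
  w
}

.fmt <- function(x) formatC(x, format = "g", digits = 17)

.write_matrix_csv <- function(m, path, col_names = NULL) {
  m <- as.matrix(m)
  txt <- apply(m, 1, function(r) paste(.fmt(r), collapse = ","))
  if (!is.null(col_names)) txt <- c(paste(col_names, collapse = ","), txt)
  writeLines(txt, path)
  invisible(path)
}

#' Run outlier detection on files and write a report
#'
#' Reads the dataset and weights, runs [spatial_ipod()] with the supplied
#' configuration, and writes `observations.csv` (per-observation shifts on
#' both scales, leverage, flag) and `summary.json` (spatial parameter,
#' coefficients, scale, selected lambda, BIC* path, configuration echo)
#' into `out_dir`. Finding no outliers is a success, reported as
#' `status = "ok"` with an empty flag set.
#'
#' @param x_path,y_path Dataset CSV paths (see [read_dataset()]).
#' @param w_path Weights file path.
#' @param out_dir Output directory (created if missing).
#' @param w_format Weights file format, see [read_weights()].
#' @param config A [run_config()].
#' @return Invisibly, `list(status, n_outliers, fit, files)`.
#' @export
detect_cmd <- function(x_path, y_path, w_path, out_dir, w_format = "csv",
                       config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prob <- read_dataset(x_path, y_path)
  w <- read_weights(w_path, format = w_format)
  if (length(attr(prob, "dropped_rows")) > 0)
    stop("rows with missing values were dropped from the dataset; ",
         "supply a weight matrix matching the retained rows", call. = FALSE)
  .log(config, "info", "detect: n = %d, p = %d, rule = %s", prob$n, prob$p,
       config$rule)
  fit <- spatial_ipod(prob$X, prob$y, w, rule = config$rule,
                      mu = config$mu, psi_kind = config$psi_kind,
                      n_lambda = config$n_lambda, tol = config$tol,
                      max_iter = config$max_iter,
                      max_support = config$max_support,
                      report_scale = config$report_scale)
  .log(config, "debug", "lambda path: %s",
       paste(signif(fit$ipod$lambda_path, 4), collapse = " "))
  obs <- cbind(index = seq_len(prob$n), y = prob$y,
               gamma_tilde = fit$gamma_tilde, gamma_back = fit$gamma_back,
               leverage = fit$leverage,
               flagged = as.integer(seq_len(prob$n) %in% fit$outlier_idx))
  obs_path <- file.path(out_dir, "observations.csv")
  .write_matrix_csv(obs, obs_path, colnames(obs))
  summ <- list(
    mu_hat = fit$sem$mu_hat,
    mu_method = fit$sem$method,
    psi_kind = fit$sem$psi_kind,
    beta_hat = as.numeric(fit$beta_hat),
    sigma_hat = fit$sem$sigma_hat,
    rule = fit$rule,
    lambda = fit$ipod$lam,
    n_outliers = length(fit$outlier_idx),
    outlier_idx = as.integer(fit$outlier_idx),
    bic_star = fit$ipod$bic_star,
    lambda_path = as.numeric(fit$ipod$lambda_path),
    bic_path = as.numeric(fit$ipod$bic_path),
    config = unclass(config))
  sum_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, sum_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  .log(config, "info", "detect: flagged %d outlier(s)",
       length(fit$outlier_idx))
  invisible(list(status = "ok", n_outliers = length(fit$outlier_idx),
                 fit = fit, files = c(obs_path, sum_path)))
}

#' Write one simulated scenario to CSV files
#'
#' Emits `X.csv`, `y.csv`, `W.csv` and `truth.csv` for a scenario, in the
#' formats [read_dataset()] and [read_weights()] accept.
#'
#' @param sc A [scenario()].
#' @param out_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
simulate_cmd <- function(sc, out_dir) {
  stopifnot(inherits(sc, "sipod_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- make_dataset(sc)
  paths <- file.path(out_dir, c("X.csv", "y.csv", "W.csv", "truth.csv"))
  .write_matrix_csv(d$X, paths[1])
  .write_matrix_csv(matrix(d$y, ncol = 1), paths[2])
  .write_matrix_csv(d$w$W, paths[3])
  writeLines(as.character(d$truth), paths[4])
  invisible(paths)
}

#' Run the benchmark and write results
#'
#' Wraps [run_benchmark()]; writes `results.csv` (one row per
#' scenario x method) and `audit.json` (replicate-level detections and
#' coefficient errors).
#'
#' @inheritParams run_benchmark
#' @param out_dir Output directory.
#' @return Invisibly, the benchmark table.
#' @export
benchmark_cmd <- function(grid, methods, n_reps, seed, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_benchmark(grid, methods, n_reps = n_reps, seed = seed, ...)
  utils::write.csv(as.data.frame(res), file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  audit <- lapply(attr(res, "outcomes"), function(oc)
    lapply(oc, function(o) list(detected = o$detected, truth = o$truth,
                                beta_err = o$beta_hat - o$beta_true)))
  jsonlite::write_json(list(mse_convention = attr(res, "mse_convention"),
                            outcomes = audit),
                       file.path(out_dir, "audit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
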