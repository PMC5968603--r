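#' Generalized-regression (GREG) calibration of survey weights
#'
#' Adjusts survey design weights so that weighted cell totals hit
#' external benchmark totals while minimally perturbing the design
#' weights, in the GREGWT family of calibration estimators: the new
#' weights minimise the chi-square distance `sum((w - d)^2 / d)` subject
#' to the benchmark constraints, solved through the linear-calibration
#' system `w = d * (1 + X lambda)` with
#' `lambda = (X' D X)^+ (T - X' d)`. Weights breaching the
#' multiplicative bounds are clamped to the bound and the remaining
#' records re-solved for the residual targets until no new clamps appear
#' or `max_iter` passes are used.
#'
#' Constraint matrices from overlapping benchmark variables (e.g. two
#' full partitions of the same population) are rank-deficient but
#' consistent; the pseudoinverse solution calibrates them exactly.
#'
#' @param data Person tibble containing every variable referenced by
#'   the benchmark constraints.
#' @param benchmarks A [generate_benchmarks()] result, or any tibble
#'   with columns `variable`, `level`, `target` (composite variables are
#'   written `"age_group:sex"` with levels `"45-49:female"`).
#' @param year Projection year to calibrate to (filters the benchmark
#'   rows when a `year` column is present).
#' @param weight_col Name of the design-weight column.
#' @param bounds Multiplicative weight bounds relative to the design
#'   weight, default `c(0.1, 10)`. Use `c(0, Inf)` for unbounded
#'   calibration.
#' @param tol Relative tolerance on achieved constraint totals.
#' @param max_iter Maximum clamp-and-resolve passes.
#' @return An object of class `plycost_calibration`: a list with
#'   `weights`, `lambda`, `iterations`, `max_constraint_gap`,
#'   `bounded_count`, `converged` and the constraint table with achieved
#'   totals. Use [tidy()] / [glance()] to inspect it.
#' @export
calibrate_weights <- function(data, benchmarks, year = NULL,
                              weight_col = "survey_weight",
                              bounds = c(0.1, 10), tol = 1e-6,
                              max_iter = 50L) {
  cons <- tibble::as_tibble(benchmarks)
  if (!is.null(year) && "year" %in% names(cons)) {
    cons <- dplyr::filter(cons, .data$year == !!as.integer(year))
  }
  if (nrow(cons) == 0) stop("no benchmark constraints for year ", year)
  if (any(cons$target < 0)) stop("benchmark targets must be non-negative")
  d <- data[[weight_col]]
  if (any(d <= 0)) stop("design weights must be strictly positive")
  X <- constraint_matrix(data, cons)
  fit <- greg_fit(d, X, cons$target, bounds = bounds, tol = tol,
                  max_iter = max_iter)
  achieved <- as.numeric(crossprod(X, fit$weights))
  structure(list(
    weights = fit$weights, lambda = fit$lambda,
    iterations = fit$iterations, max_constraint_gap = fit$gap,
    bounded_count = fit$bounded_count, converged = fit$gap <= tol,
    constraints = dplyr::mutate(cons, achieved = achieved,
                                rel_gap = abs(achieved - .data$target) /
                                  pmax(1, abs(.data$target))),
    tol = tol, bounds = bounds
  ), class = "plycost_calibration")
}

# Indicator matrix: one column per constraint row, 1 where the record
# falls in the constraint cell.
constraint_matrix <- function(data, cons) {
  vals <- list()
  X <- matrix(0, nrow(data), nrow(cons))
  for (v in unique(cons$variable)) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    missing_vars <- setdiff(parts, names(data))
    if (length(missing_vars))
      stop("constraint references absent variable(s): ",
           paste(missing_vars, collapse = ", "))
    vals[[v]] <- do.call(paste, c(lapply(parts, function(p) {
      as.character(data[[p]])
    }), sep = ":"))
  }
  for (j in seq_len(nrow(cons))) {
    X[, j] <- as.numeric(vals[[cons$variable[j]]] == cons$level[j])
  }
  X
}

# Core chi-square calibration with multiplicative truncation.
greg_fit <- function(d, X, targets, bounds = c(0, Inf), tol = 1e-6,
                     max_iter = 50L) {
  n <- length(d)
  stopifnot(nrow(X) == n, length(targets) == ncol(X))
  lo <- bounds[1] * d
  hi <- bounds[2] * d
  capacity <- if (is.finite(bounds[2])) as.numeric(crossprod(X, hi)) else Inf
  floor_tot <- as.numeric(crossprod(X, lo))
  if (any(targets > capacity * (1 + 1e-12)) ||
      any(targets < floor_tot * (1 - 1e-12)))
    stop("infeasible constraints: target outside the weight-bound capacity")

  w <- d
  free <- rep(TRUE, n)
  lambda <- rep(0, ncol(X))
  gap_of <- function(w) {
    ach <- as.numeric(crossprod(X, w))
    max(abs(ach - targets) / pmax(1, abs(targets)))
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Xf <- X[free, , drop = FALSE]
    df <- d[free]
    resid_targets <- targets - as.numeric(crossprod(X[!free, , drop = FALSE],
                                                    w[!free]))
    A <- crossprod(Xf, Xf * df)
    b <- resid_targets - as.numeric(crossprod(Xf, df))
    lambda <- drop(MASS::ginv(A) %*% b)
    w[free] <- df * (1 + drop(Xf %*% lambda))
    clamped <- free & (w < lo | w > hi)
    w <- pmin(pmax(w, lo), hi)
    if (!any(clamped) || iter >= max_iter) break
    free <- free & !clamped
    if (!any(free)) break
  }
  gap <- gap_of(w)
  if (gap > tol)
    stop("calibration did not converge within ", max_iter,
         " passes; best relative gap ", signif(gap, 4))
  list(weights = w, lambda = lambda, iterations = iter, gap = gap,
       bounded_count = sum(w <= lo * (1 + 1e-12) | w >= hi * (1 - 1e-12)))
}

#' @export
print.plycost_calibration <- function(x, ...) {
  cat("<plycost_calibration>\n")
  cat("  records:", length(x$weights),
      " constraints:", nrow(x$constraints), "\n")
  cat("  passes:", x$iterations,
      " max relative gap:", format(x$max_constraint_gap, digits = 3),
      " bounded weights:", x$bounded_count, "\n")
  invisible(x)
}

#' Tidy a calibration result
#'
#' @param x A [calibrate_weights()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per constraint (variable, level, target,
#'   achieved total, relative gap). `glance()`: a one-row summary.
#' @export
tidy.plycost_calibration <- function(x, ...) {
  x$constraints
}

#' @rdname tidy.plycost_calibration
#' @export
glance.plycost_calibration <- function(x, ...) {
  tibble::tibble(
    n = length(x$weights), n_constraints = nrow(x$constraints),
    iterations = x$iterations, max_constraint_gap = x$max_constraint_gap,
    bounded_count = x$bounded_count, converged = x$converged
  )
}
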