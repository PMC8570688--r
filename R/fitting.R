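#' Reduced chi-square between a simulated and a target modulation curve
#'
#' `X2_r = (1/F) sum_f (sim_f - target_f)^2 / sd_f^2` over the common grid
#' (frequencies or time points).
#'
#' @param sim_curve simulated modulation values.
#' @param target_median target (experimental or surrogate) median modulation.
#' @param target_sd per-point standard deviation of the target; must be
#'   positive everywhere.
#' @return the reduced chi-square (dimensionless scalar).
#' @export
#' @examples
#' reduced_chi2(c(1, 2, 0), c(0, 0, 0), c(1, 1, 1))  # 5/3
reduced_chi2 <- function(sim_curve, target_median, target_sd) {
  if (length(sim_curve) != length(target_median) ||
      length(sim_curve) != length(target_sd))
    stop("curves must share a common grid", call. = FALSE)
  if (any(target_sd <= 0))
    stop("degenerate target: zero variance at some grid point", call. = FALSE)
  mean(((sim_curve - target_median) / target_sd)^2)
}

#' Grid specification for the thalamic-input searches
#'
#' Default exhaustive grids: `A` and `A0` from 0 to 100 sp/s in steps of 10;
#' `S` and `S0` from 500 to 1000 sp/s in steps of 100; `beta` from 0 to
#' 400 sp/s in eight uniform steps; `alpha` from 0 to `A0` in steps of 10
#' (handled by the paired-grid constraint in [grid_search]).
#'
#' @param parameter one of "A", "S", "A0", "alpha", "S0", "beta".
#' @param values optional explicit grid values (sp/s).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(parameter = c("A", "S", "A0", "alpha", "S0", "beta"),
                      values = NULL) {
  parameter <- match.arg(parameter)
  if (is.null(values)) {
    values <- switch(parameter,
                     A = seq(0, 100, by = 10),
                     A0 = seq(0, 100, by = 10),
                     alpha = seq(0, 100, by = 10),
                     S = seq(500, 1000, by = 100),
                     S0 = seq(500, 1000, by = 100),
                     beta = seq(0, 400, length.out = 9))
  }
  if (length(values) == 0) stop("empty grid", call. = FALSE)
  structure(list(parameter = parameter, values = sort(values)),
            class = "grid_spec")
}

#' Exhaustive grid search
#'
#' Evaluates `objective` at every admissible grid point and returns the
#' minimizer.  With one `grid_spec` the objective receives a single named
#' value; with two it receives both (all combinations, subject to
#' `constraint`, e.g. `alpha <= A0` for the paired time-dependent grids).
#' Ties are broken deterministically towards the smallest parameter values.
#' Non-finite objective values are excluded and flagged.
#'
#' @param objective function taking named parameter arguments and returning
#'   a scalar (e.g. a reduced chi-square).
#' @param grid a `grid_spec` or a list of two `grid_spec`s.
#' @param constraint optional function of the named parameters returning
#'   TRUE for admissible combinations.
#' @return object of class `fit_result`: list with `best` (named vector),
#'   `objective` (minimum value), `surface` (data.frame of all evaluated
#'   points), `n_excluded`.
#' @export
#' @examples
#' fit <- grid_search(function(A) (A - 30)^2, grid_spec("A"))
#' fit$best  # A = 30
grid_search <- function(objective, grid, constraint = NULL) {
  grids <- if (inherits(grid, "grid_spec")) list(grid) else grid
  stopifnot(all(vapply(grids, inherits, TRUE, "grid_spec")))
  pts <- expand.grid(lapply(grids, `[[`, "values"))
  names(pts) <- vapply(grids, `[[`, "", "parameter")
  if (!is.null(constraint)) {
    keep <- vapply(seq_len(nrow(pts)), function(i)
      isTRUE(do.call(constraint, as.list(pts[i, , drop = FALSE]))), TRUE)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) == 0) stop("empty admissible grid", call. = FALSE)
  # deterministic tie-break: order by parameter values, pick the first minimum
  pts <- pts[do.call(order, as.list(pts)), , drop = FALSE]
  vals <- vapply(seq_len(nrow(pts)), function(i)
    do.call(objective, as.list(pts[i, , drop = FALSE])), 0)
  finite <- is.finite(vals)
  if (!any(finite))
    stop("objective non-finite on the whole grid", call. = FALSE)
  if (!all(finite))
    warning(sprintf("%d grid points excluded (non-finite objective)",
                    sum(!finite)))
  sub <- which(finite)
  best_i <- sub[which.min(vals[sub])]
  surface <- cbind(pts, objective = vals)
  rownames(surface) <- NULL
  structure(list(best = unlist(pts[best_i, , drop = FALSE]),
                 objective = vals[best_i], surface = surface,
                 n_excluded = sum(!finite)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("grid-search minimum:",
      paste(names(x$best), signif(x$best, 6), sep = " = ", collapse = ", "),
      sprintf("(objective %.4g)\n", x$objective))
  invisible(x)
}

#' Piecewise-linear thalamic input functions of contrast
#'
#' The fitted contrast dependence of the two input components:
#' `A(K) = (42.8 - 1.4 K) u(K) u(30 - K)` (periodic amplitude, zero for
#' K > 30) and `S(K) = (384.8 + 3.8 K) u(K - 30)` (sustained rate) with the
#' Heaviside convention `u(x) = 1` for `x >= 0`.  The sustained component is
#' floored at 500 sp/s, the model's baseline value for all K < 30 (this
#' reconciles the formula, which would otherwise be zero below K = 30, with
#' the stated baseline).
#'
#' @param K contrast level(s) in percent, within `[0, 100]`.
#' @return data.frame with columns `K`, `A`, `S` (sp/s).
#' @export
#' @examples
#' piecewise_linear_input_functions(c(0, 40, 90))
piecewise_linear_input_functions <- function(K) {
  if (any(K < 0 | K > 100))
    stop("contrast K must lie in [0, 100]", call. = FALSE)
  u <- function(x) as.numeric(x >= 0)
  A <- (42.8 - 1.4 * K) * u(K) * u(30 - K)
  S <- pmax((384.8 + 3.8 * K) * u(K - 30), 500)
  data.frame(K = K, A = A, S = S)
}

#' Refit the piecewise-linear coefficients from tabulated optima
#'
#' Utility for re-deriving the `A(K)` and `S(K)` line coefficients by least
#' squares from a table of per-contrast optimal values (e.g. the shipped
#' parameter table or a user's own fits).  The shipped closed forms in
#' [piecewise_linear_input_functions] are the published coefficients; this
#' helper exposes the fit so users can check or update them against their
#' own data.
#'
#' @param table data.frame with columns `K`, `A`, `S`.
#' @param k_split boundary contrast (default 30).
#' @return list with `A_coef` (intercept, slope over K <= k_split) and
#'   `S_coef` (intercept, slope over K >= k_split).
#' @export
refit_input_functions <- function(table = thalamic_table(), k_split = 30) {
  lowk <- table$K <= k_split
  highk <- table$K >= k_split
  a_fit <- lm(A ~ K, data = table[lowk, ])
  s_fit <- lm(S ~ K, data = table[highk, ])
  list(A_coef = unname(coef(a_fit)), S_coef = unname(coef(s_fit)))
}
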