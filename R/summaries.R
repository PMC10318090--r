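#' Windowed time averages of a trajectory
#'
#' Trapezoid-rule time average of each state variable over `[t0, t1]`. With
#' `window = c(0, t_end)` this is the running-time-average operator
#' `<f(t)> = t^{-1} integral_0^t f(s) ds` that the persistence notions are
#' stated in; a window collapsing to a point returns the point value.
#'
#' @param traj A trajectory tibble with a `t` column (e.g. from
#'   [simulate_path()]).
#' @param window Length-2 numeric `c(t0, t1)` inside the trajectory span.
#' @param vars Columns to average (default: all numeric columns but `t`).
#'
#' @return A tibble with columns `variable`, `c_avg`.
#' @examples
#' fx <- fixture("set40-fig1b")
#' traj <- simulate_path(fx$model, sim_config(10, 0.01, seed = 1),
#'                       fx$x0, fx$tox0)
#' time_average(traj, c(5, 10))
#' @export
time_average <- function(traj, window, vars = NULL) {
  if (!is.data.frame(traj) || !"t" %in% names(traj)) {
    stop("`traj` must be a data frame with a `t` column.", call. = FALSE)
  }
  if (length(window) != 2L || window[1] > window[2]) {
    stop("`window` must be c(t0, t1) with t0 <= t1.", call. = FALSE)
  }
  tol <- 1e-9 * max(1, abs(window))
  if (window[1] < min(traj$t) - tol || window[2] > max(traj$t) + tol) {
    stop("`window` must lie within the trajectory span.", call. = FALSE)
  }
  if (is.null(vars)) {
    vars <- setdiff(names(traj)[vapply(traj, is.numeric, TRUE)], "t")
  }
  keep <- traj$t >= window[1] - tol & traj$t <= window[2] + tol
  tt <- traj$t[keep]
  if (length(tt) == 1L) {
    return(tibble::tibble(
      variable = vars,
      c_avg = vapply(vars, function(v) traj[[v]][keep], numeric(1),
                     USE.NAMES = FALSE)))
  }
  dt <- diff(tt)
  span <- tt[length(tt)] - tt[1L]
  avg1 <- function(v) {
    y <- traj[[v]][keep]
    sum(dt * (y[-1L] + y[-length(y)]) / 2) / span
  }
  tibble::tibble(variable = vars,
                 c_avg = vapply(vars, avg1, numeric(1), USE.NAMES = FALSE))
}

#' Finite-horizon extinction surrogate
#'
#' Flags a trajectory as (numerically) extinct when the chosen density
#' stays below `threshold` at every recorded time in the final `dwell`
#' span. This is the finite-horizon stand-in for the asymptotic notion
#' "density tends to zero"; it is monotone in `threshold`.
#'
#' @inheritParams time_average
#' @param threshold Density threshold (should exceed the simulator floor).
#' @param dwell Length of the final time span that must stay
#'   sub-threshold; must not exceed the trajectory span.
#' @param var `"total"` (default, `x1 + x2`), `"x1"` or `"x2"`.
#' @return `TRUE` or `FALSE`.
#' @export
extinction_flag <- function(traj, threshold = 0.01, dwell = NULL,
                            var = c("total", "x1", "x2")) {
  var <- match.arg(var)
  if (!is.data.frame(traj) || !all(c("t", "x1", "x2") %in% names(traj))) {
    stop("`traj` must have columns t, x1, x2.", call. = FALSE)
  }
  span <- max(traj$t) - min(traj$t)
  if (is.null(dwell)) dwell <- 0.2 * span
  if (dwell > span + 1e-9) {
    stop("`dwell` exceeds the trajectory span.", call. = FALSE)
  }
  y <- switch(var, total = traj$x1 + traj$x2, x1 = traj$x1, x2 = traj$x2)
  keep <- traj$t >= max(traj$t) - dwell - 1e-9
  all(y[keep] < threshold)
}

#' Empirical p-moment of the total population across an ensemble
#'
#' Mean over paths of `(x1(t) + x2(t))^p` with a standard-error estimate,
#' for comparison against the analytic bound [pmoment_bound()].
#'
#' @param ensemble A `tox_ensemble` from [simulate_ensemble()] (with
#'   `keep_paths = TRUE` for interior times).
#' @param p Moment exponent, `> 1`.
#' @param t Time at which to evaluate (nearest recorded point is used);
#'   defaults to the horizon.
#' @return A list with `p`, `t`, `value`, `se`.
#' @export
empirical_pmoment <- function(ensemble, p, t = NULL) {
  stopifnot(inherits(ensemble, "tox_ensemble"))
  stop_if_not_scalar(p = p)
  if (p <= 1) stop("`p` must be greater than 1.", call. = FALSE)
  if (is.null(t)) t <- ensemble$config$t_end
  if (t < min(ensemble$summary$t) - 1e-9 ||
      t > max(ensemble$summary$t) + 1e-9) {
    stop("`t` must lie within the recorded span.", call. = FALSE)
  }
  if (is.null(ensemble$x1)) {
    stop("ensemble was built with `keep_paths = FALSE`.", call. = FALSE)
  }
  j <- which.min(abs(ensemble$summary$t - t))
  tot <- ensemble$x1[, j] + ensemble$x2[, j]
  v <- tot^p
  list(p = p, t = ensemble$summary$t[j], value = mean(v),
       se = stats::sd(v) / sqrt(length(v)))
}
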