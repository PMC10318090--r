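#' Simulation configuration
#'
#' Settings for the positivity-preserving truncated Euler-Maruyama
#' integrator. The step must subdivide the pulse period exactly
#' (`gamma / dt` integer to within `1e-9`) so that impulse times fall on the
#' grid; the toxicant forcing itself is advanced by its exact closed form,
#' so only the population states carry discretization error.
#'
#' @param t_end Time horizon (positive).
#' @param dt Step size (positive, `<= t_end`).
#' @param n_paths Ensemble size (positive integer).
#' @param seed Base RNG seed; path `i` of an ensemble uses `seed + i`.
#' @param scheme `"ppt-em"` (Euler-Maruyama with a positivity floor,
#'   default) or `"log-em"` (Euler-Maruyama on log densities, exactly
#'   positive).
#' @param floor Positivity floor for `"ppt-em"` (small positive density).
#' @param record_stride Keep every `record_stride`-th grid point in
#'   trajectory and ensemble output (the integration always uses `dt`).
#'
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(t_end = 300, dt = 0.005, n_paths = 200, seed = 42)
#' @export
sim_config <- function(t_end, dt, n_paths = 1L, seed = 1L,
                       scheme = c("ppt-em", "log-em"),
                       floor = 1e-10, record_stride = 1L) {
  scheme <- match.arg(scheme)
  stop_if_not_scalar(t_end = t_end, dt = dt, n_paths = n_paths,
                     seed = seed, floor = floor,
                     record_stride = record_stride)
  if (dt <= 0) stop("`dt` must be positive.", call. = FALSE)
  if (t_end < dt) stop("`t_end` must be at least `dt`.", call. = FALSE)
  if (n_paths < 1) stop("`n_paths` must be at least 1.", call. = FALSE)
  if (floor <= 0) stop("`floor` must be positive.", call. = FALSE)
  if (record_stride < 1) stop("`record_stride` must be >= 1.", call. = FALSE)
  structure(list(t_end = t_end, dt = dt, n_paths = as.integer(n_paths),
                 seed = as.integer(seed), scheme = scheme, floor = floor,
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}

check_alignment <- function(model, config) {
  ratio <- model$toxicant$gamma / config$dt
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(sprintf(
      "`gamma` (%g) must be an integer multiple of `dt` (%g) so impulses fall on the grid.",
      model$toxicant$gamma, config$dt), call. = FALSE)
  }
  invisible(NULL)
}

# precompute coefficient vectors on the step grid (left endpoints) plus the
# exact toxicant states on the full grid. Drift at a pulse instant uses the
# post-pulse environmental concentration; recorded trajectories report the
# pre-pulse value.
sim_coefficients <- function(model, config) {
  dt <- config$dt
  n_steps <- round(config$t_end / dt)
  t_grid <- seq(0, by = dt, length.out = n_steps + 1L)
  tox <- solve_toxicant(model$toxicant, t_grid,
                        c_o0 = attr(config, "c_o0") %||% 0,
                        c_e0 = attr(config, "c_e0") %||% 0)
  # post-pulse c_e for the drift on [n*gamma, n*gamma + dt)
  gam <- model$toxicant$gamma
  steps_per_period <- round(gam / dt)
  ce_drift <- tox$c_e
  if (steps_per_period <= n_steps) {
    pulse_idx <- seq(steps_per_period, n_steps, by = steps_per_period) + 1L
    ce_drift[pulse_idx] <- ce_drift[pulse_idx] + model$toxicant$b
  }
  tl <- t_grid[seq_len(n_steps)]
  list(t_grid = t_grid, n_steps = n_steps, tox = tox,
       r1 = mean_growth(model$patch1, tl) - model$delta * tox$c_o[seq_len(n_steps)],
       r2 = mean_growth(model$patch2, tl),
       d12t = migration_rate(model$migration, ce_drift[seq_len(n_steps)]),
       s1 = sigma_t(model$patch1, tl),
       s2 = sigma_t(model$patch2, tl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one trajectory of the two-patch population SDE
#'
#' Advances the population densities by Euler-Maruyama (scheme per
#' [sim_config()]) with the toxicant forcing evaluated by its exact
#' closed-form solution on the same grid. Gaussian increments are drawn
#' independently per step and patch from the configured seed, so equal
#' seed and configuration reproduce the trajectory bit for bit.
#'
#' @param model A [model_params()] object.
#' @param config A [sim_config()] object.
#' @param x0 Initial densities `c(x1, x2)`, strictly positive.
#' @param tox0 Initial toxicant state `c(c_o, c_e)`.
#' @param increments Optional list with matrices/vectors `z1`, `z2` of
#'   standard normal increments (length `t_end/dt`); used instead of
#'   drawing from the seed, e.g. to drive several resolutions with one
#'   Brownian path.
#'
#' @return A `tox_trajectory`: a tibble with columns `t`, `x1`, `x2`,
#'   `c_o`, `c_e` (thinned by `record_stride`), with the seed, scheme and
#'   config stored as attributes.
#' @examples
#' fx <- fixture("set40-fig1b")
#' cfg <- sim_config(t_end = 20, dt = 0.01, seed = 7)
#' sim <- simulate_path(fx$model, cfg, fx$x0, fx$tox0)
#' head(sim)
#' @export
simulate_path <- function(model, config, x0 = c(0.8, 0.5),
                          tox0 = c(0.2, 0.6), increments = NULL) {
  stopifnot(inherits(model, "model_params"), inherits(config, "sim_config"))
  if (length(x0) != 2L || any(x0 <= 0)) {
    stop("`x0` must be two strictly positive densities.", call. = FALSE)
  }
  if (length(tox0) != 2L || any(tox0 < 0)) {
    stop("`tox0` must be two nonnegative concentrations.", call. = FALSE)
  }
  check_alignment(model, config)
  attr(config, "c_o0") <- tox0[1L]
  attr(config, "c_e0") <- tox0[2L]
  cf <- sim_coefficients(model, config)
  if (is.null(increments)) {
    set.seed(config$seed)
    z1 <- stats::rnorm(cf$n_steps)
    z2 <- stats::rnorm(cf$n_steps)
  } else {
    z1 <- increments$z1
    z2 <- increments$z2
  }
  xs <- em_path_core(x0[1L], x0[2L], cf$r1, cf$r2, cf$d12t,
                     model$migration$d21, model$patch1$a, model$patch2$a,
                     cf$s1, cf$s2, z1, z2, config$dt, config$floor,
                     if (config$scheme == "log-em") 1L else 0L, 1e6)
  keep <- seq(1L, cf$n_steps + 1L, by = config$record_stride)
  out <- tibble::tibble(t = cf$t_grid[keep],
                        x1 = xs[keep, 1L], x2 = xs[keep, 2L],
                        c_o = cf$tox$c_o[keep], c_e = cf$tox$c_e[keep])
  attr(out, "seed") <- config$seed
  attr(out, "scheme") <- config$scheme
  attr(out, "config") <- config
  class(out) <- c("tox_trajectory", class(out))
  out
}

#' Simulate an ensemble and summarize it
#'
#' Runs `n_paths` independent trajectories (path `i` seeded with
#' `seed + i`) and reduces them on the fly to pointwise statistics and
#' per-path summaries, so memory stays flat in the number of steps.
#'
#' @inheritParams simulate_path
#' @param window Time window (length 2) over which per-path time averages
#'   are taken; defaults to the second half of the horizon.
#' @param ext_threshold,ext_dwell Extinction surrogate: a path is flagged
#'   extinct when the density stays below `ext_threshold` over the final
#'   `ext_dwell` time units (defaults: 0.01 and `0.2 * t_end`).
#' @param p Exponent for the recorded empirical moment of `x1 + x2` at the
#'   horizon.
#' @param keep_paths Keep the thinned per-path state matrices (needed by
#'   [empirical_pmoment()] at interior times); default `TRUE`.
#'
#' @return A `tox_ensemble` object: list with `summary` (tibble of
#'   pointwise mean/median/5-95% quantiles of `x1`, `x2` on the thinned
#'   grid), `paths` (one-row-per-path tibble of time averages, final
#'   states and extinction flags), `pmoment` (list `p`, `value`, `se` at
#'   `t_end`), plus `window`, `config`, `model`.
#' @examples
#' fx <- fixture("set40-fig1b")
#' cfg <- sim_config(t_end = 30, dt = 0.01, n_paths = 20, seed = 1,
#'                   record_stride = 20)
#' ens <- simulate_ensemble(fx$model, cfg, fx$x0, fx$tox0)
#' ens$paths
#' @export
simulate_ensemble <- function(model, config, x0 = c(0.8, 0.5),
                              tox0 = c(0.2, 0.6), window = NULL,
                              ext_threshold = 0.01, ext_dwell = NULL,
                              p = 2, keep_paths = TRUE) {
  stopifnot(inherits(model, "model_params"), inherits(config, "sim_config"))
  check_alignment(model, config)
  if (is.null(window)) window <- c(config$t_end / 2, config$t_end)
  if (is.null(ext_dwell)) ext_dwell <- 0.2 * config$t_end

  n <- config$n_paths
  first <- NULL
  x1m <- x2m <- NULL
  paths <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    traj <- tryCatch(
      simulate_path(model, cfg_i, x0, tox0),
      error = function(e) {
        stop(sprintf("path %d failed: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    if (is.null(first)) {
      first <- traj
      x1m <- matrix(NA_real_, n, nrow(traj))
      x2m <- matrix(NA_real_, n, nrow(traj))
    }
    x1m[i, ] <- traj$x1
    x2m[i, ] <- traj$x2
    avg <- time_average(traj, window)
    paths[[i]] <- tibble::tibble(
      path = i, seed = cfg_i$seed,
      avg_x1 = avg$c_avg[avg$variable == "x1"],
      avg_x2 = avg$c_avg[avg$variable == "x2"],
      avg_total = avg$c_avg[avg$variable == "x1"] +
        avg$c_avg[avg$variable == "x2"],
      final_x1 = traj$x1[nrow(traj)], final_x2 = traj$x2[nrow(traj)],
      extinct = extinction_flag(traj, ext_threshold, ext_dwell),
      extinct_x1 = extinction_flag(traj, ext_threshold, ext_dwell,
                                   var = "x1"),
      extinct_x2 = extinction_flag(traj, ext_threshold, ext_dwell,
                                   var = "x2"))
  }
  paths <- dplyr::bind_rows(paths)
  qs <- function(m, pr) apply(m, 2, stats::quantile, probs = pr, names = FALSE)
  summary <- tibble::tibble(
    t = first$t,
    x1_mean = colMeans(x1m), x2_mean = colMeans(x2m),
    x1_median = qs(x1m, 0.5), x2_median = qs(x2m, 0.5),
    x1_q05 = qs(x1m, 0.05), x1_q95 = qs(x1m, 0.95),
    x2_q05 = qs(x2m, 0.05), x2_q95 = qs(x2m, 0.95),
    c_o = first$c_o, c_e = first$c_e)
  tot_end <- x1m[, ncol(x1m)] + x2m[, ncol(x2m)]
  pm <- tot_end^p
  out <- list(summary = summary, paths = paths,
              pmoment = list(p = p, t = config$t_end, value = mean(pm),
                             se = stats::sd(pm) / sqrt(n)),
              window = window, config = config, model = model)
  if (keep_paths) {
    out$x1 <- x1m
    out$x2 <- x2m
  }
  structure(out, class = "tox_ensemble")
}

#' @export
print.tox_ensemble <- function(x, ...) {
  cat("<tox_ensemble>", x$config$n_paths, "paths, t_end =",
      x$config$t_end, ", dt =", x$config$dt, ", scheme =",
      x$config$scheme, "\n")
  cat(sprintf("  extinct fraction: %.3f (x1: %.3f, x2: %.3f)\n",
              mean(x$paths$extinct), mean(x$paths$extinct_x1),
              mean(x$paths$extinct_x2)))
  cat(sprintf("  mean <x1+x2> over [%g, %g]: %.4f\n", x$window[1],
              x$window[2], mean(x$paths$avg_total)))
  cat(sprintf("  E[(x1+x2)^%g] at t = %g: %.4g (se %.3g)\n",
              x$pmoment$p, x$pmoment$t, x$pmoment$value, x$pmoment$se))
  invisible(x)
}

#' Simulate the unpolluted reduction of the model
#'
#' With no toxicant input the model degenerates to plain stochastic
#' two-patch logistic migration. This enforces `delta = 0`, `rho = 0`,
#' `b = 0` and then delegates to [simulate_path()], so with equal seed the
#' trajectory is identical to the full model under that substitution.
#'
#' @inheritParams simulate_path
#' @return A `tox_trajectory` tibble (with `c_o = c_e = 0` throughout).
#' @export
simulate_unpolluted <- function(model, config, x0 = c(0.8, 0.5),
                                increments = NULL) {
  stopifnot(inherits(model, "model_params"))
  tox0 <- model$toxicant
  clean <- model_params(
    patch1 = model$patch1, patch2 = model$patch2,
    migration = migration_params(model$migration$d12, model$migration$d21,
                                 rho = 0, alpha = model$migration$alpha),
    toxicant = toxicant_params(tox0$f, tox0$g, tox0$m, tox0$h, b = 0,
                               gamma = tox0$gamma),
    delta = 0)
  simulate_path(clean, config, x0, tox0 = c(0, 0), increments = increments)
}
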