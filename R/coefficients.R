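#' Deterministic part of the OU-driven growth rate
#'
#' The mean-reverting growth process has pathwise solution
#' `r_e + (r_0 - r_e) exp(-mu t)` plus white noise with amplitude
#' [sigma_t()]; this returns the deterministic part.
#'
#' @param patch A [patch_params()] object.
#' @param t Nonnegative time(s).
#' @return Numeric vector of growth rates.
#' @examples
#' p <- patch_params(0.3, 0.6, mu = 0.1, xi = 0.4, a = 0.1)
#' mean_growth(p, c(0, 10, 1000))
#' @export
mean_growth <- function(patch, t) {
  stopifnot(inherits(patch, "patch_params"))
  if (any(t < 0)) stop("`t` must be nonnegative.", call. = FALSE)
  patch$r_e + (patch$r_0 - patch$r_e) * exp(-patch$mu * t)
}

#' Time-varying noise amplitude of the OU-driven growth rate
#'
#' `sigma(t) = xi / sqrt(2 mu) * sqrt(1 - exp(-2 mu t))`; nondecreasing in
#' `t` with limit `xi / sqrt(2 mu)`, so `sigma(t)^2 <= xi^2 / (2 mu)`.
#'
#' @inheritParams mean_growth
#' @return Numeric vector of noise amplitudes.
#' @export
sigma_t <- function(patch, t) {
  stopifnot(inherits(patch, "patch_params"))
  if (any(t < 0)) stop("`t` must be nonnegative.", call. = FALSE)
  patch$xi / sqrt(2 * patch$mu) * sqrt(-expm1(-2 * patch$mu * t))
}

#' Toxicant-amplified migration rate out of the polluted patch
#'
#' Holling type-III response of emigration to the environmental toxicant:
#' `d12 * (1 + rho * c_e^2 / (1 + alpha * c_e^2))`, nondecreasing in `c_e`
#' and bounded by `d12 * (1 + rho)`.
#'
#' @param mig A [migration_params()] object.
#' @param c_e Environmental toxicant concentration(s), nonnegative.
#' @return Numeric vector of migration rates.
#' @export
migration_rate <- function(mig, c_e) {
  stopifnot(inherits(mig, "migration_params"))
  if (any(c_e < 0)) stop("`c_e` must be nonnegative.", call. = FALSE)
  mig$d12 * (1 + mig$rho * c_e^2 / (1 + mig$alpha * c_e^2))
}

#' Drift and diffusion coefficients of the population SDE
#'
#' Evaluates the right-hand side of the two-patch population SDE at a given
#' state: \deqn{drift_1 = x_1 (r_1(t) - a_1 x_1) + d_{21} x_2 - d_{12}(t) x_1}
#' \deqn{drift_2 = x_2 (r_2(t) - a_2 x_2) + d_{12}(t) x_1 - d_{21} x_2}
#' with `r_1(t)` the OU mean growth minus the lethality term
#' `delta * c_o`, `d_12(t)` the toxicant-amplified migration rate, and
#' diffusion `sigma_i(t) * x_i` per patch.
#'
#' @param model A [model_params()] object.
#' @param t Time (nonnegative scalar).
#' @param x1,x2 Population densities (nonnegative).
#' @param c_o,c_e Toxicant concentrations in organism and environment.
#'
#' @return A list with numeric length-2 vectors `drift` and `diffusion`.
#' @export
drift_diffusion <- function(model, t, x1, x2, c_o, c_e) {
  stopifnot(inherits(model, "model_params"))
  stop_if_not_scalar(t = t, x1 = x1, x2 = x2, c_o = c_o, c_e = c_e)
  if (x1 < 0 || x2 < 0) {
    stop("densities must be nonnegative.", call. = FALSE)
  }
  if (t < 0) stop("`t` must be nonnegative.", call. = FALSE)
  r1 <- mean_growth(model$patch1, t) - model$delta * c_o
  r2 <- mean_growth(model$patch2, t)
  d12t <- migration_rate(model$migration, c_e)
  d21 <- model$migration$d21
  drift <- c(x1 * (r1 - model$patch1$a * x1) + d21 * x2 - d12t * x1,
             x2 * (r2 - model$patch2$a * x2) + d12t * x1 - d21 * x2)
  diffusion <- c(sigma_t(model$patch1, t) * x1,
                 sigma_t(model$patch2, t) * x2)
  list(drift = drift, diffusion = diffusion)
}
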