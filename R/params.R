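#' Toxicokinetic parameters of the pulsed toxicant subsystem
#'
#' Bundles the constants of the impulsive toxicant model: organisms take up
#' toxicant from the environment at rate `f`, lose it by egestion (`g`) and
#' metabolism (`m`); the environmental concentration decays at rate `h` and
#' receives an instantaneous pulse of size `b` every `gamma` time units.
#'
#' Because both concentrations are dimensionless fractions in `[0, 1]`, the
#' parameters must satisfy `f <= g + m` and `b <= 1 - exp(-h * gamma)`;
#' otherwise the body burden or the environmental concentration would
#' eventually exceed 1. Violations are errors unless `strict = FALSE`, in
#' which case they downgrade to warnings.
#'
#' @param f Uptake rate of environmental toxicant by organisms (per time).
#' @param g Egestion rate (per time).
#' @param m Metabolic loss rate (per time).
#' @param h Environmental degradation/loss rate (per time), must be positive.
#' @param b Pulse input amount (dimensionless concentration, `>= 0`).
#' @param gamma Pulse period (time, positive).
#' @param strict Treat boundedness constraints as errors (default) or warnings.
#'
#' @return An object of class `toxicant_params` (a validated named list).
#' @examples
#' toxicant_params(f = 0.5, g = 0.3, m = 0.2, h = 0.3, b = 0.1, gamma = 1)
#' @export
toxicant_params <- function(f, g, m, h, b, gamma, strict = TRUE) {
  stop_if_not_scalar(f = f, g = g, m = m, h = h, b = b, gamma = gamma)
  if (f < 0 || g < 0 || m < 0) {
    stop("`f`, `g`, `m` must be nonnegative.", call. = FALSE)
  }
  if (h <= 0) stop("`h` must be positive.", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive.", call. = FALSE)
  if (b < 0) stop("`b` must be nonnegative.", call. = FALSE)
  complain <- if (strict) stop else warning
  if (f > g + m + 1e-12) {
    complain(sprintf("boundedness requires f <= g + m (f = %g, g + m = %g).",
                     f, g + m), call. = FALSE)
  }
  bmax <- 1 - exp(-h * gamma)
  if (b > bmax + 1e-12) {
    complain(sprintf(
      "boundedness requires b <= 1 - exp(-h*gamma) = %g (b = %g).", bmax, b),
      call. = FALSE)
  }
  structure(list(f = f, g = g, m = m, h = h, b = b, gamma = gamma),
            class = "toxicant_params")
}

#' Patch-level growth parameters
#'
#' The per-patch growth rate follows a mean-reverting Ornstein-Uhlenbeck
#' process reverting to `r_e` at speed `mu` with noise intensity `xi`,
#' started at `r_0`. Substituting the OU solution into the population
#' equation yields a deterministic transient `r_e + (r_0 - r_e) exp(-mu t)`
#' plus white noise with time-varying amplitude
#' `sigma(t) = xi / sqrt(2 mu) * sqrt(1 - exp(-2 mu t))`. `a` is the
#' intraspecific competition coefficient.
#'
#' @param r_e Asymptotic mean growth rate (per time, positive).
#' @param r_0 Initial growth rate (per time, nonnegative).
#' @param mu Reversion speed (per time, positive).
#' @param xi Noise intensity (nonnegative).
#' @param a Intraspecific competition coefficient (positive).
#'
#' @return An object of class `patch_params`.
#' @examples
#' patch_params(r_e = 0.3, r_0 = 0.6, mu = 0.1, xi = 0.4, a = 0.1)
#' @export
patch_params <- function(r_e, r_0, mu, xi, a) {
  stop_if_not_scalar(r_e = r_e, r_0 = r_0, mu = mu, xi = xi, a = a)
  if (r_e <= 0) stop("`r_e` must be positive.", call. = FALSE)
  if (r_0 < 0) stop("`r_0` must be nonnegative.", call. = FALSE)
  if (mu <= 0) stop("`mu` must be positive.", call. = FALSE)
  if (xi < 0) stop("`xi` must be nonnegative.", call. = FALSE)
  if (a <= 0) stop("`a` must be positive.", call. = FALSE)
  structure(list(r_e = r_e, r_0 = r_0, mu = mu, xi = xi, a = a),
            class = "patch_params")
}

#' Migration parameters with toxicant-driven emigration
#'
#' Baseline migration rates `d12` (patch 1 to 2) and `d21` (patch 2 to 1).
#' Emigration from the polluted patch is amplified by the environmental
#' toxicant through a Holling type-III response:
#' `d12(t) = d12 * (1 + rho * c_e^2 / (1 + alpha * c_e^2))`, where `rho`
#' scales the toxicant-driven component and `alpha` sets the saturation.
#'
#' @param d12 Baseline migration rate patch 1 -> 2 (per time, nonnegative).
#' @param d21 Migration rate patch 2 -> 1 (per time, nonnegative).
#' @param rho Toxicant-driven migration amplification (dimensionless, `>= 0`).
#' @param alpha Holling-III saturation constant (dimensionless, positive).
#'
#' @return An object of class `migration_params`.
#' @examples
#' migration_params(d12 = 0.5, d21 = 0.6, rho = 1.2, alpha = 0.2)
#' @export
migration_params <- function(d12, d21, rho, alpha) {
  stop_if_not_scalar(d12 = d12, d21 = d21, rho = rho, alpha = alpha)
  if (d12 < 0 || d21 < 0 || rho < 0) {
    stop("`d12`, `d21`, `rho` must be nonnegative.", call. = FALSE)
  }
  if (alpha <= 0) stop("`alpha` must be positive.", call. = FALSE)
  structure(list(d12 = d12, d21 = d21, rho = rho, alpha = alpha),
            class = "migration_params")
}

#' Full two-patch model parameterization
#'
#' Assembles the complete model: two patches with OU-driven growth, migration
#' with toxicant-amplified emigration from patch 1, the impulsive
#' toxicokinetic subsystem, and the lethality coefficient `delta` converting
#' patch-1 body burden into extra mortality (`delta * c_o(t)` reduces the
#' patch-1 growth rate).
#'
#' @param patch1,patch2 [patch_params()] objects.
#' @param migration A [migration_params()] object.
#' @param toxicant A [toxicant_params()] object.
#' @param delta Lethality coefficient (per time per unit body burden, `>= 0`).
#'
#' @return An object of class `model_params`.
#' @seealso [fixture()] for the built-in published parameter sets.
#' @export
model_params <- function(patch1, patch2, migration, toxicant, delta) {
  stopifnot(inherits(patch1, "patch_params"),
            inherits(patch2, "patch_params"),
            inherits(migration, "migration_params"),
            inherits(toxicant, "toxicant_params"))
  stop_if_not_scalar(delta = delta)
  if (delta < 0) stop("`delta` must be nonnegative.", call. = FALSE)
  structure(list(patch1 = patch1, patch2 = patch2, migration = migration,
                 toxicant = toxicant, delta = delta),
            class = "model_params")
}

#' @export
print.toxicant_params <- function(x, ...) {
  cat("<toxicant_params> f =", x$f, " g =", x$g, " m =", x$m,
      " h =", x$h, " b =", x$b, " gamma =", x$gamma, "\n")
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat("  patch 1: r_e =", x$patch1$r_e, " r_0 =", x$patch1$r_0,
      " mu =", x$patch1$mu, " xi =", x$patch1$xi, " a =", x$patch1$a, "\n")
  cat("  patch 2: r_e =", x$patch2$r_e, " r_0 =", x$patch2$r_0,
      " mu =", x$patch2$mu, " xi =", x$patch2$xi, " a =", x$patch2$a, "\n")
  cat("  migration: d12 =", x$migration$d12, " d21 =", x$migration$d21,
      " rho =", x$migration$rho, " alpha =", x$migration$alpha, "\n")
  cat("  toxicant: f =", x$toxicant$f, " g =", x$toxicant$g,
      " m =", x$toxicant$m, " h =", x$toxicant$h, " b =", x$toxicant$b,
      " gamma =", x$toxicant$gamma, "\n")
  cat("  delta =", x$delta, "\n")
  invisible(x)
}

# all args length-1 finite numerics
stop_if_not_scalar <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number.", nm), call. = FALSE)
    }
  }
  invisible(NULL)
}
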