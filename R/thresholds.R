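#' Derived constants entering the survival thresholds
#'
#' Computes every constant the extinction/persistence criteria are written
#' in: the patch-1 effective growth rate at minimum and maximum body burden
#' (`r1_up = r_1e - delta c_o^m`, `r1_low = r_1e - delta c_o^M`), the
#' migration rate at maximum and minimum environmental toxicant (`d12_up`,
#' `d12_low`), the aggregated noise intensities
#' \deqn{\sigma^2 = \frac{\xi_1^2 \xi_2^2}{2\mu_1\xi_2^2 + 2\mu_2\xi_1^2},
#'       \quad
#'       \hat\sigma^2 = \max\{\xi_1^2/2\mu_1, \xi_2^2/2\mu_2\},}
#' and the period averages `mean_co` and `eta` of the toxicant orbit.
#'
#' @param model A [model_params()] object.
#' @return An object of class `derived_constants` (named list), with the
#'   underlying [periodic_toxicant()] solution attached as attribute
#'   `"orbit"`.
#' @examples
#' fx <- fixture("set40-fig1a")
#' derived_constants(fx$model)
#' @export
derived_constants <- function(model) {
  stopifnot(inherits(model, "model_params"))
  orbit <- periodic_toxicant(model$toxicant, model$migration$alpha)
  p1 <- model$patch1; p2 <- model$patch2
  xi1 <- p1$xi; xi2 <- p2$xi; mu1 <- p1$mu; mu2 <- p2$mu
  denom <- 2 * mu1 * xi2^2 + 2 * mu2 * xi1^2
  sigma2 <- if (denom > 0) xi1^2 * xi2^2 / denom else 0
  out <- list(
    r1_up = p1$r_e - model$delta * orbit$co_min,
    r1_low = p1$r_e - model$delta * orbit$co_max,
    d12_up = migration_rate(model$migration, orbit$ce_max),
    d12_low = migration_rate(model$migration, orbit$ce_min),
    sigma2 = sigma2,
    sigma_hat2 = max(xi1^2 / (2 * mu1), xi2^2 / (2 * mu2)),
    mean_co = orbit$mean_co,
    eta = orbit$eta)
  structure(out, orbit = orbit, class = "derived_constants")
}

#' @export
print.derived_constants <- function(x, ...) {
  cat("<derived_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' @rdname derived_constants
#' @param x A `derived_constants` object.
#' @param ... Unused.
#' @export
tidy.derived_constants <- function(x, ...) {
  tibble::tibble(quantity = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

# shared margin for the case-(ii)/(iii) spectral-type expressions:
# (ra + rb - dstar - d21) + sqrt((ra - rb + d21 - dstar)^2 + 4 dstar d21)
survival_expression <- function(ra, rb, dstar, d21) {
  (ra + rb - dstar - d21) +
    sqrt((ra - rb + d21 - dstar)^2 + 4 * dstar * d21)
}

#' Extinction criterion
#'
#' Evaluates the sufficient condition for almost-sure extinction. The case
#' is selected by the sign of `r_1^* - r_2e` (equality within `1e-12` is
#' case "i"): case "i" compares `r_1^* + r_2e` to `sigma^2`; cases "ii"
#' (`r_1^* < r_2e`, using `d_12^*`) and "iii" (`r_1^* > r_2e`, using
#' `(d_12)_*`) compare a spectral-bound expression to `sigma^2`. The
#' functional is reported as a signed margin (expression minus `sigma^2`),
#' so extinction is concluded when it is negative.
#'
#' @param model A [model_params()] object.
#' @param constants Optionally, a precomputed [derived_constants()] object.
#' @return A list with elements `case` ("i", "ii" or "iii"), `functional`
#'   (signed margin) and `verdict` (`TRUE` if the criterion fires).
#' @examples
#' extinction_check(fixture("set40-fig1a")$model)
#' @export
extinction_check <- function(model, constants = derived_constants(model)) {
  k <- constants
  diff <- k$r1_up - model$patch2$r_e
  r2e <- model$patch2$r_e
  d21 <- model$migration$d21
  if (abs(diff) <= 1e-12) {
    case <- "i"
    functional <- k$r1_up + r2e - k$sigma2
  } else if (diff < 0) {
    case <- "ii"
    functional <- survival_expression(k$r1_up, r2e, k$d12_up, d21) - k$sigma2
  } else {
    case <- "iii"
    functional <- survival_expression(k$r1_up, r2e, k$d12_low, d21) - k$sigma2
  }
  list(case = case, functional = functional, verdict = functional < 0)
}

#' Noise-independent extinction criterion
#'
#' Extinction follows regardless of the noise intensities when
#' `r_1^* < 0` and `d_12^* r_2e + r_1^* d_21 - r_1^* r_2e < 0`.
#'
#' @inheritParams extinction_check
#' @return `TRUE` or `FALSE`.
#' @export
noise_free_extinction <- function(model, constants = derived_constants(model)) {
  k <- constants
  r2e <- model$patch2$r_e
  d21 <- model$migration$d21
  (k$r1_up < 0) && (k$d12_up * r2e + k$r1_up * d21 - k$r1_up * r2e < 0)
}

#' Stochastic permanence criterion
#'
#' The population is stochastically permanent (stays within positive bounds
#' with probability arbitrarily close to one) when
#' `min(r_1e - delta c_o^M, r_2e) > 0.5 * sigma_hat^2`.
#'
#' @inheritParams extinction_check
#' @return `TRUE` or `FALSE`.
#' @export
stochastic_permanence_check <- function(model,
                                        constants = derived_constants(model)) {
  k <- constants
  min(k$r1_low, model$patch2$r_e) > 0.5 * k$sigma_hat2
}

#' Persistence-in-mean criterion
#'
#' Evaluates the sufficient condition for strong persistence in the mean.
#' Mirrors [extinction_check()] with the conservative constants: the case is
#' selected by the sign of `(r_1)_* - r_2e`; case "ii" uses `(d_12)_*`,
#' case "iii" uses `d_12^*`, and the comparison noise level is
#' `sigma_hat^2`. The functional is the signed margin (expression minus
#' `sigma_hat^2`); persistence is concluded when it is positive.
#'
#' @inheritParams extinction_check
#' @return A list with `case`, `functional` and `verdict`.
#' @examples
#' persistence_mean_check(fixture("set40-fig1b")$model)
#' @export
persistence_mean_check <- function(model,
                                   constants = derived_constants(model)) {
  k <- constants
  r2e <- model$patch2$r_e
  d21 <- model$migration$d21
  diff <- k$r1_low - r2e
  if (abs(diff) <= 1e-12) {
    case <- "i"
    functional <- k$r1_low + r2e - k$sigma_hat2
  } else if (diff < 0) {
    case <- "ii"
    functional <- survival_expression(k$r1_low, r2e, k$d12_low, d21) -
      k$sigma_hat2
  } else {
    case <- "iii"
    functional <- survival_expression(k$r1_low, r2e, k$d12_up, d21) -
      k$sigma_hat2
  }
  list(case = case, functional = functional, verdict = functional > 0)
}

#' Lower bounds on long-run time averages
#'
#' When `r_1e - delta f b / (h (g+m) gamma) - d12 (1 + rho eta) > 0` and
#' `r_2e - d21 > 0`, the long-run time averages of the two patch densities
#' admit the closed-form lower bounds returned here (numerator over the
#' competition coefficient). `applicable` reports whether both hypotheses
#' hold.
#'
#' @inheritParams extinction_check
#' @return A list with `bound_x1`, `bound_x2`, `applicable`.
#' @export
mean_lower_bounds <- function(model, constants = derived_constants(model)) {
  k <- constants
  num1 <- model$patch1$r_e - model$delta * k$mean_co -
    model$migration$d12 * (1 + model$migration$rho * k$eta)
  num2 <- model$patch2$r_e - model$migration$d21
  list(bound_x1 = num1 / model$patch1$a,
       bound_x2 = num2 / model$patch2$a,
       applicable = num1 > 0 && num2 > 0)
}

#' Asymptotic p-moment bound
#'
#' Bound `K(p)` on the limiting p-th moment of the total population
#' `E[(x1 + x2)^p]`: `K(p) = (r/a)^p` with
#' `r = p max(r_1e + r_10, r_2e + r_20) + 0.5 p (p-1) max(xi_i^2 / 2 mu_i)`
#' and `a = p min(a_1, a_2) / 2`.
#'
#' @param model A [model_params()] object.
#' @param p Moment exponent, `> 1`.
#' @return A single number `K(p)`.
#' @examples
#' pmoment_bound(fixture("set40-fig1b")$model, p = 2) # 342.25
#' @export
pmoment_bound <- function(model, p) {
  stopifnot(inherits(model, "model_params"))
  stop_if_not_scalar(p = p)
  if (p <= 1) stop("`p` must be greater than 1.", call. = FALSE)
  p1 <- model$patch1; p2 <- model$patch2
  r <- p * max(p1$r_e + p1$r_0, p2$r_e + p2$r_0) +
    0.5 * p * (p - 1) * max(p1$xi^2 / (2 * p1$mu), p2$xi^2 / (2 * p2$mu))
  a <- p * min(p1$a, p2$a) / 2
  (r / a)^p
}

#' Thresholds for the unpolluted two-patch model
#'
#' With no toxicant the model reduces to plain stochastic two-patch
#' logistic migration; both survival criteria then use the raw rates:
#' the common expression
#' `r_1e + r_2e - d12 - d21 + sqrt((r_1e - r_2e + d21 - d12)^2 + 4 d12 d21)`
#' is compared to `sigma^2` (extinction, below) and `sigma_hat^2`
#' (persistence in the mean, above).
#'
#' @inheritParams extinction_check
#' @return A list with the signed margins `extinction_functional`,
#'   `persistence_functional` and the booleans `extinction_verdict`,
#'   `persistence_verdict`.
#' @export
unpolluted_thresholds <- function(model,
                                  constants = derived_constants(model)) {
  p1 <- model$patch1; p2 <- model$patch2
  d12 <- model$migration$d12; d21 <- model$migration$d21
  expr <- survival_expression(p1$r_e, p2$r_e, d12, d21)
  list(extinction_functional = expr - constants$sigma2,
       persistence_functional = expr - constants$sigma_hat2,
       extinction_verdict = expr - constants$sigma2 < 0,
       persistence_verdict = expr - constants$sigma_hat2 > 0)
}

#' Full survival classification
#'
#' Evaluates every sufficient criterion and aggregates them into a single
#' auditable report. The summary note applies the precedence: extinction
#' conditions first, then stochastic permanence, then persistence in the
#' mean; `"inconclusive"` when no sufficient condition fires (the criteria
#' are sufficient, not exhaustive, so all verdicts may be false).
#'
#' @param model A [model_params()] object.
#' @return An object of class `threshold_report`.
#' @examples
#' classify(fixture("set40-fig1a")$model)
#' @export
classify <- function(model) {
  stopifnot(inherits(model, "model_params"))
  k <- derived_constants(model)
  ext <- extinction_check(model, k)
  nfe <- noise_free_extinction(model, k)
  sp <- stochastic_permanence_check(model, k)
  per <- persistence_mean_check(model, k)
  mb <- mean_lower_bounds(model, k)
  note <- if (ext$verdict) {
    paste0("extinction (case ", ext$case, ")")
  } else if (nfe) {
    "extinction (noise-free criterion)"
  } else if (sp) {
    "stochastically permanent"
  } else if (per$verdict) {
    paste0("persistent in mean (case ", per$case, ")")
  } else {
    "inconclusive"
  }
  structure(list(constants = k,
                 extinction_case = ext$case,
                 extinction_functional = ext$functional,
                 extinction_verdict = ext$verdict,
                 noise_free_extinction = nfe,
                 stochastic_permanence_verdict = sp,
                 persistence_case = per$case,
                 persistence_functional = per$functional,
                 persistence_verdict = per$verdict,
                 mean_bounds = mb,
                 notes = note),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>\n")
  cat(sprintf("  extinction:            case %-3s margin %+ .5f  %s\n",
              x$extinction_case, x$extinction_functional,
              if (x$extinction_verdict) "FIRES" else "-"))
  cat(sprintf("  noise-free extinction: %s\n",
              if (x$noise_free_extinction) "FIRES" else "-"))
  cat(sprintf("  stochastic permanence: %s\n",
              if (x$stochastic_permanence_verdict) "FIRES" else "-"))
  cat(sprintf("  persistence in mean:   case %-3s margin %+ .5f  %s\n",
              x$persistence_case, x$persistence_functional,
              if (x$persistence_verdict) "FIRES" else "-"))
  if (x$mean_bounds$applicable) {
    cat(sprintf("  mean lower bounds:     <x1> >= %.4f, <x2> >= %.4f\n",
                x$mean_bounds$bound_x1, x$mean_bounds$bound_x2))
  }
  cat("  summary:", x$notes, "\n")
  invisible(x)
}

#' Tidy a threshold report
#'
#' One row per survival criterion with its case, signed margin and verdict.
#'
#' @param x A `threshold_report` from [classify()].
#' @param ... Unused.
#' @return A tibble with columns `criterion`, `case`, `functional`,
#'   `verdict`.
#' @export
tidy.threshold_report <- function(x, ...) {
  tibble::tibble(
    criterion = c("extinction", "noise_free_extinction",
                  "stochastic_permanence", "persistence_in_mean"),
    case = c(x$extinction_case, NA, NA, x$persistence_case),
    functional = c(x$extinction_functional, NA, NA, x$persistence_functional),
    verdict = c(x$extinction_verdict, x$noise_free_extinction,
                x$stochastic_permanence_verdict, x$persistence_verdict))
}

#' Glance at a threshold report
#'
#' @param x A `threshold_report` from [classify()].
#' @param ... Unused.
#' @return A one-row tibble with the derived noise constants and the
#'   summary verdict.
#' @export
glance.threshold_report <- function(x, ...) {
  k <- x$constants
  tibble::tibble(r1_up = k$r1_up, r1_low = k$r1_low, d12_up = k$d12_up,
                 d12_low = k$d12_low, sigma2 = k$sigma2,
                 sigma_hat2 = k$sigma_hat2, summary = x$notes)
}

#' Serialize a threshold report to JSON
#'
#' @param x A `threshold_report` from [classify()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "threshold_report"))
  obj <- unclass(x)
  obj$constants <- unclass(obj$constants)
  attr(obj$constants, "orbit") <- NULL
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
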