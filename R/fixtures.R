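#' Published benchmark parameter sets
#'
#' Returns one of the built-in parameterizations used in the reference
#' numerical experiments, as a list with the `model`, the initial densities
#' `x0 = (x1(0), x2(0))` and the initial toxicant state
#' `tox0 = (c_o(0), c_e(0))`.
#'
#' Two base sets are provided, each with figure-panel variants that change
#' only the noise, reversion-speed, pulse or migration settings:
#' \describe{
#'   \item{`set40`}{patch 1: `r_1e = 0.3, r_10 = 0.6, a_1 = 0.1`; patch 2:
#'     `r_2e = 0.15, r_20 = 0.3, a_2 = 0.5`; `d12 = 0.5, d21 = 0.6,
#'     rho = 1.2, alpha = 0.2`; toxicant `f = 0.5, g = 0.3, m = 0.2,
#'     h = 0.3`; `delta = 0.8`. Base noise/pulse settings equal the
#'     `fig1b` panel (`mu = 0.1, xi = 0.1, gamma = 1, b = 0.1`).}
#'   \item{`set40-fig1a`}{`xi = 0.4` (extinction by noise).}
#'   \item{`set40-fig1b`}{`xi = 0.1` (persistence in mean).}
#'   \item{`set40-fig1c`}{`mu = 0.01, xi = 0.1` (extinction by slow
#'     reversion).}
#'   \item{`set40-fig1d`}{`gamma = 0.8, b = 0.2` (extinction by heavier
#'     pulsing).}
#'   \item{`set41`}{patch 1: `r_1e = 0.25, r_10 = 0.4, a_1 = 0.1`; patch 2:
#'     `r_2e = 0.2, r_20 = 0.1, a_2 = 0.6`; `alpha = 0.1, h = 0.3,
#'     gamma = 1, b = 0.12, xi = 0.1, mu = 0.2, delta = 0.8`; toxicokinetic
#'     rates `f = 0.5, g = 0.3, m = 0.2` carried over from `set40`. Base
#'     migration equals the `fig2a` panel (`d12 = d21 = 0`).}
#'   \item{`set41-fig2a`}{`d12 = d21 = 0` (no migration).}
#'   \item{`set41-fig2b`}{`d12 = 0.4, d21 = 0.2, rho = 1.2`.}
#'   \item{`set41-fig2c`}{`d12 = 0.2, d21 = 0.8, rho = 0.4`.}
#' }
#' Both sets start from `x0 = (0.8, 0.5)`, `tox0 = (0.2, 0.6)`.
#'
#' @param name Fixture name (see above).
#' @return A list with elements `name`, `model`, `x0`, `tox0`.
#' @examples
#' fixture("set40-fig1a")$model
#' @export
fixture <- function(name) {
  known <- c("set40", "set40-fig1a", "set40-fig1b", "set40-fig1c",
             "set40-fig1d", "set41", "set41-fig2a", "set41-fig2b",
             "set41-fig2c")
  if (!is.character(name) || length(name) != 1L || !(name %in% known)) {
    stop("unknown fixture; available: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  if (startsWith(name, "set40")) {
    mu <- if (name == "set40-fig1c") 0.01 else 0.1
    xi <- if (name == "set40-fig1a") 0.4 else 0.1
    gam <- if (name == "set40-fig1d") 0.8 else 1
    b <- if (name == "set40-fig1d") 0.2 else 0.1
    model <- model_params(
      patch1 = patch_params(r_e = 0.3, r_0 = 0.6, mu = mu, xi = xi, a = 0.1),
      patch2 = patch_params(r_e = 0.15, r_0 = 0.3, mu = mu, xi = xi, a = 0.5),
      migration = migration_params(d12 = 0.5, d21 = 0.6, rho = 1.2,
                                   alpha = 0.2),
      toxicant = toxicant_params(f = 0.5, g = 0.3, m = 0.2, h = 0.3,
                                 b = b, gamma = gam),
      delta = 0.8)
  } else {
    mig <- switch(name,
      "set41-fig2b" = migration_params(d12 = 0.4, d21 = 0.2, rho = 1.2,
                                       alpha = 0.1),
      "set41-fig2c" = migration_params(d12 = 0.2, d21 = 0.8, rho = 0.4,
                                       alpha = 0.1),
      migration_params(d12 = 0, d21 = 0, rho = 1.2, alpha = 0.1))
    model <- model_params(
      patch1 = patch_params(r_e = 0.25, r_0 = 0.4, mu = 0.2, xi = 0.1,
                            a = 0.1),
      patch2 = patch_params(r_e = 0.2, r_0 = 0.1, mu = 0.2, xi = 0.1,
                            a = 0.6),
      migration = mig,
      toxicant = toxicant_params(f = 0.5, g = 0.3, m = 0.2, h = 0.3,
                                 b = 0.12, gamma = 1),
      delta = 0.8)
  }
  list(name = name, model = model, x0 = c(0.8, 0.5), tox0 = c(0.2, 0.6))
}

# flat key set mirroring the conventional symbols
config_keys <- c("r1e", "r10", "mu1", "xi1", "a1",
                 "r2e", "r20", "mu2", "xi2", "a2",
                 "d12", "d21", "rho", "alpha", "delta",
                 "f", "g", "m", "h", "b", "gamma")

#' Write a model configuration file
#'
#' Serializes a [model_params()] object to a flat YAML file whose keys
#' mirror the conventional symbols (`r1e, r10, mu1, xi1, a1, r2e, ...,
#' rho, alpha, delta, f, g, m, h, b, gamma`), for auditability against
#' published tables. Values are written at full double precision, so
#' write/read round-trips are lossless.
#'
#' @param model A [model_params()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [read_model_config()]
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "model_params"))
  p1 <- model$patch1; p2 <- model$patch2
  mg <- model$migration; tx <- model$toxicant
  vals <- list(r1e = p1$r_e, r10 = p1$r_0, mu1 = p1$mu, xi1 = p1$xi,
               a1 = p1$a,
               r2e = p2$r_e, r20 = p2$r_0, mu2 = p2$mu, xi2 = p2$xi,
               a2 = p2$a,
               d12 = mg$d12, d21 = mg$d21, rho = mg$rho, alpha = mg$alpha,
               delta = model$delta,
               f = tx$f, g = tx$g, m = tx$m, h = tx$h, b = tx$b,
               gamma = tx$gamma)
  yaml::write_yaml(vals, path, precision = 17L)
  invisible(path)
}

#' Read a model configuration file
#'
#' Parses a flat YAML parameter file written by [write_model_config()] (or
#' by hand) and validates it into a [model_params()] object. Missing or
#' non-numeric keys are reported by name. Boundedness violations of the
#' toxicokinetic constraints are errors by default; `strict = FALSE`
#' downgrades them to warnings.
#'
#' @param path Path to the YAML file.
#' @param strict Treat toxicant boundedness violations as errors.
#' @return A [model_params()] object.
#' @export
read_model_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  vals <- yaml::read_yaml(path)
  missing <- setdiff(config_keys, names(vals))
  if (length(missing) > 0L) {
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- config_keys[!vapply(vals[config_keys],
                             function(v) is.numeric(v) && length(v) == 1L,
                             TRUE)]
  if (length(bad) > 0L) {
    stop("config keys must be single numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- vals
  model_params(
    patch1 = patch_params(v$r1e, v$r10, v$mu1, v$xi1, v$a1),
    patch2 = patch_params(v$r2e, v$r20, v$mu2, v$xi2, v$a2),
    migration = migration_params(v$d12, v$d21, v$rho, v$alpha),
    toxicant = toxicant_params(v$f, v$g, v$m, v$h, v$b, v$gamma,
                               strict = strict),
    delta = v$delta)
}

#' Write a trajectory to CSV
#'
#' Full-double-precision CSV with header `t,x1,x2,c_o,c_e` (or `t,c_o,c_e`
#' for a pure toxicant trajectory), one row per recorded grid time.
#'
#' @param traj A trajectory tibble.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(is.data.frame(traj), "t" %in% names(traj))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
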