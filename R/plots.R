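#' Plot a simulated trajectory
#'
#' Time-series panels of the two patch densities and, optionally, the
#' toxicant concentrations.
#'
#' @param object A `tox_trajectory` from [simulate_path()].
#' @param toxicant Include the `c_o`, `c_e` panels (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tox_trajectory <- function(object, toxicant = TRUE, ...) {
  vars <- c("x1", "x2", if (toxicant) c("c_o", "c_e"))
  long <- tidyr::pivot_longer(object[, c("t", vars)], -"t",
                              names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble summary
#'
#' Pointwise mean of each patch density with the 5-95% quantile band.
#'
#' @param object A `tox_ensemble` from [simulate_ensemble()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tox_ensemble <- function(object, ...) {
  s <- object$summary
  long <- dplyr::bind_rows(
    tibble::tibble(t = s$t, mean = s$x1_mean, lo = s$x1_q05, hi = s$x1_q95,
                   variable = "x1"),
    tibble::tibble(t = s$t, mean = s$x2_mean, lo = s$x2_q05, hi = s$x2_q95,
                   variable = "x2"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = "density",
                  subtitle = sprintf("%d paths, mean with 5-95%% band",
                                     object$config$n_paths)) +
    ggplot2::theme_minimal()
}

#' Render trajectories or an ensemble to an image file
#'
#' Thin wrapper over the [autoplot()] methods that writes a PNG.
#'
#' @param x A `tox_trajectory`, a `tox_ensemble`, or a non-empty list of
#'   trajectories (overlaid).
#' @param out_path Output image path (`.png`).
#' @param width,height Device size in inches.
#' @return `out_path`, invisibly.
#' @export
plot_trajectories <- function(x, out_path, width = 7, height = 5) {
  if (is.list(x) && !is.data.frame(x) && !inherits(x, "tox_ensemble")) {
    if (length(x) == 0L) stop("empty trajectory list.", call. = FALSE)
    long <- dplyr::bind_rows(
      lapply(seq_along(x), function(i) {
        tibble::tibble(t = x[[i]]$t, x1 = x[[i]]$x1, x2 = x[[i]]$x2,
                       path = factor(i))
      }))
    long <- tidyr::pivot_longer(long, c("x1", "x2"),
                                names_to = "variable", values_to = "value")
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                            group = .data$path)) +
      ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
      ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
      ggplot2::labs(x = "time", y = "density") +
      ggplot2::theme_minimal()
  } else if (inherits(x, "tox_ensemble") || inherits(x, "tox_trajectory")) {
    p <- ggplot2::autoplot(x)
  } else {
    stop("`x` must be a trajectory, an ensemble, or a list of trajectories.",
         call. = FALSE)
  }
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = 150)
  invisible(out_path)
}
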