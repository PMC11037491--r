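#' Plot logit response curves
#'
#' Draws the standard two-panel figure: logit probability of perceiving the
#' relative 0-degree orientation against aspect ratio (log-spaced x axis),
#' for the first lattice and for the second lattice split by the conditioning
#' first-lattice percept.
#'
#' @param summary A `logit_summary` tibble from [summarize_logit()], or a list
#'   of them (e.g. expected and sampled) given as named elements, overlaid
#'   with shared axes.
#' @return A ggplot object.
#' @export
plot_curves <- function(summary) {
  if (!inherits(summary, "logit_summary") && is.list(summary) &&
      all(vapply(summary, inherits, logical(1), "logit_summary"))) {
    nms <- names(summary) %||% as.character(seq_along(summary))
    summary <- purrr::map2_dfr(summary, nms,
                               function(s, nm) dplyr::mutate(as_tibble(s), source = nm))
  } else {
    summary <- dplyr::mutate(as_tibble(summary), source = "model")
  }
  if (any(summary$lattice == "L2") &&
      !any(summary$lattice == "L2" & summary$r1 == 90)) {
    abort("No r1 = 90 rows to plot in the L2 panel.",
          class = "dotlattice_input_error")
  }
  summary$curve <- ifelse(summary$lattice == "L1", "L1",
                          paste0("L2, r1 = ", summary$r1, "°"))
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$aspect_ratio, y = .data$logit,
                               colour = .data$curve, shape = .data$source,
                               group = interaction(.data$curve, .data$source))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log",
                                breaks = default_aspect_ratios(),
                                labels = function(x) sprintf("%.2f", x)) +
    ggplot2::facet_wrap(~lattice, scales = "free_y") +
    ggplot2::labs(x = "aspect ratio |a|/|b| (log scale)",
                  y = "logit p(relative 0°)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot method for logit summaries
#'
#' @param object A `logit_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logit_summary
#' @export
autoplot.logit_summary <- function(object, ...) {
  plot_curves(object)
}

#' Scatter plots of per-individual effects
#'
#' One panel per effect pair, mirroring the correlation report.
#'
#' @param object An `effect_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effect_estimates
#' @export
autoplot.effect_estimates <- function(object, ...) {
  d <- as_tibble(object)
  long <- dplyr::bind_rows(
    dplyr::transmute(d, x = .data$adaptation, y = .data$hysteresis,
                     pair = "hysteresis vs adaptation"),
    dplyr::transmute(d, x = .data$proximity, y = .data$adaptation,
                     pair = "adaptation vs proximity"),
    dplyr::transmute(d, x = .data$proximity, y = .data$hysteresis,
                     pair = "hysteresis vs proximity")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a density on the orientation grid
#'
#' @param density A density tibble (`theta_deg`, `density`).
#' @param ... Additional densities, named, overlaid in colour.
#' @return A ggplot object.
#' @export
plot_density <- function(density, ...) {
  extra <- list(...)
  all <- c(list(density = density), extra)
  nms <- names(all)
  nms[nms == ""] <- paste0("density_", which(nms == ""))
  d <- purrr::map2_dfr(all, nms,
                       function(x, nm) dplyr::mutate(x, which = nm))
  ggplot2::ggplot(d, ggplot2::aes(.data$theta_deg, .data$density,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "orientation (deg)", y = "density (per radian)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
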