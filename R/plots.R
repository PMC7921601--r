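#' Plot a fitted photobleaching trajectory
#'
#' The raw trace with the piecewise-constant change-point fit overlaid.
#' @param object a `step_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.step_fit <- function(object, ...) {
  d <- tibble(frame = seq_along(object$trace), intensity = object$trace,
              fitted = rep(object$levels, object$dwells))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$intensity),
                       colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted),
                       colour = "#C0392B", linewidth = 0.7) +
    ggplot2::labs(x = "Frame", y = "Intensity (a.u.)") +
    ggplot2::theme_classic()
}

#' Plot a single-step intensity distribution
#'
#' Histogram of pooled I_s values with the fitted Gaussian single-step
#' component.
#' @param object a `step_distribution`.
#' @param binwidth histogram bin width (a.u.).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.step_distribution <- function(object, binwidth = 25, ...) {
  v <- tibble(I_s = object$values)
  xs <- seq(0, max(object$values), length.out = 400)
  z <- pnorm(object$lower_bound, object$I_s_mean, object$I_s_sigma,
             lower.tail = FALSE)
  dens <- tibble(
    x = xs,
    y = object$n * binwidth * object$single_weight *
      dnorm(xs, object$I_s_mean, max(object$I_s_sigma, 1e-9)) / max(z, 1e-12)
  )
  ggplot2::ggplot(v, ggplot2::aes(x = .data$I_s)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "#C0392B", linewidth = 0.8) +
    ggplot2::labs(x = expression(I[s] ~ "(a.u.)"), y = "Count") +
    ggplot2::theme_classic()
}

#' Plot one-phase association kinetics
#' @param object a `one_phase_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.one_phase_fit <- function(object, ...) {
  ts <- seq(min(object$fitted$time), max(object$fitted$time),
            length.out = 200)
  curve <- tibble(
    time = ts,
    fitted = object$y0 + (object$plateau - object$y0) * (1 - exp(-object$k * ts))
  )
  ggplot2::ggplot(object$fitted,
                  ggplot2::aes(x = .data$time, y = .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$time, y = .data$fitted),
                       colour = "#2C6FBB") +
    ggplot2::labs(x = "Time (h)", y = "Colocalized fraction (%)") +
    ggplot2::theme_classic()
}

#' Plot a stoichiometry abundance heatmap
#' @param object an `abundance_heatmap`.
#' @param trim drop all-zero rows/columns beyond the occupied range.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.abundance_heatmap <- function(object, trim = TRUE, ...) {
  d <- tidy(object)
  if (trim) {
    occ <- d[d$abundance > 0, ]
    d <- d[d$n_client <= max(occ$n_client) &
             d$n_chaperone <= max(occ$n_chaperone), ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_chaperone, y = .data$n_client,
                                  fill = .data$abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Relative\nabundance") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Chaperone subunits", y = "Client subunits",
                  title = if (is.null(object$condition)) NULL else
                    format(object$condition)) +
    ggplot2::theme_minimal()
}

#' Violin-style size-distribution plot
#'
#' Kernel density outline with median and interquartile range per group,
#' from [size_violin_summary()] output.
#' @param summary output of [size_violin_summary()].
#' @return a ggplot.
#' @export
plot_size_violins <- function(summary) {
  stopifnot(is.list(summary), all(c("summary", "density") %in% names(summary)))
  dens <- summary$density |>
    group_by(.data$group) |>
    mutate(half_width = 0.4 * .data$density / max(.data$density)) |>
    ungroup()
  gid <- match(dens$group, unique(dens$group))
  dens$x0 <- gid
  stats <- summary$summary
  stats$x0 <- match(stats$group, unique(dens$group))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = dens |>
        group_by(.data$group) |>
        dplyr::reframe(x = c(.data$x0 + .data$half_width,
                             rev(.data$x0 - .data$half_width)),
                       y = c(.data$x, rev(.data$x))),
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$group),
      fill = "grey92", colour = "black", linewidth = 0.3
    ) +
    ggplot2::geom_segment(
      data = stats,
      ggplot2::aes(x = .data$x0 - 0.2, xend = .data$x0 + 0.2,
                   y = .data$median, yend = .data$median),
      colour = "#C0392B", linewidth = 0.9
    ) +
    ggplot2::geom_segment(
      data = stats,
      ggplot2::aes(x = .data$x0, xend = .data$x0,
                   y = .data$q25, yend = .data$q75),
      colour = "#2C6FBB", linewidth = 1.2
    ) +
    ggplot2::scale_x_continuous(breaks = seq_along(unique(dens$group)),
                                labels = unique(dens$group)) +
    ggplot2::labs(x = NULL, y = "Subunits") +
    ggplot2::theme_classic()
}

#' Plot aggregation assay curves
#' @param curves tibble from [simulate_aggregation()] or plate-reader data
#'   with `time`, `condition`, `a340`.
#' @return a ggplot.
#' @export
plot_aggregation_curves <- function(curves) {
  stopifnot(is.data.frame(curves),
            all(c("time", "condition", "a340") %in% names(curves)))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$a340,
                                       colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Light scatter at 340 nm (a.u.)",
                  colour = NULL) +
    ggplot2::theme_classic()
}
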