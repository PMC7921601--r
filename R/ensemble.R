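#' Endpoint change of an aggregation curve
#'
#' Change in light scatter over the assay: mean of the last
#' `endpoint_window` readings minus mean of the first `endpoint_window`
#' readings. Window 1 reproduces the single-endpoint difference; wider
#' windows trade a little bias for lower variance on noisy plate-reader
#' traces.
#'
#' @param curve data frame with the time and absorbance columns, ordered in
#'   time (or a numeric vector of readings).
#' @param endpoint_window readings averaged at each end.
#' @param value absorbance column name when `curve` is a data frame.
#' @return the change in absorbance (a.u.).
#' @export
curve_delta <- function(curve, endpoint_window = 1, value = "a340") {
  if (is.data.frame(curve)) {
    if (!value %in% names(curve)) {
      abort_bad_arg("curve lacks column `%s`.", value)
    }
    if ("time" %in% names(curve)) curve <- curve[order(curve$time), ]
    y <- as.numeric(curve[[value]])
  } else {
    y <- as.numeric(curve)
  }
  check_number(endpoint_window, "endpoint_window", min = 1, integerish = TRUE)
  if (endpoint_window > length(y)) {
    abort_bad_arg("endpoint_window (%d) exceeds curve length (%d).",
                  endpoint_window, length(y))
  }
  w <- endpoint_window
  mean(y[(length(y) - w + 1):length(y)]) - mean(y[1:w])
}

#' Percent inhibition of aggregation
#'
#' `100 * (delta_Ic - delta_Is) / delta_Ic`, where `delta_Ic` and `delta_Is`
#' are the endpoint light-scatter changes without and with chaperone.
#' Negative values (aggregation enhancement) are reported, not clipped.
#'
#' @param delta_Ic control (no chaperone) change in absorbance; must be > 0.
#' @param delta_Is chaperone-present change in absorbance.
#' @return tibble with `delta_Ic`, `delta_Is`, `percent_inhibition`.
#' @examples
#' percent_inhibition(0.5, 0.2)  # 60 %
#' @export
percent_inhibition <- function(delta_Ic, delta_Is) {
  check_number(delta_Ic, "delta_Ic")
  check_number(delta_Is, "delta_Is")
  if (delta_Ic <= 0) {
    abort_bad_arg("delta_Ic must be positive (the control did not aggregate).")
  }
  tibble(
    delta_Ic = delta_Ic,
    delta_Is = delta_Is,
    percent_inhibition = 100 * (delta_Ic - delta_Is) / delta_Ic
  )
}

#' Percent inhibition across molar ratios
#'
#' Computes the per-replicate percent inhibition of every chaperone
#' condition against the control curves and summarises mean and sd per
#' molar ratio.
#'
#' @param curves long-format data frame with columns `time`, `condition`,
#'   `replicate`, `a340`, `ratio` (`ratio = NA` or 0 for the control rows is
#'   accepted when `control_condition` identifies them).
#' @param control_condition value of `condition` labelling the control.
#' @param endpoint_window see [curve_delta()].
#' @return tibble per ratio: `ratio`, `n`, `mean_inhibition`,
#'   `sd_inhibition`; attribute `monotone` flags whether the means are
#'   non-decreasing in ratio.
#' @export
inhibition_by_ratio <- function(curves, control_condition = "control",
                                endpoint_window = 1) {
  stopifnot(is.data.frame(curves))
  need <- c("time", "condition", "replicate", "a340", "ratio")
  if (!all(need %in% names(curves))) {
    abort_bad_arg("curves need columns %s.", paste(need, collapse = ", "))
  }
  ctrl <- curves[curves$condition == control_condition, , drop = FALSE]
  trt <- curves[curves$condition != control_condition, , drop = FALSE]
  if (nrow(ctrl) == 0) {
    abort_bad_arg("no rows with condition `%s`.", control_condition)
  }
  ctrl_delta <- vapply(split(ctrl, ctrl$replicate), curve_delta,
                       numeric(1), endpoint_window = endpoint_window)
  ctrl_mean <- mean(ctrl_delta)

  per_rep <- trt |>
    group_by(.data$ratio, .data$replicate) |>
    summarise(delta = curve_delta(dplyr::pick("time", "a340"),
                                  endpoint_window = endpoint_window),
              .groups = "drop") |>
    mutate(percent = 100 * (ctrl_mean - .data$delta) / ctrl_mean)

  out <- per_rep |>
    group_by(.data$ratio) |>
    summarise(n = dplyr::n(),
              mean_inhibition = mean(.data$percent),
              sd_inhibition = ifelse(dplyr::n() > 1, sd(.data$percent), 0),
              .groups = "drop") |>
    arrange(.data$ratio)
  attr(out, "monotone") <- !is.unsorted(out$mean_inhibition)
  out
}
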