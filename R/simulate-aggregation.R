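#' Simulate a light-scatter aggregation assay
#'
#' Generates a matched pair of light-scatter (A340) curves for a heat-
#' destabilized client aggregating alone (control) and in the presence of a
#' chaperone. The control follows a monotone sigmoid
#' `A(t) = A_max * t^h / (t50^h + t^h)`; the chaperone curve is the control
#' scaled by `1 - s`, where the suppression `s` depends on the chaperone:
#' client molar ratio. Scaling the whole curve reduces both the absolute
#' aggregation rate and the plateau, and makes the endpoint percent
#' inhibition equal `100 * s` exactly on noise-free curves.
#'
#' @param client_conc client concentration (uM); sets the plateau amplitude.
#' @param chaperone_ratio chaperone:client molar ratio.
#' @param growth_rate inverse half-time of aggregation (1/h); `t50 =
#'   1/growth_rate`.
#' @param suppression either a function of the molar ratio returning a value
#'   in `[0, 1]`, or a single number in `[0, 1]` used directly.
#' @param n_timepoints number of samples over the assay window.
#' @param t_end assay duration (h).
#' @param hill sigmoid steepness exponent.
#' @param noise_sd additive measurement noise sd (a.u.).
#' @param seed optional integer seed.
#' @return a tibble with columns `time` (h), `condition`
#'   (`"control"`/`"chaperone"`), `a340` (a.u.); the suppression actually
#'   applied is stored in attribute `suppression`.
#' @examples
#' curves <- simulate_aggregation(50, chaperone_ratio = 0.5, suppression = 0.6)
#' @export
simulate_aggregation <- function(client_conc = 50, chaperone_ratio = 0.5,
                                 growth_rate = 0.25,
                                 suppression = default_suppression,
                                 n_timepoints = 100, t_end = 20, hill = 2,
                                 noise_sd = 0, seed = NULL) {
  check_number(client_conc, "client_conc", min = 1e-9)
  check_number(chaperone_ratio, "chaperone_ratio", min = 0)
  check_number(growth_rate, "growth_rate", min = 1e-9)
  check_number(n_timepoints, "n_timepoints", min = 2, integerish = TRUE)
  check_number(t_end, "t_end", min = 1e-9)
  check_number(noise_sd, "noise_sd", min = 0)
  s <- if (is.function(suppression)) suppression(chaperone_ratio) else
    suppression
  check_number(s, "suppression", min = 0, max = 1)
  set_seed_if_given(seed)

  t <- seq(0, t_end, length.out = n_timepoints)
  a_max <- client_conc / 50           # ~1 a.u. plateau at 50 uM client
  t50 <- 1 / growth_rate
  ctrl <- a_max * t^hill / (t50^hill + t^hill)
  chap <- (1 - s) * ctrl
  if (noise_sd > 0) {
    ctrl <- ctrl + rnorm(length(t), 0, noise_sd)
    chap <- chap + rnorm(length(t), 0, noise_sd)
  }
  out <- bind_rows(
    tibble(time = t, condition = "control", a340 = ctrl),
    tibble(time = t, condition = "chaperone", a340 = chap)
  )
  attr(out, "suppression") <- s
  out
}

#' Default ratio-dependent aggregation suppression
#'
#' Saturating suppression `s(r) = r / (r + k)`: protection grows with the
#' chaperone:client molar ratio and approaches complete inhibition at excess
#' chaperone.
#' @param ratio chaperone:client molar ratio.
#' @param k ratio at half-maximal suppression.
#' @return suppression in `[0, 1)`.
#' @export
default_suppression <- function(ratio, k = 0.1) {
  ratio / (ratio + k)
}
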