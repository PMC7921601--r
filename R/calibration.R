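#' Calibrate the single-step intensity from a batch of trajectories
#'
#' End-to-end single-step calibration: runs change-point detection on every
#' trajectory, pools accepted downward step heights, and fits the censored
#' Gaussian single-step model (with the unresolved-double component enabled).
#' Detection runs at `min_dwell = 1` so near-coincident bleach events are
#' resolved rather than summed; the dwell quality rule is applied at pooling
#' instead, where ambiguous steps are discarded rather than merged.
#'
#' @param traces tibble with columns `trace_id`, `frame`, `intensity` (as
#'   returned by [simulate_trajectories()]), or a list of numeric vectors.
#' @param penalty change-point penalty multiplier (see [detect_steps()]).
#' @param min_dwell flanking-dwell rule for pooling (frames).
#' @param min_n minimum pool size for the fit.
#' @param label channel/protein label.
#' @return a `step_distribution` (see [fit_single_step_distribution()]),
#'   with the pooled values and censoring bound attached.
#' @examples
#' tr <- simulate_trajectories(rep(3, 60), photophysics(170.5, 99),
#'                             n_frames = 200, noise_sd = 25, seed = 1)
#' calibrate_single_step(tr, min_n = 50)
#' @export
calibrate_single_step <- function(traces, penalty = 2, min_dwell = 3,
                                  min_n = 50, label = NA_character_) {
  if (is.data.frame(traces)) {
    stopifnot(all(c("trace_id", "intensity") %in% names(traces)))
    traces <- split(traces$intensity, traces$trace_id)
  }
  stopifnot(is.list(traces))
  fits <- map(traces, detect_steps, penalty = penalty, min_dwell = 1)
  pool <- pool_single_steps(fits, min_dwell = min_dwell)
  fit_single_step_distribution(pool, doubles = TRUE, min_n = min_n,
                               label = label)
}
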