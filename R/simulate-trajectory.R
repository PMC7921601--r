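#' Simulate a photobleaching fluorescence trajectory
#'
#' Builds the per-frame intensity of one diffraction-limited focus containing
#' `n_fluors` fluorophores. Each fluorophore draws a constant emission level
#' from `N(step_mu, step_sigma)` truncated at zero, stays on until its
#' geometric bleach frame (derived from the exponential `bleach_rate`), then
#' contributes nothing; additive Gaussian noise is applied per frame. With
#' blinking enabled a fluorophore also toggles through reversible dark states.
#'
#' @param n_fluors number of fluorophores in the focus (>= 0).
#' @param phot a [photophysics()] object.
#' @param n_frames number of frames (>= 1).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param seed optional integer seed.
#' @return a tibble with columns `frame`, `intensity`, carrying attributes
#'   `truth` (a tibble with one row per fluorophore: `fluor`, `step_height`,
#'   `bleach_frame`) and `frame_interval`.
#' @examples
#' traj <- simulate_trajectory(3, photophysics(100, 0), 50, noise_sd = 0,
#'                             seed = 1)
#' attr(traj, "truth")
#' @export
simulate_trajectory <- function(n_fluors, phot, n_frames, noise_sd = 0,
                                seed = NULL) {
  check_number(n_fluors, "n_fluors", min = 0, integerish = TRUE)
  check_number(n_frames, "n_frames", min = 1, integerish = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  stopifnot(inherits(phot, "photophysics"))
  set_seed_if_given(seed)
  n_fluors <- as.integer(n_fluors)
  n_frames <- as.integer(n_frames)

  heights <- rnorm_truncated0(n_fluors, phot$step_mu, phot$step_sigma)
  p_frame <- 1 - exp(-phot$bleach_rate)
  ## bleach at the end of frame b: the fluorophore is visible in frames 1..b
  bleach <- if (n_fluors > 0) rgeom(n_fluors, p_frame) + 1L else integer(0)

  trace <- numeric(n_frames)
  for (i in seq_len(n_fluors)) {
    on <- fluor_on_frames(n_frames, bleach[i], phot)
    trace <- trace + heights[i] * on
  }
  if (noise_sd > 0) trace <- trace + rnorm(n_frames, 0, noise_sd)

  out <- tibble(frame = seq_len(n_frames), intensity = trace)
  attr(out, "truth") <- tibble(
    fluor = seq_len(n_fluors),
    step_height = heights,
    bleach_frame = bleach
  )
  attr(out, "frame_interval") <- 0.2
  out
}

## 0/1 emission indicator over frames 1..n for one fluorophore
fluor_on_frames <- function(n_frames, bleach_frame, phot) {
  on <- as.numeric(seq_len(n_frames) <= bleach_frame)
  if (!is.null(phot$blink_off) && phot$blink_off > 0) {
    p_off <- 1 - exp(-phot$blink_off)
    p_on <- 1 - exp(-(phot$blink_on %||% 0))
    state <- 1
    for (f in seq_len(min(bleach_frame, n_frames))) {
      on[f] <- on[f] * state
      state <- if (state == 1) {
        if (runif(1) < p_off) 0 else 1
      } else {
        if (runif(1) < p_on) 1 else 0
      }
    }
  }
  on
}

rnorm_truncated0 <- function(n, mu, sigma, lower = 0) {
  if (n == 0L) return(numeric(0))
  if (sigma == 0) return(rep(mu, n))
  ## inverse-CDF sampling of N(mu, sigma) truncated below at `lower`
  p_lo <- pnorm(lower, mu, sigma)
  qnorm(p_lo + runif(n) * (1 - p_lo), mu, sigma)
}

#' Simulate a batch of photobleaching trajectories
#'
#' Vectorised wrapper around [simulate_trajectory()]: one trajectory per
#' element of `n_fluors`, all sharing the same photophysics and noise level.
#'
#' @param n_fluors integer vector, fluorophore count per trajectory.
#' @param phot a [photophysics()] object.
#' @param n_frames frames per trajectory.
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param seed optional integer seed (one seed for the whole batch; traces
#'   consume independent portions of the stream).
#' @return a tibble with columns `trace_id`, `frame`, `intensity` and a
#'   `truth` attribute (tibble: `trace_id`, `fluor`, `step_height`,
#'   `bleach_frame`).
#' @export
simulate_trajectories <- function(n_fluors, phot, n_frames, noise_sd = 0,
                                  seed = NULL) {
  set_seed_if_given(seed)
  sims <- map(seq_along(n_fluors), function(i) {
    simulate_trajectory(n_fluors[i], phot, n_frames, noise_sd, seed = NULL)
  })
  traces <- list_rbind(imap(sims, function(s, i) {
    tibble(trace_id = i, frame = s$frame, intensity = s$intensity)
  }))
  truth <- list_rbind(imap(sims, function(s, i) {
    tr <- attr(s, "truth")
    if (nrow(tr) == 0) return(NULL)
    mutate(tr, trace_id = i, .before = 1)
  }))
  attr(traces, "truth") <- truth
  traces
}

#' Binomial thinning by fluorescent labeling efficiency
#'
#' Converts a true subunit count into the number of fluorescently labeled
#' subunits, each subunit carrying a dye independently with probability
#' `p_label` (the degree of labeling).
#'
#' @param true_count integer vector of true subunit counts.
#' @param p_label labeling probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return integer vector of labeled counts, elementwise `<= true_count`.
#' @examples
#' thin_by_labeling(c(10, 10, 10), p_label = 0.86, seed = 1)
#' @export
thin_by_labeling <- function(true_count, p_label, seed = NULL) {
  if (!is.numeric(true_count) || anyNA(true_count) || any(true_count < 0) ||
      any(abs(true_count - round(true_count)) > 1e-8)) {
    abort_bad_arg("`true_count` must be non-negative whole numbers.")
  }
  check_number(p_label, "p_label", min = 0, max = 1)
  set_seed_if_given(seed)
  rbinom(length(true_count), size = as.integer(round(true_count)),
         prob = p_label)
}
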