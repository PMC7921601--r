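#' Initial intensity of a trajectory
#'
#' The arithmetic mean of the first 20 frames. Frame averaging (rather than a
#' change-point plateau) is used because change-point fitting becomes
#' unreliable for foci with many fluorophores, while the first-frames mean
#' does not.
#'
#' @param traj numeric vector or data frame with an `intensity` column.
#' @param n_initial number of initial frames averaged (default 20).
#' @param first_change_point optional frame of the first detected
#'   photobleaching step (e.g. `detect_steps(traj)$change_points[1]`). When
#'   supplied and smaller than `n_initial`, the average stops there so that
#'   a fluorophore bleaching inside the averaging window does not drag the
#'   initial intensity down; with no early step this is exactly the plain
#'   `n_initial`-frame mean.
#' @return the initial intensity I0 (a.u.).
#' @examples
#' initial_intensity(c(rep(100, 10), rep(0, 30)), n_initial = 20)  # 50
#' @export
initial_intensity <- function(traj, n_initial = 20,
                              first_change_point = NULL) {
  x <- trajectory_intensity(traj)
  check_number(n_initial, "n_initial", min = 1, integerish = TRUE)
  if (length(x) < n_initial) {
    abort_bad_arg("trajectory has %d frames but the initial intensity requires the first %d frames.",
                  length(x), n_initial)
  }
  w <- n_initial
  if (!is.null(first_change_point) && length(first_change_point) == 1L &&
      is.finite(first_change_point)) {
    check_number(first_change_point, "first_change_point", min = 1,
                 integerish = TRUE)
    w <- min(w, as.integer(first_change_point))
  }
  mean(x[seq_len(w)])
}

#' Detect photobleaching steps by penalized change-point segmentation
#'
#' Fits a piecewise-constant model to a fluorescence trajectory by optimal
#' partitioning (exact dynamic programming over least-squares segment costs)
#' with a BIC-type penalty `penalty * sigma^2 * log(n)` per change point,
#' where `sigma` is a robust noise estimate from first differences. Segments
#' shorter than `min_dwell` are excluded during the recursion, and adjacent
#' plateaus whose level difference falls below `min_step` are merged
#' afterwards. On an exactly piecewise-constant trace the segmentation is
#' exact (zero residual) with the minimal number of change points.
#'
#' @param traj numeric vector or data frame with an `intensity` column.
#' @param penalty penalty strength multiplier (model-selection strength).
#' @param min_step smallest retained level change (a.u.); default half the
#'   robust noise sd of the trace.
#' @param min_dwell shortest allowed plateau (frames).
#' @return an object of class `step_fit`: list with `change_points` (last
#'   frame of each plateau except the final one), `levels` (plateau means),
#'   `dwells` (plateau lengths), `steps` (tibble: `change_point`,
#'   `step_height` positive for downward, `dwell_before`, `dwell_after`),
#'   `sigma` (robust noise sd), `residual_ss`, and the input trace.
#' @examples
#' fit <- detect_steps(c(rep(200, 50), rep(0, 50)))
#' fit$steps
#' @export
detect_steps <- function(traj, penalty = 2, min_step = NULL, min_dwell = 3) {
  x <- trajectory_intensity(traj)
  check_number(penalty, "penalty", min = 1e-9)
  check_number(min_dwell, "min_dwell", min = 1, integerish = TRUE)
  n <- length(x)
  if (n < 2 * min_dwell) {
    abort_bad_arg("trajectory needs at least 2 * min_dwell = %d frames.",
                  2 * min_dwell)
  }
  sigma <- robust_noise_sd(x)
  if (is.null(min_step)) min_step <- 0.5 * sigma
  check_number(min_step, "min_step", min = 0)

  ## penalty floor keeps the segmentation minimal on noise-free traces
  beta <- max(penalty * sigma^2 * log(n), 1e-8 * max(1, mean(x^2)))
  cps <- cpp_segment_trace(x, beta, as.integer(min_dwell))
  seg <- segment_summary(x, cps)

  ## merge level changes below min_step (smallest first, recompute levels)
  if (min_step > 0) {
    repeat {
      if (length(seg$levels) < 2) break
      dl <- abs(diff(seg$levels))
      if (all(dl >= min_step)) break
      drop <- which.min(dl)
      cps <- seg$change_points[-drop]
      seg <- segment_summary(x, cps)
    }
  }

  k <- length(seg$levels)
  steps <- if (k >= 2) {
    tibble(
      change_point = seg$change_points,
      step_height = -diff(seg$levels),
      dwell_before = seg$dwells[-k],
      dwell_after = seg$dwells[-1]
    )
  } else {
    tibble(change_point = integer(0), step_height = numeric(0),
           dwell_before = integer(0), dwell_after = integer(0))
  }

  structure(
    list(change_points = seg$change_points, levels = seg$levels,
         dwells = seg$dwells, steps = steps, sigma = sigma,
         residual_ss = seg$residual_ss, trace = x),
    class = "step_fit"
  )
}

segment_summary <- function(x, cps) {
  bounds <- c(0L, as.integer(cps), length(x))
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(x[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  dwells <- diff(bounds)
  fitted <- rep(levels, dwells)
  list(change_points = as.integer(cps), levels = levels, dwells = dwells,
       residual_ss = sum((x - fitted)^2))
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d frames, %d change points, sigma = %.2f a.u.\n",
              length(x$trace), length(x$change_points), x$sigma))
  if (nrow(x$steps)) print(x$steps, n = 5)
  invisible(x)
}

#' Pool single-photobleaching-step intensities from many trajectories
#'
#' Programmatic surrogate for the manual curation of trajectories with
#' distinct photobleaching events. A trajectory is accepted when (a) its
#' final plateau has returned to background (all fluorophores bleached) and
#' (b) it contains no upward step beyond the blinking threshold; from
#' accepted trajectories, a step contributes to the pool when it is downward,
#' larger than `step_floor` and flanked on both sides by plateaus dwelling at
#' least `min_dwell` frames (steps next to very short plateaus are
#' ambiguous splits of near-coincident bleaches).
#'
#' @param stepfits list of `step_fit` objects (or a single one).
#' @param min_dwell minimum flanking plateau dwell (frames).
#' @param step_floor smallest pooled step height (a.u.); default `2 *
#'   median(sigma)` over the trajectories. Recorded as the pool's censoring
#'   bound for downstream fitting.
#' @param final_level_tol tolerance for "final plateau at background", in
#'   units of the trace noise sd; default 5.
#' @return numeric vector of pooled step heights `I_s`, with attributes
#'   `lower_bound` (the censoring bound actually applied), `n_traces_used`
#'   and `n_traces_total`.
#' @export
pool_single_steps <- function(stepfits, min_dwell = 3, step_floor = NULL,
                              final_level_tol = 5) {
  if (inherits(stepfits, "step_fit")) stepfits <- list(stepfits)
  stopifnot(all(vapply(stepfits, inherits, TRUE, "step_fit")))
  check_number(min_dwell, "min_dwell", min = 1, integerish = TRUE)
  sigmas <- vapply(stepfits, function(f) f$sigma, numeric(1))
  if (is.null(step_floor)) step_floor <- 2 * median(sigmas)
  check_number(step_floor, "step_floor", min = 0)

  used <- 0L
  pool <- numeric(0)
  for (f in stepfits) {
    if (nrow(f$steps) == 0) next
    blink_thr <- max(0.5 * f$sigma, 1e-9)
    if (any(f$steps$step_height < -blink_thr)) next   # upward step: blinking
    final_tol <- final_level_tol * max(f$sigma, 1e-9)
    if (abs(f$levels[length(f$levels)]) > final_tol) next  # not fully bleached
    used <- used + 1L
    ok <- f$steps$step_height > step_floor &
      f$steps$dwell_before >= min_dwell &
      f$steps$dwell_after >= min_dwell
    pool <- c(pool, f$steps$step_height[ok])
  }
  attr(pool, "lower_bound") <- step_floor
  attr(pool, "n_traces_used") <- used
  attr(pool, "n_traces_total") <- length(stepfits)
  pool
}

#' Fit a Gaussian to pooled single-step intensities
#'
#' Maximum-likelihood Gaussian location/scale fit of the pooled `I_s`
#' values, reporting the mean single-photobleaching-event intensity
#' `I_s_mean`. Two refinements of the plain Gaussian fit are available:
#' a known left-censoring bound (`lower_bound`; the pool only contains steps
#' above its acceptance floor) and an unresolved-double component
#' (`doubles = TRUE`) modelling two fluorophores bleaching within the same
#' frame as `N(2 * mu, 2 * sigma^2)` with a free mixture weight, sharing
#' `(mu, sigma)` with the single-step component. With `lower_bound = 0` and
#' `doubles = FALSE` (the defaults) the fit reduces to the plain Gaussian
#' MLE (sample mean and sd).
#'
#' @param is_values numeric vector of pooled step heights; a `lower_bound`
#'   attribute (as set by [pool_single_steps()]) is honoured when the
#'   argument is left `NULL`.
#' @param lower_bound known left-censoring bound of the pool (a.u.).
#' @param doubles model an unresolved-double component.
#' @param min_n minimum pool size.
#' @param label channel/protein label carried through to the result.
#' @return an object of class `step_distribution`: list with `I_s_mean`,
#'   `I_s_sigma`, `n`, `single_weight`, `lower_bound`, `label`, `values`.
#' @export
fit_single_step_distribution <- function(is_values, lower_bound = NULL,
                                         doubles = FALSE, min_n = 50,
                                         label = NA_character_) {
  check_number(min_n, "min_n", min = 1, integerish = TRUE)
  if (is.null(lower_bound)) {
    lower_bound <- attr(is_values, "lower_bound") %||% 0
  }
  check_number(lower_bound, "lower_bound", min = 0)
  v <- as.numeric(is_values)
  v <- v[!is.na(v)]
  if (length(v) < min_n) {
    abort_bad_arg("need at least %d pooled step values, got %d.",
                  min_n, length(v))
  }

  if (sd(v) < 1e-12) {
    ## degenerate pool: all values identical
    fit <- list(mu = v[1], sigma = 0, w = 1)
  } else if (!doubles && lower_bound <= 0) {
    fit <- list(mu = mean(v), sigma = sqrt(mean((v - mean(v))^2)), w = 1)
  } else {
    fit <- fit_censored_gaussian(v, lower_bound, doubles)
  }

  structure(
    list(I_s_mean = fit$mu, I_s_sigma = fit$sigma, n = length(v),
         single_weight = fit$w, lower_bound = lower_bound,
         doubles = doubles, label = label, values = v),
    class = "step_distribution"
  )
}

## ML fit of a Gaussian (optionally + an unresolved-double component at
## (2 mu, sqrt(2) sigma) with shared parameters), left-censored at L.
fit_censored_gaussian <- function(v, L, doubles) {
  nll <- function(p) {
    mu <- p[1]
    sg <- exp(p[2])
    w <- if (doubles) stats::plogis(p[3]) else 1
    if (!is.finite(mu) || mu <= 0 || !is.finite(sg)) return(1e12)
    z1 <- pnorm(L, mu, sg, lower.tail = FALSE)
    z2 <- if (doubles) pnorm(L, 2 * mu, sqrt(2) * sg, lower.tail = FALSE) else 0
    denom <- w * z1 + (1 - w) * z2
    if (denom <= 0) return(1e12)
    d <- w * dnorm(v, mu, sg)
    if (doubles) d <- d + (1 - w) * dnorm(v, 2 * mu, sqrt(2) * sg)
    -sum(log(pmax(d / denom, 1e-300)))
  }
  starts <- list(
    c(median(v), log(max(mad(v), 1e-6))),
    c(stats::quantile(v, 0.4), log(max(mad(v) * 0.8, 1e-6))),
    c(mean(v) / 1.2, log(max(sd(v) * 0.7, 1e-6)))
  )
  if (doubles) starts <- map(starts, ~ c(.x, stats::qlogis(0.93)))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(as.numeric(st), nll, method = "Nelder-Mead",
            control = list(maxit = 3000)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort_bad_arg("Gaussian fit failed to converge.")
  list(mu = best$par[1], sigma = exp(best$par[2]),
       w = if (doubles) stats::plogis(best$par[3]) else 1)
}

#' @export
print.step_distribution <- function(x, ...) {
  cat(sprintf("<step_distribution>%s I_s_mean = %.1f a.u., sigma = %.1f a.u., n = %d\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$I_s_mean, x$I_s_sigma, x$n))
  invisible(x)
}

#' Fluorescently labeled proteins per point (FPP)
#'
#' `FPP = I_0 / I_s_mean`, converted to an integer subunit count by rounding
#' half up and clamping at a minimum of 1 (a detected focus implies at least
#' one fluorophore). Counts above `max_subunits` (default 20, where
#' self-quenching makes intensities unreliable) are retained but flagged
#' `excluded`.
#'
#' @param I_0 initial intensity (a.u.), scalar or vector.
#' @param dist a `step_distribution` (or a single positive number used
#'   directly as `I_s_mean`).
#' @param max_subunits exclusion threshold on the subunit count.
#' @return tibble with `I_0`, `fpp`, `subunit_count`, `excluded`.
#' @examples
#' compute_fpp(852.5, 170.5)   # FPP = 5, count 5
#' @export
compute_fpp <- function(I_0, dist, max_subunits = 20) {
  if (inherits(dist, "step_distribution")) dist <- dist$I_s_mean
  check_number(dist, "I_s_mean", min = 1e-12)
  check_number(max_subunits, "max_subunits", min = 1, integerish = TRUE)
  if (!is.numeric(I_0) || anyNA(I_0)) {
    abort_bad_arg("`I_0` must be numeric and non-missing.")
  }
  fpp <- I_0 / dist
  count <- pmax(1L, as.integer(floor(fpp + 0.5)))
  tibble(
    I_0 = as.numeric(I_0),
    fpp = fpp,
    subunit_count = count,
    excluded = count > max_subunits
  )
}

#' Proximity-ratio FRET trace from donor and acceptor trajectories
#'
#' Corrects the acceptor for donor leakage (`A' = A - alpha * D`) and
#' computes the apparent FRET efficiency `E = A' / (A' + D)` per frame,
#' clipped to `[0, 1]`. Frames with non-positive total corrected intensity
#' are flagged invalid. E is a proximity ratio, not a gamma-corrected,
#' distance-calibrated efficiency.
#'
#' @param donor,acceptor numeric vectors or data frames with `intensity`.
#' @param alpha donor leakage fraction into the acceptor channel, `[0, 1)`.
#' @return tibble with `frame`, `donor`, `acceptor`, `acceptor_corrected`,
#'   `E`, `valid`.
#' @examples
#' fret_trace(donor = c(100, 100), acceptor = c(100, 300), alpha = 0)
#' @export
fret_trace <- function(donor, acceptor, alpha = 0) {
  d <- trajectory_intensity(donor)
  a <- trajectory_intensity(acceptor)
  if (length(d) != length(a)) {
    abort_bad_arg("donor (%d frames) and acceptor (%d frames) lengths differ.",
                  length(d), length(a))
  }
  check_number(alpha, "alpha", min = 0, max = 1 - 1e-12)
  a_corr <- a - alpha * d
  tot <- a_corr + d
  valid <- tot > 0
  E <- ifelse(valid, pmin(pmax(a_corr / tot, 0), 1), NA_real_)
  tibble(frame = seq_along(d), donor = d, acceptor = a,
         acceptor_corrected = a_corr, E = E, valid = valid)
}
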