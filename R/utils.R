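## internal argument checking helpers --------------------------------------

abort_bad_arg <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "smstoich_argument_error")
}

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_bad_arg("`%s` must be a single non-missing number.", name)
  }
  if (x < min || x > max) {
    abort_bad_arg("`%s` must be in [%s, %s], got %s.", name,
                  format(min), format(max), format(x))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_bad_arg("`%s` must be a whole number, got %s.", name, format(x))
  }
  invisible(x)
}

check_probability_vector <- function(p, name) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0)) {
    abort_bad_arg("`%s` must be a non-negative probability vector.", name)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort_bad_arg("`%s` must sum to 1 (got %.6f).", name, sum(p))
  }
  invisible(p)
}

set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    check_number(seed, "seed", integerish = TRUE)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

## robust per-frame noise scale from first differences; steps occupy few
## frames so the median absolute first difference is noise-dominated
robust_noise_sd <- function(x) {
  d <- diff(x)
  if (length(d) == 0L) return(0)
  median(abs(d)) / (0.6744898 * sqrt(2))
}

#' Extract the intensity vector from a trajectory input
#'
#' Accepts a numeric vector, or a data frame with an `intensity` column
#' (ordered by `frame` when present).
#' @param traj numeric vector or data frame.
#' @return numeric vector of per-frame intensities.
#' @keywords internal
trajectory_intensity <- function(traj) {
  if (is.numeric(traj)) return(as.numeric(traj))
  if (is.data.frame(traj)) {
    if (!"intensity" %in% names(traj)) {
      abort_bad_arg("trajectory data frame must have an `intensity` column.")
    }
    if ("frame" %in% names(traj)) traj <- traj[order(traj$frame), ]
    return(as.numeric(traj$intensity))
  }
  abort_bad_arg("trajectory must be a numeric vector or a data frame.")
}
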