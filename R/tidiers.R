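#' Tidy a step fit
#'
#' One row per detected photobleaching step.
#' @param x a `step_fit`.
#' @param ... unused.
#' @return tibble with `change_point`, `step_height`, `dwell_before`,
#'   `dwell_after`.
#' @export
tidy.step_fit <- function(x, ...) x$steps

#' @rdname tidy.step_fit
#' @return for `glance()`: one-row tibble with `n_frames`, `n_steps`,
#'   `sigma`, `residual_ss`, `final_level`.
#' @export
glance.step_fit <- function(x, ...) {
  tibble(
    n_frames = length(x$trace),
    n_steps = nrow(x$steps),
    sigma = x$sigma,
    residual_ss = x$residual_ss,
    final_level = x$levels[length(x$levels)]
  )
}

#' Tidy a single-step intensity distribution
#' @param x a `step_distribution`.
#' @param ... unused.
#' @return one row per pooled I_s value.
#' @export
tidy.step_distribution <- function(x, ...) {
  tibble(I_s = x$values)
}

#' @rdname tidy.step_distribution
#' @export
glance.step_distribution <- function(x, ...) {
  tibble(I_s_mean = x$I_s_mean, I_s_sigma = x$I_s_sigma, n = x$n,
         single_weight = x$single_weight, lower_bound = x$lower_bound,
         label = x$label)
}

#' Tidy a one-phase association fit
#' @param x a `one_phase_fit`.
#' @param ... unused.
#' @return tibble with `term` and `estimate` (y0, plateau, k).
#' @export
tidy.one_phase_fit <- function(x, ...) {
  tibble(term = c("y0", "plateau", "k"),
         estimate = c(x$y0, x$plateau, x$k))
}

#' @rdname tidy.one_phase_fit
#' @export
glance.one_phase_fit <- function(x, ...) {
  tibble(y0 = x$y0, plateau = x$plateau, k = x$k,
         residual_sd = x$residual_sd, n = x$n)
}

#' Tidy a size-distribution comparison
#' @param x a `size_comparison`.
#' @param ... unused.
#' @return the pairwise Dunn test table.
#' @export
tidy.size_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.size_comparison
#' @export
glance.size_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         method = x$method)
}

#' Tidy an abundance heatmap
#' @param x an `abundance_heatmap`.
#' @param ... unused.
#' @return long tibble with `n_client`, `n_chaperone`, `abundance`.
#' @export
tidy.abundance_heatmap <- function(x, ...) {
  m <- x$matrix
  tibble(
    n_client = rep(seq_len(nrow(m)), times = ncol(m)),
    n_chaperone = rep(seq_len(ncol(m)), each = nrow(m)),
    abundance = as.vector(m)
  )
}
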