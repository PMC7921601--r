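#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Values are rounded and clamped to the 16-bit range; one page per frame.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  pages <- map(seq_len(d[1]), function(f) {
    m <- stack$frames[f, , ]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param frame_interval seconds per frame.
#' @param channel channel label.
#' @return an [image_stack()] with intensities on the original 0-65535 scale.
#' @export
read_image_stack <- function(path, frame_interval = 0.2, channel = "A") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (f in seq_along(pages)) frames[f, , ] <- pages[[f]] * 65535
  image_stack(frames, frame_interval, channel)
}

#' Write per-focus trajectories to CSV
#'
#' @param traces tibble with at least `trace_id`/`focus_id`, `frame`,
#'   `intensity`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read per-focus trajectories from CSV
#'
#' @param path CSV path as written by [write_trajectories_csv()].
#' @return a tibble.
#' @export
read_trajectories_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a single-step distribution as JSON
#'
#' Serialises the fit summary (`I_s_mean`, `I_s_sigma`, `n`,
#' `single_weight`, `lower_bound`, `label`), not the raw pool.
#'
#' @param dist a `step_distribution`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_step_distribution_json <- function(dist, path) {
  stopifnot(inherits(dist, "step_distribution"))
  jsonlite::write_json(
    list(I_s_mean = dist$I_s_mean, I_s_sigma = dist$I_s_sigma, n = dist$n,
         single_weight = dist$single_weight, lower_bound = dist$lower_bound,
         label = dist$label),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
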