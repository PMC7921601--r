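#' Render a synthetic two-channel single-molecule movie
#'
#' Renders a population of surface-immobilized complexes as diffraction-
#' limited foci in two spectrally separate channels. Channel A carries the
#' client fluorophores (`n_client` per focus), channel B the chaperone
#' fluorophores (`n_chaperone`). Each focus gets an independent
#' photobleaching trajectory per channel (see [simulate_trajectory()]) and is
#' rendered as a pixel-integrated 2-D Gaussian PSF scaled by the
#' instantaneous trajectory value; the camera then applies flat-field gain,
#' electronic offset and Gaussian read noise. Foci are immobilized (no
#' diffusion), matching a surface-tethered assay.
#'
#' @param complexes data frame with columns `n_client` and `n_chaperone`
#'   (counts of labeled subunits per focus) and optionally `row`, `col`
#'   (pixel positions, 1-based, sub-pixel allowed). Missing positions are
#'   sampled uniformly with a minimum separation of `4 * psf_sigma` unless
#'   `allow_overlap`.
#' @param phot_a,phot_b [photophysics()] for channels A and B.
#' @param camera a [camera_model()].
#' @param n_frames frames to render.
#' @param allow_overlap permit foci closer than the minimum separation.
#' @param seed optional integer seed.
#' @return an object of class `two_color_movie`: list with `channel_a`,
#'   `channel_b` ([image_stack()]s), `truth` (list of tibbles: `foci` with
#'   positions and true counts, `fluors` with per-fluorophore step heights
#'   and bleach frames, `trajectories` with noise-free per-focus traces) and
#'   `camera`.
#' @export
render_two_color_movie <- function(complexes, phot_a, phot_b, camera,
                                   n_frames, allow_overlap = FALSE,
                                   seed = NULL) {
  stopifnot(inherits(phot_a, "photophysics"),
            inherits(phot_b, "photophysics"),
            inherits(camera, "camera_model"))
  check_number(n_frames, "n_frames", min = 1, integerish = TRUE)
  if (!is.data.frame(complexes) ||
      !all(c("n_client", "n_chaperone") %in% names(complexes))) {
    abort_bad_arg("`complexes` needs columns n_client and n_chaperone.")
  }
  set_seed_if_given(seed)
  n_frames <- as.integer(n_frames)
  n_foci <- nrow(complexes)
  margin <- ceiling(4 * camera$psf_sigma) + 3

  if (!all(c("row", "col") %in% names(complexes))) {
    pos <- sample_positions(n_foci, camera$nrow, camera$ncol, margin,
                            min_sep = 4 * camera$psf_sigma,
                            allow_overlap = allow_overlap)
    complexes$row <- pos$row
    complexes$col <- pos$col
  }
  if (any(complexes$row < 1 | complexes$row > camera$nrow |
          complexes$col < 1 | complexes$col > camera$ncol)) {
    abort_bad_arg("focus positions must lie inside the %d x %d pixel grid.",
                  camera$nrow, camera$ncol)
  }

  sig_a <- array(0, dim = c(n_frames, camera$nrow, camera$ncol))
  sig_b <- sig_a
  fluors <- list()
  trajs <- list()

  for (i in seq_len(n_foci)) {
    for (ch in c("A", "B")) {
      k <- if (ch == "A") complexes$n_client[i] else complexes$n_chaperone[i]
      phot <- if (ch == "A") phot_a else phot_b
      tr <- simulate_trajectory(k, phot, n_frames, noise_sd = 0)
      tt <- attr(tr, "truth")
      if (nrow(tt) > 0) {
        fluors[[length(fluors) + 1L]] <-
          mutate(tt, focus_id = i, channel = ch, .before = 1)
      }
      trajs[[length(trajs) + 1L]] <-
        tibble(focus_id = i, channel = ch, frame = tr$frame,
               intensity = tr$intensity)
      if (any(tr$intensity != 0)) {
        ker <- psf_kernel(complexes$row[i], complexes$col[i],
                          camera$psf_sigma, camera$nrow, camera$ncol)
        tgt <- if (ch == "A") "sig_a" else "sig_b"
        acc <- get(tgt)
        for (f in which(tr$intensity != 0)) {
          acc[f, ker$rows, ker$cols] <- acc[f, ker$rows, ker$cols] +
            tr$intensity[f] * ker$weights
        }
        assign(tgt, acc)
      }
    }
  }

  stack_a <- apply_camera(sig_a, camera)
  stack_b <- apply_camera(sig_b, camera)

  structure(
    list(
      channel_a = image_stack(stack_a, channel = "A"),
      channel_b = image_stack(stack_b, channel = "B"),
      truth = list(
        foci = tibble(focus_id = seq_len(n_foci),
                      row = complexes$row, col = complexes$col,
                      n_client = as.integer(complexes$n_client),
                      n_chaperone = as.integer(complexes$n_chaperone)),
        fluors = if (length(fluors)) list_rbind(fluors) else
          tibble(focus_id = integer(0), channel = character(0),
                 fluor = integer(0), step_height = numeric(0),
                 bleach_frame = integer(0)),
        trajectories = list_rbind(trajs)
      ),
      camera = camera
    ),
    class = "two_color_movie"
  )
}

#' @export
print.two_color_movie <- function(x, ...) {
  cat(sprintf("<two_color_movie> %d foci, %d frames, %d x %d px\n",
              nrow(x$truth$foci), dim(x$channel_a)[1],
              x$camera$nrow, x$camera$ncol))
  invisible(x)
}

## pixel-integrated Gaussian PSF restricted to a +/- 5 sigma window;
## weights integrate to ~1 over the full grid (edge truncation aside)
psf_kernel <- function(row, col, sigma, nrow, ncol) {
  half <- ceiling(5 * sigma)
  rows <- max(1, floor(row) - half):min(nrow, ceiling(row) + half)
  cols <- max(1, floor(col) - half):min(ncol, ceiling(col) + half)
  wr <- pnorm(rows + 0.5, row, sigma) - pnorm(rows - 0.5, row, sigma)
  wc <- pnorm(cols + 0.5, col, sigma) - pnorm(cols - 0.5, col, sigma)
  list(rows = rows, cols = cols, weights = outer(wr, wc))
}

sample_positions <- function(n, nrow, ncol, margin, min_sep,
                             allow_overlap = FALSE, max_tries = 20000) {
  rows <- numeric(0)
  cols <- numeric(0)
  tries <- 0
  while (length(rows) < n) {
    r <- runif(1, margin, nrow - margin)
    c <- runif(1, margin, ncol - margin)
    ok <- allow_overlap || length(rows) == 0 ||
      all((rows - r)^2 + (cols - c)^2 >= min_sep^2)
    if (ok) {
      rows <- c(rows, r)
      cols <- c(cols, c)
    }
    tries <- tries + 1
    if (tries > max_tries) {
      abort_bad_arg("could not place %d foci with min separation %.1f px on a %d x %d grid.",
                    n, min_sep, nrow, ncol)
    }
  }
  list(row = rows, col = cols)
}

apply_camera <- function(signal, camera) {
  n_frames <- dim(signal)[1]
  out <- signal
  for (f in seq_len(n_frames)) {
    fr <- camera$offset + camera$flatfield * signal[f, , ]
    if (camera$read_noise_sd > 0) {
      fr <- fr + matrix(rnorm(length(fr), 0, camera$read_noise_sd),
                        nrow(fr), ncol(fr))
    }
    out[f, , ] <- fr
  }
  out
}
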