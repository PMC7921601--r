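#' Fluorophore photophysics parameters
#'
#' Describes the generative model for a single fluorophore: its emission
#' intensity is drawn once from `N(step_mu, step_sigma)` truncated at zero and
#' held constant until it photobleaches; the bleach frame is geometric,
#' derived from a continuous exponential rate per frame. Optional two-state
#' blinking (off by default) models reversible dark states; the experiments
#' this emulates suppress blinking with an oxygen scavenger system.
#'
#' @param step_mu mean single-fluorophore intensity (a.u.), > 0.
#' @param step_sigma standard deviation of per-fluorophore intensity (a.u.).
#' @param bleach_rate exponential bleaching rate per frame (1/frame); the
#'   per-frame bleaching probability is `1 - exp(-bleach_rate)`.
#' @param blink_on rate (1/frame) of dark -> emitting recovery; `NULL`
#'   disables blinking.
#' @param blink_off rate (1/frame) of emitting -> dark transitions; `NULL`
#'   disables blinking.
#' @return an object of class `photophysics`.
#' @examples
#' photophysics(step_mu = 170.5, step_sigma = 99, bleach_rate = 1/30)
#' @export
photophysics <- function(step_mu, step_sigma, bleach_rate = 1 / 30,
                         blink_on = NULL, blink_off = NULL) {
  check_number(step_mu, "step_mu", min = 1e-12)
  check_number(step_sigma, "step_sigma", min = 0)
  check_number(bleach_rate, "bleach_rate", min = 1e-12)
  p_frame <- 1 - exp(-bleach_rate)
  if (p_frame <= 0 || p_frame >= 1) {
    abort_bad_arg("bleach_rate must give a per-frame probability in (0, 1).")
  }
  blinking <- !is.null(blink_on) || !is.null(blink_off)
  if (blinking) {
    check_number(blink_on %||% 0, "blink_on", min = 0)
    check_number(blink_off %||% 0, "blink_off", min = 0)
  }
  structure(
    list(step_mu = step_mu, step_sigma = step_sigma,
         bleach_rate = bleach_rate,
         blink_on = if (blinking) blink_on %||% 0 else NULL,
         blink_off = if (blinking) blink_off %||% 0 else NULL),
    class = "photophysics"
  )
}

#' @export
print.photophysics <- function(x, ...) {
  cat(sprintf("<photophysics> step_mu = %g a.u., step_sigma = %g a.u., bleach_rate = %g /frame%s\n",
              x$step_mu, x$step_sigma, x$bleach_rate,
              if (is.null(x$blink_off)) "" else ", blinking on"))
  invisible(x)
}

#' Two-step sHsp-client binding kinetics configuration
#'
#' Parameters of the stochastic two-step assembly mechanism: free sHsp seed
#' species (monomers to trimers) first capture free misfolded client
#' oligomers; captured complexes then accrete further sHsp subunits from the
#' free pool (and may lose them) until the system equilibrates. Only a
#' fraction `plateau_bound_fraction` of clients is capture-competent, so the
#' expected bound-client fraction follows the one-phase association curve
#' `plateau_bound_fraction * (1 - exp(-k_bind * t))`.
#'
#' @param client_oligomer_dist probabilities of client oligomer sizes
#'   `1..length(client_oligomer_dist)`; sizes are drawn once per client and
#'   frozen (aggregation is arrested by the chaperone).
#' @param shsp_seed_dist probabilities of the initially binding sHsp species
#'   sizes (default mass on monomers-trimers).
#' @param k_bind per-client capture rate (1/h).
#' @param k_accrete per-complex subunit addition rate at a full free pool
#'   (1/h); scaled by the instantaneous free-pool fraction.
#' @param k_off per-excess-subunit dissociation rate (1/h); complexes never
#'   drop below one bound sHsp subunit.
#' @param molar_ratio sHsp:client subunit molar ratio; sets the size of the
#'   free sHsp subunit pool.
#' @param plateau_bound_fraction equilibrium fraction of clients in complex.
#' @return an object of class `binding_kinetics`.
#' @examples
#' binding_kinetics(k_bind = 1.5, plateau_bound_fraction = 0.5)
#' @export
binding_kinetics <- function(client_oligomer_dist = default_client_dist(),
                             shsp_seed_dist = c(0.50, 0.35, 0.15),
                             k_bind = 1.5, k_accrete = 1.0, k_off = 0.2,
                             molar_ratio = 2, plateau_bound_fraction = 0.5) {
  check_probability_vector(client_oligomer_dist, "client_oligomer_dist")
  check_probability_vector(shsp_seed_dist, "shsp_seed_dist")
  check_number(k_bind, "k_bind", min = 0)
  check_number(k_accrete, "k_accrete", min = 0)
  check_number(k_off, "k_off", min = 0)
  check_number(molar_ratio, "molar_ratio", min = 0)
  check_number(plateau_bound_fraction, "plateau_bound_fraction",
               min = 0, max = 1)
  structure(
    list(client_oligomer_dist = client_oligomer_dist,
         shsp_seed_dist = shsp_seed_dist,
         k_bind = k_bind, k_accrete = k_accrete, k_off = k_off,
         molar_ratio = molar_ratio,
         plateau_bound_fraction = plateau_bound_fraction),
    class = "binding_kinetics"
  )
}

#' Default client oligomer size distribution
#'
#' A geometric-decay distribution over sizes 1-12 (most clients monomeric or
#' small oligomers, rare species up to 12-mers), matching the observed range
#' of client subunits within complexes.
#' @param decay geometric decay factor per additional subunit.
#' @param max_size largest client oligomer.
#' @return numeric probability vector over sizes `1:max_size`.
#' @export
default_client_dist <- function(decay = 0.55, max_size = 12) {
  w <- decay^(seq_len(max_size) - 1)
  w / sum(w)
}

#' @export
print.binding_kinetics <- function(x, ...) {
  cat(sprintf(paste0("<binding_kinetics> k_bind = %g/h, k_accrete = %g/h, ",
                     "k_off = %g/h, molar_ratio = %g, plateau = %g\n"),
              x$k_bind, x$k_accrete, x$k_off, x$molar_ratio,
              x$plateau_bound_fraction))
  invisible(x)
}

#' EMCCD-like camera model
#'
#' Additive-Gaussian camera for movie rendering: recorded value =
#' `offset + flatfield * signal + N(0, read_noise_sd)`. The flat-field map
#' models excitation-beam inhomogeneity (vignetting); `correct_stack()`
#' inverts offset and flat field exactly in the noise-free case.
#'
#' @param nrow,ncol pixel grid dimensions.
#' @param offset electronic offset (a.u.).
#' @param read_noise_sd Gaussian read noise sd (a.u.).
#' @param psf_sigma Gaussian PSF sd in pixels.
#' @param flatfield per-pixel gain matrix (strictly positive, mean ~1);
#'   default uniform.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(nrow = 128, ncol = 128, offset = 100,
                         read_noise_sd = 10, psf_sigma = 1.3,
                         flatfield = NULL) {
  check_number(nrow, "nrow", min = 4, integerish = TRUE)
  check_number(ncol, "ncol", min = 4, integerish = TRUE)
  check_number(offset, "offset", min = 0)
  check_number(read_noise_sd, "read_noise_sd", min = 0)
  check_number(psf_sigma, "psf_sigma", min = 1e-6)
  if (is.null(flatfield)) {
    flatfield <- matrix(1, nrow, ncol)
  }
  if (!is.matrix(flatfield) || any(dim(flatfield) != c(nrow, ncol))) {
    abort_bad_arg("flatfield must be a %d x %d matrix.", nrow, ncol)
  }
  if (any(flatfield <= 0)) {
    abort_bad_arg("flatfield must be strictly positive.")
  }
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol), offset = offset,
         read_noise_sd = read_noise_sd, psf_sigma = psf_sigma,
         flatfield = flatfield),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %d x %d px, offset = %g, read noise sd = %g, psf sigma = %g px\n",
              x$nrow, x$ncol, x$offset, x$read_noise_sd, x$psf_sigma))
  invisible(x)
}

#' Construct an image stack
#'
#' A light wrapper around a 3-D array with dimensions (frame, row, col).
#'
#' @param frames 3-D numeric array `[frame, row, col]` (a 2-D matrix is
#'   treated as a single frame).
#' @param frame_interval seconds between frames (default 0.2 s, i.e. 5 Hz).
#' @param channel channel label.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval = 0.2, channel = "A") {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, nrow(frames), ncol(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L || dim(frames)[1] < 1L) {
    abort_bad_arg("frames must be a [frame, row, col] array with >= 1 frame.")
  }
  check_number(frame_interval, "frame_interval", min = 1e-9)
  structure(
    list(frames = frames, frame_interval = frame_interval,
         channel = as.character(channel)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> channel %s: %d frames of %d x %d px (%g s/frame)\n",
              x$channel, d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)
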