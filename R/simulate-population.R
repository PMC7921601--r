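#' Simulate a population of chaperone-client complexes over time
#'
#' Exact event-driven (Gillespie) simulation of the two-step binding
#' mechanism. Free sHsp seed species (sizes drawn from `shsp_seed_dist`)
#' capture capture-competent free clients at rate `k_bind` per client; bound
#' complexes then accrete single sHsp subunits from the well-mixed,
#' depletable free pool at rate `k_accrete * free_pool_fraction` per complex
#' and lose excess subunits at `k_off` per subunit above one. Each client is
#' independently capture-competent with probability `plateau_bound_fraction`,
#' so the expected bound-client fraction is
#' `plateau_bound_fraction * (1 - exp(-k_bind * t))` - one-phase association.
#'
#' @param cfg a [binding_kinetics()] configuration.
#' @param timepoints sorted non-negative times (hours) at which to snapshot
#'   the population.
#' @param n_clients number of client oligomers in the system.
#' @param seed optional integer seed.
#' @return an object of class `complex_population`: a list with
#'   * `complexes`: tibble (`time`, `complex_id`, `n_client`, `n_chaperone`),
#'   * `free_clients`: tibble (`time`, `client_id`, `size`),
#'   * `free_shsp_subunits`: tibble (`time`, `subunits`),
#'   * `bound_fraction`: tibble (`time`, `fraction`),
#'   * `config`, `n_clients`.
#' @examples
#' pop <- simulate_complex_population(binding_kinetics(), c(0, 1, 4, 10),
#'                                    n_clients = 100, seed = 1)
#' pop$bound_fraction
#' @export
simulate_complex_population <- function(cfg, timepoints, n_clients,
                                        seed = NULL) {
  stopifnot(inherits(cfg, "binding_kinetics"))
  if (length(timepoints) == 0) {
    abort_bad_arg("`timepoints` must contain at least one time.")
  }
  if (anyNA(timepoints) || any(timepoints < 0) || is.unsorted(timepoints)) {
    abort_bad_arg("`timepoints` must be sorted and non-negative.")
  }
  check_number(n_clients, "n_clients", min = 1, integerish = TRUE)
  set_seed_if_given(seed)
  n_clients <- as.integer(n_clients)

  sizes <- sample.int(length(cfg$client_oligomer_dist), n_clients,
                      replace = TRUE, prob = cfg$client_oligomer_dist)
  competent <- runif(n_clients) < cfg$plateau_bound_fraction
  s_total <- max(1L, as.integer(round(cfg$molar_ratio * sum(sizes))))
  s_free <- s_total

  free_ids <- which(competent)           # capture-eligible free clients
  incompetent_ids <- which(!competent)
  cx_client <- integer(0)                # client oligomer size per complex
  cx_chap <- integer(0)                  # bound sHsp subunits per complex
  cx_of_client <- integer(0)             # originating client id

  t_now <- 0
  t_end <- max(timepoints)
  snapshots <- vector("list", length(timepoints))
  snap_idx <- 1L

  take_snapshots_until <- function(t_next) {
    while (snap_idx <= length(timepoints) && timepoints[snap_idx] <= t_next) {
      snapshots[[snap_idx]] <<- list(
        time = timepoints[snap_idx],
        cx_client = cx_client, cx_chap = cx_chap,
        cx_of_client = cx_of_client,
        free_ids = c(free_ids, incompetent_ids),
        s_free = s_free
      )
      snap_idx <<- snap_idx + 1L
    }
  }

  repeat {
    r_capture <- if (s_free > 0) cfg$k_bind * length(free_ids) else 0
    r_accrete <- if (s_free > 0) {
      cfg$k_accrete * (s_free / s_total) * length(cx_chap)
    } else 0
    r_off <- cfg$k_off * sum(pmax(cx_chap - 1L, 0L))
    r_tot <- r_capture + r_accrete + r_off
    if (r_tot <= 0) {
      take_snapshots_until(t_end)
      break
    }
    dt <- rexp(1, r_tot)
    if (t_now + dt > t_end) {
      take_snapshots_until(t_end)
      break
    }
    take_snapshots_until(t_now + dt)
    t_now <- t_now + dt

    u <- runif(1) * r_tot
    if (u < r_capture) {
      pick <- sample.int(length(free_ids), 1L)
      cid <- free_ids[pick]
      free_ids <- free_ids[-pick]
      seed_size <- sample.int(length(cfg$shsp_seed_dist), 1L,
                              prob = cfg$shsp_seed_dist)
      seed_size <- min(seed_size, s_free)
      s_free <- s_free - seed_size
      cx_client <- c(cx_client, sizes[cid])
      cx_chap <- c(cx_chap, seed_size)
      cx_of_client <- c(cx_of_client, cid)
    } else if (u < r_capture + r_accrete) {
      pick <- sample.int(length(cx_chap), 1L)
      cx_chap[pick] <- cx_chap[pick] + 1L
      s_free <- s_free - 1L
    } else {
      excess <- pmax(cx_chap - 1L, 0L)
      pick <- sample.int(length(cx_chap), 1L, prob = excess)
      cx_chap[pick] <- cx_chap[pick] - 1L
      s_free <- s_free + 1L
    }
  }

  complexes <- list_rbind(map(snapshots, function(s) {
    if (length(s$cx_client) == 0) {
      return(tibble(time = numeric(0), complex_id = integer(0),
                    n_client = integer(0), n_chaperone = integer(0)))
    }
    tibble(time = s$time, complex_id = seq_along(s$cx_client),
           n_client = as.integer(s$cx_client),
           n_chaperone = as.integer(s$cx_chap))
  }))
  free_clients <- list_rbind(map(snapshots, function(s) {
    tibble(time = s$time, client_id = s$free_ids,
           size = as.integer(sizes[s$free_ids]))
  }))
  free_shsp <- list_rbind(map(snapshots, function(s) {
    tibble(time = s$time, subunits = as.integer(s$s_free))
  }))
  bound <- list_rbind(map(snapshots, function(s) {
    tibble(time = s$time,
           fraction = length(s$cx_client) / n_clients)
  }))

  structure(
    list(complexes = complexes, free_clients = free_clients,
         free_shsp_subunits = free_shsp, bound_fraction = bound,
         config = cfg, n_clients = n_clients),
    class = "complex_population"
  )
}

#' @export
print.complex_population <- function(x, ...) {
  cat(sprintf("<complex_population> %d clients, %d timepoints, final bound fraction %.3f\n",
              x$n_clients, nrow(x$bound_fraction),
              x$bound_fraction$fraction[nrow(x$bound_fraction)]))
  invisible(x)
}

#' @describeIn simulate_complex_population tidy accessor: the per-timepoint
#'   complex stoichiometry table.
#' @param x a `complex_population`.
#' @param ... unused.
#' @export
tidy.complex_population <- function(x, ...) x$complexes

#' Sample a colocalization timecourse from a population simulation
#'
#' Emulates the experimental readout of colocalization kinetics: at each
#' snapshot an aliquot of `n_molecules` client molecules is scored for being
#' in complex, so each observed fraction carries binomial counting noise
#' around the simulated bound fraction.
#'
#' @param pop a `complex_population`.
#' @param n_molecules molecules scored per timepoint.
#' @param seed optional integer seed.
#' @return tibble with columns `time` (h) and `percent` (0-100).
#' @export
sample_colocalized_fraction <- function(pop, n_molecules = 500, seed = NULL) {
  stopifnot(inherits(pop, "complex_population"))
  check_number(n_molecules, "n_molecules", min = 1, integerish = TRUE)
  set_seed_if_given(seed)
  f <- pop$bound_fraction
  tibble(
    time = f$time,
    percent = 100 * rbinom(nrow(f), n_molecules, f$fraction) / n_molecules
  )
}
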