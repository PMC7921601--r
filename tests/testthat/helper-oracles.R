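## Independent oracles and small utilities shared across tests.

## Mean-field ODE for the two-step binding mechanism, integrated with
## deSolve; used to cross-check the stochastic population simulator.
## State: Cf = free competent clients, N = complexes, B = bound sHsp subunits.
population_ode_oracle <- function(cfg, n_clients, times) {
  mean_client <- sum(seq_along(cfg$client_oligomer_dist) *
                       cfg$client_oligomer_dist)
  mean_seed <- sum(seq_along(cfg$shsp_seed_dist) * cfg$shsp_seed_dist)
  s_total <- round(cfg$molar_ratio * n_clients * mean_client)
  rhs <- function(t, y, parms) {
    Cf <- y[1]; N <- y[2]; B <- y[3]
    s_free <- max(s_total - B, 0)
    dCf <- -cfg$k_bind * Cf
    dN <- cfg$k_bind * Cf
    dB <- cfg$k_bind * Cf * mean_seed +
      cfg$k_accrete * (s_free / s_total) * N -
      cfg$k_off * max(B - N, 0)
    list(c(dCf, dN, dB))
  }
  y0 <- c(Cf = n_clients * cfg$plateau_bound_fraction, N = 0, B = 0)
  out <- deSolve::ode(y0, times, rhs, parms = NULL)
  tibble::tibble(
    time = out[, "time"],
    bound_fraction = out[, "N"] / n_clients,
    mean_chaperone = ifelse(out[, "N"] > 0, out[, "B"] / out[, "N"], NA_real_)
  )
}

## Exhaustive minimum-total-distance one-to-one matching within a radius,
## by enumerating all injective assignments (tiny inputs only).
brute_force_matching <- function(foci_a, foci_b, radius) {
  na <- nrow(foci_a); nb <- nrow(foci_b)
  dmat <- sqrt(outer(foci_a$row, foci_b$row, `-`)^2 +
                 outer(foci_a$col, foci_b$col, `-`)^2)
  best <- NULL; best_cost <- Inf; best_size <- 0
  assign_rec <- function(i, used_b, pairs, cost) {
    if (i > na) {
      size <- nrow(pairs)
      if (size > best_size || (size == best_size && cost < best_cost)) {
        best <<- pairs; best_cost <<- cost; best_size <<- size
      }
      return(invisible())
    }
    assign_rec(i + 1, used_b, pairs, cost)  # leave focus i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && dmat[i, j] <= radius) {
        used_b[j] <- TRUE
        assign_rec(i + 1, used_b,
                   rbind(pairs, data.frame(a = i, b = j)),
                   cost + dmat[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  assign_rec(1, rep(FALSE, nb), data.frame(a = integer(0), b = integer(0)), 0)
  best
}

## Total-variation distance between two joint count histograms given as
## data frames with columns n_client, n_chaperone.
tv_distance_joint <- function(a, b, max_n = 20) {
  key <- function(d) paste(pmin(d$n_client, max_n), pmin(d$n_chaperone, max_n))
  lev <- union(key(a), key(b))
  pa <- table(factor(key(a), lev)) / nrow(a)
  pb <- table(factor(key(b), lev)) / nrow(b)
  sum(abs(pa - pb)) / 2
}

## Mean of a normal truncated below at `lower` (closed form).
truncated_normal_mean <- function(mu, sigma, lower = 0) {
  a <- (lower - mu) / sigma
  mu + sigma * dnorm(a) / pnorm(a, lower.tail = FALSE)
}

## Build a noise-free piecewise-constant photobleaching trace with the given
## step heights and dwell lengths (n_steps + 1 plateaus).
make_staircase <- function(heights, dwells) {
  levels <- rev(cumsum(c(0, rev(heights))))
  rep(levels, dwells)
}

## Full image pipeline on one rendered movie: detect, colocalize, extract
## (aperture-corrected), calibrate I_s per channel, FPP, pair. Returns the
## paired stoichiometries plus per-channel focus matches to ground truth.
run_stoichiometry_pipeline <- function(movie, radius = 2, min_n = 30) {
  st_a <- correct_stack(movie$channel_a, offset = movie$camera$offset,
                        flatfield = movie$camera$flatfield)
  st_b <- correct_stack(movie$channel_b, offset = movie$camera$offset,
                        flatfield = movie$camera$flatfield)
  foci_a <- detect_foci(st_a)
  foci_b <- detect_foci(st_b)
  pairs <- colocalize(foci_a, foci_b, radius = radius)
  psf <- movie$camera$psf_sigma

  channel_fpp <- function(stack, foci) {
    traces <- lapply(seq_len(nrow(foci)), function(i) {
      extract_trajectory(stack, foci[i, ], psf_sigma = psf)$intensity
    })
    fits <- lapply(traces, detect_steps, min_dwell = 1)
    pool <- pool_single_steps(fits)
    dist <- fit_single_step_distribution(pool, doubles = TRUE, min_n = min_n)
    i0 <- vapply(seq_along(traces), function(i) {
      initial_intensity(traces[[i]],
                        first_change_point = fits[[i]]$change_points[1])
    }, numeric(1))
    fpp <- compute_fpp(i0, dist)
    fpp$focus_id <- foci$focus_id
    list(fpp = fpp, dist = dist)
  }
  ca <- channel_fpp(st_a, foci_a)
  cb <- channel_fpp(st_b, foci_b)
  records <- pair_stoichiometries(pairs, ca$fpp, cb$fpp)
  list(records = records, foci_a = foci_a, foci_b = foci_b,
       pairs = pairs, dist_a = ca$dist, dist_b = cb$dist,
       fpp_a = ca$fpp, fpp_b = cb$fpp)
}

## Match detected foci to true positions within a radius; returns indices of
## the true focus for each detected one (NA if none).
match_to_truth <- function(foci, truth, radius = 2) {
  vapply(seq_len(nrow(foci)), function(i) {
    d2 <- (truth$row - foci$row[i])^2 + (truth$col - foci$col[i])^2
    j <- which.min(d2)
    if (d2[j] <= radius^2) j else NA_integer_
  }, integer(1))
}
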