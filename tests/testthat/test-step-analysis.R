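test_that("initial intensity averages the first 20 frames", {
  expect_equal(initial_intensity(rep(100, 30)), 100)
  expect_equal(initial_intensity(c(rep(100, 10), rep(0, 30))), 50)
  expect_error(initial_intensity(rep(1, 10)), "20")
})

test_that("initial intensity of a quiet noise-free trace sums the drawn heights", {
  ## slow bleaching: no fluorophore lost within the first 20 frames
  tr <- simulate_trajectory(5, photophysics(150, 40, bleach_rate = 1 / 5000),
                            60, noise_sd = 0, seed = 13)
  truth <- attr(tr, "truth")
  expect_true(all(truth$bleach_frame > 20))
  expect_equal(initial_intensity(tr), sum(truth$step_height))
})

test_that("a noise-free two-level trace yields one exact change point", {
  fit <- detect_steps(c(rep(200, 50), rep(0, 50)))
  expect_equal(fit$change_points, 50L)
  expect_equal(fit$steps$step_height, 200)
  expect_equal(fit$residual_ss, 0)
})

test_that("a constant trace yields zero change points", {
  fit <- detect_steps(rep(77, 40))
  expect_equal(length(fit$change_points), 0)
  expect_equal(fit$levels, 77)
})

test_that("noise-free staircases with 1-8 steps are segmented exactly", {
  set.seed(17)
  for (k in 1:8) {
    heights <- runif(k, 60, 250)
    dwells <- sample(4:25, k + 1, replace = TRUE)
    x <- make_staircase(heights, dwells)
    fit <- detect_steps(x)
    expect_equal(length(fit$change_points), k)
    expect_equal(fit$change_points, cumsum(dwells)[seq_len(k)])
    expect_equal(fit$steps$step_height, heights, tolerance = 1e-12)
    expect_equal(fit$residual_ss, 0)
  }
})

test_that("3-step traces at step SNR 5 are recovered reliably", {
  n_ok <- 0
  n_tr <- 60
  set.seed(23)
  for (i in seq_len(n_tr)) {
    heights <- rep(170, 3)
    dwells <- sample(15:40, 4, replace = TRUE)
    x <- make_staircase(heights, dwells) + rnorm(sum(dwells), 0, 34)
    fit <- detect_steps(x, min_dwell = 3)
    if (nrow(fit$steps) == 3 &&
        all(abs(fit$change_points - cumsum(dwells)[1:3]) <= 2)) {
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_tr, 0.9)
})

test_that("pooling keeps clean downward steps and rejects blinking traces", {
  two_level <- detect_steps(c(rep(180, 30), rep(0, 30)))
  pool <- pool_single_steps(list(two_level), step_floor = 10)
  expect_equal(as.numeric(pool), 180)

  upward <- detect_steps(c(rep(100, 20), rep(250, 20), rep(0, 20)))
  pool2 <- pool_single_steps(list(upward), step_floor = 10)
  expect_equal(length(pool2), 0)

  ## a trace that never bleaches to background contributes nothing
  unfinished <- detect_steps(c(rep(300, 30), rep(150, 30)))
  pool3 <- pool_single_steps(list(unfinished), step_floor = 10)
  expect_equal(length(pool3), 0)
})

test_that("pooled step heights recover the generative mean (Monte Carlo)", {
  tb <- simulate_trajectories(sample(2:6, 500, replace = TRUE),
                              photophysics(170.5, 20, 1 / 30), 200,
                              noise_sd = 20, seed = 29)
  traces <- split(tb$intensity, tb$trace_id)
  fits <- lapply(traces, detect_steps, min_dwell = 1)
  pool <- pool_single_steps(fits)
  se <- sd(pool) / sqrt(length(pool))
  ## with narrow height dispersion truncation is negligible
  expect_lt(abs(mean(pool) - 170.5), 3 * se + 2)
})

test_that("the Gaussian step fit handles degenerate and clean pools", {
  d <- fit_single_step_distribution(rep(150, 60))
  expect_equal(d$I_s_mean, 150)
  expect_equal(d$I_s_sigma, 0)

  ## symmetric bimodal pool: mean is the midpoint
  d2 <- fit_single_step_distribution(rep(c(120, 180), each = 100))
  expect_equal(d2$I_s_mean, 150)

  expect_error(fit_single_step_distribution(rnorm(10, 100, 5)),
               class = "smstoich_argument_error")
})

test_that("plain ML on truncated draws matches the closed-form truncated mean", {
  set.seed(41)
  x <- rnorm(4000, 170.5, 99)
  v <- x[x > 0][1:1000]
  d <- fit_single_step_distribution(v)
  oracle <- truncated_normal_mean(170.5, 99, 0)
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(d$I_s_mean - oracle), 3 * se)
})

test_that("censoring-aware fitting recovers the generative location", {
  set.seed(43)
  x <- rnorm(30000, 166, 119)
  v <- x[x > 60][1:4000]
  d <- fit_single_step_distribution(v, lower_bound = 60)
  expect_lt(abs(d$I_s_mean - 166) / 166, 0.05)
  expect_lt(abs(d$I_s_sigma - 119) / 119, 0.10)
})

test_that("FPP arithmetic, rounding and exclusion follow the counting rules", {
  r <- compute_fpp(852.5, 170.5)
  expect_equal(r$fpp, 5)
  expect_equal(r$subunit_count, 5L)
  expect_false(r$excluded)

  r2 <- compute_fpp(170.5, 170.5)
  expect_equal(r2$fpp, 1)
  expect_equal(r2$subunit_count, 1L)

  r3 <- compute_fpp(21 * 170.5, 170.5)
  expect_equal(r3$subunit_count, 21L)
  expect_true(r3$excluded)

  ## round half up; clamp at 1
  expect_equal(compute_fpp(c(0.4, 1.5, 2.49) * 100, 100)$subunit_count,
               c(1L, 2L, 2L))
  expect_error(compute_fpp(100, 0), class = "smstoich_argument_error")
})

test_that("FPP is monotone in I_0 and scale-equivariant", {
  i0 <- seq(50, 4000, by = 50)
  counts <- compute_fpp(i0, 170.5)$subunit_count
  expect_true(!is.unsorted(counts))
  a <- compute_fpp(i0, 170.5)
  b <- compute_fpp(3.7 * i0, 3.7 * 170.5)
  expect_equal(a$fpp, b$fpp)
})

test_that("FRET proximity ratio handles leakage, symmetry and invalid frames", {
  ## pure leakage: corrected acceptor is zero
  d <- rep(400, 10)
  tr <- fret_trace(d, 0.07 * d, alpha = 0.07)
  expect_equal(tr$E, rep(0, 10))

  tr2 <- fret_trace(rep(0, 5), rep(100, 5), alpha = 0)
  expect_equal(tr2$E, rep(1, 5))

  tr3 <- fret_trace(rep(120, 5), rep(120, 5), alpha = 0)
  expect_equal(tr3$E, rep(0.5, 5))

  ## common positive scaling leaves E unchanged
  dd <- runif(20, 50, 300)
  aa <- runif(20, 50, 300)
  expect_equal(fret_trace(dd, aa, 0.1)$E, fret_trace(5 * dd, 5 * aa, 0.1)$E)

  tr4 <- fret_trace(c(10, 0), c(5, 0), alpha = 0.8)
  expect_false(tr4$valid[2])
  expect_true(is.na(tr4$E[2]))
  expect_error(fret_trace(1:5, 1:4), class = "smstoich_argument_error")
})

test_that("full-trace calibration recovers a known single-step mean", {
  tb <- simulate_trajectories(sample(2:8, 400, replace = TRUE),
                              photophysics(170.5, 99, 1 / 30), 200,
                              noise_sd = 25, seed = 47)
  d <- calibrate_single_step(tb)
  expect_lt(abs(d$I_s_mean - 170.5) / 170.5, 0.06)
  expect_gt(d$n, 500)
})
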