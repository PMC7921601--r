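make_stack <- function(frames) image_stack(frames)

test_that("correct_stack with zero offset and unit flatfield is the identity", {
  arr <- array(runif(4 * 16 * 16, 0, 100), dim = c(4, 16, 16))
  st <- make_stack(arr)
  out <- correct_stack(st, offset = 0)
  expect_equal(out$frames, arr)
})

test_that("a uniform frame at the offset value corrects to zero", {
  arr <- array(37.5, dim = c(2, 8, 8))
  out <- correct_stack(make_stack(arr), offset = 37.5)
  expect_equal(out$frames, array(0, dim = c(2, 8, 8)))
})

test_that("synthetic vignetting divides out to uniform", {
  nr <- 24
  vig <- outer(seq(-1, 1, length.out = nr)^2,
               seq(-1, 1, length.out = nr)^2, `+`)
  ff <- 1.2 - 0.4 * vig / max(vig)
  flat <- matrix(200, nr, nr)
  arr <- array(0, dim = c(1, nr, nr))
  arr[1, , ] <- 10 + flat * ff
  out <- correct_stack(make_stack(arr), offset = 10, flatfield = ff)
  expect_lt(max(abs(out$frames[1, , ] - 200)), 1e-6)
})

test_that("correct_stack validates flatfield dimensions and positivity", {
  st <- make_stack(array(1, dim = c(1, 8, 8)))
  expect_error(correct_stack(st, 0, matrix(1, 4, 4)),
               class = "smstoich_argument_error")
  expect_error(correct_stack(st, 0, matrix(0, 8, 8)),
               class = "smstoich_argument_error")
})

test_that("a blank noise-free stack yields no foci", {
  st <- make_stack(array(5, dim = c(3, 20, 20)))
  expect_equal(nrow(detect_foci(st, detect_window = 3)), 0)
})

test_that("a single bright PSF is found within one pixel at high SNR", {
  cam <- camera_model(40, 40, offset = 0, read_noise_sd = 1)
  cx <- tibble::tibble(n_client = 2, n_chaperone = 0, row = 17.4, col = 23.8)
  mv <- render_two_color_movie(cx, photophysics(200, 0, 1 / 1000),
                               photophysics(200, 0), cam, 12, seed = 6)
  foci <- detect_foci(mv$channel_a)
  expect_equal(nrow(foci), 1)
  expect_lt(sqrt((foci$row - 17.4)^2 + (foci$col - 23.8)^2), 1)
})

test_that("detection of 50 well-separated foci reaches 95% recall and precision", {
  cam <- camera_model(192, 192, offset = 100, read_noise_sd = 5)
  cx <- tibble::tibble(n_client = rep(2, 50), n_chaperone = rep(0, 50))
  mv <- render_two_color_movie(cx, photophysics(170, 20, 1 / 500),
                               photophysics(170, 20), cam, 12, seed = 7)
  st <- correct_stack(mv$channel_a, offset = 100)
  foci <- detect_foci(st)
  matched <- match_to_truth(foci, mv$truth$foci, radius = 2)
  recall <- dplyr::n_distinct(stats::na.omit(matched)) / 50
  precision <- mean(!is.na(matched))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("a constant stack extracts a constant zero trajectory", {
  st <- make_stack(array(42, dim = c(5, 24, 24)))
  tr <- extract_trajectory(st, list(row = 12, col = 12))
  expect_equal(tr$intensity, rep(0, 5))
})

test_that("extraction recovers the rendered plateau within 10%", {
  cam <- camera_model(40, 40, offset = 0, read_noise_sd = 0)
  cx <- tibble::tibble(n_client = 1, n_chaperone = 0, row = 20, col = 20)
  mv <- render_two_color_movie(cx, photophysics(170.5, 0, 1 / 1000),
                               photophysics(170.5, 0), cam, 25, seed = 8)
  tr <- extract_trajectory(mv$channel_a, list(row = 20, col = 20))
  expect_lt(abs(mean(tr$intensity) - 170.5) / 170.5, 0.1)
})

test_that("annulus subtraction removes a frame-wise uniform background ramp", {
  cam <- camera_model(40, 40, offset = 0, read_noise_sd = 0)
  cx <- tibble::tibble(n_client = 1, n_chaperone = 0, row = 20, col = 20)
  mv <- render_two_color_movie(cx, photophysics(170.5, 0, 1 / 1000),
                               photophysics(170.5, 0), cam, 20, seed = 9)
  base <- extract_trajectory(mv$channel_a, list(row = 20, col = 20))
  ramped <- mv$channel_a$frames
  for (f in 1:20) ramped[f, , ] <- ramped[f, , ] + 3 * f
  tr <- extract_trajectory(image_stack(ramped), list(row = 20, col = 20))
  expect_equal(tr$intensity, base$intensity, tolerance = 1e-9)
})

test_that("apertures outside the image raise an argument error", {
  st <- make_stack(array(0, dim = c(2, 20, 20)))
  expect_error(extract_trajectory(st, list(row = 2, col = 10)),
               class = "smstoich_argument_error")
})

test_that("identical coordinate lists pair completely", {
  f <- tibble::tibble(focus_id = 1:4, row = c(3, 9, 15, 3),
                      col = c(3, 9, 3, 15))
  p <- colocalize(f, f, radius = 2)
  expect_equal(nrow(p), 4)
  expect_equal(attr(p, "fraction_a"), 1)
  expect_equal(p$distance, rep(0, 4))
})

test_that("distant coordinate lists do not pair", {
  fa <- tibble::tibble(focus_id = 1:2, row = c(2, 4), col = c(2, 4))
  fb <- tibble::tibble(focus_id = 1:2, row = c(50, 60), col = c(50, 60))
  p <- colocalize(fa, fb, radius = 2)
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "fraction_a"), 0)
})

test_that("greedy matching agrees with the exhaustive minimum-distance oracle", {
  ## one B focus equidistant-near two A foci plus distractors
  fa <- tibble::tibble(focus_id = 1:3, row = c(10, 12, 30), col = c(10, 10, 30))
  fb <- tibble::tibble(focus_id = 1:2, row = c(11, 30.5), col = c(10, 30))
  p <- colocalize(fa, fb, radius = 2)
  oracle <- brute_force_matching(fa, fb, radius = 2)
  expect_equal(nrow(p), nrow(oracle))
  expect_equal(sum(p$distance), with(oracle, sum(
    sqrt((fa$row[a] - fb$row[b])^2 + (fa$col[a] - fb$col[b])^2))),
    tolerance = 1e-9)

  ## randomized instances: same number of pairs, same total distance
  set.seed(21)
  for (i in 1:20) {
    fa <- tibble::tibble(focus_id = 1:4, row = runif(4, 0, 12),
                         col = runif(4, 0, 12))
    fb <- tibble::tibble(focus_id = 1:4, row = runif(4, 0, 12),
                         col = runif(4, 0, 12))
    p <- colocalize(fa, fb, radius = 3)
    oracle <- brute_force_matching(fa, fb, radius = 3)
    expect_equal(nrow(p), nrow(oracle))
  }
})

test_that("chance colocalization is bounded by the permutation-shuffle rate", {
  ## two unrelated point sets at a known density
  set.seed(31)
  n <- 60
  fa <- tibble::tibble(focus_id = 1:n, row = runif(n, 5, 250),
                       col = runif(n, 5, 250))
  fb <- tibble::tibble(focus_id = 1:n, row = runif(n, 5, 250),
                       col = runif(n, 5, 250))
  obs <- attr(colocalize(fa, fb, radius = 2), "fraction_a")
  perm <- replicate(60, {
    shuffled <- fb
    shuffled$row <- runif(n, 5, 250)
    shuffled$col <- runif(n, 5, 250)
    attr(colocalize(fa, shuffled, radius = 2), "fraction_a")
  })
  expect_lte(obs, stats::quantile(perm, 0.99) + 2 / n)
})

test_that("labeling-efficiency correction reproduces the worked ratios", {
  r <- corrected_abundance(86, 73, 0.86, 0.73)
  expect_equal(r$abundance, c(0.5, 0.5))
  r2 <- corrected_abundance(100, 100, 0.5, 1.0)
  expect_equal(r2$abundance, c(2 / 3, 1 / 3))
  r3 <- corrected_abundance(10, 10, 0.9, 0.9)
  expect_equal(r3$abundance, c(0.5, 0.5))
  expect_error(corrected_abundance(10, 10, 0, 0.5),
               class = "smstoich_argument_error")
})
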