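fpp_table <- function(ids, counts, excluded = FALSE) {
  tibble::tibble(focus_id = ids, subunit_count = as.integer(counts),
                 excluded = rep_len(excluded, length(ids)))
}

test_that("pairing joins counts and propagates exclusion", {
  pairs <- tibble::tibble(focus_a = 1L, focus_b = 1L, distance = 0.5)
  rec <- pair_stoichiometries(pairs, fpp_table(1, 1), fpp_table(1, 1),
                              condition = "0.25h")
  expect_equal(rec$n_client, 1L)
  expect_equal(rec$n_chaperone, 1L)
  expect_false(rec$excluded)
  expect_equal(rec$condition, "0.25h")

  rec2 <- pair_stoichiometries(pairs, fpp_table(1, 2),
                               fpp_table(1, 21, excluded = TRUE))
  expect_true(rec2$excluded)

  expect_error(
    pair_stoichiometries(tibble::tibble(focus_a = 5L, focus_b = 1L),
                         fpp_table(1, 1), fpp_table(1, 1)),
    "A:5")
})

test_that("paired joint histogram matches the generative joint distribution", {
  set.seed(51)
  n <- 1000
  true_client <- sample(1:6, n, replace = TRUE,
                        prob = c(0.35, 0.25, 0.16, 0.12, 0.08, 0.04))
  true_chap <- sample(1:8, n, replace = TRUE,
                      prob = 0.6^(0:7) / sum(0.6^(0:7)))
  pairs <- tibble::tibble(focus_a = 1:n, focus_b = 1:n, distance = 0)
  rec <- pair_stoichiometries(pairs, fpp_table(1:n, true_client),
                              fpp_table(1:n, true_chap))
  truth <- tibble::tibble(n_client = true_client, n_chaperone = true_chap)
  expect_lte(tv_distance_joint(rec, truth), 0.1)
})

test_that("heatmaps are normalized joint histograms", {
  rec <- tibble::tibble(n_client = 3L, n_chaperone = 5L, excluded = FALSE)
  hm <- abundance_heatmap(rec)
  expect_equal(hm$matrix[3, 5], 1)
  expect_equal(sum(hm$matrix), 1)

  set.seed(53)
  rec2 <- tibble::tibble(n_client = sample(1:12, 400, TRUE),
                         n_chaperone = sample(1:12, 400, TRUE),
                         excluded = FALSE)
  hm2 <- abundance_heatmap(rec2)
  expect_lt(abs(sum(hm2$matrix) - 1), 1e-12)

  ## exhaustive 3x3 grid equals the hand-computed histogram
  grid <- expand.grid(n_client = 1:3, n_chaperone = 1:3)
  grid$excluded <- FALSE
  reps <- grid[rep(seq_len(9), times = 1:9), ]
  hm3 <- abundance_heatmap(reps)
  manual <- matrix(0, 3, 3)
  for (i in seq_len(9)) manual[grid$n_client[i], grid$n_chaperone[i]] <- i
  manual <- manual / sum(manual)
  expect_equal(unname(hm3$matrix[1:3, 1:3]), unname(manual))
})

test_that("heatmap marginals equal the per-channel count histograms", {
  set.seed(55)
  rec <- tibble::tibble(n_client = sample(1:8, 300, TRUE),
                        n_chaperone = sample(1:10, 300, TRUE),
                        excluded = FALSE)
  hm <- abundance_heatmap(rec)
  client_marg <- rowSums(hm$matrix)
  chap_marg <- colSums(hm$matrix)
  expect_equal(unname(client_marg[1:8]),
               as.vector(table(factor(rec$n_client, 1:8))) / 300)
  expect_equal(unname(chap_marg[1:10]),
               as.vector(table(factor(rec$n_chaperone, 1:10))) / 300)
})

test_that("heatmap construction fails when everything is excluded", {
  rec <- tibble::tibble(n_client = 21L, n_chaperone = 1L, excluded = TRUE)
  expect_error(abundance_heatmap(rec), class = "smstoich_argument_error")
  ## excluded records are reported as a fraction, never silently dropped
  rec2 <- tibble::tibble(n_client = c(2L, 21L), n_chaperone = c(2L, 22L),
                         excluded = c(FALSE, TRUE))
  hm <- abundance_heatmap(rec2)
  expect_equal(hm$excluded_fraction, 0.5)
  expect_equal(hm$n_excluded, 1)
})

test_that("one-phase association recovers exact synthetic parameters", {
  t <- c(0, 0.5, 1, 2, 4, 8)
  y <- 0 + (50 - 0) * (1 - exp(-2 * t))
  fit <- colocalized_fraction_kinetics(tibble::tibble(time = t, percent = y))
  expect_equal(fit$y0, 0, tolerance = 1e-6)
  expect_equal(fit$plateau, 50, tolerance = 1e-6)
  expect_equal(fit$k, 2, tolerance = 1e-6)
})

test_that("flat kinetics data give plateau = y0 with a warning", {
  d <- tibble::tibble(time = c(0, 1, 2, 4), percent = rep(30, 4))
  expect_warning(fit <- colocalized_fraction_kinetics(d), "flat")
  expect_equal(fit$plateau, 30)
  expect_equal(fit$y0, 30)
  expect_equal(fit$k, 0)
})

test_that("kinetics fitting is invariant to timepoint order", {
  t <- c(0, 0.25, 0.5, 1, 4, 8)
  set.seed(57)
  y <- 5 + 45 * (1 - exp(-1.5 * t)) + rnorm(6, 0, 1)
  d <- tibble::tibble(time = t, percent = y)
  f1 <- colocalized_fraction_kinetics(d)
  f2 <- colocalized_fraction_kinetics(d[sample(6), ])
  expect_equal(f1$plateau, f2$plateau, tolerance = 1e-8)
  expect_equal(f1$k, f2$k, tolerance = 1e-8)
})

test_that("binomial sampling noise leaves the fitted plateau unbiased", {
  t <- c(0, 0.25, 0.5, 0.75, 1, 4, 8, 10)
  truth <- 50 * (1 - exp(-1.5 * t))
  set.seed(59)
  plateaus <- replicate(100, {
    y <- 100 * rbinom(length(t), 500, truth / 100) / 500
    colocalized_fraction_kinetics(tibble::tibble(time = t, percent = y))$plateau
  })
  se <- sd(plateaus) / sqrt(length(plateaus))
  expect_lt(abs(mean(plateaus) - 50), 3 * se)
})

test_that("identical groups give a null omnibus result", {
  g <- c(1, 2, 2, 3, 4, 5, 5, 6)
  cmp <- compare_size_distributions(list(a = g, b = g, c = g))
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1)
  expect_true(all(cmp$pairwise$p_adjusted == 1))
})

test_that("a 3-subunit shift at n = 200 is overwhelmingly significant", {
  set.seed(61)
  a <- sample(1:6, 200, replace = TRUE)
  b <- a + 3
  cmp <- compare_size_distributions(list(small = a, large = b))
  expect_lt(cmp$p_value, 1e-6)
  expect_lt(cmp$pairwise$p_adjusted[1], 1e-6)
})

test_that("omnibus p matches a permutation oracle on a small instance", {
  x <- list(a = c(1, 3, 4), b = c(2, 6, 7), c = c(5, 8, 9))
  cmp <- compare_size_distributions(x)
  pooled <- unlist(x)
  g <- rep(names(x), lengths(x))
  set.seed(63)
  n_perm <- 4000
  h_obs <- cmp$statistic
  h_perm <- replicate(n_perm, {
    kruskal.test(pooled, factor(sample(g)))$statistic
  })
  p_perm <- (1 + sum(h_perm >= h_obs - 1e-12)) / (n_perm + 1)
  expect_lt(abs(cmp$p_value - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / n_perm) + 0.02)
})

test_that("empty groups are rejected", {
  expect_error(compare_size_distributions(list(a = 1:5, b = numeric(0))),
               class = "smstoich_argument_error")
})

test_that("violin summaries report median, IQR and a unit-mass density", {
  rec <- tibble::tibble(n_client = c(1, 2, 3, 4, 5),
                        n_chaperone = rep(1, 5),
                        condition = "a")
  vs <- size_violin_summary(rec, channel = "client")
  expect_equal(vs$summary$median, 3)
  expect_equal(vs$summary$q25, 2)
  expect_equal(vs$summary$q75, 4)

  rec2 <- tibble::tibble(n_client = rep(4, 6), n_chaperone = rep(1, 6),
                         condition = "b")
  vs2 <- size_violin_summary(rec2, channel = "client")
  expect_equal(vs2$summary$q75 - vs2$summary$q25, 0)

  ## density integrates to 1 within 1e-3
  set.seed(65)
  rec3 <- tibble::tibble(n_client = sample(1:10, 200, TRUE),
                         n_chaperone = rep(1, 200), condition = "c")
  vs3 <- size_violin_summary(rec3, channel = "client")
  dx <- diff(vs3$density$x[1:2])
  expect_lt(abs(sum(vs3$density$density) * dx - 1), 1e-3)
})

test_that("bound/free selectors split records on chaperone occupancy", {
  rec <- tibble::tibble(n_client = c(1, 2, 3), n_chaperone = c(0, 2, 0),
                        condition = "x")
  bound <- size_violin_summary(rec, "client", selector = "bound")
  free <- size_violin_summary(rec, "client", selector = "free")
  expect_equal(bound$summary$n, 1)
  expect_equal(free$summary$n, 2)
})
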