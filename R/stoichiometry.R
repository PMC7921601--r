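#' Pair per-channel subunit counts into complex stoichiometries
#'
#' Joins colocalized focus pairs with the FPP subunit counts of both
#' channels, producing one stoichiometry record per complex. The exclusion
#' flag (count above the self-quenching limit) propagates from either
#' channel. Excluded records are retained and flagged, never dropped.
#'
#' @param pairs tibble from [colocalize()] (`focus_a`, `focus_b`).
#' @param fpp_a,fpp_b FPP tibbles (from [compute_fpp()]) with a `focus_id`
#'   column identifying the focus in the respective channel.
#' @param condition condition label (timepoint or molar ratio) attached to
#'   every record.
#' @return tibble with `focus_a`, `focus_b`, `n_client`, `n_chaperone`,
#'   `excluded`, `condition`.
#' @export
pair_stoichiometries <- function(pairs, fpp_a, fpp_b, condition = NA) {
  stopifnot(is.data.frame(pairs), is.data.frame(fpp_a), is.data.frame(fpp_b))
  for (nm in c("fpp_a", "fpp_b")) {
    f <- get(nm)
    if (!all(c("focus_id", "subunit_count", "excluded") %in% names(f))) {
      abort_bad_arg("`%s` needs columns focus_id, subunit_count, excluded.", nm)
    }
  }
  miss_a <- setdiff(pairs$focus_a, fpp_a$focus_id)
  miss_b <- setdiff(pairs$focus_b, fpp_b$focus_id)
  if (length(miss_a) || length(miss_b)) {
    abort_bad_arg("missing FPP results for foci: %s",
                  paste(c(paste0("A:", miss_a), paste0("B:", miss_b)),
                        collapse = ", "))
  }
  ia <- match(pairs$focus_a, fpp_a$focus_id)
  ib <- match(pairs$focus_b, fpp_b$focus_id)
  tibble(
    focus_a = pairs$focus_a,
    focus_b = pairs$focus_b,
    n_client = as.integer(fpp_a$subunit_count[ia]),
    n_chaperone = as.integer(fpp_b$subunit_count[ib]),
    excluded = fpp_a$excluded[ia] | fpp_b$excluded[ib],
    condition = condition
  )
}

#' Relative-abundance heatmap of complex stoichiometries
#'
#' Normalized joint histogram of (client subunits, chaperone subunits) over
#' the non-excluded records of one condition.
#'
#' @param records stoichiometry tibble (see [pair_stoichiometries()]).
#' @param condition optional label; defaults to the records' condition.
#' @param max_subunits heatmap axis limit.
#' @return an object of class `abundance_heatmap`: list with `matrix`
#'   (`max_subunits` x `max_subunits`, rows = client subunits, cols =
#'   chaperone subunits, entries summing to 1), `n`, `n_excluded`,
#'   `excluded_fraction`, `condition`.
#' @export
abundance_heatmap <- function(records, condition = NULL, max_subunits = 20) {
  stopifnot(is.data.frame(records))
  if (!all(c("n_client", "n_chaperone") %in% names(records))) {
    abort_bad_arg("records need columns n_client and n_chaperone.")
  }
  excl <- records$excluded %||% rep(FALSE, nrow(records))
  keep <- records[!excl, , drop = FALSE]
  if (nrow(keep) == 0) {
    abort_bad_arg("all %d records are excluded; no heatmap can be formed.",
                  nrow(records))
  }
  m <- matrix(0, max_subunits, max_subunits,
              dimnames = list(client = 1:max_subunits,
                              chaperone = 1:max_subunits))
  cc <- pmin(pmax(keep$n_client, 1L), max_subunits)
  ch <- pmin(pmax(keep$n_chaperone, 1L), max_subunits)
  for (i in seq_along(cc)) m[cc[i], ch[i]] <- m[cc[i], ch[i]] + 1
  m <- m / sum(m)
  structure(
    list(matrix = m, n = nrow(keep), n_excluded = sum(excl),
         excluded_fraction = sum(excl) / nrow(records),
         condition = condition %||% records[["condition"]][1]),
    class = "abundance_heatmap"
  )
}

#' @export
print.abundance_heatmap <- function(x, ...) {
  cat(sprintf("<abundance_heatmap> condition %s: n = %d (%.1f%% excluded)\n",
              format(x$condition), x$n, 100 * x$excluded_fraction))
  invisible(x)
}

#' Fit one-phase association kinetics to colocalized fractions
#'
#' Least-squares fit of `y(t) = y0 + (plateau - y0) * (1 - exp(-k * t))` by
#' Levenberg-Marquardt. Degenerate flat data yield `plateau = y0 = mean(y)`
#' and `k = 0` with a warning.
#'
#' @param data data frame with the time and response columns.
#' @param time,response column names (tidy-select style strings).
#' @return an object of class `one_phase_fit`: list with `y0`, `plateau`,
#'   `k` (1/h), `residual_sd`, `n`, `fitted` tibble.
#' @examples
#' d <- tibble::tibble(t = c(0, 0.5, 1, 2, 4, 8),
#'                     y = 50 * (1 - exp(-2 * c(0, 0.5, 1, 2, 4, 8))))
#' colocalized_fraction_kinetics(d, time = "t", response = "y")
#' @export
colocalized_fraction_kinetics <- function(data, time = "time",
                                          response = "percent") {
  stopifnot(is.data.frame(data))
  if (!all(c(time, response) %in% names(data))) {
    abort_bad_arg("data needs columns `%s` and `%s`.", time, response)
  }
  t <- as.numeric(data[[time]])
  y <- as.numeric(data[[response]])
  ok <- complete.cases(t, y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 3) abort_bad_arg("need at least 3 timepoints.")

  if (sd(y) < 1e-12) {
    warning("flat response: plateau = y0, k = 0", call. = FALSE)
    fit <- list(y0 = mean(y), plateau = mean(y), k = 0,
                residual_sd = 0)
  } else {
    k0 <- 1 / max(median(t[t > 0]), 1e-6)
    nls_fit <- minpack.lm::nlsLM(
      y ~ y0 + (plateau - y0) * (1 - exp(-k * t)),
      start = list(y0 = min(y), plateau = max(y), k = k0),
      lower = c(-Inf, -Inf, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- coef(nls_fit)
    fit <- list(y0 = unname(cf["y0"]), plateau = unname(cf["plateau"]),
                k = unname(cf["k"]),
                residual_sd = sqrt(sum(stats::resid(nls_fit)^2) /
                                     max(length(y) - 3, 1)))
  }
  structure(
    c(fit, list(
      n = length(y),
      fitted = tibble(
        time = t, observed = y,
        fitted = fit$y0 + (fit$plateau - fit$y0) * (1 - exp(-fit$k * t))
      )
    )),
    class = "one_phase_fit"
  )
}

#' @export
print.one_phase_fit <- function(x, ...) {
  cat(sprintf("<one_phase_fit> y0 = %.2f, plateau = %.2f, k = %.3f /h (n = %d)\n",
              x$y0, x$plateau, x$k, x$n))
  invisible(x)
}

#' Compare subunit-size distributions across groups
#'
#' Kruskal-Wallis omnibus rank test (with tie correction) followed by Dunn's
#' pairwise z-tests with multiplicity adjustment.
#'
#' @param data data frame with a group column and a value column; or a named
#'   list of numeric vectors.
#' @param value,group column names when `data` is a data frame.
#' @param p_adjust multiplicity adjustment method for the pairwise tests
#'   (default `"bonferroni"`, the common convention for Dunn's procedure).
#' @return an object of class `size_comparison`: list with `statistic`
#'   (tie-corrected H), `df`, `p_value`, `pairwise` tibble (`group1`,
#'   `group2`, `z`, `p_unadjusted`, `p_adjusted`), `groups`, `method`.
#' @export
compare_size_distributions <- function(data, value = "subunits",
                                       group = "group",
                                       p_adjust = "bonferroni") {
  if (is.data.frame(data)) {
    if (!all(c(value, group) %in% names(data))) {
      abort_bad_arg("data needs columns `%s` and `%s`.", value, group)
    }
    samples <- split(as.numeric(data[[value]]), data[[group]])
  } else if (is.list(data)) {
    samples <- map(data, as.numeric)
    if (is.null(names(samples))) {
      names(samples) <- paste0("group", seq_along(samples))
    }
  } else {
    abort_bad_arg("data must be a data frame or a named list.")
  }
  ns <- lengths(samples)
  if (length(samples) < 2) abort_bad_arg("need at least 2 groups.")
  if (any(ns == 0)) {
    abort_bad_arg("empty group(s): %s",
                  paste(names(samples)[ns == 0], collapse = ", "))
  }

  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), ns), levels = names(samples))
  kw <- kruskal.test(x, g)

  ## Dunn's z statistics on the pooled mid-ranks with tie correction
  r <- rank(x)
  n <- length(x)
  rbar <- tapply(r, g, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  combos <- utils::combn(names(samples), 2)
  pair <- map(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- if (se > 0) (rbar[[g1]] - rbar[[g2]]) / se else 0
    tibble(group1 = g1, group2 = g2, z = z,
           p_unadjusted = 2 * pnorm(abs(z), lower.tail = FALSE))
  })
  pairwise <- list_rbind(pair)
  pairwise$p_adjusted <- pmin(p.adjust(pairwise$p_unadjusted,
                                       method = p_adjust), 1)

  structure(
    list(statistic = unname(kw$statistic), df = unname(kw$parameter),
         p_value = unname(kw$p.value), pairwise = pairwise,
         groups = tibble(group = names(samples), n = unname(as.integer(ns))),
         method = paste0("Kruskal-Wallis + Dunn (", p_adjust, ")")),
    class = "size_comparison"
  )
}

#' @export
print.size_comparison <- function(x, ...) {
  cat(sprintf("<size_comparison> H = %.3f (df = %d), p = %.3g; %d pairwise tests\n",
              x$statistic, x$df, x$p_value, nrow(x$pairwise)))
  invisible(x)
}

#' Summarise subunit-size distributions (violin-plot statistics)
#'
#' Per-group median, interquartile range and kernel probability density of
#' the subunit counts. The density uses Silverman's bandwidth with
#' reflection at the lower bound of the support (counts cannot fall below
#' 1), so it integrates to 1.
#'
#' @param records stoichiometry tibble.
#' @param channel `"client"` or `"chaperone"` - which subunit counts to
#'   summarise.
#' @param selector optional: `"bound"` keeps records with at least one
#'   chaperone subunit, `"free"` keeps chaperone-free records; `NULL` keeps
#'   everything.
#' @param group optional grouping column (e.g. `"condition"`).
#' @param lower_bound reflection boundary of the density.
#' @return list with `summary` tibble (`group`, `n`, `median`, `q25`,
#'   `q75`) and `density` tibble (`group`, `x`, `density`).
#' @export
size_violin_summary <- function(records, channel = c("client", "chaperone"),
                                selector = NULL, group = "condition",
                                lower_bound = 1) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(records))
  col <- paste0("n_", channel)
  if (!col %in% names(records)) {
    abort_bad_arg("records lack column `%s`.", col)
  }
  if (!is.null(selector)) {
    selector <- match.arg(selector, c("bound", "free"))
    keep <- if (selector == "bound") records$n_chaperone >= 1 else
      records$n_chaperone == 0
    records <- records[keep, , drop = FALSE]
  }
  grp <- if (!is.null(group) && group %in% names(records)) {
    as.character(records[[group]])
  } else {
    rep("all", nrow(records))
  }
  vals <- split(as.numeric(records[[col]]), grp)
  if (length(vals) == 0 || all(lengths(vals) == 0)) {
    abort_bad_arg("no records to summarise.")
  }

  summary <- list_rbind(imap(vals, function(v, g) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble(group = g, n = length(v), median = q[2], q25 = q[1], q75 = q[3])
  }))
  dens <- list_rbind(imap(vals, function(v, g) {
    d <- reflected_density(v, lower_bound)
    tibble(group = g, x = d$x, density = d$y)
  }))
  list(summary = summary, density = dens)
}

## Gaussian KDE with reflection at `lb` so mass below the support folds back
reflected_density <- function(v, lb) {
  if (length(v) == 1L || sd(v) == 0) {
    ## degenerate sample: narrow Gaussian spike at the value
    bw <- 0.1
  } else {
    bw <- stats::bw.nrd0(v)
  }
  d <- density(c(v, 2 * lb - v), bw = bw, n = 1024,
               from = lb, to = max(v) + 4 * bw)
  d$y <- 2 * d$y   # reflection doubles the retained half
  ## renormalise numerically over the evaluated grid
  area <- sum(d$y) * diff(d$x[1:2])
  d$y <- d$y / area
  list(x = d$x, y = d$y)
}
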