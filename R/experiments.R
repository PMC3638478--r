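# Ensemble experiments: paired healthy vs. partially occluded capillary
# networks, with per-network pipelines (generate -> flow -> residue ->
# characterize) and paired statistics over the ensemble.

#' Run the full pipeline on an ensemble condition
#'
#' For each seed: generate a network (optionally occlude a fraction of
#' its vessels with the same seed, so conditions are paired on the same
#' parent network), solve the flow at `delta_p`, compute the exact
#' residue function, the transit-time distribution (MTT, CTTH) and
#' perfusion metrics, and fit mono- and bigamma characterizations.
#' Per-network failures (e.g. occlusion severing every perfusable path)
#' are recorded and excluded, not fatal.
#'
#' @param config Generator configuration ([default_network_config()]).
#' @param seeds Integer seeds, one network per seed.
#' @param occlusion Fraction of vessels to block (0 = healthy condition).
#' @param delta_p Boundary pressure difference, Pa.
#' @param fit_starts Multi-start count for the mixture fits.
#' @param ... Further arguments passed to [solve_flow()].
#' @return Data frame with one row per seed (columns: morphometry,
#'   CBF/CBV/MTT, CTTH from the raw atoms and from the bigamma fit,
#'   bigamma parameters `k1, alpha1, alpha2, beta1, beta2`, mono/bi RSS,
#'   decay times `time_to_R01`/`time_to_R001`, and a `failed` flag);
#'   failures carry NA metrics. Attribute `n_failed` counts them.
#' @export
run_condition <- function(config = default_network_config(), seeds = 1:20,
                          occlusion = 0, delta_p = 1000, fit_starts = 20L,
                          ...) {
  rows <- lapply(seeds, function(seed) {
    tryCatch({
      net <- generate_network(config, seed = seed)
      if (occlusion > 0) net <- occlude(net, occlusion, seed = seed)
      sol <- solve_flow(net, delta_p = delta_p, ...)
      h <- haemodynamics(sol)
      R <- network_residue(sol)
      ttd <- transit_time_distribution(R)
      st <- network_stats(net)
      fit1 <- fit_residue(R, 1, seed = seed, n_starts = fit_starts)
      fit2 <- fit_residue(R, 2, seed = seed, n_starts = fit_starts)
      mx <- fit2$mixture
      data.frame(
        seed = seed, failed = FALSE,
        n_vessels = st$n_vessels, vessel_density = st$vessel_density,
        connectivity = st$connectivity,
        length_mean = st$length_mean, length_sd = st$length_sd,
        diameter_mean = st$diameter_mean, diameter_sd = st$diameter_sd,
        CBF = h$CBF, CBV = h$CBV, MTT = h$MTT,
        mtt_residue = residue_integral(R),
        ctth_raw = ttd$CTTH, ctth_fit = fit2$CTTH, mtt_fit = fit2$MTT,
        k1 = mx$k[1], alpha1 = mx$alpha[1], alpha2 = mx$alpha[2],
        beta1 = mx$beta[1], beta2 = mx$beta[2],
        rss_mono = fit1$rss, rss_bi = fit2$rss,
        time_to_R01 = residue_time_below(R, 0.1),
        time_to_R001 = residue_time_below(R, 0.01)
      )
    }, capres_error = function(e) {
      row <- data.frame(seed = seed, failed = TRUE)
      for (col in c("n_vessels", "vessel_density", "connectivity",
                    "length_mean", "length_sd", "diameter_mean", "diameter_sd",
                    "CBF", "CBV", "MTT", "mtt_residue", "ctth_raw", "ctth_fit",
                    "mtt_fit", "k1", "alpha1", "alpha2", "beta1", "beta2",
                    "rss_mono", "rss_bi", "time_to_R01", "time_to_R001"))
        row[[col]] <- NA_real_
      row
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- sum(out$failed)
  out
}

ENSEMBLE_QUANTITIES <- c("k1", "alpha1", "alpha2", "beta1", "beta2", "CBF",
                         "CBV", "MTT", "ctth_raw", "ctth_fit",
                         "rss_mono", "rss_bi", "time_to_R01", "time_to_R001")

#' Aggregate paired ensemble conditions and run paired t-tests
#'
#' Computes mean, s.d., median and quartiles of each reported quantity
#' per condition, and a two-sided paired t-test (normal vs. occluded) per
#' quantity over the seeds present and non-failed in both conditions.
#' If the paired differences are all (numerically) zero the p-value is
#' reported as 1.
#'
#' @param rows_normal,rows_occluded Data frames from [run_condition()],
#'   produced with the same seeds.
#' @return List of class `ensemble_result`: `summary` (long data frame of
#'   descriptive statistics per quantity and condition), `tests` (one row
#'   per quantity with mean difference and p-value), `n_pairs`.
#' @export
aggregate_and_test <- function(rows_normal, rows_occluded) {
  if (!identical(rows_normal$seed, rows_occluded$seed))
    abort_capres("conditions are not paired: seed vectors differ",
                 "capres_validation_error")
  ok <- !rows_normal$failed & !rows_occluded$failed
  qn <- intersect(ENSEMBLE_QUANTITIES, names(rows_normal))

  summarize <- function(df, condition) {
    do.call(rbind, lapply(qn, function(q) {
      x <- df[[q]][!df$failed & is.finite(df[[q]])]
      data.frame(quantity = q, condition = condition, n = length(x),
                 mean = mean(x), sd = stats::sd(x),
                 median = stats::median(x),
                 q1 = unname(stats::quantile(x, 0.25)),
                 q3 = unname(stats::quantile(x, 0.75)))
    }))
  }
  summ <- rbind(summarize(rows_normal, "normal"),
                summarize(rows_occluded, "occluded"))

  tests <- do.call(rbind, lapply(qn, function(q) {
    x <- rows_normal[[q]][ok]
    y <- rows_occluded[[q]][ok]
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    d <- y - x
    if (length(d) < 2 || stats::sd(d) == 0) {
      p <- if (all(abs(d) < 1e-12)) 1 else NA_real_
      stat <- 0
    } else {
      tt <- stats::t.test(y, x, paired = TRUE)
      p <- tt$p.value
      stat <- unname(tt$statistic)
    }
    data.frame(quantity = q, n = length(d), mean_diff = mean(d),
               t = stat, p_value = p)
  }))

  structure(list(summary = summ, tests = tests, n_pairs = sum(ok)),
            class = "ensemble_result")
}

#' Run the paired healthy-vs-occluded ensemble study
#'
#' Generates `n` networks, runs the full pipeline on each in the healthy
#' condition and again with a fraction of vessels occluded (paired on the
#' same parent network), and aggregates with paired t-tests.
#'
#' @param config Generator configuration.
#' @param n Ensemble size (default 20).
#' @param occlusion Occluded fraction (default 0.2).
#' @param seed_base First seed; seeds are `seed_base + 0:(n-1)`.
#' @param delta_p Pressure difference, Pa (default 1000).
#' @param ... Passed to [run_condition()].
#' @return List with `normal`, `occluded` (per-network data frames) and
#'   `aggregate` (an `ensemble_result`).
#' @export
run_ensemble <- function(config = default_network_config(), n = 20,
                         occlusion = 0.2, seed_base = 1L, delta_p = 1000,
                         ...) {
  seeds <- as.integer(seed_base) + seq_len(n) - 1L
  normal <- run_condition(config, seeds, occlusion = 0,
                          delta_p = delta_p, ...)
  occluded <- run_condition(config, seeds, occlusion = occlusion,
                            delta_p = delta_p, ...)
  list(normal = normal, occluded = occluded,
       aggregate = aggregate_and_test(normal, occluded))
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d paired networks\n", x$n_pairs))
  wide <- stats::reshape(
    x$summary[, c("quantity", "condition", "mean", "sd")],
    direction = "wide", idvar = "quantity", timevar = "condition")
  merged <- merge(wide, x$tests[, c("quantity", "p_value")], by = "quantity",
                  sort = FALSE)
  print(merged, row.names = FALSE, digits = 4)
  invisible(x)
}
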