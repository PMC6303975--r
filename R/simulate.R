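# Run `expr` under a local RNG state seeded with `seed` (if non-NULL),
# restoring the caller's state afterwards.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-scenario substream seed: a Lehmer-style hash of the
# scenario's defining parameters folded into the root seed, so adding or
# reordering scenarios in a grid never perturbs other scenarios' draws.
scenario_seed <- function(seed, scenario) {
  key <- sprintf("%.12g|%s|%.12g|%.12g|%d",
                 scenario$expected_total, scenario$population,
                 scenario$rate_ratio, scenario$total_population,
                 length(scenario$denominators))
  m <- 2147483647  # 2^31 - 1
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 48271 + b) %% m
  as.integer((h + seed) %% m)
}

#' Draw one replicate of stratified Poisson counts
#'
#' Event counts in each age group are independent Poisson with means
#' `lambda_i = d_i * theta_i`. Uses (and advances) the current R random
#' number generator state.
#'
#' @param scenario a [make_scenario()] object.
#' @return Integer vector of counts, one per group.
#' @export
draw_counts <- function(scenario) {
  stopifnot(inherits(scenario, "dsr_scenario"))
  stats::rpois(length(scenario$lambda), scenario$lambda)
}

# Shared simulation core: draws `n_reps` replicates and returns
# per-replicate coverage indicators, normalized limits and zero-group
# counts for all three methods.
simulate_replicates <- function(scenario, n_reps, level) {
  lambda <- scenario$lambda
  G <- length(lambda)
  x <- matrix(stats::rpois(G * n_reps, lambda), nrow = G)
  ci <- ci_engine(x, scenario$denominators, scenario$stdpop$weight, level,
                  n_groups = G)
  truth <- scenario$true_dsr
  methods <- c("normal", "dobson", "tiwari")
  # Replicates with zero total events are tallied as non-covering for
  # every method: the normal and Dobson intervals degenerate to [0, 0],
  # and although the Tiwari interval keeps positive width at X = 0 it is
  # tallied as non-covering as well (an estimate with no observed events
  # carries no rate information). See the methods vignette.
  nonzero <- ci$total > 0
  covered <- lapply(ci[methods], function(m) {
    m$lower <= truth & truth <= m$upper & nonzero
  })
  names(covered) <- methods
  list(
    total = ci$total,
    zero_groups = colSums(x == 0L),
    covered = covered,
    lcl_ratio = lapply(ci[methods], function(m) m$lower / truth),
    ucl_ratio = lapply(ci[methods], function(m) m$upper / truth)
  )
}

#' Simulate interval coverage for a scenario
#'
#' Draws `n_reps` replicates of stratified Poisson counts, computes the
#' DSR and all three confidence intervals per replicate, and tallies, per
#' method, the percentage of replicates whose interval contains the true
#' DSR (equivalently, whose interval divided by the true DSR contains 1;
#' containment is closed) along with the medians of the normalized
#' confidence limits. Replicates with zero total events are retained in
#' the tallies but counted as non-covering for all three methods: the
#' normal and Dobson intervals degenerate to `[0, 0]`, and the Tiwari
#' interval, though of positive width, is likewise tallied as
#' non-covering when no events at all were observed.
#'
#' @param scenario a [make_scenario()] object.
#' @param n_reps number of Monte Carlo replicates (default 10,000).
#' @param seed optional integer seed; the caller's RNG state is restored
#'   on exit. Identical `(scenario, n_reps, seed)` give identical results.
#' @param level confidence level (default 0.95).
#' @return A `dsr_sim` object: list with `scenario`, `n_reps`, `seed`,
#'   `level`, a per-method summary data frame `methods` (columns
#'   `method`, `coverage_pct`, `median_lcl_ratio`, `median_ucl_ratio`,
#'   `classification`), a named vector `zero_histogram` (replicates by
#'   number of zero-count groups), and `coverage_by_zero`, a data frame
#'   of per-method coverage within each zero-count stratum.
#' @export
run_scenario <- function(scenario, n_reps = 10000, seed = NULL,
                         level = 0.95) {
  stopifnot(inherits(scenario, "dsr_scenario"))
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  sim <- with_local_seed(seed, simulate_replicates(scenario, n_reps, level))
  methods <- names(sim$covered)
  summ <- do.call(rbind, lapply(methods, function(m) {
    cov_pct <- 100 * mean(sim$covered[[m]])
    data.frame(
      method = m,
      coverage_pct = cov_pct,
      median_lcl_ratio = stats::median(sim$lcl_ratio[[m]]),
      median_ucl_ratio = stats::median(sim$ucl_ratio[[m]]),
      classification = classify_coverage(cov_pct, 100 * level)
    )
  }))
  rownames(summ) <- NULL

  zero_tab <- table(factor(sim$zero_groups,
                           levels = sort(unique(sim$zero_groups))))
  zero_hist <- stats::setNames(as.integer(zero_tab), names(zero_tab))
  by_zero <- do.call(rbind, lapply(as.integer(names(zero_tab)), function(z) {
    idx <- sim$zero_groups == z
    row <- data.frame(n_zero_groups = z, n_reps = sum(idx),
                      rel_freq_pct = 100 * mean(idx))
    for (m in methods) {
      row[[paste0("coverage_", m)]] <- 100 * mean(sim$covered[[m]][idx])
    }
    row
  }))
  rownames(by_zero) <- NULL

  out <- list(scenario = scenario, n_reps = n_reps, seed = seed,
              level = level, methods = summ, zero_histogram = zero_hist,
              coverage_by_zero = by_zero)
  class(out) <- "dsr_sim"
  out
}

#' @export
print.dsr_sim <- function(x, ...) {
  cat(sprintf(
    "Coverage simulation: E = %g events, population %s, rate ratio %g (%d reps, %g%% CIs)\n",
    x$scenario$expected_total, x$scenario$population,
    x$scenario$rate_ratio, x$n_reps, 100 * x$level))
  print(x$methods, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Exact coverage for standard-proportional populations
#'
#' When the sample population is proportional to the standard population,
#' every interval method depends on the data only through the total count
#' `X`, which is Poisson with mean `expected_total`. Coverage can then be
#' computed exactly by Poisson summation instead of Monte Carlo:
#' `100 * sum_k P(X = k) * 1[interval at total k covers the true rate]`.
#'
#' @param expected_total expected total number of events `E`.
#' @param method `"normal"`, `"dobson"` or `"tiwari"`.
#' @param level confidence level.
#' @param total_population total exposed population (default 190,000).
#' @param stdpop standard population.
#' @param max_k upper summation bound; defaults to a bound leaving
#'   Poisson tail mass below 1e-12.
#' @return Exact coverage in percent.
#' @export
analytic_coverage_esp <- function(expected_total, method, level = 0.95,
                                  total_population = 190000,
                                  stdpop = esp2013(), max_k = NULL) {
  method <- match.arg(method, c("normal", "dobson", "tiwari"))
  sp <- as_standard_pop(stdpop)
  G <- nrow(sp)
  d <- esp_proportional_population(total_population, sp)
  truth <- expected_total / total_population
  if (is.null(max_k)) {
    max_k <- stats::qpois(1e-12, expected_total, lower.tail = FALSE) + 10
  }
  ks <- 0:max_k
  # allocation across groups is irrelevant when d is proportional to w:
  # place each total in the first group
  x <- matrix(0, nrow = G, ncol = length(ks))
  x[1, ] <- ks
  ci <- ci_engine(x, d, sp$weight, level, n_groups = G)[[method]]
  # same zero-total convention as run_scenario: k = 0 never covers
  covers <- ci$lower <= truth & truth <= ci$upper & ks > 0
  100 * sum(stats::dpois(ks, expected_total) * covers)
}

#' Tail probabilities of the observed total event count
#'
#' For each expected total `E`, the total observed count is Poisson(`E`)
#' (a sum of independent Poisson strata). Tabulates the probability of
#' observing `k` or more events, both simulated and exact
#' (`100 * P(Poisson(E) >= k)`).
#'
#' @param expected_totals expected totals `E` (default 1 to 5).
#' @param thresholds integer thresholds `k` (default 0 to 16).
#' @param n_reps Monte Carlo replicates per expected total.
#' @param seed optional integer seed.
#' @return A `dsr_tail_table` data frame with columns `expected`,
#'   `threshold`, `simulated_pct`, `exact_pct`.
#' @examples
#' tt <- observed_tail_table(1, thresholds = 0:2, n_reps = 1000, seed = 1)
#' @export
observed_tail_table <- function(expected_totals = 1:5, thresholds = 0:16,
                                n_reps = 10000, seed = NULL) {
  if (any(expected_totals <= 0)) {
    stop("`expected_totals` must be positive", call. = FALSE)
  }
  if (any(thresholds < 0) || any(thresholds != round(thresholds))) {
    stop("`thresholds` must be nonnegative integers", call. = FALSE)
  }
  out <- with_local_seed(seed, {
    do.call(rbind, lapply(expected_totals, function(E) {
      totals <- stats::rpois(n_reps, E)
      data.frame(
        expected = E,
        threshold = thresholds,
        simulated_pct = vapply(thresholds,
                               function(k) 100 * mean(totals >= k), 0),
        exact_pct = 100 * stats::ppois(thresholds - 1, E,
                                       lower.tail = FALSE)
      )
    }))
  })
  rownames(out) <- NULL
  class(out) <- c("dsr_tail_table", "data.frame")
  out
}

#' Coverage by number of zero-count age groups
#'
#' Groups simulation replicates by how many age groups observed no
#' events, and reports each group's relative frequency and empirical
#' coverage for one interval method. Groups seen in less than 1% of
#' replicates are flagged as rare (their coverage estimates are noisy).
#'
#' @inheritParams run_scenario
#' @param method `"normal"`, `"dobson"` or `"tiwari"`.
#' @return Data frame with columns `n_zero_groups`, `n_reps`,
#'   `rel_freq_pct`, `coverage_pct`, `rare`.
#' @export
zero_category_breakdown <- function(scenario, n_reps = 10000, seed = NULL,
                                    level = 0.95, method = "dobson") {
  method <- match.arg(method, c("normal", "dobson", "tiwari"))
  sim <- run_scenario(scenario, n_reps = n_reps, seed = seed, level = level)
  bz <- sim$coverage_by_zero
  out <- data.frame(
    n_zero_groups = bz$n_zero_groups,
    n_reps = bz$n_reps,
    rel_freq_pct = bz$rel_freq_pct,
    coverage_pct = bz[[paste0("coverage_", method)]],
    rare = bz$rel_freq_pct < 1
  )
  rownames(out) <- NULL
  out
}
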