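#' Linear age structure for a sample population
#'
#' Denominators fall linearly across age groups from youngest to oldest,
#' with a given youngest-to-oldest ratio and a fixed total. With
#' `ratio = 1` all groups are the same size.
#'
#' @param total total exposed population across all groups.
#' @param ratio ratio of the youngest group's size to the oldest's
#'   (`>= 1`).
#' @param n_groups number of age groups (`>= 2`).
#' @return Numeric vector of denominators `d_i` summing to `total`
#'   (real-valued, not rounded).
#' @examples
#' linear_population(190000, 1, 19)   # all 10,000
#' linear_population(190000, 50, 19)  # 19607.8 down to 392.2
#' @export
linear_population <- function(total, ratio, n_groups) {
  if (!is.numeric(total) || total <= 0) {
    stop("`total` must be positive", call. = FALSE)
  }
  if (!is.numeric(ratio) || ratio < 1) {
    stop("`ratio` (youngest to oldest) must be >= 1", call. = FALSE)
  }
  if (n_groups < 2) stop("`n_groups` must be at least 2", call. = FALSE)
  d_old <- 2 * total / (n_groups * (1 + ratio))
  d_young <- ratio * d_old
  d_young + (seq_len(n_groups) - 1) * (d_old - d_young) / (n_groups - 1)
}

#' Sample population proportional to a standard population
#'
#' Allocates a total population across groups with the same age
#' distribution as the standard population: `d_i = total * w_i / sum(w)`.
#' For such populations `w_i / d_i` is constant, so the Dobson and Tiwari
#' intervals coincide with the exact Poisson (Garwood) interval for the
#' total count divided by the total population.
#'
#' @param total total exposed population.
#' @param stdpop standard population (default ESP2013).
#' @return Numeric vector of denominators.
#' @export
esp_proportional_population <- function(total, stdpop = esp2013()) {
  if (!is.numeric(total) || total <= 0) {
    stop("`total` must be positive", call. = FALSE)
  }
  w <- as_standard_pop(stdpop)$weight
  total * w / sum(w)
}

#' Linear age-specific rate schedule calibrated to an expected total
#'
#' Rates rise linearly across age groups with a given oldest-to-youngest
#' ratio, with the base rate solved so that the expected total event
#' count `sum(d_i * theta_i)` equals `expected_total` exactly.
#'
#' @param rate_ratio ratio of the oldest group's rate to the youngest's
#'   (`>= 1`; 1 means no association with age).
#' @param denominators group denominators `d_i`.
#' @param expected_total target expected total number of events (> 0).
#' @return Numeric vector of rates `theta_i` (events per person).
#' @examples
#' d <- rep(10000, 19)
#' th <- linear_rate_schedule(1, d, 5)    # constant 5/190000
#' sum(d * th)                            # exactly 5
#' @export
linear_rate_schedule <- function(rate_ratio, denominators, expected_total) {
  if (!is.numeric(rate_ratio) || rate_ratio < 1) {
    stop("`rate_ratio` (oldest to youngest) must be >= 1", call. = FALSE)
  }
  if (!is.numeric(expected_total) || expected_total <= 0) {
    stop("`expected_total` must be positive", call. = FALSE)
  }
  if (any(denominators <= 0)) {
    stop("`denominators` must be strictly positive", call. = FALSE)
  }
  n <- length(denominators)
  shape <- 1 + (seq_len(n) - 1) * (rate_ratio - 1) / (n - 1)
  theta1 <- expected_total / sum(denominators * shape)
  theta1 * shape
}

#' True standardized rate of a rate schedule
#'
#' Standardizes the generating age-specific rates themselves:
#' `sum(w_i * theta_i) / sum(w_i)`. This is the estimand of a simulation
#' scenario.
#'
#' @param rates age-specific rates `theta_i`.
#' @param stdpop standard population.
#' @return The true DSR (events per person).
#' @export
true_dsr <- function(rates, stdpop = esp2013()) {
  w <- as_standard_pop(stdpop)$weight
  if (length(rates) != length(w)) {
    stop("`rates` must have one entry per standard-population group",
         call. = FALSE)
  }
  if (any(rates < 0)) stop("`rates` must be nonnegative", call. = FALSE)
  sum(w * rates) / sum(w)
}

#' Variability of standard-to-sample population weights
#'
#' A scale-invariant diagnostic of how much a sample population's age
#' distribution differs from the standard population, based on the
#' ratios `r_i = w_i / d_i`. It is exactly 0 when the sample has the
#' standard's age distribution. Because the source description of this
#' measure is ambiguous, the variance estimator and normalizer are
#' selectable; the default divides the sample variance of `r_i` by
#' `(sum r_i)^2`. The measure is purely descriptive and gates no logic.
#'
#' @param stdpop standard population.
#' @param denominators sample-population denominators `d_i`.
#' @param denominator normalizer: `"sum_squared"` for `(sum r)^2`
#'   (default) or `"sum_of_squares"` for `sum(r^2)`.
#' @param variance `"sample"` (default, divisor n-1) or `"population"`
#'   (divisor n).
#' @return A nonnegative scalar.
#' @examples
#' weight_variability(esp2013(), esp_proportional_population(190000))  # 0
#' @export
weight_variability <- function(stdpop, denominators,
                               denominator = c("sum_squared", "sum_of_squares"),
                               variance = c("sample", "population")) {
  denominator <- match.arg(denominator)
  variance <- match.arg(variance)
  w <- as_standard_pop(stdpop)$weight
  if (length(denominators) != length(w)) {
    stop("`denominators` must have one entry per standard-population group",
         call. = FALSE)
  }
  if (any(denominators <= 0)) {
    stop("`denominators` must be strictly positive", call. = FALSE)
  }
  r <- w / denominators
  v <- if (variance == "sample") stats::var(r) else mean((r - mean(r))^2)
  den <- if (denominator == "sum_squared") sum(r)^2 else sum(r^2)
  v / den
}

#' Construct a simulation scenario
#'
#' A scenario fixes the generating process of one simulation condition:
#' group denominators, age-specific rates calibrated to an expected total
#' event count, and hence the Poisson means `lambda_i = d_i * theta_i`
#' and the true DSR. Construction is deterministic.
#'
#' @param expected_total target expected total events `sum(d_i theta_i)`.
#' @param population either `"EU"` (sample population proportional to the
#'   standard) or a numeric youngest-to-oldest ratio `>= 1` for a linear
#'   age structure (1 = equal group sizes).
#' @param rate_ratio oldest-to-youngest rate ratio `>= 1`.
#' @param total_population total exposed population (default 190,000).
#' @param stdpop standard population.
#' @return A `dsr_scenario` object: list with elements `denominators`,
#'   `rates`, `lambda`, `expected_total`, `true_dsr`, `population`,
#'   `rate_ratio`, `total_population`, `stdpop`.
#' @examples
#' sc <- make_scenario(5, population = 1, rate_ratio = 5000)
#' sum(sc$lambda)  # 5
#' @export
make_scenario <- function(expected_total, population = 1, rate_ratio = 1,
                          total_population = 190000, stdpop = esp2013()) {
  sp <- as_standard_pop(stdpop)
  n <- nrow(sp)
  pop_label <- as.character(population)
  if (identical(pop_label, "EU")) {
    d <- esp_proportional_population(total_population, sp)
  } else {
    ratio <- suppressWarnings(as.numeric(population))
    if (is.na(ratio)) {
      stop("`population` must be \"EU\" or a numeric youngest-to-oldest ratio",
           call. = FALSE)
    }
    d <- linear_population(total_population, ratio, n)
  }
  theta <- linear_rate_schedule(rate_ratio, d, expected_total)
  out <- list(
    denominators = d,
    rates = theta,
    lambda = d * theta,
    expected_total = expected_total,
    true_dsr = true_dsr(theta, sp),
    population = pop_label,
    rate_ratio = rate_ratio,
    total_population = total_population,
    stdpop = sp
  )
  class(out) <- "dsr_scenario"
  out
}

#' @export
print.dsr_scenario <- function(x, ...) {
  cat(sprintf(
    "DSR simulation scenario: %d groups, population %s (total %s), rate ratio %g\n",
    length(x$denominators), x$population,
    format(x$total_population, big.mark = ","), x$rate_ratio))
  cat(sprintf("  expected total events: %g\n", x$expected_total))
  cat(sprintf("  true DSR: %.6g per person\n", x$true_dsr))
  invisible(x)
}
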