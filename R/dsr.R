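#' Directly standardized rate
#'
#' The directly standardized rate (DSR) is the weighted average of the
#' stratum-specific rates `x_i / d_i`, with weights `w_i` taken from a
#' standard population:
#' \deqn{R = \frac{1}{\sum w_i} \sum \frac{w_i x_i}{d_i}.}
#'
#' @param events nonnegative integer event counts `x_i`, one per stratum.
#' @param population strictly positive person(-year) denominators `d_i`.
#' @param stdpop a standard population (see [standard_pop()]); defaults
#'   to the 2013 European Standard Population.
#' @return The DSR, in events per person(-year).
#' @examples
#' dsr(events = c(2, 1), population = c(1000, 100),
#'     stdpop = c(a = 5000, b = 1000))  # 1/300
#' @export
dsr <- function(events, population, stdpop = esp2013()) {
  w <- as_standard_pop(stdpop)$weight
  check_counts(events, population, w)
  sum(w * events / population) / sum(w)
}

#' Upper-tail chi-squared quantile
#'
#' Returns the value `q` such that `P(X > q) = p` for a chi-squared
#' random variable `X` with `df` degrees of freedom, i.e. the
#' 100(1-p)th percentile. All interval formulas in this package use this
#' upper-tail convention through this one function. For `df = 0` the
#' distribution is a point mass at zero and the quantile is 0.
#'
#' @param p upper-tail probability, strictly between 0 and 1.
#' @param df degrees of freedom, nonnegative (need not be integer).
#' @return The quantile(s); vectorized over both arguments.
#' @examples
#' chisq_quantile(0.975, 20)  # 9.5908
#' chisq_quantile(0.025, 22)  # 36.781
#' @export
chisq_quantile <- function(p, df) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("`p` must be strictly between 0 and 1", call. = FALSE)
  }
  if (any(df < 0)) stop("`df` must be nonnegative", call. = FALSE)
  stats::qchisq(p, df, lower.tail = FALSE)
}

#' Confidence intervals for a directly standardized rate
#'
#' Computes the DSR and its confidence limits by one or more of three
#' methods:
#'
#' * `"normal"`: the asymptotic interval `R +/- z * sqrt(V)` with
#'   `V = sum(w_i^2 x_i / d_i^2) / (sum w_i)^2`. Symmetric about `R`;
#'   the lower limit may be negative and is not truncated.
#' * `"dobson"`: maps the exact (Garwood) chi-squared interval for the
#'   total count `X = sum(x_i)` onto the DSR scale through the ratio of
#'   the DSR's standard error to that of the total count. The lower limit
#'   is truncated at zero (the mapping can otherwise dip marginally below
#'   zero when the observed events carry little standardization weight).
#' * `"tiwari"`: a modified gamma interval for a weighted sum of Poisson
#'   counts, with a small-sample correction term `1/n` spread over the
#'   `n` strata; its upper limit is strictly positive even for zero
#'   observed events.
#'
#' When no events are observed at all, the normal and Dobson intervals
#' degenerate to `[0, 0]` (their scale factors are 0/0 limits), while
#' the Tiwari correction terms keep its upper limit positive.
#'
#' @inheritParams dsr
#' @param method character vector, any of `"dobson"`, `"tiwari"`,
#'   `"normal"`, or `"all"`.
#' @param level confidence level, e.g. `0.95`.
#' @param n_groups the `n` of the Tiwari correction terms: the number of
#'   strata. Defaults to the number of groups in `stdpop`.
#' @return A data frame with one row per method and columns `method`,
#'   `level`, `rate`, `lower`, `upper`.
#' @examples
#' sp <- esp2013()
#' x <- rep(1, 19)
#' d <- rep(10000, 19)
#' dsr_ci(x, d, sp, method = "all")
#' @export
dsr_ci <- function(events, population, stdpop = esp2013(),
                   method = c("dobson", "tiwari", "normal"),
                   level = 0.95, n_groups = NULL) {
  sp <- as_standard_pop(stdpop)
  w <- sp$weight
  check_counts(events, population, w)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  if ("all" %in% method) method <- c("normal", "dobson", "tiwari")
  method <- match.arg(method, c("dobson", "tiwari", "normal"),
                      several.ok = TRUE)
  if (is.null(n_groups)) n_groups <- length(w)
  ci <- ci_engine(matrix(events, ncol = 1), population, w, level, n_groups)
  out <- do.call(rbind, lapply(method, function(m) {
    data.frame(method = m, level = level, rate = ci$rate,
               lower = ci[[m]]$lower, upper = ci[[m]]$upper)
  }))
  rownames(out) <- NULL
  out
}

# Vectorized interval engine. `x` is a groups-by-replicates matrix;
# returns per-replicate rates, totals and limits for all three methods.
# This is the single code path used by dsr_ci() and the simulation engine.
ci_engine <- function(x, d, w, level, n_groups = length(w)) {
  alpha <- 1 - level
  sw <- sum(w)
  r1 <- w / d          # w_i / d_i
  r2 <- r1^2           # w_i^2 / d_i^2
  X <- colSums(x)
  R <- colSums(x * r1) / sw
  S <- colSums(x * r2)               # sum w_i^2 x_i / d_i^2
  V <- S / sw^2

  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(V)
  normal <- list(lower = R - half, upper = R + half)

  # Dobson: degenerate [0, 0] when X = 0 (0/0 scale factor)
  pos <- X > 0
  Fd <- numeric(length(X))
  Fd[pos] <- sqrt(V[pos] / X[pos])
  dob_l <- dob_u <- numeric(length(X))
  if (any(pos)) {
    Xp <- X[pos]
    # the mapping can push the lower limit marginally below zero when the
    # events sit in strata with little weight leverage; a rate bound is
    # truncated at zero (coverage is unaffected: the true rate is positive)
    dob_l[pos] <- pmax(0, R[pos] + Fd[pos] *
      (chisq_quantile(1 - alpha / 2, 2 * Xp) / 2 - Xp))
    dob_u[pos] <- R[pos] + Fd[pos] *
      (chisq_quantile(alpha / 2, 2 * Xp + 2) / 2 - Xp)
  }
  dobson <- list(lower = dob_l, upper = dob_u)

  # Tiwari modified gamma; correction terms keep the UCL positive at X = 0
  tiw_l <- numeric(length(X))
  if (any(pos)) {
    df_l <- 2 * R[pos]^2 * sw^2 / S[pos]
    tiw_l[pos] <- S[pos] / (2 * R[pos] * sw^2) *
      chisq_quantile(1 - alpha / 2, df_l)
  }
  A <- S + sum(r2) / n_groups
  B <- R + sum(r1) / (n_groups * sw)
  tiw_u <- A / (2 * sw^2 * B) * chisq_quantile(alpha / 2, 2 * B^2 * sw^2 / A)
  tiwari <- list(lower = tiw_l, upper = tiw_u)

  list(rate = R, total = X, normal = normal, dobson = dobson,
       tiwari = tiwari)
}

check_counts <- function(events, population, w) {
  if (length(events) != length(w) || length(population) != length(w)) {
    stop(sprintf(
      "`events` and `population` must each have one entry per standard-population group (%d)",
      length(w)), call. = FALSE)
  }
  if (anyNA(events) || anyNA(population)) {
    stop("`events` and `population` must not contain missing values",
         call. = FALSE)
  }
  if (any(population <= 0)) {
    stop("all `population` denominators must be strictly positive",
         call. = FALSE)
  }
  if (any(events < 0) || any(abs(events - round(events)) > 1e-8)) {
    stop("`events` must be nonnegative integers", call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify empirical coverage as accurate, conservative or liberal
#'
#' A confidence interval's empirical coverage is *accurate* when it is
#' within 40% of the nominal error rate of the nominal level: for a 95%
#' interval, between 93% and 97%. Coverage above the band is
#' *conservative*, below it *liberal*.
#'
#' @param coverage_pct empirical coverage, in percent (0-100); vectorized.
#' @param nominal_pct nominal level in percent, default 95.
#' @return Character vector: `"accurate"`, `"conservative"` or `"liberal"`.
#' @examples
#' classify_coverage(c(95, 97.5, 92.9))  # accurate, conservative, liberal
#' @export
classify_coverage <- function(coverage_pct, nominal_pct = 95) {
  if (any(coverage_pct < 0) || any(coverage_pct > 100)) {
    stop("`coverage_pct` must lie in [0, 100]", call. = FALSE)
  }
  if (any(nominal_pct <= 0) || any(nominal_pct >= 100)) {
    stop("`nominal_pct` must lie strictly between 0 and 100", call. = FALSE)
  }
  err <- 100 - nominal_pct
  lo <- nominal_pct - 0.4 * err
  hi <- nominal_pct + 0.4 * err
  ifelse(coverage_pct > hi, "conservative",
         ifelse(coverage_pct < lo, "liberal", "accurate"))
}
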