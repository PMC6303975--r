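---
title: "Standardized rates from sparse counts: methods and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized rates from sparse counts: methods and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrci)
```

## The problem

Directly standardized rates (DSRs) let event rates — deaths, incident
cancers, suicides — be compared across populations with different age
structures. Each population's age-specific rates are applied to a common
standard age distribution, so that differences in the standardized rates
reflect differences in risk rather than differences in demography.
National statistical agencies publish DSRs routinely, and many of the
reporting units (districts, registries, rare diagnoses) observe only a
handful of events. The question this package is built around is: *how
small can the event count get before the DSR's confidence interval stops
meaning what it says?*

With events $x_i$ and person denominators $d_i$ in $n$ age groups, and
standard weights $w_i$, the DSR is

$$R = \frac{1}{\sum_i w_i} \sum_i \frac{w_i x_i}{d_i},$$

a weighted sum of independent Poisson counts scaled by $w_i/d_i$. The
default standard is the 2013 European Standard Population: 19 five-year
groups (0–4 through 90+) with weights summing to 100,000. Any standard
can be substituted (`standard_pop()`, `read_standard_pop()`).

## The three interval estimators

All three methods are exposed through `dsr_ci()`. Throughout,
$X = \sum_i x_i$, $S = \sum_i w_i^2 x_i / d_i^2$, $W = \sum_i w_i$, and
$V = S / W^2$ is the variance estimate of $R$. Chi-squared quantiles are
taken upper-tail through one shared function, `chisq_quantile(p, df)`
($=$ the $100(1-p)$th percentile), so no formula can mix its tails.

**Normal approximation.** $R \pm z_{1-\alpha/2}\sqrt{V}$. Symmetric, and
the lower limit is deliberately *not* truncated at zero: producing
impossible negative rate bounds at small counts is part of this method's
observed behaviour. It is the benchmark the other two methods are judged
against, and it needs on the order of 100 events to be trustworthy.

**Dobson.** The exact (Garwood) chi-squared interval for the total count
$X$, mapped onto the DSR scale by the ratio of standard errors
$F = \sqrt{V/X}$:

$$\mathrm{LCL} = R + F\left(\tfrac{1}{2}\chi^2_{2X}(1-\alpha/2) - X\right),
\qquad
\mathrm{UCL} = R + F\left(\tfrac{1}{2}\chi^2_{2X+2}(\alpha/2) - X\right),$$

with $\chi^2_\nu(p)$ upper-tail. One non-obvious numerical point: the
Cauchy–Schwarz inequality bounds $R \le \sqrt{V X}$ (not the reverse), so
when the observed events sit in strata with very little standardization
leverage the raw lower limit can dip slightly below zero. Since a rate is
nonnegative, `dsr_ci()` truncates the Dobson lower limit at zero; this
never changes coverage, because the true rate is positive.

**Tiwari modified gamma.** A gamma-type interval for the weighted Poisson
sum with a small-sample correction of one extra "average" event spread
across the $n$ strata:

$$\mathrm{LCL} = \frac{S}{2RW^2}\,
  \chi^2_{2R^2W^2/S}(1-\alpha/2), \qquad
\mathrm{UCL} = \frac{S + \tfrac{1}{n}\sum_i w_i^2/d_i^2}
  {2W^2\left(R + \tfrac{1}{nW}\sum_i w_i/d_i\right)}\,
  \chi^2_{\nu^*}(\alpha/2),$$

where $\nu^*$ is the matched degrees of freedom of the corrected
numerator. The $n$ here is the number of age categories (19 by default);
that choice is configurable via `n_groups` but there is no reason to vary
it when the counts span all strata. When the sample population has
exactly the standard's age distribution ($d_i \propto w_i$), both the
Dobson and Tiwari formulas reduce algebraically to the Garwood interval
for $X$ divided by the total population, so the two methods coincide —
the test suite checks this identity to $10^{-9}$ relative and against an
independently coded Garwood oracle.

**Zero total events.** At $X = 0$ the Dobson scale factor is a $0/0$
limit, so the normal and Dobson intervals are reported as the degenerate
$[0, 0]$. The Tiwari correction terms stay positive, so its interval is
$[0, \mathrm{UCL} > 0]$ — a usable upper bound even with no events. In
coverage *tallies*, however, zero-total replicates are counted as
non-covering for all three methods: an estimate built on no events
carries no rate information, and treating the Tiwari interval as covering
there would overstate its small-count coverage by up to ~0.7 percentage
points at five expected events (we verified both conventions; only this
one reproduces the published simulation behaviour of all three methods
simultaneously).

## What "accurate" means

`classify_coverage()` labels empirical coverage of a $100p\%$ interval
*accurate* when it is within 40% of the nominal error rate: between 93%
and 97% for a 95% interval (inclusive band edges). Above the band is
*conservative*, below is *liberal*. Conservative intervals are usually
the lesser evil; liberal ones silently overstate certainty.

## The simulation framework

`make_scenario()` constructs the generating process; `run_scenario()`
simulates it. A scenario is fully determined by four quantities:

| parameter | meaning | default / grid values |
|---|---|---|
| `expected_total` | expected events $E=\sum_i d_i\theta_i$ | 1–15, 25, 100 |
| `population` | youngest:oldest denominator ratio (linear in age), or `"EU"` for the standard's own distribution | 1, 5, 50, `"EU"` |
| `rate_ratio` | oldest:youngest rate ratio (linear in age) | 1, 50, 500, 5000 |
| `total_population` | $\sum_i d_i$ | 190,000 |

Denominators fall linearly from youngest to oldest (`linear_population()`),
and rates rise linearly with age (`linear_rate_schedule()`), with the base
rate solved exactly so that $\sum_i d_i \theta_i = E$. A rate ratio of
5000 is realistic: stroke mortality in the oldest men exceeds that of
teenagers by more than that factor. The total of 190,000 is a typical
English local-authority scale (10,000 per stratum on average); results
are insensitive to it because everything is tallied relative to the true
DSR $\sum_i w_i \theta_i / \sum_i w_i$. Linearity is not restrictive:
the DSR is invariant to permuting strata together with their weights, so
the schedules simply control how strongly events cluster into few
strata. Counts are independent Poisson draws — appropriate for rare,
non-contagious events, and *not* for infectious outbreaks or
shared-shock mortality, where these intervals should not be used. The
generator also does not emulate real demographic age pyramids beyond the
linear and standard-proportional shapes, nor non-Poisson overdispersion;
passing coverage here demonstrates correctness of the estimators under
the Poisson model, not robustness to model failure.

Each replicate's three intervals are divided by the true DSR and checked
for containing 1 (closed intervals; identical to checking the unscaled
interval against the true DSR — the suite asserts this equivalence).
The default 10,000 replicates put the Monte Carlo standard error of a
coverage estimate near 95% at about 0.22 percentage points; the full
30-scenario headline grid takes a few seconds. Medians of the normalized
limits use R's default midpoint interpolation at even replicate counts.

**Seeding.** `run_grid()` derives one deterministic substream per
scenario by hashing the scenario's defining parameters into the root
seed (a Lehmer-style integer hash, kept below $2^{31}$), so extending
the grid never perturbs existing rows, and identical configurations are
bit-reproducible. All simulation entry points restore the caller's RNG
state.

**Exact oracle.** For standard-proportional populations every method
depends on the data only through $X \sim \mathrm{Poisson}(E)$, so
`analytic_coverage_esp()` computes coverage exactly by Poisson summation
(tail mass below $10^{-12}$ truncated). The suite requires the 10,000-rep
simulation to sit within three binomial standard errors of this exact
value — a strong end-to-end check of the whole chain.

## The small-count suppression rule

In practice the *expected* number of events is unknown; only the
observed count is available. `observed_tail_table()` tabulates
$P(X \ge k)$ by expected total, simulated and exact: observing 10 or more
events is very unlikely (under 1%) whenever the expected count is four
or fewer, so an observed count of 10+ essentially guarantees the regime
where both Dobson and Tiwari intervals are accurate. `dsr_rates()`
therefore flags units with fewer than 10 total events as `suppressed`
(threshold configurable; 9 is defensible in less cautious settings).
The rule depends only on the total count and the threshold.

## Known limitations

* The Poisson assumption excludes contagious processes and common-shock
  event clusters.
* The weight-variability diagnostic (`weight_variability()`) summarizes
  how far a sample population departs from the standard; published uses
  of this measure state its algebra ambiguously, so the estimator and
  normalizer are selectable arguments, the default being the sample
  variance of $w_i/d_i$ over $(\sum_i w_i/d_i)^2$. It is descriptive
  only and gates no logic in this package.
* Coverage conclusions apply to 95% intervals over 19 strata; other
  nominal levels and much coarser stratifications are supported by the
  code but were not the focus of the validation grid.

## A worked example

```{r example}
sp <- esp2013()
counts <- data.frame(
  age_group = sp$age_group,
  events = c(0, 0, 0, 1, 0, 1, 0, 2, 1, 0, 2, 1, 3, 2, 4, 3, 2, 1, 1),
  population = round(linear_population(170000, 5, 19))
)
dsr_rates(counts, scale = 10000)
```

The unit has 24 events, so the rate is publishable; the Dobson and
Tiwari limits nearly agree, while the normal limits are visibly
narrower — at 24 events the normal approximation is still slightly
liberal.

```{r coverage}
sc <- make_scenario(10, population = "EU", rate_ratio = 1)
run_scenario(sc, n_reps = 2000, seed = 1)
analytic_coverage_esp(10, "dobson")
```
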