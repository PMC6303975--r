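#' Default coverage-study grid configuration
#'
#' The 30-scenario grid of the headline coverage study: expected totals
#' 5, 10, 15, 25 and 100; sample populations with equal group sizes,
#' a 50:1 youngest-to-oldest linear structure, and the standard
#' population's own age distribution (`"EU"`); oldest-to-youngest rate
#' ratios 1 and 5000; 10,000 replicates of 95% intervals over a total
#' population of 190,000.
#'
#' @param n_reps,seed,level overrides for the simulation settings.
#' @return A named list understood by [run_grid()].
#' @export
coverage_grid_config <- function(n_reps = 10000, seed = 1, level = 0.95) {
  list(
    expected_totals = c(5, 10, 15, 25, 100),
    populations = c("1", "50", "EU"),
    rate_ratios = c(1, 5000),
    n_reps = n_reps,
    seed = seed,
    level = level,
    total_population = 190000
  )
}

#' Read a grid configuration from a YAML file
#'
#' Recognized keys are those of [coverage_grid_config()]; missing keys
#' take that default. Unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return A validated config list.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- coverage_grid_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  out <- utils::modifyList(base, cfg)
  validate_grid_config(out)
  out
}

validate_grid_config <- function(config) {
  need <- names(coverage_grid_config())
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop(sprintf("config is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  et <- config$expected_totals
  if (length(et) && (!is.numeric(et) || any(et <= 0))) {
    stop("config field `expected_totals` must be positive numbers",
         call. = FALSE)
  }
  rr <- config$rate_ratios
  if (length(rr) && (!is.numeric(rr) || any(rr < 1))) {
    stop("config field `rate_ratios` must be numbers >= 1", call. = FALSE)
  }
  pops <- as.character(config$populations)
  bad <- pops[pops != "EU" & is.na(suppressWarnings(as.numeric(pops)))]
  if (length(bad)) {
    stop(sprintf("config field `populations` has invalid entries: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  num <- pops[pops != "EU"]
  if (length(num) && any(as.numeric(num) < 1)) {
    stop("config field `populations` ratios must be >= 1", call. = FALSE)
  }
  if (!is.numeric(config$n_reps) || config$n_reps < 1) {
    stop("config field `n_reps` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    stop("config field `seed` must be a single integer", call. = FALSE)
  }
  if (!is.numeric(config$level) || config$level <= 0 || config$level >= 1) {
    stop("config field `level` must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (!is.numeric(config$total_population) || config$total_population <= 0) {
    stop("config field `total_population` must be positive", call. = FALSE)
  }
  invisible(config)
}

config_hash <- function(config) {
  key <- paste(deparse(config[order(names(config))]), collapse = "")
  m <- 2147483647
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 48271 + b) %% m
  sprintf("%08x", as.integer(h))
}

#' Run the full simulation grid
#'
#' Runs [run_scenario()] for every combination of expected total, sample
#' population and rate ratio in the configuration and returns one row per
#' scenario and method. Each scenario draws from its own deterministic
#' substream of the root seed, so results are reproducible and adding
#' scenarios never perturbs existing ones.
#'
#' @param config a list as returned by [coverage_grid_config()] or
#'   [read_grid_config()].
#' @param stdpop standard population.
#' @param quiet suppress the log message (seed, replicates, config hash).
#' @return Data frame with columns `expected_total`, `population`,
#'   `rate_ratio`, `method`, `coverage_pct`, `median_lcl_ratio`,
#'   `median_ucl_ratio`, `classification`, `n_reps`, `seed`.
#' @export
run_grid <- function(config = coverage_grid_config(), stdpop = esp2013(),
                     quiet = FALSE) {
  validate_grid_config(config)
  sp <- as_standard_pop(stdpop)
  if (!quiet) {
    message(sprintf("coverage grid: seed %d, %d replicates, config %s",
                    as.integer(config$seed), as.integer(config$n_reps),
                    config_hash(config)))
  }
  grid <- expand.grid(
    expected_total = config$expected_totals,
    population = as.character(config$populations),
    rate_ratio = config$rate_ratios,
    stringsAsFactors = FALSE
  )
  if (nrow(grid) == 0) {
    return(data.frame(expected_total = numeric(), population = character(),
                      rate_ratio = numeric(), method = character(),
                      coverage_pct = numeric(), median_lcl_ratio = numeric(),
                      median_ucl_ratio = numeric(),
                      classification = character(), n_reps = integer(),
                      seed = integer()))
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- make_scenario(grid$expected_total[i], grid$population[i],
                        grid$rate_ratio[i],
                        total_population = config$total_population,
                        stdpop = sp)
    sub <- scenario_seed(config$seed, sc)
    sim <- run_scenario(sc, n_reps = config$n_reps, seed = sub,
                        level = config$level)
    cbind(grid[i, , drop = FALSE], sim$methods,
          n_reps = config$n_reps, seed = sub, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a tail table to CSV
#'
#' Runs [observed_tail_table()] and writes the result. The machine layout
#' (default) is one long row per (expected, threshold) at full precision;
#' the display layout is wide with one row per threshold and, per expected
#' total, simulated and exact columns rounded to one decimal.
#'
#' @param path output CSV path.
#' @inheritParams observed_tail_table
#' @param layout `"long"` (full precision) or `"wide"` (rounded display).
#' @return The table written, invisibly.
#' @export
emit_tail_table <- function(path, expected_totals = 1:5, thresholds = 0:16,
                            n_reps = 10000, seed = NULL,
                            layout = c("long", "wide")) {
  layout <- match.arg(layout)
  tt <- observed_tail_table(expected_totals, thresholds, n_reps, seed)
  if (layout == "long") {
    utils::write.csv(as.data.frame(tt), path, row.names = FALSE)
    invisible(tt)
  } else {
    wide <- data.frame(observed = ifelse(thresholds == 0, "None",
                                         as.character(thresholds)))
    for (E in expected_totals) {
      sub <- tt[tt$expected == E, ]
      wide[[sprintf("expected_%g_simulated", E)]] <- round(sub$simulated_pct, 1)
      wide[[sprintf("expected_%g_exact", E)]] <- round(sub$exact_pct, 1)
    }
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
    invisible(wide)
  }
}

#' Standardized rates for user-supplied stratified counts
#'
#' Applies the DSR and all three interval methods to a table of
#' age-stratified event counts and person denominators, one or more
#' reporting units (e.g. districts) at a time, and flags units whose
#' total observed events fall below the publication threshold (default
#' 10: rates based on fewer events should be suppressed rather than
#' published).
#'
#' @param data data frame with columns `age_group`, `events`,
#'   `population` and optionally `unit` (defaults to a single unit
#'   `"all"`). Every unit must have exactly one row per standard-population
#'   age group.
#' @param stdpop standard population.
#' @param level confidence level.
#' @param scale multiplier for reported rates (e.g. `10000` for rates per
#'   10,000 persons). Default 1 (per person).
#' @param threshold minimum total events for publication (default 10).
#' @return Data frame with one row per unit: `unit`, `total_events`,
#'   `dsr`, `<method>_lower`/`<method>_upper` for the three methods (all
#'   on the `scale` requested), and logical `suppressed`.
#' @examples
#' d <- data.frame(age_group = esp2013()$age_group,
#'                 events = rep(1, 19), population = rep(10000, 19))
#' dsr_rates(d, scale = 10000)
#' @export
dsr_rates <- function(data, stdpop = esp2013(), level = 0.95, scale = 1,
                      threshold = 10) {
  sp <- as_standard_pop(stdpop)
  need <- c("age_group", "events", "population")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop(sprintf("input data is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"unit" %in% names(data)) data$unit <- "all"
  unknown <- setdiff(unique(data$age_group), sp$age_group)
  if (length(unknown)) {
    stop(sprintf("unknown age-group label(s): %s\nvalid labels: %s",
                 paste(unknown, collapse = ", "),
                 paste(sp$age_group, collapse = ", ")), call. = FALSE)
  }
  units <- unique(data$unit)
  out <- do.call(rbind, lapply(units, function(u) {
    sub <- data[data$unit == u, ]
    if (anyDuplicated(sub$age_group)) {
      stop(sprintf("unit '%s' has duplicated age-group rows", u),
           call. = FALSE)
    }
    absent <- setdiff(sp$age_group, sub$age_group)
    if (length(absent)) {
      stop(sprintf("unit '%s' is missing age group(s): %s", u,
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
    sub <- sub[match(sp$age_group, sub$age_group), ]
    ci <- dsr_ci(sub$events, sub$population, sp, method = "all",
                 level = level)
    row <- data.frame(unit = u, total_events = sum(sub$events),
                      dsr = scale * ci$rate[1])
    for (m in c("normal", "dobson", "tiwari")) {
      row[[paste0(m, "_lower")]] <- scale * ci$lower[ci$method == m]
      row[[paste0(m, "_upper")]] <- scale * ci$upper[ci$method == m]
    }
    row$suppressed <- row$total_events < threshold
    row
  }))
  rownames(out) <- NULL
  out
}

#' Read stratified count inputs from CSV
#'
#' Either a single joint file with columns `age_group`, `events`,
#' `population` (and optionally `unit`), or a counts file
#' (`age_group`, `events`[, `unit`]) plus a separate population file
#' (`age_group`, `population`[, `unit`]) merged on unit and age group.
#' Non-numeric count or population cells raise a parse error naming the
#' offending row.
#'
#' @param counts_csv path to the counts (or joint) CSV.
#' @param population_csv optional path to a separate population CSV.
#' @return A data frame suitable for [dsr_rates()].
#' @export
read_rate_inputs <- function(counts_csv, population_csv = NULL) {
  counts <- utils::read.csv(counts_csv, stringsAsFactors = FALSE)
  if (!"age_group" %in% names(counts)) {
    stop("counts CSV must have an 'age_group' column", call. = FALSE)
  }
  if (is.null(population_csv)) {
    need <- c("events", "population")
    miss <- setdiff(need, names(counts))
    if (length(miss)) {
      stop(sprintf("joint CSV is missing column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    dat <- counts
  } else {
    pop <- utils::read.csv(population_csv, stringsAsFactors = FALSE)
    if (!all(c("age_group", "population") %in% names(pop))) {
      stop("population CSV must have columns 'age_group' and 'population'",
           call. = FALSE)
    }
    if (!"events" %in% names(counts)) {
      stop("counts CSV must have an 'events' column", call. = FALSE)
    }
    by <- intersect(c("unit", "age_group"), intersect(names(counts),
                                                      names(pop)))
    dat <- merge(counts, pop, by = by)
  }
  dat$events <- check_numeric_column(dat, "events", counts_csv)
  dat$population <- check_numeric_column(dat, "population",
                                         if (is.null(population_csv)) counts_csv
                                         else population_csv)
  dat
}

check_numeric_column <- function(dat, col, path) {
  v <- dat[[col]]
  if (is.character(v)) {
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed) & !is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' value in %s at data row %d: '%s'",
                   col, path, bad[1], v[bad[1]]), call. = FALSE)
    }
    v <- parsed
  }
  if (anyNA(v)) {
    stop(sprintf("missing '%s' value in %s at data row %d", col, path,
                 which(is.na(v))[1]), call. = FALSE)
  }
  v
}
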