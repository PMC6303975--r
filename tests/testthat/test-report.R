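small_config <- function() {
  coverage_grid_config(n_reps = 300, seed = 17)
}

test_that("the grid runs one row per scenario and method, deterministically", {
  cfg <- small_config()
  cfg$expected_totals <- c(5, 10)
  cfg$populations <- c("1", "EU")
  cfg$rate_ratios <- 1
  g1 <- run_grid(cfg, quiet = TRUE)
  expect_equal(nrow(g1), 2 * 2 * 1 * 3)
  expect_setequal(unique(g1$method), c("normal", "dobson", "tiwari"))
  g2 <- run_grid(cfg, quiet = TRUE)
  expect_identical(g1, g2)
  # rerun written to CSV is byte-identical
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(g1, f1, row.names = FALSE)
  write.csv(g2, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # round trip: re-reading reproduces the in-memory summaries
  back <- read.csv(f1, stringsAsFactors = FALSE,
                   colClasses = sapply(g1, class))
  expect_equal(back$coverage_pct, g1$coverage_pct)
  expect_equal(back$classification, g1$classification)
})

test_that("scenario substreams isolate scenarios from one another", {
  cfg <- small_config()
  cfg$expected_totals <- 5
  cfg$populations <- "1"
  cfg$rate_ratios <- 1
  g_small <- run_grid(cfg, quiet = TRUE)
  cfg$expected_totals <- c(5, 10, 15)
  g_big <- run_grid(cfg, quiet = TRUE)
  expect_equal(g_big[g_big$expected_total == 5, ], g_small,
               ignore_attr = TRUE)
})

test_that("empty scenario lists yield a header-only table", {
  cfg <- small_config()
  cfg$expected_totals <- numeric()
  g <- run_grid(cfg, quiet = TRUE)
  expect_equal(nrow(g), 0)
  expect_true(all(c("expected_total", "population", "rate_ratio", "method",
                    "coverage_pct", "classification") %in% names(g)))
})

test_that("invalid configurations are rejected naming the field", {
  cfg <- small_config()
  cfg$expected_totals <- c(5, -1)
  expect_error(run_grid(cfg, quiet = TRUE), "expected_totals")
  cfg <- small_config()
  cfg$rate_ratios <- 0.5
  expect_error(run_grid(cfg, quiet = TRUE), "rate_ratios")
  cfg <- small_config()
  cfg$populations <- c("1", "narrow")
  expect_error(run_grid(cfg, quiet = TRUE), "populations")
  cfg <- small_config()
  cfg$n_reps <- 0
  expect_error(run_grid(cfg, quiet = TRUE), "n_reps")
  cfg <- small_config()
  cfg$level <- 1.05
  expect_error(run_grid(cfg, quiet = TRUE), "level")
  cfg <- small_config()
  cfg$total_population <- NULL
  expect_error(run_grid(cfg, quiet = TRUE), "total_population")
})

test_that("YAML configurations are read, defaulted and validated", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("expected_totals: [5, 10]",
               "populations: ['50', 'EU']",
               "rate_ratios: [1]",
               "n_reps: 100",
               "seed: 3"), f)
  cfg <- read_grid_config(f)
  expect_equal(cfg$expected_totals, c(5, 10))
  expect_equal(cfg$level, 0.95)            # defaulted
  expect_equal(cfg$total_population, 190000)
  writeLines(c("n_reps: 100", "bogus_key: 1"), f)
  expect_error(read_grid_config(f), "bogus_key")
})

test_that("tail tables are written in long and wide layouts", {
  f <- withr::local_tempfile(fileext = ".csv")
  tt <- emit_tail_table(f, expected_totals = c(1, 2), thresholds = 0:5,
                        n_reps = 500, seed = 5, layout = "long")
  back <- read.csv(f)
  expect_equal(back$simulated_pct, tt$simulated_pct)
  expect_equal(back$exact_pct, tt$exact_pct)
  wide <- emit_tail_table(f, expected_totals = c(1, 2), thresholds = 0:5,
                          n_reps = 500, seed = 5, layout = "wide")
  back <- read.csv(f, check.names = FALSE)
  expect_equal(back$observed[1], "None")
  expect_equal(back[["expected_1_simulated"]][1], 100)
  expect_equal(back[["expected_2_exact"]][1], 100)
  expect_equal(ncol(back), 1 + 2 * 2)
})

make_unit <- function(unit, events, population = rep(10000, 19)) {
  data.frame(unit = unit, age_group = esp2013()$age_group,
             events = events, population = population)
}

test_that("rate reports compute DSRs per unit and flag small counts for suppression", {
  d <- rbind(make_unit("nine", counts_spread(9)),
             make_unit("ten", counts_spread(10)),
             make_unit("none", rep(0, 19)))
  out <- dsr_rates(d, scale = 10000)
  expect_equal(out$suppressed, c(TRUE, FALSE, TRUE))
  expect_equal(out$total_events[out$unit == "ten"], 10)
  # all-zero unit: zero rate, degenerate normal/Dobson, positive Tiwari UCL
  none <- out[out$unit == "none", ]
  expect_equal(none$dsr, 0)
  expect_equal(none$dobson_upper, 0)
  expect_gt(none$tiwari_upper, 0)
  # threshold is configurable
  out9 <- dsr_rates(d, scale = 10000, threshold = 9)
  expect_equal(out9$suppressed, c(FALSE, FALSE, TRUE))
  # a constant-rate unit reports exactly scale * rate
  u <- make_unit("const", rep(2, 19), rep(10000, 19))  # rate 2e-4
  expect_equal(dsr_rates(u, scale = 10000)$dsr, 2)
})

test_that("rate inputs are validated with actionable errors", {
  d <- make_unit("a", counts_spread(12))
  bad <- d
  bad$age_group[3] <- "10 to 14"
  expect_error(dsr_rates(bad), "10 to 14.*valid labels")
  expect_error(dsr_rates(d[-5, ]), "missing age group")
  dup <- rbind(d, d[1, ])
  expect_error(dsr_rates(dup), "duplicated")
  expect_error(dsr_rates(d[, -3]), "missing column")
})

test_that("CSV inputs parse jointly or as separate count and population files", {
  d <- make_unit("a", counts_spread(12))
  joint <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, joint, row.names = FALSE)
  got <- dsr_rates(read_rate_inputs(joint))
  expect_equal(got$total_events, 12)
  counts_f <- withr::local_tempfile(fileext = ".csv")
  pop_f <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[, c("unit", "age_group", "events")], counts_f,
            row.names = FALSE)
  write.csv(d[, c("unit", "age_group", "population")], pop_f,
            row.names = FALSE)
  got2 <- dsr_rates(read_rate_inputs(counts_f, pop_f))
  expect_equal(got2$dsr, got$dsr)
  # a non-numeric cell is a parse error naming the row
  d2 <- d
  d2$events <- as.character(d2$events)
  d2$events[4] <- "four"
  write.csv(d2, joint, row.names = FALSE)
  expect_error(read_rate_inputs(joint), "non-numeric 'events'.*row 4")
})
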