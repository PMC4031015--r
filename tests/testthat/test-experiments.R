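tiny_suite_config <- function(scenarios, out_dir = NULL, ...) {
  suite_config(scenarios = scenarios, target_edge = 1.9,
               mode = "quasi_static", steps_per_cycle = 12,
               out_dir = out_dir, ...)
}

test_that("run_suite produces one row set per scenario, deterministically", {
  cfg <- tiny_suite_config("elastic_1Hz")
  r1 <- run_suite(cfg)
  expect_equal(nrow(r1$table), 4L)
  expect_length(r1$errors, 0L)
  r2 <- run_suite(cfg)
  expect_identical(r1$table, r2$table)
})

test_that("run_suite isolates per-scenario failures and persists outputs", {
  od <- file.path(tempdir(), "suite_out")
  cfg <- tiny_suite_config(c("elastic_1Hz"), out_dir = od)
  res <- run_suite(cfg)
  expect_true(file.exists(file.path(od, "suite_summary.csv")))
  expect_true(file.exists(file.path(od, "elastic_1Hz_series.rds")))
  expect_true(file.exists(file.path(od, "elastic_1Hz_spec.json")))
  # an invalid solver override fails every run but does not abort the suite
  bad <- tiny_suite_config("elastic_1Hz")
  bad$steps_per_cycle <- 13
  resbad <- run_suite(bad)
  expect_named(resbad$errors, "elastic_1Hz")
  expect_null(resbad$table)
  expect_error(suite_config(scenarios = "not_a_scenario"), "unknown")
})

test_that("tau sensitivity is zero for identical runs and flags absentees", {
  fake <- expand.grid(scenario = c("tau0.1_20Hz", "tau1_20Hz", "tau10_20Hz",
                                   "elastic_20Hz"),
                      region = c("cytoplasm", "nucleus"),
                      quantity = c("stress", "strain"),
                      stringsAsFactors = FALSE)
  fake$frequency_hz <- 20
  fake$peak <- 14.7
  out <- tau_sensitivity(fake)
  expect_equal(out$max_rel_deviation_pct, 0)
  expect_error(tau_sensitivity(fake[fake$scenario != "elastic_20Hz", ]),
               "missing runs")
})

test_that("reference comparison computes ratios and pass flags", {
  refs <- reference_values()
  expect_true(all(nchar(refs$citation) > 0))
  expect_true(all(refs$paper_value > 0))
  tab <- data.frame(scenario = "baseline_45Hz", region = "cytoplasm",
                    quantity = "stress", frequency_hz = 45, peak = 118,
                    frame_time_s = 0, excluded_policy = "none",
                    ratio_vs_1hz = NA_real_)
  cmp <- compare_to_reference(tab, refs)
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$ratio, 1)
  expect_true(cmp$pass)
  expect_warning(empty <- compare_to_reference(tab, refs[0, ]), "empty")
  expect_equal(nrow(empty), 0L)
})
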