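test_that("default configuration carries the published base-case inputs", {
  cfg <- default_config()
  expect_identical(cfg$horizon_cycles, 120L)
  expect_equal(unname(cfg$initial_nyha), c(0.045, 0.716, 0.231, 0.008))
  expect_equal(cfg$start_age, 64)
  expect_equal(cfg$discount_rate_annual, 0.035)
  expect_equal(cfg$params$cost_sacval_monthly, 17.12)
  expect_equal(cfg$params$cost_enalapril_monthly, 10.65)
  expect_equal(unname(cfg$wtp_thresholds), c(10276, 30828))
  expect_length(validate_config(cfg), 0)
})

test_that("drug cost decomposition is internally consistent", {
  cfg <- default_config()
  for (d in cfg$drugs) {
    expect_equal(d$monthly_cost, d$monthly_price * (1 - d$copay_ratio),
                 tolerance = 0.01 / d$monthly_cost)
  }
  # the copay switch flips the patient share and must surface in validation
  cfg$options$drug_copay_is_reimbursed <- FALSE
  expect_match(validate_config(cfg), "monthly_cost", all = FALSE)
})

test_that("parameter manifest enumerates the full registry", {
  man <- parameter_manifest(default_config())
  expected <- c(
    "p_hosp_baseline", "p_cvdeath_baseline", "readmission",
    "nyha_progress_enalapril", "nyha_progress_sacval",
    "hr_hosp_sacval", "hr_cvdeath_sacval", "hr_hosp_nyha3", "hr_hosp_nyha4",
    "rr_cvdeath_nyha3", "rr_cvdeath_nyha4",
    "utility_nyha12", "utility_nyha3", "utility_nyha4",
    "disutility_hosp", "disutility_readmit",
    "cost_sacval_monthly", "cost_enalapril_monthly",
    "cost_outpatient_monthly", "copay_inpatient",
    "cost_hosp_event", "cost_readmit_event")
  expect_setequal(man$name, expected)
  # every ordinary manifest parameter exists in the config registry
  ordinary <- setdiff(man$name, c("p_hosp_baseline", "p_cvdeath_baseline"))
  expect_true(all(ordinary %in% names(default_config()$params)))
  # and low <= base <= up as printed (the raw hospitalization baseline sits
  # below its band by design)
  ok <- man$low <= man$base & man$base <= man$up
  expect_true(all(ok[man$name != "p_hosp_baseline"]))
})

test_that("set_param reaches every manifest entry including the baselines", {
  cfg <- default_config()
  cfg2 <- set_param(cfg, "utility_nyha3", 0.7)
  expect_equal(cfg2$params$utility_nyha3, 0.7)
  cfg3 <- set_param(cfg, "p_cvdeath_baseline", 0.00844)
  expect_equal(monthly_prob_exponential(cfg3$hazards$cv_death$lam), 0.00844)
  cfg4 <- set_param(cfg, "p_hosp_baseline", 0.0145)
  expect_identical(cfg4$options$weibull_mode, "calibrated")
  expect_equal(cfg4$options$hosp_anchor, 0.0145)
  expect_error(set_param(cfg, "not_a_parameter", 1), "unknown parameter")
})

test_that("validation reports each violated invariant by name", {
  cfg <- default_config()
  cfg$params$utility_nyha4 <- 1.2
  f <- suppressWarnings(validate_config(cfg))
  expect_match(f, "utility_nyha4", all = FALSE)

  cfg <- default_config()
  cfg$nyha_matrix[2, 3] <- cfg$nyha_matrix[2, 3] + 0.1
  expect_match(validate_config(cfg), "NYHA_II", all = FALSE)

  cfg <- default_config()
  cfg$initial_nyha[1] <- cfg$initial_nyha[1] - 0.1
  expect_match(validate_config(cfg), "initial_nyha", all = FALSE)

  cfg <- default_config()
  cfg$hazards$cv_death$lam <- 0.01
  expect_match(validate_config(cfg), "cv_death", all = FALSE)
})

test_that("configuration round-trips losslessly through YAML", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  expect_equal(unclass(load_config(path)), unclass(cfg), tolerance = 1e-9)

  # a modified config round-trips too
  cfg$params$cost_sacval_monthly <- 150
  cfg$horizon_cycles <- 60L
  save_config(cfg, path)
  # the price override sits outside its printed range: load warns (does not
  # clamp) and preserves the value
  expect_warning(back <- load_config(path), "outside printed range")
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-9)
})

test_that("the packaged default file reproduces default_config()", {
  path <- system.file("extdata", "default_config.yaml", package = "hfcea")
  expect_true(nzchar(path))
  expect_equal(unclass(load_config(path)), unclass(default_config()),
               tolerance = 1e-9)
})

test_that("loading rejects unknown keys, missing keys, and bad values", {
  path <- withr::local_tempfile(fileext = ".yaml")

  save_config(default_config(), path)
  writeLines(c(readLines(path), "not_a_key: 1"), path)
  expect_error(load_config(path), "unknown configuration key")

  writeLines("horizon_cycles: 60", path)
  expect_error(load_config(path), "missing configuration key")
  cfg <- load_config(path, allow_partial = TRUE)
  expect_identical(cfg$horizon_cycles, 60L)
  expect_equal(cfg$params$cost_sacval_monthly, 17.12)  # filled from defaults

  # single-field override leaves everything else at default
  writeLines(c("params:", "  cost_sacval_monthly: 150"), path)
  expect_warning(cfg <- load_config(path, allow_partial = TRUE),
                 "outside printed range")
  expect_equal(cfg$params$cost_sacval_monthly, 150)
  cfg$params$cost_sacval_monthly <- 17.12
  expect_equal(unclass(cfg), unclass(default_config()), tolerance = 1e-9)

  # invariant violation at load time is an error naming the culprit
  bad <- default_config()
  bad$initial_nyha[2] <- bad$initial_nyha[2] - 0.1
  save_config(bad, path)
  expect_error(load_config(path), "initial_nyha")
})
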