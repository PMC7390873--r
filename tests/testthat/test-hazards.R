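test_that("exponential baseline gives the constant monthly probability", {
  expect_equal(monthly_prob_exponential(-0.00577), 0.0057534,
               tolerance = 1e-5)
  # memoryless: the cycle argument is irrelevant
  expect_identical(monthly_prob_exponential(-0.00577, 1L),
                   monthly_prob_exponential(-0.00577, 120L))
  # within the printed plausible band
  expect_gt(monthly_prob_exponential(-0.00577), 0.00412)
  expect_lt(monthly_prob_exponential(-0.00577), 0.00844)
  # vanishing hazard
  expect_lt(monthly_prob_exponential(-1e-12), 1e-11)
  expect_error(monthly_prob_exponential(0.001), "negative")
})

test_that("Weibull baseline nests the exponential and rises when shape > 1", {
  lam <- -0.00097
  expect_equal(monthly_prob_weibull(lam, 1, 1:120),
               rep(monthly_prob_exponential(lam), 120))
  p <- monthly_prob_weibull(lam, 1.02685, 1:120)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  expect_error(monthly_prob_weibull(lam, 1.02685, 0), "cycle")
  expect_error(monthly_prob_weibull(0.001, 1.02685, 1), "negative")
})

test_that("calibration anchors the horizon-mean monthly probability", {
  for (anchor in c(0.00868, 0.0145)) {
    lam_c <- calibrate_weibull_lambda(anchor, -0.00097, 1.02685, 120L)
    expect_equal(mean(monthly_prob_weibull(lam_c, 1.02685, 1:120)), anchor,
                 tolerance = 1e-9)
  }
})

test_that("hazard ratios act on the rate scale and match the rate oracle", {
  expect_equal(apply_hazard_ratio(0.0057534, 0.80), 0.0046050,
               tolerance = 2e-4)
  expect_identical(apply_hazard_ratio(0.42, 1), 0.42)
  expect_identical(apply_hazard_ratio(0, 3.3), 0)
  expect_error(apply_hazard_ratio(1, 0.5), "certain event")
  expect_error(apply_hazard_ratio(0.1, -1), "positive")

  # independent oracle: transform the probability to a rate, scale the rate,
  # transform back
  set.seed(7)
  for (i in 1:200) {
    p <- stats::runif(1, 0, 0.99)
    hr <- stats::runif(1, 0.05, 5)
    oracle <- 1 - exp(hr * log(1 - p))
    expect_equal(apply_hazard_ratio(p, hr), oracle, tolerance = 1e-12)
  }

  # monotone in both arguments
  p <- seq(0.001, 0.9, length.out = 30)
  expect_true(all(diff(apply_hazard_ratio(p, 1.7)) > 0))
  hr <- seq(0.1, 4, length.out = 30)
  expect_true(all(diff(apply_hazard_ratio(0.01, hr)) > 0))
})

test_that("relative risks multiply the probability and respect bounds", {
  expect_equal(apply_relative_risk(0.0057534, 1.372), 0.0057534 * 1.372)
  expect_error(apply_relative_risk(0.8, 1.5), "above 1")
  expect_error(apply_relative_risk(0.1, 0), "positive")
})

test_that("background mortality is a left step-function converted monthly", {
  mt <- default_config()$mortality
  expect_equal(background_mortality_monthly(mt, 65), 0.00055982,
               tolerance = 1e-4)
  # step: any age in [65, 70) maps to the age-65 entry
  expect_identical(background_mortality_monthly(mt, 67.5),
                   background_mortality_monthly(mt, 65))
  # age 64 falls in the 60-64 band
  expect_identical(background_mortality_monthly(mt, 64),
                   background_mortality_monthly(mt, 60))
  expect_identical(background_mortality_monthly(mt, 100), 1)
  expect_identical(background_mortality_monthly(mt, 104), 1)
  expect_error(background_mortality_monthly(mt, 0.5), "below")
})

test_that("event probabilities chain arm and class effects correctly", {
  cfg <- default_config()
  e2 <- event_probabilities("enalapril", 2, 1, 64, cfg)
  expect_equal(e2$p_cv_death, 0.0057534, tolerance = 1e-5)
  expect_equal(e2$p_nyha_change, 0.0088)
  expect_equal(e2$p_readmit, 0.0147)

  s2 <- event_probabilities("sacval", 2, 1, 64, cfg)
  expect_lt(s2$p_hosp, e2$p_hosp)
  expect_lt(s2$p_cv_death, e2$p_cv_death)
  expect_equal(s2$p_nyha_change, 0.0068)

  # class multipliers: NYHA IV hospitalization ~ 3.4x the class-II value in
  # the small-probability limit
  e4 <- event_probabilities("enalapril", 4, 1, 64, cfg)
  expect_equal(e4$p_hosp / e2$p_hosp, 3.4, tolerance = 0.01)
  expect_equal(e4$p_cv_death / e2$p_cv_death, 1.640, tolerance = 1e-9)

  # probabilities non-decreasing in their multipliers
  cfg_hi <- set_param(cfg, "hr_hosp_nyha4", 6.84)
  e4hi <- event_probabilities("enalapril", 4, 1, 64, cfg_hi)
  expect_gt(e4hi$p_hosp, e4$p_hosp)
})

test_that("transition matrices are row-stochastic with absorbing deaths", {
  for (cfg in list(default_config(),
                   set_param(default_config(), "p_hosp_baseline", 0.0145))) {
    for (arm in arms()) {
      for (t in c(1L, 13L, 60L, 120L)) {
        m <- build_transition_matrix(arm, t, cfg)
        expect_equal(unname(rowSums(m)), rep(1, 6), tolerance = 1e-9)
        expect_true(all(m >= 0 & m <= 1))
        expect_identical(unname(m["DEATH_CV", ]), c(0, 0, 0, 0, 1, 0))
        expect_identical(unname(m["DEATH_NONCV", ]), c(0, 0, 0, 0, 0, 1))
      }
    }
  }
})

test_that("a NYHA IV class change can only land in class III", {
  m <- build_transition_matrix("enalapril", 1, default_config())
  ev <- attr(m, "events")
  moved <- ev$p_nyha_change[4]
  expect_equal(m["NYHA_IV", "NYHA_III"], moved)
  expect_equal(m["NYHA_IV", "NYHA_I"], 0)
  expect_equal(m["NYHA_IV", "NYHA_II"], 0)
})

test_that("with no events the transition matrix is the identity", {
  cfg <- eventless_config()
  m <- build_transition_matrix("enalapril", 1, cfg)
  expect_equal(unname(m), diag(6), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the fast per-cycle probability path matches the matrix builder", {
  cfg <- default_config()
  for (arm in arms()) {
    pc <- hfcea:::arm_cycle_probs(arm, cfg)
    for (t in c(1L, 37L, 120L)) {
      ev <- attr(build_transition_matrix(arm, t, cfg), "events")
      surv <- (1 - pc$p_cvd[t, ]) * (1 - pc$p_ncv[t])
      expect_equal(ev$p_hosp, surv * pc$p_hosp[t, ], tolerance = 1e-12)
      expect_equal(ev$p_cv_death, pc$p_cvd[t, ], tolerance = 1e-12)
    }
  }
})
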