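# Direct samplers used as independent oracles for the recovery fits: they
# generate discrete event times from S(t) = exp(lam * t^shape) without
# touching the package's simulation engine.
r_discrete_weibull <- function(n, lam, shape) {
  u <- stats::runif(n)
  as.integer(ceiling((log(u) / lam)^(1 / shape)))
}
censor_at <- function(t, horizon) {
  data.frame(time = pmin(t, horizon), event = as.integer(t <= horizon))
}

test_that("an eventless patient accrues exactly the fixed monthly costs", {
  cfg <- eventless_config(horizon_cycles = 120L, start_class = 2L)
  pat <- simulate_patient("enalapril", cfg, seed = 1L)
  d <- (1.035)^(-((1:120) - 0.5) / 12)
  expect_equal(pat$cost, sum(d) * (10.65 + 41.56), tolerance = 1e-8)
  expect_equal(pat$qaly, sum(d) * 0.780 / 12, tolerance = 1e-8)
  expect_identical(nrow(pat$events), 0L)
  expect_true(all(pat$states == "NYHA_II"))
})

test_that("certain first-cycle CV death leaves half-cycle accruals only", {
  cfg <- eventless_config(horizon_cycles = 12L, start_class = 2L)
  cfg$hazards$cv_death$lam <- -30  # monthly death probability ~ 1
  cfg$params$rr_cvdeath_nyha3 <- 1  # keep class III/IV rows inside [0,1]
  cfg$params$rr_cvdeath_nyha4 <- 1
  pat <- simulate_patient("enalapril", cfg, seed = 2L)
  d1 <- (1.035)^(-0.5 / 12)
  expect_equal(pat$cost, d1 * 0.5 * (10.65 + 41.56), tolerance = 1e-8)
  expect_equal(pat$qaly, d1 * 0.780 / 2 / 12, tolerance = 1e-8)
  expect_identical(pat$events$event, "cv_death")
  expect_identical(pat$states[2], "DEATH_CV")
})

test_that("simulate_patient is the n = 1 population simulation", {
  cfg <- short_config(36L)
  pat <- simulate_patient("sacval", cfg, seed = 11L)
  pop <- simulate_population("sacval", 1L, cfg, seed = 11L,
                             keep_trajectories = TRUE)
  expect_identical(pat, pop$trajectories[[1]])
  expect_equal(pop$estimates$mean[1], pat$cost)
})

test_that("population simulation is reproducible from its seed", {
  cfg <- short_config(24L)
  a <- simulate_population("enalapril", 300L, cfg, seed = 4L)
  b <- simulate_population("enalapril", 300L, cfg, seed = 4L)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$events, b$events)
  c <- simulate_population("enalapril", 300L, cfg, seed = 5L)
  expect_false(identical(a$events, c$events))
})

test_that("patient trajectories satisfy the pathway invariants", {
  pop <- simulate_population("sacval", 40L, default_config(), seed = 8L,
                             keep_trajectories = TRUE)
  for (traj in pop$trajectories) {
    st <- traj$states
    dead_at <- which(st %in% c("DEATH_CV", "DEATH_NONCV"))
    if (length(dead_at)) {
      first <- dead_at[1]
      # absorbing: once dead, always dead, in the same state
      expect_true(all(st[first:length(st)] == st[first]))
      # no events recorded after the death cycle
      expect_true(all(traj$events$cycle <= first - 1))
    }
    expect_lte(sum(traj$events$event %in% c("cv_death", "noncv_death")), 1L)
  }
})

test_that("event-time records stay inside the horizon with sane censoring", {
  cfg <- short_config(60L)
  pop <- simulate_population("enalapril", 2000L, cfg, seed = 3L)
  ev <- pop$events
  expect_true(all(ev$hosp_time[ev$hosp_event == 1] >= 1))
  expect_true(all(ev$hosp_time <= 60 & ev$cvdeath_time <= 60))
  # a censored first-hospitalization time is either the horizon (patient
  # completed follow-up event-free) or the last fully observed cycle before
  # a death
  cens <- ev$hosp_event == 0
  expect_true(any(cens))
  expect_true(all(ev$hosp_time[cens] == 60 |
                    ev$hosp_time[cens] == ev$cvdeath_time[cens] - 1))
})

test_that("population means match the cohort engine within 3 SE", {
  cfg <- default_config()
  for (arm in arms()) {
    pop <- simulate_population(arm, 20000L, cfg, seed = 21L)
    coh <- run_cohort(arm, cfg)
    est <- pop$estimates
    expect_lt(abs(est$mean[1] - coh$total_cost), 3 * est$se[1])
    expect_lt(abs(est$mean[2] - coh$total_qaly), 3 * est$se[2])
    expect_lt(abs(est$mean[3] - death_fraction(coh, 10)), 3 * est$se[3])
  }
})

test_that("the exponential MLE recovers a known rate from censored data", {
  set.seed(31)
  p <- monthly_prob_exponential(-0.00577)
  t_true <- stats::rgeom(50000, p) + 1L
  ds <- censor_at(t_true, 120L)
  fit <- recover_exponential(ds$time, ds$event)
  expect_equal(fit$lam, -0.00577, tolerance = 0.10)
  expect_gte(fit$n_events, 100)
})

test_that("the Weibull MLE recovers scale and shape from censored data", {
  set.seed(32)
  ds <- censor_at(r_discrete_weibull(50000, -0.00097, 1.02685), 120L)
  fit <- recover_weibull(ds$time, ds$event)
  expect_equal(fit$shape, 1.02685, tolerance = 0.10)
  expect_equal(fit$lam, -0.00097, tolerance = 0.25)
  expect_true(fit$converged)
  # the Weibull fit can only improve on the nested exponential fit
  e <- recover_exponential(ds$time, ds$event)
  expect_gte(fit$loglik, e$loglik - 1e-6)
})

test_that("doubling the hazard halves the median event time", {
  set.seed(33)
  m1 <- stats::median(r_discrete_weibull(20000, -0.05, 1))
  m2 <- stats::median(r_discrete_weibull(20000, -0.10, 1))
  expect_equal(m1 / m2, 2, tolerance = 0.1)
})

test_that("exponential data rarely reject the nested model", {
  set.seed(34)
  rejections <- 0L
  for (r in 1:20) {
    ds <- censor_at(stats::rgeom(2000, 1 - exp(-0.1)) + 1L, 120L)
    w <- recover_weibull(ds$time, ds$event)
    e <- recover_exponential(ds$time, ds$event)
    lrt <- 2 * (w$loglik - e$loglik)
    if (lrt > stats::qchisq(0.95, df = 1)) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)  # >= 90% non-rejection at nominal 5% size
})

test_that("recovery preconditions are enforced", {
  expect_error(recover_exponential(rep(120, 50), rep(0, 50)), "no uncensored")
  expect_error(recover_exponential(c(rep(3, 50), rep(120, 50)),
                                   c(rep(1, 50), rep(0, 50))),
               "at least 100")
  expect_error(recover_weibull(rep(5, 400), rep(1, 400)), "at least 500")
})
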