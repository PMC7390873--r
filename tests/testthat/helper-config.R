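# Shared fixtures: all built in code, no stored data.

# Base configuration with a shorter horizon for cheap property loops.
short_config <- function(horizon_cycles = 24L) {
  cfg <- default_config()
  cfg$horizon_cycles <- as.integer(horizon_cycles)
  cfg
}

# Configuration in which the two arms are clinically and economically
# identical (unit hazard ratios, equal drug costs, equal NYHA progression).
equal_arm_config <- function(cfg = default_config()) {
  cfg$params$hr_hosp_sacval <- 1
  cfg$params$hr_cvdeath_sacval <- 1
  cfg$params$cost_sacval_monthly <- cfg$params$cost_enalapril_monthly
  cfg$params$nyha_progress_sacval <- cfg$params$nyha_progress_enalapril
  cfg$drugs$sacval <- cfg$drugs$enalapril
  cfg
}

# Configuration with (numerically) no events: survival coefficients pushed
# to machine-negligible hazards, no class changes, no readmission, and a
# zeroed background-mortality table (the age-100 closing row stays at 1).
eventless_config <- function(horizon_cycles = 120L, start_class = 2L) {
  cfg <- short_config(horizon_cycles)
  cfg$hazards$hospitalization$lam <- -1e-14
  cfg$hazards$cv_death$lam <- -1e-14
  cfg$params$readmission <- 0
  cfg$params$nyha_progress_sacval <- 0
  cfg$params$nyha_progress_enalapril <- 0
  cfg$mortality$annual_prob[cfg$mortality$age < 100] <- 0
  init <- c(0, 0, 0, 0)
  init[start_class] <- 1
  cfg$initial_nyha <- stats::setNames(init, names(cfg$initial_nyha))
  cfg
}

# Single-class cohort (everyone NYHA II, no class changes): baseline
# hazards apply exactly, which is what parameter-recovery needs.
single_class_config <- function(horizon_cycles = 120L) {
  cfg <- short_config(horizon_cycles)
  cfg$params$nyha_progress_sacval <- 0
  cfg$params$nyha_progress_enalapril <- 0
  cfg$initial_nyha <- stats::setNames(c(0, 1, 0, 0), names(cfg$initial_nyha))
  cfg
}

run_pair <- function(cfg) {
  list(sacval = run_cohort("sacval", cfg),
       enalapril = run_cohort("enalapril", cfg))
}

pair_icer <- function(cfg) {
  p <- run_pair(cfg)
  icer(p$sacval, p$enalapril)
}

# Minimal stand-in for a cohort result, for testing the CE arithmetic in
# isolation.
fake_result <- function(arm, cost, qaly, wtp = c(10276, 30828)) {
  structure(list(arm = arm, total_cost = cost, total_qaly = qaly,
                 config = list(wtp_thresholds = wtp)),
            class = "cohort_result")
}
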