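# Conversion of parametric survival baselines, hazard ratios, relative risks
# and the background-mortality table into per-cycle transition probabilities,
# and assembly of the row-stochastic transition matrix.

#' Monthly event probability under an exponential survival baseline
#'
#' The baseline is parameterised as `S(t) = exp(lam * t)` with `t` in months
#' and `lam < 0` the signed monthly log-survival coefficient, so the constant
#' per-cycle event probability is `1 - exp(lam)`.
#'
#' @param lam Signed survival coefficient (negative).
#' @param cycle Ignored (the exponential is memoryless); accepted so the two
#'   baseline families share a calling convention.
#' @return Monthly event probability in (0, 1).
#' @export
monthly_prob_exponential <- function(lam, cycle = 1L) {
  if (!is.numeric(lam) || any(lam >= 0))
    stop("exponential survival coefficient must be negative (survival must decay)")
  1 - exp(lam)
}

#' Monthly event probability under a Weibull survival baseline
#'
#' With `S(t) = exp(lam * t^shape)`, the probability of an event in cycle
#' `t` (the interval `(t-1, t]`) conditional on being event-free at `t-1` is
#' `1 - exp(lam * (t^shape - (t-1)^shape))`, increasing in `t` when
#' `shape > 1`.
#'
#' @param lam Signed survival scale coefficient (negative).
#' @param shape Weibull shape (`shape = 1` recovers the exponential).
#' @param cycle Cycle index `t >= 1`; vectorised.
#' @return Monthly event probability, one per cycle.
#' @export
monthly_prob_weibull <- function(lam, shape, cycle) {
  if (!is.numeric(lam) || lam >= 0)
    stop("weibull survival coefficient must be negative (survival must decay)")
  if (shape <= 0) stop("weibull shape must be positive")
  if (any(cycle < 1)) stop("cycle index must be >= 1")
  p <- 1 - exp(lam * (cycle^shape - (cycle - 1)^shape))
  if (any(p <= 0 | p >= 1)) stop("derived monthly probability outside (0,1)")
  p
}

#' Calibrate the Weibull scale coefficient to an anchor probability
#'
#' Rescales `lam` so that the mean monthly event probability over a fixed
#' window of cycles equals `anchor`, keeping the shape (and hence the time
#' trend) fixed. Used by the calibrated hospitalization-baseline mode, where
#' the anchor is constrained to the printed plausible band.
#'
#' @param anchor Target mean monthly probability in (0, 1).
#' @param lam,shape The printed Weibull coefficients.
#' @param window Number of cycles over which the mean is taken.
#' @return The rescaled (negative) coefficient.
#' @export
calibrate_weibull_lambda <- function(anchor, lam = -0.00097,
                                     shape = 1.02685, window = 120L) {
  stopifnot(anchor > 0, anchor < 1, lam < 0)
  cyc <- seq_len(window)
  dt <- cyc^shape - (cyc - 1)^shape
  f <- function(k) mean(-expm1(lam * k * dt)) - anchor
  upper <- 1
  while (f(upper) < 0 && upper < 1e12) upper <- upper * 10
  k <- stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
  lam * k
}

# The hospitalization-baseline coefficient the configuration implies: the
# printed one in raw mode, the anchored rescaling in calibrated mode.
effective_hosp_lambda <- function(config) {
  hz <- config$hazards$hospitalization
  if (identical(config$options$weibull_mode, "calibrated"))
    calibrate_weibull_lambda(config$options$hosp_anchor, hz$lam, hz$shape,
                             config$options$calibration_window)
  else hz$lam
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' On the default rate scale the transform is `1 - (1 - p)^hr`, i.e. the
#' hazard ratio multiplies the per-cycle log-survival; on the probability
#' scale it multiplies `p` directly. Monotone in both arguments and exact for
#' `hr = 1`.
#'
#' @param p Per-cycle probability in `[0, 1)`; vectorised.
#' @param hr Hazard ratio, `> 0`.
#' @param scale `"rate"` (default) or `"probability"`.
#' @return Adjusted probability.
#' @export
apply_hazard_ratio <- function(p, hr, scale = c("rate", "probability")) {
  scale <- match.arg(scale)
  if (any(hr <= 0)) stop("hazard ratio must be positive")
  if (any(p < 0) || any(p > 1)) stop("probability must lie in [0,1]")
  if (any(p == 1 & hr != 1))
    stop("cannot rescale a certain event (p = 1) with hr != 1")
  if (scale == "rate") {
    if (length(hr) == 1L && hr == 1) p else 1 - (1 - p)^hr
  } else {
    out <- p * hr
    if (any(out > 1)) stop("probability-scale hazard ratio exceeds 1")
    out
  }
}

#' Apply a relative risk to a per-cycle probability
#'
#' Relative risks act multiplicatively on the probability itself.
#'
#' @param p Per-cycle probability; vectorised.
#' @param rr Relative risk, `> 0`.
#' @return `p * rr`, with a domain error if the result exceeds 1.
#' @export
apply_relative_risk <- function(p, rr) {
  if (any(rr <= 0)) stop("relative risk must be positive")
  out <- p * rr
  if (any(out > 1)) stop("relative risk pushes probability above 1")
  out
}

#' Monthly background (non-cardiovascular) mortality
#'
#' Looks the current age up in the mortality table as a left step-function
#' (the entry of the greatest tabulated age less than or equal to `age`) and
#' converts the annual probability to a monthly one via
#' `1 - (1 - p)^(1/12)`. At or beyond age 100 the probability is 1.
#'
#' @param mortality The mortality table (`age`, `annual_prob`).
#' @param age Attained age in years; vectorised.
#' @return Monthly probability of non-CV death.
#' @export
background_mortality_monthly <- function(mortality, age) {
  if (any(age < mortality$age[1]))
    stop("age below the first tabulated age (", mortality$age[1], ")")
  idx <- findInterval(age, mortality$age)
  p_annual <- mortality$annual_prob[idx]
  ifelse(age >= 100, 1, 1 - (1 - p_annual)^(1 / 12))
}

#' Per-cycle event probabilities for one arm and NYHA class
#'
#' Builds the five monthly event probabilities that drive a cycle:
#' hospitalization (Weibull baseline, arm hazard ratio for
#' sacubitril-valsartan, class hazard ratio for NYHA III/IV, all chained on
#' the configured scale), cardiovascular death (exponential baseline, arm
#' hazard ratio, then the class relative risk on the probability scale),
#' non-CV death (background mortality at the attained age), NYHA class
#' change (arm-specific), and readmission. Classes I and II are the baseline
#' (multiplier 1).
#'
#' @param arm `"sacval"` or `"enalapril"`.
#' @param nyha_class Integer 1-4.
#' @param cycle Cycle index `t >= 1`.
#' @param age Attained age in years.
#' @param config Model configuration.
#' @return Named list with `p_hosp`, `p_readmit`, `p_cv_death`,
#'   `p_noncv_death`, `p_nyha_change`.
#' @export
event_probabilities <- function(arm, nyha_class, cycle, age, config) {
  stopifnot(nyha_class %in% 1:4)
  p <- config$params
  opt <- config$options
  hz <- config$hazards
  scale <- opt$hr_scale

  hr_arm_hosp <- if (arm == "sacval") p$hr_hosp_sacval else 1
  hr_arm_cvd  <- if (arm == "sacval") p$hr_cvdeath_sacval else 1
  hr_class_hosp <- c(1, 1, p$hr_hosp_nyha3, p$hr_hosp_nyha4)[nyha_class]
  rr_class_cvd  <- c(1, 1, p$rr_cvdeath_nyha3, p$rr_cvdeath_nyha4)[nyha_class]

  p_hosp_base <- monthly_prob_weibull(effective_hosp_lambda(config),
                                      hz$hospitalization$shape, cycle)
  p_hosp <- apply_hazard_ratio(
    apply_hazard_ratio(p_hosp_base, hr_arm_hosp, scale),
    hr_class_hosp, scale)

  p_cvd_base <- monthly_prob_exponential(hz$cv_death$lam)
  p_cv_death <- apply_relative_risk(
    apply_hazard_ratio(p_cvd_base, hr_arm_cvd, scale), rr_class_cvd)

  list(
    p_hosp = p_hosp,
    p_readmit = p$readmission,
    p_cv_death = p_cv_death,
    p_noncv_death = background_mortality_monthly(config$mortality, age),
    p_nyha_change = if (arm == "sacval") p$nyha_progress_sacval
                    else p$nyha_progress_enalapril
  )
}

#' Build the transition matrix for one arm and cycle
#'
#' Composes the event probabilities with the NYHA change matrix under the
#' death-first competing-event order: from each living class, CV death takes
#' `p_cv`, non-CV death `(1 - p_cv) * p_ncv`, and the surviving mass
#' `(1 - p_cv)(1 - p_ncv)` either changes NYHA class (probability
#' `p_change`, destination split per the change matrix) or stays put.
#' Hospitalization and readmission do not move patients between states; they
#' are returned in the `events` attribute (per origin class, probability of
#' each event this cycle, with hospitalization evaluated among cycle
#' survivors) because they drive costs and disutilities.
#'
#' @param arm `"sacval"` or `"enalapril"`.
#' @param cycle Cycle index `t >= 1`.
#' @param config Model configuration.
#' @param age Attained age; defaults to the deterministic
#'   `start_age + (cycle - 1) / 12`.
#' @return A 6x6 row-stochastic matrix over [health_states()] with an
#'   `events` attribute (data.frame, one row per living class).
#' @export
build_transition_matrix <- function(arm, cycle, config,
                                    age = config$start_age + (cycle - 1) / 12) {
  states <- health_states()
  m <- matrix(0, 6, 6, dimnames = list(states, states))
  m["DEATH_CV", "DEATH_CV"] <- 1
  m["DEATH_NONCV", "DEATH_NONCV"] <- 1
  M <- config$nyha_matrix
  ev <- vector("list", 4)
  for (k in 1:4) {
    e <- event_probabilities(arm, k, cycle, age, config)
    surv <- (1 - e$p_cv_death) * (1 - e$p_noncv_death)
    m[k, 1:4] <- surv * e$p_nyha_change * M[k, ]
    m[k, k] <- m[k, k] + surv * (1 - e$p_nyha_change)
    m[k, "DEATH_CV"] <- e$p_cv_death
    m[k, "DEATH_NONCV"] <- (1 - e$p_cv_death) * e$p_noncv_death
    ev[[k]] <- data.frame(class = states[k],
                          p_hosp = surv * e$p_hosp,
                          p_readmit = e$p_readmit,
                          p_cv_death = e$p_cv_death,
                          p_noncv_death = (1 - e$p_cv_death) * e$p_noncv_death,
                          p_nyha_change = surv * e$p_nyha_change)
  }
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("internal consistency error: transition matrix rows do not sum to 1")
  if (any(m < 0) || any(m > 1))
    stop("internal consistency error: transition probability outside [0,1]")
  attr(m, "events") <- do.call(rbind, ev)
  m
}

#' Export per-cycle transition matrices in long format
#'
#' One row per (cycle, origin, destination) with the transition probability,
#' suitable for CSV audit.
#'
#' @param arm `"sacval"` or `"enalapril"`.
#' @param config Model configuration.
#' @param path Optional CSV output path.
#' @return The long-format data.frame, invisibly if `path` is given.
#' @export
export_transition_matrices <- function(arm, config, path = NULL) {
  states <- health_states()
  rows <- lapply(seq_len(config$horizon_cycles), function(t) {
    m <- build_transition_matrix(arm, t, config)
    data.frame(cycle = t,
               from = rep(states, times = 6),
               to = rep(states, each = 6),
               probability = as.vector(m))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# Fast path used by the cohort engine and microsimulation: all per-cycle,
# per-class probabilities as H x 4 matrices (plus the per-cycle non-CV death
# vector), computed once per run. Must agree with event_probabilities() /
# build_transition_matrix() entry by entry (tested).
arm_cycle_probs <- function(arm, config) {
  H <- config$horizon_cycles
  p <- config$params
  opt <- config$options
  hz <- config$hazards
  scale <- opt$hr_scale
  cyc <- seq_len(H)

  p_hosp_base <- monthly_prob_weibull(effective_hosp_lambda(config),
                                      hz$hospitalization$shape, cyc)
  hr_arm_hosp <- if (arm == "sacval") p$hr_hosp_sacval else 1
  hr_arm_cvd  <- if (arm == "sacval") p$hr_cvdeath_sacval else 1
  hr_class_hosp <- c(1, 1, p$hr_hosp_nyha3, p$hr_hosp_nyha4)
  rr_class_cvd  <- c(1, 1, p$rr_cvdeath_nyha3, p$rr_cvdeath_nyha4)

  p_hosp <- sapply(1:4, function(k)
    apply_hazard_ratio(apply_hazard_ratio(p_hosp_base, hr_arm_hosp, scale),
                       hr_class_hosp[k], scale))
  p_cvd_base <- monthly_prob_exponential(hz$cv_death$lam)
  p_cvd_row <- apply_relative_risk(
    apply_hazard_ratio(rep(p_cvd_base, 4), hr_arm_cvd, scale), rr_class_cvd)
  p_cvd <- matrix(p_cvd_row, H, 4, byrow = TRUE)

  age <- config$start_age + (cyc - 1) / 12
  p_ncv <- background_mortality_monthly(config$mortality, age)

  list(H = H, age = age,
       p_hosp = matrix(p_hosp, H, 4),
       p_cvd = p_cvd,
       p_ncv = p_ncv,
       p_change = if (arm == "sacval") p$nyha_progress_sacval
                  else p$nyha_progress_enalapril,
       p_readmit = p$readmission,
       p_readmit_cond = 1 - (1 - p$readmission)^12,
       M = unname(config$nyha_matrix),
       utilities = class_utilities(config),
       drug_cost = arm_drug_cost(arm, config),
       outpatient = p$cost_outpatient_monthly,
       copay = p$copay_inpatient,
       c_hosp = p$cost_hosp_event,
       c_readmit = p$cost_readmit_event,
       disu_hosp = if (opt$disutility_mode == "per_month")
         p$disutility_hosp / 12 else p$disutility_hosp,
       disu_readmit = if (opt$disutility_mode == "per_month")
         p$disutility_readmit / 12 else p$disutility_readmit,
       readmission_unconditional =
         identical(opt$readmission_mode, "unconditional"),
       discount = (1 + config$discount_rate_annual)^(-(cyc - 0.5) / 12))
}
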