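# Patient-level Monte Carlo simulation of the identical clinical pathway.
# Serves two purposes: an independent oracle for the cohort engine (same
# event probabilities, sequencing, accrual and discounting conventions, so
# the estimands agree exactly in expectation, not just asymptotically), and
# a generator of synthetic event-time datasets for hazard-parameter
# recovery.

#' Simulate a population of individual patients
#'
#' Each patient starts in a NYHA class drawn from the initial distribution
#' and is pushed through the monthly cycles: cardiovascular death first,
#' then non-CV death among survivors, then NYHA class change (destination
#' per the change matrix) and — independently among cycle survivors —
#' hospitalization and readmission. Accrual mirrors the cohort engine's
#' trapezoid convention: a patient contributes the average of start- and
#' end-of-cycle state utility (zero after death, so a death cycle counts
#' half a month), fixed monthly costs in full while surviving the cycle and
#' half in the death cycle, and one-time event costs/disutilities at the
#' cycle midpoint discount factor.
#'
#' @param arm `"sacval"` or `"enalapril"`.
#' @param n Number of patients.
#' @param config Model configuration.
#' @param seed RNG seed.
#' @param keep_trajectories Record per-patient state sequences and event
#'   logs (memory-heavy; intended for small `n`).
#' @return Object of class `microsim_result`: `n`, `arm`, per-patient
#'   discounted `cost` and `qaly` vectors, `estimates` (means with Monte
#'   Carlo standard errors for cost, QALY and the death fraction at the
#'   10-year mark or horizon if shorter), and `events` — the event-time
#'   dataset: `patient_id`, first-hospitalization `hosp_time` /
#'   `hosp_event`, CV-death `cvdeath_time` / `cvdeath_event` (`event = 0`
#'   means censored: at the horizon, or at the last fully-observed cycle
#'   when death intervenes).
#' @export
simulate_population <- function(arm, n, config, seed = config$seed,
                                keep_trajectories = FALSE) {
  arm <- match.arg(arm, arms())
  stopifnot(n >= 1)
  set.seed(seed)
  pc <- arm_cycle_probs(arm, config)
  H <- pc$H
  util <- pc$utilities
  fixed <- pc$drug_cost + pc$outpatient
  Mcum <- t(apply(pc$M, 1, cumsum))

  state <- sample.int(4L, n, replace = TRUE, prob = config$initial_nyha)
  qaly <- numeric(n); cost <- numeric(n)
  qaly_undisc <- numeric(n); cost_undisc <- numeric(n)
  first_hosp <- rep(NA_integer_, n)
  death_cycle <- rep(NA_integer_, n)
  hosp_prev <- logical(n)
  if (keep_trajectories) {
    states_mat <- matrix(NA_integer_, n, H + 1)
    states_mat[, 1] <- state
    event_log <- list()
  }

  for (t in seq_len(H)) {
    idx <- which(state <= 4L)
    if (!length(idx)) break
    cls <- state[idx]
    m <- length(idx)
    d <- pc$discount[t]

    die_cv <- stats::runif(m) < pc$p_cvd[t, ][cls]
    die_ncv <- !die_cv & (stats::runif(m) < pc$p_ncv[t])
    dead <- die_cv | die_ncv
    surv <- !dead

    ch <- surv & (stats::runif(m) < pc$p_change)
    dest <- cls
    if (any(ch))
      dest[ch] <- rowSums(stats::runif(sum(ch)) >
                            Mcum[cls[ch], , drop = FALSE]) + 1L

    hosp <- surv & (stats::runif(m) < pc$p_hosp[t, ][cls])
    readmit <- if (pc$readmission_unconditional)
      surv & (stats::runif(m) < pc$p_readmit)
    else surv & hosp_prev[idx] & (stats::runif(m) < pc$p_readmit_cond)

    u_end <- ifelse(dead, 0, util[dest])
    q_cycle <- (util[cls] + u_end) / 2 / 12 -
      pc$disu_hosp * hosp - pc$disu_readmit * readmit
    c_cycle <- fixed * ifelse(dead, 0.5, 1) +
      pc$copay * (pc$c_hosp * hosp + pc$c_readmit * readmit)
    qaly[idx] <- qaly[idx] + d * q_cycle
    cost[idx] <- cost[idx] + d * c_cycle
    qaly_undisc[idx] <- qaly_undisc[idx] + q_cycle
    cost_undisc[idx] <- cost_undisc[idx] + c_cycle

    newly_hosp <- idx[hosp]
    newly_hosp <- newly_hosp[is.na(first_hosp[newly_hosp])]
    first_hosp[newly_hosp] <- t
    death_cycle[idx[dead]] <- t

    if (keep_trajectories) {
      log1 <- function(which, name) if (any(which))
        data.frame(cycle = t, patient = idx[which], event = name)
      event_log[[length(event_log) + 1]] <- rbind(
        log1(hosp, "hosp"), log1(readmit, "readmit"),
        log1(ch, "nyha_change"), log1(die_cv, "cv_death"),
        log1(die_ncv, "noncv_death"))
    }

    state[idx[die_cv]] <- 5L
    state[idx[die_ncv]] <- 6L
    state[idx[ch]] <- dest[ch]
    hosp_prev[idx] <- hosp
    if (keep_trajectories) states_mat[, t + 1] <- state
  }

  mark <- min(120L, H)
  dead10 <- !is.na(death_cycle) & death_cycle <= mark
  cv_dead <- state == 5L

  events <- data.frame(
    patient_id = seq_len(n),
    hosp_time = ifelse(!is.na(first_hosp), first_hosp,
                       ifelse(!is.na(death_cycle), death_cycle - 1L, H)),
    hosp_event = as.integer(!is.na(first_hosp)),
    cvdeath_time = ifelse(cv_dead, death_cycle,
                          ifelse(!is.na(death_cycle), death_cycle, H)),
    cvdeath_event = as.integer(cv_dead)
  )

  out <- list(
    n = n, arm = arm, seed = seed,
    cost = cost, qaly = qaly,
    cost_undisc = cost_undisc, qaly_undisc = qaly_undisc,
    estimates = data.frame(
      quantity = c("cost", "qaly", "death_fraction"),
      mean = c(mean(cost), mean(qaly), mean(dead10)),
      se = c(stats::sd(cost) / sqrt(n), stats::sd(qaly) / sqrt(n),
             sqrt(mean(dead10) * (1 - mean(dead10)) / n))
    ),
    events = events
  )
  if (keep_trajectories) {
    el <- do.call(rbind, event_log)
    out$trajectories <- lapply(seq_len(n), function(i) {
      list(arm = arm,
           states = health_states()[states_mat[i, ]],
           events = if (!is.null(el)) el[el$patient == i, c("cycle", "event")]
                    else data.frame(cycle = integer(0), event = character(0)),
           cost = cost[i], qaly = qaly[i],
           cost_undisc = cost_undisc[i], qaly_undisc = qaly_undisc[i])
    })
  }
  class(out) <- "microsim_result"
  out
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> arm=%s, n=%d patients\n", x$arm, x$n))
  e <- x$estimates
  cat(sprintf("  mean cost:  $%.2f (SE %.3f)\n", e$mean[1], e$se[1]))
  cat(sprintf("  mean QALY:  %.4f (SE %.5f)\n", e$mean[2], e$se[2]))
  cat(sprintf("  death fraction: %.3f (SE %.4f)\n", e$mean[3], e$se[3]))
  invisible(x)
}

#' Simulate a single patient trajectory
#'
#' Runs the population engine with `n = 1` and trajectory recording, so a
#' single patient follows exactly the same pathway, sequencing and accrual
#' as the population and cohort analyses.
#'
#' @param arm `"sacval"` or `"enalapril"`.
#' @param config Model configuration.
#' @param seed RNG seed.
#' @return Trajectory list: `states` (state name per cycle boundary),
#'   `events` (cycle, event), realized discounted/undiscounted `cost` and
#'   `qaly`.
#' @export
simulate_patient <- function(arm, config, seed = config$seed) {
  simulate_population(arm, 1L, config, seed,
                      keep_trajectories = TRUE)$trajectories[[1]]
}

#' Write an event-time dataset to CSV
#'
#' @param result A [simulate_population()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_event_times <- function(result, path) {
  utils::write.csv(result$events, path, row.names = FALSE)
  invisible(path)
}

# Discrete-time log-likelihood under S(t) = exp(lam * t^shape): an event
# recorded at cycle t occurred in (t-1, t]; a record censored at c was
# event-free through cycle c.
weibull_discrete_loglik <- function(lam, shape, time, event) {
  te <- time[event == 1]; tc <- time[event == 0]
  sum(log(exp(lam * (te - 1)^shape) - exp(lam * te^shape))) +
    sum(lam * tc^shape)
}

#' Recover the exponential coefficient from censored event times
#'
#' Maximum-likelihood fit of the constant-rate discrete survival model to
#' monthly event times. The MLE is closed-form: with `d` events and total
#' event-free exposure `T` (sum of `t - 1` over events plus censoring times),
#' `lam = log(T / (T + d))`.
#'
#' @param time Event or censoring time in months.
#' @param event 1 = event observed, 0 = censored.
#' @param min_events Minimum number of uncensored events (default 100).
#' @return List with `lam` (signed log-survival coefficient), `n_events`,
#'   `loglik`.
#' @export
recover_exponential <- function(time, event, min_events = 100L) {
  stopifnot(length(time) == length(event))
  d <- sum(event == 1)
  if (d == 0) stop("no uncensored events; cannot estimate a rate")
  if (d < min_events)
    stop("need at least ", min_events, " uncensored events, got ", d)
  Tfree <- sum(time[event == 1] - 1) + sum(time[event == 0])
  lam <- log(Tfree / (Tfree + d))
  list(lam = lam, n_events = d,
       loglik = weibull_discrete_loglik(lam, 1, time, event))
}

#' Recover Weibull coefficients from censored event times
#'
#' Maximum-likelihood fit of `S(t) = exp(lam * t^shape)` to monthly event
#' times by quasi-Newton optimisation on `(log(-lam), log(shape))`, started
#' from the exponential fit.
#'
#' @inheritParams recover_exponential
#' @param min_events Minimum number of uncensored events (default 500).
#' @return List with `lam`, `shape`, `n_events`, `loglik`, `converged`.
#' @export
recover_weibull <- function(time, event, min_events = 500L) {
  stopifnot(length(time) == length(event))
  d <- sum(event == 1)
  if (d == 0) stop("no uncensored events; cannot estimate a hazard")
  if (d < min_events)
    stop("need at least ", min_events, " uncensored events, got ", d)
  start <- recover_exponential(time, event, min_events = 1L)
  nll <- function(theta)
    -weibull_discrete_loglik(-exp(theta[1]), exp(theta[2]), time, event)
  fit <- stats::optim(c(log(-start$lam), 0), nll, method = "BFGS",
                      control = list(maxit = 500))
  if (fit$convergence != 0)
    stop("weibull fit did not converge (optim code ", fit$convergence, ")")
  list(lam = -exp(fit$par[1]), shape = exp(fit$par[2]),
       n_events = d, loglik = -fit$value, converged = TRUE)
}
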