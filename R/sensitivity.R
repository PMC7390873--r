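# One-way deterministic sensitivity analysis (tornado), distribution
# fitting from published means and ranges, probabilistic sensitivity
# analysis, and the cost-effectiveness acceptability curve.

#' One-way deterministic sensitivity analysis
#'
#' For each manifest parameter, reruns both arms with the parameter at its
#' low and high bound (all other inputs at base case) and records the two
#' ICERs. Entries are returned sorted by descending span, tornado-style. A
#' bound that produces an invalid model (e.g. a probability pushed above 1)
#' is recorded as skipped with the reason rather than aborting the analysis.
#'
#' @param config Base configuration.
#' @param manifest Parameter manifest; defaults to
#'   [parameter_manifest()] of `config`.
#' @return data.frame with `parameter`, `low`, `up`, `icer_low`,
#'   `icer_high`, `span`, `note`.
#' @export
one_way_dsa <- function(config, manifest = parameter_manifest(config)) {
  icer_at <- function(name, value) {
    cfg <- set_param(config, name, value)
    pair <- list(run_cohort("sacval", cfg), run_cohort("enalapril", cfg))
    icer(pair[[1]], pair[[2]])$icer
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    nm <- manifest$name[i]
    lo <- tryCatch(icer_at(nm, manifest$low[i]), error = function(e) e)
    hi <- tryCatch(icer_at(nm, manifest$up[i]), error = function(e) e)
    note <- ""
    if (inherits(lo, "error")) { note <- conditionMessage(lo); lo <- NA_real_ }
    if (inherits(hi, "error")) {
      note <- paste(note, conditionMessage(hi)); hi <- NA_real_
    }
    data.frame(parameter = nm, low = manifest$low[i], up = manifest$up[i],
               icer_low = lo, icer_high = hi,
               span = if (is.na(lo) || is.na(hi)) NA_real_ else abs(hi - lo),
               note = trimws(note))
  })
  out <- do.call(rbind, rows)
  out[order(-out$span, out$parameter), , drop = FALSE]
}

#' Fit a beta distribution by moment matching
#'
#' Treats `(up - low) / (2 * 1.96)` as the standard deviation and matches
#' mean and variance. When `low < 0` or `up > 1` (or for bounded quantities
#' such as event disutilities) the beta is fitted on the `[low, up]` support
#' rescaled to `[0, 1]` and draws are mapped back. A degenerate range yields
#' a point-mass spec with a warning.
#'
#' @param mean Base-case mean.
#' @param low,up Range (95% interval or assumed percentage variation).
#' @param support Optional `c(lo, hi)` support for a rescaled beta; default
#'   the unit interval.
#' @return A distribution spec: list with `family`, `pars`, `source`.
#' @export
fit_beta <- function(mean, low, up, support = c(0, 1)) {
  src <- list(mean = mean, low = low, up = up)
  if (up <= low || (up - low) < 1e-12) {
    warning("degenerate range for beta fit; returning point mass")
    return(list(family = "fixed", pars = list(value = mean), source = src))
  }
  width <- support[2] - support[1]
  m <- (mean - support[1]) / width
  s <- (up - low) / (2 * 1.96) / width
  if (m <= 0 || m >= 1 || s^2 >= m * (1 - m))
    stop("beta moment matching infeasible for mean ", mean,
         " with sd ", s * width)
  nu <- m * (1 - m) / s^2 - 1
  list(family = "beta",
       pars = list(shape1 = m * nu, shape2 = (1 - m) * nu,
                   support = support),
       source = src)
}

#' Fit a gamma distribution by moment matching
#'
#' @inheritParams fit_beta
#' @return A distribution spec.
#' @export
fit_gamma <- function(mean, low, up) {
  src <- list(mean = mean, low = low, up = up)
  if (up <= low || (up - low) < 1e-12) {
    warning("degenerate range for gamma fit; returning point mass")
    return(list(family = "fixed", pars = list(value = mean), source = src))
  }
  s <- (up - low) / (2 * 1.96)
  list(family = "gamma",
       pars = list(shape = mean^2 / s^2, rate = mean / s^2),
       source = src)
}

#' Fit a log-normal distribution from a point estimate and 95% CI
#'
#' `meanlog = log(point)` (the point estimate is the median) and
#' `sdlog = (log(ci_up) - log(ci_low)) / (2 * 1.96)`.
#'
#' @param point Point estimate (hazard ratio or relative risk).
#' @param ci_low,ci_up 95% confidence bounds.
#' @return A distribution spec.
#' @export
fit_lognormal <- function(point, ci_low, ci_up) {
  src <- list(mean = point, low = ci_low, up = ci_up)
  if (ci_up <= ci_low || (ci_up - ci_low) < 1e-12) {
    warning("degenerate range for log-normal fit; returning point mass")
    return(list(family = "fixed", pars = list(value = point), source = src))
  }
  stopifnot(point > 0, ci_low > 0)
  list(family = "lognormal",
       pars = list(meanlog = log(point),
                   sdlog = (log(ci_up) - log(ci_low)) / (2 * 1.96)),
       source = src)
}

#' Draw from a fitted distribution spec
#'
#' @param spec A spec from [fit_beta()], [fit_gamma()] or
#'   [fit_lognormal()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_spec <- function(spec, n = 1L) {
  switch(spec$family,
    fixed = rep(spec$pars$value, n),
    beta = {
      y <- stats::rbeta(n, spec$pars$shape1, spec$pars$shape2)
      sup <- spec$pars$support
      sup[1] + (sup[2] - sup[1]) * y
    },
    gamma = stats::rgamma(n, shape = spec$pars$shape, rate = spec$pars$rate),
    lognormal = stats::rlnorm(n, spec$pars$meanlog, spec$pars$sdlog),
    stop("unknown distribution family: ", spec$family))
}

#' Probabilistic distribution specs for every sampled parameter
#'
#' Beta for probabilities and utilities, log-normal for hazard ratios and
#' relative risks, gamma for costs; event disutilities are beta on their
#' printed magnitude range. Manifest rows with `dist = "fixed"` (the two
#' survival baselines and the inpatient copay ratio) are excluded — they are
#' varied in one-way analyses only.
#'
#' @param config Model configuration.
#' @param manifest Parameter manifest.
#' @return Named list of distribution specs.
#' @export
psa_specs <- function(config, manifest = parameter_manifest(config)) {
  specs <- list()
  for (i in seq_len(nrow(manifest))) {
    nm <- manifest$name[i]
    b <- manifest$base[i]; lo <- manifest$low[i]; up <- manifest$up[i]
    specs[[nm]] <- switch(manifest$dist[i],
      fixed = NULL,
      beta = if (manifest$kind[i] == "disutility")
        fit_beta(b, lo, up, support = c(lo, up)) else fit_beta(b, lo, up),
      gamma = fit_gamma(b, lo, up),
      lognormal = fit_lognormal(b, lo, up))
  }
  specs[!vapply(specs, is.null, logical(1))]
}

#' Run the probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: each draw samples every parameter independently
#' from its fitted distribution, runs both arms, and records costs and
#' QALYs. Draw `i` uses its own deterministically derived RNG substream
#' (`seed + i`), so results are reproducible and independent of execution
#' order. A sampled value that violates its kind's bounds (e.g. a
#' probability above 1) is redrawn, with a capped retry count.
#'
#' @param config Model configuration.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Master seed.
#' @param specs Distribution specs; defaults to [psa_specs()].
#' @return data.frame of class `psa_samples` with one row per draw:
#'   `draw`, per-arm `cost_*` and `qaly_*`, `delta_cost`, `delta_qaly`.
#'   Sampled parameter values are attached as attribute `"parameters"`.
#' @export
run_psa <- function(config, n_draws = config$psa_draws, seed = config$seed,
                    specs = psa_specs(config)) {
  stopifnot(n_draws >= 1)
  kind <- stats::setNames(parameter_manifest(config)$kind,
                          parameter_manifest(config)$name)
  sample_one <- function(spec, k) {
    for (try in 1:100) {
      v <- draw_spec(spec, 1L)
      ok <- switch(k,
                   probability = v >= 0 && v <= 1,
                   utility = v >= 0 && v <= 1,
                   v >= 0)
      if (ok) return(v)
    }
    stop("rejection sampling failed after 100 retries")
  }
  par_mat <- matrix(NA_real_, n_draws, length(specs),
                    dimnames = list(NULL, names(specs)))
  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    set.seed(seed + i)
    cfg <- config
    for (nm in names(specs)) {
      v <- sample_one(specs[[nm]], kind[[nm]])
      par_mat[i, nm] <- v
      cfg <- set_param(cfg, nm, v)
    }
    s <- run_cohort("sacval", cfg)
    e <- run_cohort("enalapril", cfg)
    out[[i]] <- c(draw = i,
                  cost_sacval = s$total_cost, qaly_sacval = s$total_qaly,
                  cost_enalapril = e$total_cost, qaly_enalapril = e$total_qaly,
                  delta_cost = s$total_cost - e$total_cost,
                  delta_qaly = s$total_qaly - e$total_qaly)
  }
  samples <- as.data.frame(do.call(rbind, out))
  attr(samples, "parameters") <- par_mat
  class(samples) <- c("psa_samples", class(samples))
  samples
}

#' Summarise PSA samples
#'
#' @param samples A [run_psa()] result.
#' @return data.frame with mean and 2.5%/97.5% quantiles of cost and QALY
#'   per arm.
#' @export
psa_summary <- function(samples) {
  qs <- function(x) c(mean = mean(x),
                      lo = unname(stats::quantile(x, 0.025)),
                      hi = unname(stats::quantile(x, 0.975)))
  rbind(
    data.frame(arm = "sacval", outcome = "cost", t(qs(samples$cost_sacval))),
    data.frame(arm = "sacval", outcome = "qaly", t(qs(samples$qaly_sacval))),
    data.frame(arm = "enalapril", outcome = "cost",
               t(qs(samples$cost_enalapril))),
    data.frame(arm = "enalapril", outcome = "qaly",
               t(qs(samples$qaly_enalapril)))
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit,
#' `wtp * delta_qaly - delta_cost > 0`, at each willingness-to-pay value.
#'
#' @param samples A [run_psa()] result (or any data.frame with
#'   `delta_cost`, `delta_qaly`).
#' @param wtp_grid Willingness-to-pay values.
#' @return data.frame with `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid) {
  stopifnot(nrow(samples) > 0)
  data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(
      wtp_grid,
      function(w) mean(w * samples$delta_qaly - samples$delta_cost > 0),
      numeric(1))
  )
}
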