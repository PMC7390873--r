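# Model inputs: every quantity the model reads lives in one configuration
# object so that the deterministic engine, the sensitivity analyses and the
# microsimulation all draw from the same registry.

#' Health-state labels
#'
#' Six states: NYHA functional classes I-IV plus two absorbing death states.
#' Cardiovascular and non-cardiovascular deaths are tracked separately for
#' event accounting but reported jointly as "death" wherever a combined
#' mortality figure is needed.
#'
#' @return Character vector of the six state names in canonical order.
#' @export
health_states <- function() {
  c("NYHA_I", "NYHA_II", "NYHA_III", "NYHA_IV", "DEATH_CV", "DEATH_NONCV")
}

# Age-specific annual probability of non-cardiovascular death (Chinese
# epidemiological data, 2018, CV deaths excluded). The final row closes the
# table: no survival past age 100.
mortality_table <- function() {
  data.frame(
    age = c(1, 5, 10, 15, 20, 25, 30, 35, 40, 45,
            50, 55, 60, 65, 70, 75, 80, 85, 100),
    annual_prob = c(0.002949, 0.000284, 0.00015, 0.000169, 0.000177,
                    0.000154, 0.000298, 0.000458, 0.000472, 0.00071,
                    0.0011998, 0.0029394, 0.0028332, 0.0066972, 0.0097194,
                    0.0121676, 0.016739, 0.0331037, 1.00)
  )
}

# Conditional destination distribution for a NYHA class change in one monthly
# cycle. Rows are origin classes I-IV, columns destination classes I-IV;
# diagonal is structurally zero (a "change" always leaves the class).
nyha_change_matrix <- function() {
  m <- rbind(
    c(0.000, 0.831, 0.169, 0.000),
    c(0.422, 0.000, 0.531, 0.047),
    c(0.000, 0.847, 0.000, 0.153),
    c(0.000, 0.000, 1.000, 0.000)
  )
  dimnames(m) <- list(health_states()[1:4], health_states()[1:4])
  m
}

#' Default model configuration
#'
#' Returns the base-case configuration: a 10-year horizon in monthly cycles,
#' cohort starting age 64, the trial-based initial NYHA distribution
#' (4.5/71.6/23.1/0.8%), a 3.5% annual discount rate, and every probability,
#' treatment-effect, utility and cost input at its base value, along with the
#' drug price decomposition (list price, insurance copay ratio, patient-borne
#' monthly cost) for both treatment arms.
#'
#' The `options` block holds the modelling conventions that the published
#' inputs leave open; each is a documented switch:
#' \describe{
#'   \item{weibull_mode}{`"raw"` (default) uses the printed Weibull
#'     coefficients for the hospitalization baseline directly;
#'     `"calibrated"` rescales the scale coefficient so the horizon-mean
#'     monthly probability equals `hosp_anchor`.}
#'   \item{hosp_anchor}{anchor (monthly probability) for the calibrated mode;
#'     must lie in the printed plausible band `[0.00868, 0.0145]`.}
#'   \item{hr_scale}{`"rate"` (default) applies hazard ratios as
#'     `1-(1-p)^HR`; `"probability"` multiplies the probability directly.}
#'   \item{disutility_mode}{`"per_event"` (default) subtracts the full
#'     one-time disutility per expected event; `"per_month"` subtracts
#'     disutility/12.}
#'   \item{readmission_mode}{`"unconditional"` (default) applies the monthly
#'     readmission probability to every cycle survivor; `"conditional"`
#'     applies the annualised value as a 30-day conditional probability to the
#'     previous cycle's hospitalized fraction.}
#'   \item{drug_copay_is_reimbursed}{`TRUE`: the drug copay ratio is the
#'     share the insurer reimburses, so patients pay `price * (1 - ratio)`.}
#'   \item{inpatient_copay_is_patient_share}{`TRUE`: the inpatient copay
#'     ratio is the share of event costs the patient bears.}
#' }
#'
#' @return A list of class `hfcea_config`.
#' @export
default_config <- function() {
  cfg <- list(
    horizon_cycles = 120L,
    cycle_length_months = 1L,
    start_age = 64,
    discount_rate_annual = 0.035,
    initial_nyha = c(NYHA_I = 0.045, NYHA_II = 0.716,
                     NYHA_III = 0.231, NYHA_IV = 0.008),
    wtp_thresholds = c(gdp_per_capita = 10276, gdp_x3 = 30828),
    psa_draws = 10000L,
    seed = 20200723L %% 1000L,  # small master seed; PSA adds the draw index
    options = list(
      weibull_mode = "raw",
      hosp_anchor = 0.00868,
      calibration_window = 120L,
      hr_scale = "rate",
      disutility_mode = "per_event",
      readmission_mode = "unconditional",
      drug_copay_is_reimbursed = TRUE,
      inpatient_copay_is_patient_share = TRUE
    ),
    hazards = list(
      hospitalization = list(family = "weibull", lam = -0.00097,
                             shape = 1.02685,
                             low = 0.00868, up = 0.0145),
      cv_death = list(family = "exponential", lam = -0.00577,
                      low = 0.00412, up = 0.00844)
    ),
    params = list(
      readmission              = 0.0147,
      nyha_progress_enalapril  = 0.0088,
      nyha_progress_sacval     = 0.0068,
      hr_hosp_sacval           = 0.79,
      hr_cvdeath_sacval        = 0.80,
      hr_hosp_nyha3            = 1.71,
      hr_hosp_nyha4            = 3.4,
      rr_cvdeath_nyha3         = 1.372,
      rr_cvdeath_nyha4         = 1.640,
      utility_nyha12           = 0.780,
      utility_nyha3            = 0.715,
      utility_nyha4            = 0.660,
      disutility_hosp          = 0.1,
      disutility_readmit       = 0.1,
      cost_sacval_monthly      = 17.12,
      cost_enalapril_monthly   = 10.65,
      cost_outpatient_monthly  = 41.56,
      copay_inpatient          = 0.3,
      cost_hosp_event          = 1920.49,
      cost_readmit_event       = 1340.05
    ),
    drugs = list(
      sacval = list(dose = "200 mg twice daily", unit_price = 1.42,
                    copay_ratio = 0.8, monthly_price = 85.61,
                    monthly_cost = 17.12),
      enalapril = list(dose = "10 mg twice daily", unit_price = 0.18,
                       copay_ratio = 0, monthly_price = 10.65,
                       monthly_cost = 10.65)
    ),
    mortality = mortality_table(),
    nyha_matrix = nyha_change_matrix()
  )
  class(cfg) <- "hfcea_config"
  cfg
}

#' Parameter manifest for sensitivity analyses
#'
#' Enumerates every tunable model input with its base value, deterministic
#' sensitivity bounds, probabilistic distribution family and semantic kind.
#' The two parametric survival baselines enter as the pseudo-parameters
#' `p_hosp_baseline` (varied through the calibrated Weibull mode) and
#' `p_cvdeath_baseline` (varied through the exponential coefficient); their
#' distribution is `fixed` because no distribution family is assigned to
#' them, so they move in one-way analyses only. The same applies to the
#' inpatient copay ratio.
#'
#' @param config A model configuration; defaults to [default_config()].
#' @return A data.frame with columns `name`, `base`, `low`, `up`, `dist`,
#'   `kind`.
#' @export
parameter_manifest <- function(config = default_config()) {
  p <- config$params
  hz <- config$hazards
  df <- rbind.data.frame(
    list("p_hosp_baseline", mean(monthly_prob_weibull(
           effective_hosp_lambda(config), hz$hospitalization$shape,
           seq_len(config$options$calibration_window))),
         hz$hospitalization$low, hz$hospitalization$up, "fixed", "probability"),
    list("p_cvdeath_baseline", monthly_prob_exponential(hz$cv_death$lam),
         hz$cv_death$low, hz$cv_death$up, "fixed", "probability"),
    list("readmission", p$readmission, 0.0132, 0.0161, "beta", "probability"),
    list("nyha_progress_enalapril", p$nyha_progress_enalapril,
         0.0079, 0.0097, "beta", "probability"),
    list("nyha_progress_sacval", p$nyha_progress_sacval,
         0.00612, 0.00748, "beta", "probability"),
    list("hr_hosp_sacval", p$hr_hosp_sacval, 0.71, 0.89,
         "lognormal", "hazard_ratio"),
    list("hr_cvdeath_sacval", p$hr_cvdeath_sacval, 0.71, 0.89,
         "lognormal", "hazard_ratio"),
    list("hr_hosp_nyha3", p$hr_hosp_nyha3, 1.33, 2.18,
         "lognormal", "hazard_ratio"),
    list("hr_hosp_nyha4", p$hr_hosp_nyha4, 1.69, 6.84,
         "lognormal", "hazard_ratio"),
    list("rr_cvdeath_nyha3", p$rr_cvdeath_nyha3, 1.303, 1.445,
         "lognormal", "relative_risk"),
    list("rr_cvdeath_nyha4", p$rr_cvdeath_nyha4, 1.503, 1.790,
         "lognormal", "relative_risk"),
    list("utility_nyha12", p$utility_nyha12, 0.741, 0.819, "beta", "utility"),
    list("utility_nyha3", p$utility_nyha3, 0.679, 0.751, "beta", "utility"),
    list("utility_nyha4", p$utility_nyha4, 0.627, 0.693, "beta", "utility"),
    list("disutility_hosp", p$disutility_hosp, 0.08, 0.13,
         "beta", "disutility"),
    list("disutility_readmit", p$disutility_readmit, 0.08, 0.13,
         "beta", "disutility"),
    list("cost_sacval_monthly", p$cost_sacval_monthly, 13.70, 30.46,
         "gamma", "cost"),
    list("cost_enalapril_monthly", p$cost_enalapril_monthly, 0.90, 12.78,
         "gamma", "cost"),
    list("cost_outpatient_monthly", p$cost_outpatient_monthly, 33.26, 49.87,
         "gamma", "cost"),
    list("copay_inpatient", p$copay_inpatient, 0.1, 1, "fixed", "rate"),
    list("cost_hosp_event", p$cost_hosp_event, 1536.39, 2304.59,
         "gamma", "cost"),
    list("cost_readmit_event", p$cost_readmit_event, 1072.04, 1608.06,
         "gamma", "cost")
  )
  names(df) <- c("name", "base", "low", "up", "dist", "kind")
  df$base <- as.numeric(df$base)
  df$low <- as.numeric(df$low)
  df$up <- as.numeric(df$up)
  df
}

#' Set a manifest parameter in a configuration
#'
#' Maps a [parameter_manifest()] name onto the configuration. Ordinary
#' parameters land in `config$params`; the survival-baseline
#' pseudo-parameters are translated back onto the hazard specifications
#' (`p_cvdeath_baseline` sets the exponential coefficient to `log(1 - p)`;
#' `p_hosp_baseline` switches the Weibull baseline into calibrated mode with
#' the value as anchor).
#'
#' @param config A model configuration.
#' @param name A manifest parameter name.
#' @param value New numeric value.
#' @return The modified configuration.
#' @export
set_param <- function(config, name, value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (name == "p_cvdeath_baseline") {
    if (value <= 0 || value >= 1) stop("baseline probability must be in (0,1)")
    config$hazards$cv_death$lam <- log(1 - value)
  } else if (name == "p_hosp_baseline") {
    if (value <= 0 || value >= 1) stop("baseline probability must be in (0,1)")
    config$options$weibull_mode <- "calibrated"
    config$options$hosp_anchor <- value
  } else if (name %in% names(config$params)) {
    config$params[[name]] <- value
  } else {
    stop("unknown parameter: ", name)
  }
  config
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration and returns the
#' findings as a character vector (empty when everything holds); validation
#' never throws, so it can be used to report all problems at once.
#'
#' @param config A model configuration.
#' @return Character vector of findings; `character(0)` if valid.
#' @export
validate_config <- function(config) {
  f <- character(0)
  note <- function(...) f <<- c(f, paste0(...))

  if (!is.numeric(config$horizon_cycles) || config$horizon_cycles < 1)
    note("horizon_cycles: must be a positive integer number of months")
  if (!is.numeric(config$discount_rate_annual) ||
      config$discount_rate_annual < 0)
    note("discount_rate_annual: must be >= 0")
  if (length(config$initial_nyha) != 4L ||
      any(config$initial_nyha < 0) ||
      abs(sum(config$initial_nyha) - 1) > 1e-9)
    note("initial_nyha: four non-negative fractions summing to 1")

  hz <- config$hazards
  if (hz$hospitalization$family != "weibull" ||
      !is.numeric(hz$hospitalization$shape))
    note("hazards$hospitalization: weibull family with a shape parameter")
  if (hz$hospitalization$lam >= 0)
    note("hazards$hospitalization$lam: survival coefficient must be negative")
  if (hz$cv_death$family != "exponential")
    note("hazards$cv_death: exponential family")
  else if (!is.null(hz$cv_death$shape))
    note("hazards$cv_death: exponential family takes no shape parameter")
  if (hz$cv_death$lam >= 0)
    note("hazards$cv_death$lam: survival coefficient must be negative")

  opt <- config$options
  if (!opt$weibull_mode %in% c("raw", "calibrated"))
    note("options$weibull_mode: must be 'raw' or 'calibrated'")
  if (opt$weibull_mode == "calibrated" &&
      (opt$hosp_anchor < hz$hospitalization$low ||
       opt$hosp_anchor > hz$hospitalization$up))
    note("options$hosp_anchor: anchor outside the plausible band [",
         hz$hospitalization$low, ", ", hz$hospitalization$up, "]")
  if (!opt$hr_scale %in% c("rate", "probability"))
    note("options$hr_scale: must be 'rate' or 'probability'")
  if (!opt$disutility_mode %in% c("per_event", "per_month"))
    note("options$disutility_mode: must be 'per_event' or 'per_month'")
  if (!opt$readmission_mode %in% c("unconditional", "conditional"))
    note("options$readmission_mode: must be 'unconditional' or 'conditional'")

  # parameter-kind bounds
  man <- tryCatch(parameter_manifest(config), error = function(e) NULL)
  if (is.null(man)) {
    note("params: manifest could not be built from this configuration")
  } else {
    for (i in seq_len(nrow(man))) {
      v <- man$base[i]; k <- man$kind[i]; nm <- man$name[i]
      if (k == "probability" && (v < 0 || v > 1))
        note(nm, ": probability must lie in [0,1], got ", v)
      if (k == "utility" && (v < 0 || v > 1))
        note(nm, ": utility must lie in [0,1], got ", v)
      if (k %in% c("cost", "disutility") && v < 0)
        note(nm, ": must be non-negative, got ", v)
      if (k %in% c("hazard_ratio", "relative_risk") && v <= 0)
        note(nm, ": must be positive, got ", v)
      if (!(man$low[i] <= v && v <= man$up[i]) &&
          !nm %in% c("p_hosp_baseline"))  # raw baseline sits below its band
        warning(nm, ": base value ", v, " outside printed range [",
                man$low[i], ", ", man$up[i], "]", call. = FALSE)
    }
  }
  if (config$params$copay_inpatient < 0 || config$params$copay_inpatient > 1)
    note("copay_inpatient: must lie in [0,1]")

  # mortality table
  mt <- config$mortality
  if (is.unsorted(mt$age, strictly = TRUE))
    note("mortality: ages must be strictly increasing")
  if (any(mt$annual_prob < 0 | mt$annual_prob > 1))
    note("mortality: annual probabilities must lie in [0,1]")
  if (mt$age[nrow(mt)] != 100 || mt$annual_prob[nrow(mt)] != 1)
    note("mortality: table must close with (age 100, probability 1)")

  # NYHA change matrix
  m <- config$nyha_matrix
  if (any(diag(m) != 0))
    note("nyha_matrix: diagonal must be structurally zero")
  if (any(m < 0))
    note("nyha_matrix: entries must be non-negative")
  bad <- which(abs(rowSums(m) - 1) > 1e-9)
  for (b in bad)
    note("nyha_matrix: row ", rownames(m)[b], " sums to ", rowSums(m)[b],
         ", expected 1")

  # drug cost decomposition
  for (d in names(config$drugs)) {
    dd <- config$drugs[[d]]
    patient_share <- if (isTRUE(opt$drug_copay_is_reimbursed))
      1 - dd$copay_ratio else dd$copay_ratio
    if (abs(dd$monthly_cost - dd$monthly_price * patient_share) > 0.01)
      note("drugs$", d, ": monthly_cost ", dd$monthly_cost,
           " inconsistent with monthly_price x patient share ",
           round(dd$monthly_price * patient_share, 2))
  }
  f
}

#' Write a configuration to a YAML file
#'
#' @param config A model configuration.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$initial_nyha <- as.list(x$initial_nyha)
  x$wtp_thresholds <- as.list(x$wtp_thresholds)
  x$mortality <- as.list(x$mortality)
  x$nyha_matrix <- apply(unname(x$nyha_matrix), 1, as.numeric,
                         simplify = FALSE)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Load and validate a configuration from a YAML (or JSON) file
#'
#' Unknown keys are rejected; missing keys are an error unless
#' `allow_partial = TRUE`, in which case they are filled from
#' [default_config()].
#'
#' @param path Path to a YAML/JSON configuration file.
#' @param allow_partial Fill missing keys from the defaults.
#' @return A validated configuration of class `hfcea_config`.
#' @export
load_config <- function(path, allow_partial = FALSE) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("config parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  def <- default_config()
  cfg <- merge_config(unclass(def), raw, allow_partial, path = "")
  cfg$mortality <- as.data.frame(cfg$mortality)
  if (is.list(cfg$nyha_matrix))
    cfg$nyha_matrix <- do.call(rbind, cfg$nyha_matrix)
  dimnames(cfg$nyha_matrix) <- dimnames(def$nyha_matrix)
  cfg$initial_nyha <- stats::setNames(unlist(cfg$initial_nyha),
                                      names(def$initial_nyha))
  cfg$wtp_thresholds <- unlist(cfg$wtp_thresholds)
  if (is.null(names(cfg$wtp_thresholds)) &&
      length(cfg$wtp_thresholds) == length(def$wtp_thresholds))
    names(cfg$wtp_thresholds) <- names(def$wtp_thresholds)
  class(cfg) <- "hfcea_config"
  findings <- validate_config(cfg)
  if (length(findings))
    stop("invalid configuration '", path, "':\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  cfg
}

# Recursive merge of a user config onto the default skeleton. Scalars and
# atomic vectors are replaced wholesale; named lists are merged key by key.
# Keys absent from the skeleton are unknown and rejected.
merge_config <- function(def, user, allow_partial, path) {
  if (!is.list(def) || !is.list(user) || is.null(names(def)))
    return(user)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown configuration key", if (length(unknown) > 1) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(names(def), names(user))
  if (length(missing) && !allow_partial)
    stop("missing configuration key", if (length(missing) > 1) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", missing)), collapse = ", "),
         "; pass allow_partial = TRUE to fill from defaults", call. = FALSE)
  out <- def
  for (k in names(user)) {
    if (k %in% c("mortality", "nyha_matrix", "drugs")) {
      out[[k]] <- user[[k]]
    } else {
      out[[k]] <- merge_config(def[[k]], user[[k]], allow_partial,
                               paste0(path, ".", k))
    }
  }
  out
}

#' @export
print.hfcea_config <- function(x, ...) {
  cat("<hfcea_config>\n")
  cat(sprintf("  horizon: %d monthly cycles (%.1f years), start age %g\n",
              x$horizon_cycles, x$horizon_cycles / 12, x$start_age))
  cat(sprintf("  initial NYHA distribution: %s\n",
              paste(sprintf("%.1f%%", 100 * x$initial_nyha), collapse = " / ")))
  cat(sprintf("  annual discount rate: %.1f%%\n",
              100 * x$discount_rate_annual))
  cat(sprintf("  drug cost (patient/month): sacubitril-valsartan $%.2f, enalapril $%.2f\n",
              x$params$cost_sacval_monthly, x$params$cost_enalapril_monthly))
  cat(sprintf("  conventions: weibull=%s, readmission=%s, disutility=%s, HR on %s scale\n",
              x$options$weibull_mode, x$options$readmission_mode,
              x$options$disutility_mode, x$options$hr_scale))
  invisible(x)
}

#' Treatment arm names
#' @return `c("sacval", "enalapril")`.
#' @export
arms <- function() c("sacval", "enalapril")

# Per-class utility vector (classes I and II share a utility).
class_utilities <- function(config) {
  p <- config$params
  c(p$utility_nyha12, p$utility_nyha12, p$utility_nyha3, p$utility_nyha4)
}

# Patient-borne monthly drug cost for an arm.
arm_drug_cost <- function(arm, config) {
  switch(arm,
         sacval = config$params$cost_sacval_monthly,
         enalapril = config$params$cost_enalapril_monthly,
         stop("unknown arm: ", arm))
}
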