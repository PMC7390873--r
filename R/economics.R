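# Comparative cost-effectiveness: increments, ICER, net monetary benefit,
# break-even (threshold) drug prices, and the two-way price grid.

#' Incremental cost-effectiveness of one arm over another
#'
#' Computes incremental discounted cost and QALYs (intervention minus
#' comparator), the ICER, and net monetary benefit at each willingness-to-pay
#' threshold. Dominance is classified by the signs of the increments:
#' `"dominant"` (more effective, cheaper), `"dominated"` (less effective,
#' costlier), `"undefined"` when the QALY increment is exactly zero, and
#' `"icer"` otherwise.
#'
#' @param intervention,comparator [run_cohort()] results from identical
#'   configurations apart from the arm.
#' @param wtp Willingness-to-pay thresholds (USD/QALY); defaults to the
#'   thresholds in the intervention's configuration.
#' @return Object of class `ce_result`: per-arm totals, `delta_cost`,
#'   `delta_qaly`, `icer` (NA unless status `"icer"`), `status`, and `nmb`
#'   (named vector, `wtp * delta_qaly - delta_cost`).
#' @export
icer <- function(intervention, comparator,
                 wtp = intervention$config$wtp_thresholds) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  status <- if (dq == 0) "undefined"
    else if (dq > 0 && dc < 0) "dominant"
    else if (dq < 0 && dc > 0) "dominated"
    else "icer"
  structure(list(
    intervention = intervention$arm,
    comparator = comparator$arm,
    cost = c(stats::setNames(intervention$total_cost, intervention$arm),
             stats::setNames(comparator$total_cost, comparator$arm)),
    qaly = c(stats::setNames(intervention$total_qaly, intervention$arm),
             stats::setNames(comparator$total_qaly, comparator$arm)),
    delta_cost = dc,
    delta_qaly = dq,
    icer = if (status == "icer") dc / dq else NA_real_,
    status = status,
    nmb = stats::setNames(wtp * dq - dc, names(wtp))
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  cost: $%.2f vs $%.2f (delta $%.2f)\n",
              x$cost[1], x$cost[2], x$delta_cost))
  cat(sprintf("  QALY: %.4f vs %.4f (delta %.4f)\n",
              x$qaly[1], x$qaly[2], x$delta_qaly))
  if (x$status == "icer")
    cat(sprintf("  ICER: $%.2f per QALY\n", x$icer))
  else cat(sprintf("  status: %s\n", x$status))
  invisible(x)
}

#' Net monetary benefit of sacubitril-valsartan at given drug prices
#'
#' Helper used by the threshold search and the two-way grid: runs both arms
#' with overridden patient-borne monthly drug costs and returns
#' `wtp * delta_qaly - delta_cost`.
#'
#' @param wtp Willingness-to-pay (USD/QALY).
#' @param sacval_cost,enalapril_cost Patient-borne monthly drug costs.
#' @param config Model configuration.
#' @return Net monetary benefit in USD.
#' @export
nmb_at_prices <- function(wtp, sacval_cost, enalapril_cost, config) {
  config$params$cost_sacval_monthly <- sacval_cost
  config$params$cost_enalapril_monthly <- enalapril_cost
  res <- icer(run_cohort("sacval", config), run_cohort("enalapril", config),
              wtp = wtp)
  unname(res$nmb)
}

#' Break-even monthly price of sacubitril-valsartan
#'
#' Finds the patient-borne monthly cost at which the net monetary benefit
#' against enalapril is zero at the given willingness-to-pay, by bracketed
#' root-finding over `interval`. NMB is strictly decreasing in the price, so
#' the root is unique when it exists; if NMB does not change sign on the
#' interval, the nearer boundary is returned with `converged = FALSE`.
#'
#' @param wtp Willingness-to-pay threshold (USD/QALY), `> 0`.
#' @param comparator_cost Enalapril patient-borne monthly cost.
#' @param config Model configuration.
#' @param interval Search bracket for the monthly cost (default $0-$150).
#' @param tol Price tolerance in USD (default $0.01).
#' @return Object of class `threshold_result`: `wtp`, `comparator_cost`,
#'   `breakeven_cost`, `nmb_at_breakeven`, `converged`.
#' @export
breakeven_price <- function(wtp, comparator_cost, config,
                            interval = c(0, 150), tol = 0.01) {
  stopifnot(wtp >= 0, length(interval) == 2, interval[1] < interval[2])
  f <- function(p) nmb_at_prices(wtp, p, comparator_cost, config)
  f_lo <- f(interval[1]); f_hi <- f(interval[2])
  if (sign(f_lo) == sign(f_hi)) {
    at <- if (abs(f_lo) < abs(f_hi)) interval[1] else interval[2]
    out <- list(wtp = wtp, comparator_cost = comparator_cost,
                breakeven_cost = at, nmb_at_breakeven = f(at),
                converged = FALSE)
  } else {
    root <- stats::uniroot(f, interval, f.lower = f_lo, f.upper = f_hi,
                           tol = tol / 10)
    out <- list(wtp = wtp, comparator_cost = comparator_cost,
                breakeven_cost = root$root, nmb_at_breakeven = root$f.root,
                converged = TRUE)
  }
  class(out) <- "threshold_result"
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> WTP $%s/QALY, comparator $%.2f/month\n",
              format(x$wtp, big.mark = ","), x$comparator_cost))
  cat(sprintf("  break-even monthly cost: $%.2f%s\n", x$breakeven_cost,
              if (!x$converged) " (boundary, no sign change)" else ""))
  invisible(x)
}

#' Two-way sensitivity grid over both drug prices
#'
#' Labels each (sacubitril-valsartan price, enalapril price) cell
#' cost-effective or not by the sign of net monetary benefit at each
#' willingness-to-pay. QALYs do not depend on drug prices, so each axis
#' value requires one cohort run per arm.
#'
#' @param sacval_costs,enalapril_costs Numeric axes of patient-borne monthly
#'   costs.
#' @param wtp Vector of willingness-to-pay thresholds.
#' @param config Model configuration.
#' @return data.frame with `sacval_cost`, `enalapril_cost`, `wtp`, `nmb`,
#'   `cost_effective`.
#' @export
two_way_grid <- function(sacval_costs, enalapril_costs, wtp, config) {
  run_at <- function(arm, cost_name, v) {
    config$params[[cost_name]] <- v
    run_cohort(arm, config)
  }
  s_runs <- lapply(sacval_costs, function(v)
    run_at("sacval", "cost_sacval_monthly", v))
  e_runs <- lapply(enalapril_costs, function(v)
    run_at("enalapril", "cost_enalapril_monthly", v))
  grid <- expand.grid(si = seq_along(sacval_costs),
                      ei = seq_along(enalapril_costs),
                      w = wtp)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- s_runs[[grid$si[i]]]; e <- e_runs[[grid$ei[i]]]
    nmb <- grid$w[i] * (s$total_qaly - e$total_qaly) -
      (s$total_cost - e$total_cost)
    data.frame(sacval_cost = sacval_costs[grid$si[i]],
               enalapril_cost = enalapril_costs[grid$ei[i]],
               wtp = grid$w[i], nmb = nmb, cost_effective = nmb > 0)
  })
  do.call(rbind, rows)
}
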