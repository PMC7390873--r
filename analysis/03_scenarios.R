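#!/usr/bin/env Rscript
# Scenario analyses: time horizon (5/10/15/20 years) under the trial
# initial NYHA distribution and under a high-risk distribution
# (5% I, 20% II, 45% III, 30% IV) reflecting the severity mix of heart
# failure in China.

suppressPackageStartupMessages(library(hfcea))
dir.create("results", showWarnings = FALSE)

cfg <- default_config()
dists <- list(trial = NULL, high_risk = c(0.05, 0.20, 0.45, 0.30))

rows <- list()
for (d in names(dists)) {
  for (y in c(5, 10, 15, 20)) {
    p <- scenario_run(cfg, horizon_years = y, initial_nyha = dists[[d]])
    r <- icer(p$sacval, p$enalapril)
    rows[[length(rows) + 1]] <- data.frame(
      distribution = d, horizon_years = y,
      cost_sacval = round(r$cost[["sacval"]], 2),
      qaly_sacval = round(r$qaly[["sacval"]], 3),
      cost_enalapril = round(r$cost[["enalapril"]], 2),
      qaly_enalapril = round(r$qaly[["enalapril"]], 3),
      incr_cost = round(r$delta_cost, 2),
      incr_qaly = round(r$delta_qaly, 4),
      icer = round(r$icer, 2))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/scenarios.csv", row.names = FALSE)

cat("Scenario ICERs ($/QALY):\n\n")
print(tab[, c("distribution", "horizon_years", "incr_cost", "incr_qaly",
              "icer")], row.names = FALSE)
cat("\nThe ICER falls steadily as the horizon extends (the mortality\n")
cat("benefit compounds), and rises under the high-risk initial\n")
cat("distribution (severe patients lose more quality of life and die\n")
cat("sooner, trimming the incremental QALYs). Full table:\n")
cat("results/scenarios.csv\n")
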