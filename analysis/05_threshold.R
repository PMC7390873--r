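#!/usr/bin/env Rscript
# Two-way price sensitivity and threshold analysis: how expensive can
# sacubitril-valsartan be and remain cost-effective, as a function of the
# enalapril price and the willingness-to-pay threshold? The intervention
# price axis extends to $150/month (roughly five times the top of its
# printed range) to cover post-negotiation pricing.

suppressPackageStartupMessages(library(hfcea))
dir.create("results", showWarnings = FALSE)

cfg <- default_config()
wtps <- cfg$wtp_thresholds

# break-even price at each (WTP, comparator price) corner
rows <- list()
for (w in wtps) {
  for (ec in c(0.90, 10.65, 12.78)) {
    b <- breakeven_price(w, ec, cfg)
    rows[[length(rows) + 1]] <- data.frame(
      wtp = w, enalapril_cost = ec,
      breakeven_sacval_cost = round(b$breakeven_cost, 2),
      converged = b$converged)
  }
}
thr <- do.call(rbind, rows)
write.csv(thr, "results/threshold.csv", row.names = FALSE)

grid <- two_way_grid(seq(0, 150, by = 5), c(0.90, 5, 10.65, 12.78),
                     wtp = unname(wtps), config = cfg)
write.csv(grid, "results/two_way_grid.csv", row.names = FALSE)

cat("Break-even monthly cost of sacubitril-valsartan:\n\n")
print(thr, row.names = FALSE)
lo <- thr$breakeven_sacval_cost
cat(sprintf("\nAt the GDP-per-capita threshold ($%s) the price can rise to\n",
            format(wtps[1], big.mark = ",")))
cat(sprintf("$%.2f-$%.2f/month over the current enalapril price range, and\n",
            min(lo[thr$wtp == wtps[1]]), max(lo[thr$wtp == wtps[1]])))
cat(sprintf("to $%.2f-$%.2f/month at three times GDP per capita.\n",
            min(lo[thr$wtp == wtps[2]]), max(lo[thr$wtp == wtps[2]])))
cat("Grid labels: results/two_way_grid.csv\n")
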