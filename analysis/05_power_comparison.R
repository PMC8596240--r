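#!/usr/bin/env Rscript
# Step 5 — compare occurrence rates across radiation powers.
#
# Paired Wilcoxon signed-rank tests over the 24 microchannel electrodes
# between adjacent power conditions, mirroring the study's statistics
# (M +/- SD, P <= 0.05).

suppressMessages(library(axonmea))

res_dir <- "results/stats"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
lay <- read_layout("results/simulated/layout.json")
mc_ids <- microchannel_electrodes(lay)

load_tab <- function(nm) {
  df <- read.csv(file.path("results/responses", paste0(nm, "_probability.csv")))
  df[df$electrode_id %in% mc_ids, ]
}
conds <- c("power_0p20W", "power_0p33W", "power_0p50W")
tabs <- lapply(conds, load_tab)
names(tabs) <- conds

rows <- NULL
for (k in 1:2) {
  a <- tabs[[conds[k + 1]]]; b <- tabs[[conds[k]]]
  res <- wilcoxon_signed_rank(a, b)
  rows <- rbind(rows, data.frame(
    comparison = paste(conds[k], "vs", conds[k + 1]),
    mean_low = mean(b$prob), sd_low = sd(b$prob),
    mean_high = mean(a$prob), sd_high = sd(a$prob),
    W = res$statistic, n_effective = res$n_effective,
    p_value = res$p_value, significant = res$significant))
  message(sprintf("  %s: %.1f+/-%.1f%% vs %.1f+/-%.1f%%  (W = %g, p = %.3g%s)",
                  rows$comparison[k], 100 * rows$mean_low[k],
                  100 * rows$sd_low[k], 100 * rows$mean_high[k],
                  100 * rows$sd_high[k], res$statistic, res$p_value,
                  if (res$significant) ", significant" else ""))
}
write.csv(rows, file.path(res_dir, "power_comparison.csv"), row.names = FALSE)
message("Comparison table written to ", res_dir, "/power_comparison.csv.")
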