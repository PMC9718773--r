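#!/usr/bin/env Rscript
# Antibody-panel optimization: pick each antibody's optimal (lowest
# sufficient) concentration, compare the optimized panel's total antibody
# amount with the full panel at the recommended concentration and with a
# 137plex reference panel used entirely at 1x.

library(citetitrate)

ds <- read_count_bundle("results/data")
calls <- read.csv("results/detect_calls.csv")

plan <- build_optimized_panel(calls, ds$panel, ds$arms)
write.csv(plan$plan, "results/panel_plan.csv", row.names = FALSE)

summary <- list(
  class_counts = as.list(plan$class_counts),
  n_retained = plan$n_retained,
  relative_amount = plan$relative_amount,
  saving_vs_full_panel_pct = round(compare_panels(plan$relative_amount, 1)),
  saving_vs_137plex_pct = round(compare_panels(
    plan$relative_amount, relative_amount(c("1x" = 137, "drop" = 55), 192)))
)
writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE),
           "results/panel_summary.json")

print(plan)
cat(sprintf("savings: %d%% vs the full panel, %d%% vs a 137plex panel at 1x\n",
            summary$saving_vs_full_panel_pct, summary$saving_vs_137plex_pct))
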