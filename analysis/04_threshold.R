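#!/usr/bin/env Rscript
# Per-antibody, per-concentration thresholding and detectability calling:
# two-component mixture per antibody and arm, threshold at the 95th
# percentile of the negative population (or the 5th percentile of the
# positive population for ubiquitous antigens), with the pooled isotype
# controls as the background yardstick.

library(citetitrate)

ds <- read_count_bundle("results/data")
ann <- read.csv("results/gated_annotations.csv")
clr <- clr_normalize(ds$adt_counts)

calls <- threshold_antibodies(clr, ann, ds$panel, seed = 1)
write.csv(calls, "results/detect_calls.csv", row.names = FALSE)

det <- detectable_counts(calls, ds$panel)
cat("detectable target antibodies per arm (of",
    sum(!ds$panel$is_isotype_control), "):\n")
print(det)
truth <- read.csv("results/data/truth_detectability.csv", check.names = FALSE)
cat("generator truth:\n")
print(colSums(truth[, -1]))
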