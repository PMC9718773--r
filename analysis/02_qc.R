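#!/usr/bin/env Rscript
# Droplet quality control and hashtag demultiplexing: remove low-viability
# (mito > 10%), poorly stained (< 200 or > 100000 ADT), doublet (HTO
# max/mean > 3) and HTO-negative (max <= 20) droplets; assign the survivors
# to concentration arms by their hashtag.

library(citetitrate)

ds <- read_count_bundle("results/data")
res <- run_qc(ds)

dir.create("results", showWarnings = FALSE)
write.csv(res$annotations, "results/qc_annotations.csv", row.names = FALSE)
writeLines(jsonlite::toJSON(res$report, auto_unbox = TRUE, pretty = TRUE),
           "results/qc_report.json")

cat(sprintf("QC: %d droplets in, %d retained\n",
            res$report$n_input, res$report$n_remaining))
print(unlist(res$report$n_removed_per_reason))
print(table(res$annotations$arm_label, useNA = "ifany"))
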