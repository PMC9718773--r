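#!/usr/bin/env Rscript
# Concentration-comparison statistics: cell recovery per type relative to
# 1x, antigens detected per cell (with ANOVA/Tukey across arms), ADT depth
# and detecting-vs-non-detecting comparisons, dose-response fits, antigen
# sharing across types, and RNA marker genes.

library(citetitrate)

ds <- read_count_bundle("results/data")
ann <- read.csv("results/gated_annotations.csv")
calls <- read.csv("results/detect_calls.csv")
clr <- clr_normalize(ds$adt_counts)
binary <- binarize(clr, calls, ann)

## cell recovery relative to the recommended concentration
pci <- percent_correctly_identified(ann)
write.csv(pci, "results/percent_correct.csv", row.names = FALSE)

## antigens per cell, with one-way ANOVA across arms per major type
apc <- antigens_per_cell(binary, ann)
write.csv(apc$summary, "results/antigens_per_cell.csv", row.names = FALSE)
anova_rows <- lapply(setdiff(unique(apc$per_cell$major_type), "remaining"),
                     function(t) {
  sub <- apc$per_cell[apc$per_cell$major_type == t, ]
  a <- compare_groups_anova(sub$n_antigens, sub$arm_label)
  cbind(major_type = t, F = a$F, p = a$p)
})
write.csv(do.call(rbind, anova_rows), "results/antigens_anova.csv",
          row.names = FALSE)

## ADT depth metrics and Mann-Whitney tests
dm <- adt_depth_metrics(ds$adt_counts, ann, calls, ds$panel)
write.csv(dm$arm_depth, "results/adt_depth_by_arm.csv", row.names = FALSE)
write.csv(dm$per_antibody, "results/adt_per_antibody.csv", row.names = FALSE)
write.csv(dm$tests, "results/adt_depth_tests.csv", row.names = FALSE)

## dose-response curves per antibody and type
dr <- dose_response_table(clr, ann, ds$arms)
write.csv(dr, "results/dose_response.csv", row.names = FALSE)

## antigen sharing across the five major types at 1x
sh <- antigen_sharing(binary, ann, calls)
write.csv(sh$profiles, "results/antigen_sharing.csv", row.names = FALSE)

## top marker genes per type from the transcriptome
keep <- ann$qc_pass
mk <- marker_genes(lognorm_rna(ds$rna_counts[, keep]), ann[keep, ])
write.csv(mk$top, "results/marker_genes_top.csv", row.names = FALSE)

cat("cell recovery vs 1x (percent):\n")
print(reshape(pci[, c("major_type", "arm_label", "percent")],
              direction = "wide", idvar = "major_type",
              timevar = "arm_label"), digits = 4)
cat("\nADT depth ratios vs 1x:\n")
print(dm$arm_depth, digits = 3)
cat("\nantigen sharing categories:\n")
print(sh$counts)
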