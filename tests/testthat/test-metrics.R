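make_annotations <- function(types_by_arm) {
  do.call(rbind, lapply(names(types_by_arm), function(arm) {
    data.frame(barcode = paste0(arm, seq_along(types_by_arm[[arm]])),
               qc_pass = TRUE, qc_fail_reason = "none", arm_label = arm,
               major_type = types_by_arm[[arm]], stringsAsFactors = FALSE)
  }))
}

test_that("percent correctly identified is normalized to the reference arm", {
  ann <- make_annotations(list(
    `1x` = c(rep("B", 20), rep("CD4T", 80)),
    `0.2x` = c(rep("B", 10), rep("CD4T", 90))
  ))
  out <- percent_correctly_identified(ann)
  get <- function(t, a) out$percent[out$major_type == t & out$arm_label == a]
  expect_equal(get("B", "1x"), 100)
  expect_equal(get("CD4T", "1x"), 100)
  expect_equal(get("B", "0.2x"), 50)   # 0.10 vs 0.20
  expect_equal(get("CD4T", "0.2x"), 112.5)
  expect_equal(get("NK", "0.2x"), NA_real_)  # absent at the reference arm
  expect_equal(out$proportion[out$major_type == "NK" & out$arm_label == "0.2x"], 0)
})

test_that("antigens per cell counts positives and summarizes by type and arm", {
  ann <- make_annotations(list(`1x` = c("B", "B", "CD4T")))
  bin <- matrix(c(TRUE, FALSE, FALSE,
                  TRUE, TRUE, FALSE,
                  FALSE, FALSE, FALSE), nrow = 3, byrow = TRUE)
  out <- antigens_per_cell(bin, ann)
  expect_equal(out$per_cell$n_antigens, c(2L, 1L, 0L))
  s <- out$summary
  expect_equal(s$mean[s$major_type == "B"], 1.5)
  expect_equal(s$mean[s$major_type == "CD4T"], 0)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  oracle_F <- function(values, groups) {
    groups <- factor(groups)
    grand <- mean(values)
    ssb <- sum(tapply(values, groups, function(g) length(g) * (mean(g) - grand)^2))
    ssw <- sum(tapply(values, groups, function(g) sum((g - mean(g))^2)))
    k <- nlevels(groups); n <- length(values)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  vals <- c(1, 2, 3, 1, 2, 3, 11, 12, 13)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups_anova(vals, grp)
  expect_equal(res$F, oracle_F(vals, grp))
  expect_equal(res$F, 100)  # SSB = 200 (df 2), SSW = 6 (df 6)
  expect_lt(res$p, 0.001)

  # equal group means: F = 0, p = 1
  res0 <- compare_groups_anova(rep(c(1, 2, 3), 4), rep(1:4, each = 3))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # Tukey adjusted p-values are symmetric in group order
  res_rev <- compare_groups_anova(rev(vals), rev(grp))
  expect_equal(sort(res$tukey$p_adj), sort(res_rev$tukey$p_adj),
               tolerance = 1e-9)
  expect_error(compare_groups_anova(1:3, c("a", "a", "b")), "at least 2")
})

test_that("Mann-Whitney p-values match full enumeration for small samples", {
  enumeration_p <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    splits <- combn(length(pooled), n)
    u_of <- function(idx) {
      xs <- pooled[idx]; ys <- pooled[-idx]
      sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    }
    us <- apply(splits, 2L, u_of)
    u_obs <- u_of(seq_len(n))
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  expect_equal(stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(enumeration_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1))
    expect_equal(stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 enumeration_p(x, y), tolerance = 1e-12)
  }
  # identical groups: no shift
  expect_equal(stats::wilcox.test(c(1, 2, 3), c(1, 2, 3),
                                  exact = FALSE)$p.value, 1)
})

test_that("ADT depth metrics separate detecting and non-detecting antibodies", {
  pip <- default_pipeline()
  dm <- adt_depth_metrics(pip$dataset$adt_counts, pip$annotations,
                          pip$calls, pip$dataset$panel)
  ratios <- stats::setNames(dm$arm_depth$ratio_vs_reference,
                            dm$arm_depth$arm_label)
  expect_gt(ratios[["2x"]], 1)
  expect_lt(ratios[["0.04x"]], 0.25)
  expect_true(all(dm$tests$p < 0.001))
  # detecting antibodies have the larger mean counts
  expect_gt(median(dm$per_antibody$mean_count[dm$per_antibody$detectable]),
            median(dm$per_antibody$mean_count[!dm$per_antibody$detectable]))
})

test_that("dose-response fit recovers exact exponential means", {
  factors <- c(2, 1, 0.2, 0.04)
  means <- exp(1 + 0.5 * log10(factors))
  fit <- fit_dose_response(means, factors)
  expect_equal(fit$b0, 1, tolerance = 1e-6)
  expect_equal(fit$b1, 0.5, tolerance = 1e-6)
  expect_equal(fit$fitted, means, tolerance = 1e-6)

  flat <- fit_dose_response(rep(2.5, 4), factors)
  expect_equal(flat$b1, 0, tolerance = 1e-6)

  zero <- fit_dose_response(rep(0, 4), factors)
  expect_true(zero$flat)
  expect_equal(zero$b1, 0)

  inc <- fit_dose_response(c(4, 3, 1.5, 0.5), c(2, 1, 0.2, 0.04))
  expect_gt(inc$b1, 0)
  expect_error(fit_dose_response(c(1, 2), c(1, 2)), "3 arms")
})

test_that("dose-response slopes are positive where saturation has not set in", {
  pip <- default_pipeline()
  plan <- default_config()$panel_plan
  dr <- dose_response_table(pip$clr, pip$annotations, pip$dataset$arms)
  pi <- match(dr$antibody_id, plan$antibody_id)
  expressing <- mapply(function(i, t) t %in% plan$expressing_types[[i]],
                       pi, dr$major_type)
  unsaturated <- !is.na(plan$floor_factor[pi]) & plan$floor_factor[pi] >= 0.2
  expect_true(all(dr$b1[expressing & unsaturated] > 0))
})

test_that("antigen sharing categorizes constructed profiles by the 10% rule", {
  types <- c("B", "CD4T", "CD8T", "CM", "NK")
  ann <- make_annotations(list(`1x` = rep(types, each = 20)))
  bin <- rbind(
    everywhere = rep(TRUE, 100),
    b_only = rep(c(TRUE, FALSE), c(20, 80)),
    weak = c(TRUE, rep(FALSE, 99)),  # 5% of B cells: below the 10% rule
    two_types = rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), each = 20)
  )
  calls <- data.frame(antibody_id = rownames(bin), arm_label = "1x",
                      detectable = TRUE, mode = "negative95",
                      threshold = 0, separation = 5, positive_fraction = 0.5)
  out <- antigen_sharing(bin, ann, calls)
  cat_of <- stats::setNames(out$profiles$category, out$profiles$antibody_id)
  expect_equal(cat_of[["everywhere"]], "all_five")
  expect_equal(cat_of[["b_only"]], "exclusive_B")
  expect_equal(cat_of[["weak"]], "none")
  expect_equal(cat_of[["two_types"]], "multi")
})

test_that("sharing categories on synthetic data match the generator truth", {
  pip <- default_pipeline()
  plan <- default_config()$panel_plan
  sh <- antigen_sharing(pip$binary, pip$annotations, pip$calls)
  truth <- table(factor(plan$category[!is.na(plan$floor_factor)],
                        levels = c("all_five", "exclusive_B", "exclusive_CM",
                                   "exclusive_NK", "exclusive_other", "multi")))
  # ubiquitous antibodies are expressed in all five types too
  expect_equal(as.integer(sh$counts[names(truth)]), as.integer(truth))
})

test_that("marker genes rank an exclusive marker first with Bonferroni control", {
  set.seed(19)
  n_genes <- 20
  cells <- 120
  m <- matrix(rnorm(n_genes * cells, 1, 0.3), n_genes, cells,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)), NULL))
  ann <- make_annotations(list(`1x` = rep(c("CD4T", "B"), each = 60)))
  m["G01", 1:60] <- m["G01", 1:60] + 3   # CD4T-exclusive marker
  m["G02", ] <- 1                        # constant gene: never significant
  out <- marker_genes(m, ann, types = c("CD4T", "B"), top_k = 3)
  top_cd4 <- out$top[out$top$major_type == "CD4T", ]
  expect_equal(top_cd4$gene[1], "G01")
  expect_lt(top_cd4$p_adj[1], 0.05)
  expect_false(out$table$significant[out$table$gene == "G02" &
                                       out$table$major_type == "CD4T"])
  expect_equal(out$table$p_adj, pmin(1, out$table$p * n_genes))
})

test_that("synthetic marker genes are recovered for every major type", {
  pip <- default_pipeline()
  logn <- lognorm_rna(pip$dataset$rna_counts[,
    pip$annotations$qc_pass, drop = FALSE])
  ann <- pip$annotations[pip$annotations$qc_pass, ]
  out <- marker_genes(logn, ann)
  for (t in c("B", "CD4T", "CD8T", "CM", "NK")) {
    top10 <- out$top$gene[out$top$major_type == t]
    expect_gte(sum(startsWith(top10, paste0("MRK-", t))), 9)
  }
})
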