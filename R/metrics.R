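## Concentration-comparison statistics: cell-recovery percentages, antigens
## per cell, ADT depth, dose-response fits, antigen sharing, marker genes.

#' Percent correctly identified cells per type and arm
#'
#' For each major type and arm, the type's proportion among the arm's
#' QC-passing gated cells, normalized to its proportion at the reference
#' (recommended) concentration and expressed in percent — 100 means the
#' dilution recovers the type as well as 1x does.
#'
#' @param annotations Gated annotations (from [gate_all()]).
#' @param reference_arm Arm label of the recommended concentration
#'   (default `"1x"`).
#' @return Data.frame with `major_type`, `arm_label`, `proportion`,
#'   `percent` (percent is `NA` for types absent at the reference arm, and 0
#'   for types with no cells at an arm).
#' @export
percent_correctly_identified <- function(annotations, reference_arm = "1x") {
  cells <- annotations[annotations$qc_pass & !is.na(annotations$major_type), ]
  if (!reference_arm %in% cells$arm_label) {
    stop("reference arm ", reference_arm, " has no gated cells", call. = FALSE)
  }
  arms <- unique(cells$arm_label)
  types <- MAJOR_TYPES
  out <- expand.grid(major_type = types, arm_label = arms,
                     stringsAsFactors = FALSE)
  prop <- function(type, arm) {
    in_arm <- cells$arm_label == arm
    if (!any(in_arm)) return(0)
    mean(cells$major_type[in_arm] == type)
  }
  out$proportion <- mapply(prop, out$major_type, out$arm_label)
  ref <- out$proportion[out$arm_label == reference_arm]
  names(ref) <- out$major_type[out$arm_label == reference_arm]
  out$percent <- ifelse(ref[out$major_type] > 0,
                        100 * out$proportion / ref[out$major_type],
                        NA_real_)
  out
}

#' Antigens detected per cell
#'
#' Counts the thresholded-positive antibodies in every cell and summarizes
#' by (major type, arm) as mean and SD — the per-cell information content of
#' the panel at each concentration.
#'
#' @param binary_calls Logical antibodies x droplets matrix from
#'   [binarize()].
#' @param annotations Gated annotations aligned with the columns.
#' @return List with `per_cell` (barcode, arm_label, major_type, n_antigens
#'   for QC-passing gated cells) and `summary` (major_type, arm_label, n,
#'   mean, sd).
#' @export
antigens_per_cell <- function(binary_calls, annotations) {
  stopifnot(ncol(binary_calls) == nrow(annotations))
  counts <- Matrix::colSums(binary_calls)
  keep <- annotations$qc_pass & !is.na(annotations$major_type)
  per_cell <- data.frame(barcode = annotations$barcode[keep],
                         arm_label = annotations$arm_label[keep],
                         major_type = annotations$major_type[keep],
                         n_antigens = as.integer(counts[keep]),
                         stringsAsFactors = FALSE)
  agg <- stats::aggregate(n_antigens ~ major_type + arm_label, per_cell,
                          function(x) c(n = length(x), mean = mean(x),
                                        sd = stats::sd(x)))
  summary <- data.frame(major_type = agg$major_type,
                        arm_label = agg$arm_label,
                        n = agg$n_antigens[, "n"],
                        mean = agg$n_antigens[, "mean"],
                        sd = agg$n_antigens[, "sd"],
                        stringsAsFactors = FALSE)
  list(per_cell = per_cell, summary = summary)
}

#' One-way ANOVA with Tukey HSD across concentration arms
#'
#' Classical one-way ANOVA of per-cell antigen counts (or any per-cell
#' statistic) across groups, with Tukey's honestly-significant-difference
#' pairwise comparisons.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of the same length, at least two
#'   levels with at least two observations each.
#' @return List with `F` (statistic), `df`, `p`, and `tukey` (data.frame
#'   comparison, diff, lwr, upr, p_adj).
#' @export
compare_groups_anova <- function(values, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("ANOVA needs at least 2 groups with at least 2 observations each",
         call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = an[["F value"]][1L],
       df = an[["Df"]],
       p = an[["Pr(>F)"]][1L],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' ADT sequencing-depth metrics
#'
#' Raw (pre-threshold) ADT depth per arm and per antibody: mean total ADT
#' per QC-passing cell and its ratio versus the reference arm; per-antibody
#' mean and SD of counts per cell at the reference arm; and two-sided
#' Mann-Whitney U tests comparing those statistics between target-detecting
#' and non-detecting antibodies (isotype controls excluded).
#'
#' @param adt_counts Raw antibodies x droplets count matrix.
#' @param annotations Gated annotations.
#' @param calls A `detect_calls` table (detectability at the reference arm
#'   defines the two antibody groups).
#' @param panel A [panel_definition()] (isotype controls are excluded from
#'   the group comparison).
#' @param reference_arm Default `"1x"`.
#' @return List with `arm_depth`, `per_antibody` and `tests`.
#' @export
adt_depth_metrics <- function(adt_counts, annotations, calls, panel,
                              reference_arm = "1x") {
  keep <- annotations$qc_pass & !is.na(annotations$arm_label)
  totals <- Matrix::colSums(adt_counts)
  arms <- unique(annotations$arm_label[keep])
  mean_total <- vapply(arms, function(a) {
    mean(totals[keep & annotations$arm_label == a])
  }, 0)
  ref_total <- mean_total[arms == reference_arm]
  arm_depth <- data.frame(arm_label = arms, mean_total_adt = mean_total,
                          ratio_vs_reference = mean_total / ref_total,
                          stringsAsFactors = FALSE)

  ref_cells <- which(keep & annotations$arm_label == reference_arm)
  m <- as.matrix(adt_counts[, ref_cells, drop = FALSE])
  ca <- calls[calls$arm_label == reference_arm, ]
  det <- ca$detectable[match(rownames(adt_counts), ca$antibody_id)]
  per_antibody <- data.frame(antibody_id = rownames(adt_counts),
                             mean_count = rowMeans(m),
                             sd_count = apply(m, 1L, stats::sd),
                             detectable = det,
                             stringsAsFactors = FALSE)

  iso <- per_antibody$antibody_id %in%
    panel$antibody_id[panel$is_isotype_control]
  grp_det <- per_antibody[!iso & per_antibody$detectable, ]
  grp_non <- per_antibody[!iso & !per_antibody$detectable, ]
  run_test <- function(x, y, label) {
    if (length(x) == 0L || length(y) == 0L) {
      warning("Mann-Whitney test skipped for ", label, ": empty group")
      return(data.frame(statistic = label, W = NA_real_, p = NA_real_))
    }
    wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
    data.frame(statistic = label, W = unname(wt$statistic), p = wt$p.value)
  }
  tests <- rbind(
    run_test(grp_det$mean_count, grp_non$mean_count, "mean_count"),
    run_test(grp_det$sd_count, grp_non$sd_count, "sd_count")
  )
  list(arm_depth = arm_depth, per_antibody = per_antibody, tests = tests)
}

#' Fit a log-link dose-response curve to per-arm mean expression
#'
#' Fits `mean(c) = exp(b0 + b1 * log10(c))` to the per-arm average CLR
#' values by least squares (log link, identity variance). Average CLR values
#' can be negative, so means are clipped at zero before fitting; this is a
#' display-grade curve characterization, not an inference claim. All-zero
#' (clipped) means give a flagged flat fit with `b1 = 0`.
#'
#' @param means Per-arm mean expression values (one per arm).
#' @param factors Concentration factors of the arms (same length, >= 3
#'   defined values).
#' @return List with `b0`, `b1`, `fitted` (per arm), `flat` (logical).
#' @export
fit_dose_response <- function(means, factors) {
  ok <- is.finite(means) & is.finite(factors)
  if (sum(ok) < 3L) {
    stop("dose-response fit needs at least 3 arms with defined means",
         call. = FALSE)
  }
  x <- log10(factors[ok])
  m <- pmax(means[ok], 0)
  if (all(m == 0)) {
    return(list(b0 = NA_real_, b1 = 0, fitted = rep(0, length(factors)),
                flat = TRUE))
  }
  pos <- m > 0
  start <- if (sum(pos) >= 2L) {
    stats::coef(stats::lm(log(m[pos]) ~ x[pos]))
  } else {
    c(log(max(m)), 0)
  }
  obj <- function(b) sum((m - exp(b[1] + b[2] * x))^2)
  opt <- stats::optim(unname(start), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  b <- opt$par
  list(b0 = b[1], b1 = b[2],
       fitted = exp(b[1] + b[2] * log10(factors)), flat = FALSE)
}

#' Dose-response fits for every antibody and major type
#'
#' @param clr_adt CLR-normalized ADT matrix.
#' @param annotations Gated annotations.
#' @param arms A [concentration_arms()] table.
#' @param types Major types to fit (default the five gated populations).
#' @return Data.frame: `antibody_id`, `major_type`, `b0`, `b1`, `flat`, and
#'   one fitted-mean column per arm.
#' @export
dose_response_table <- function(clr_adt, annotations, arms,
                                types = setdiff(MAJOR_TYPES, "remaining")) {
  res <- list()
  for (ab in rownames(clr_adt)) {
    for (t in types) {
      means <- vapply(arms$label, function(a) {
        cells <- annotations$qc_pass & !is.na(annotations$major_type) &
          annotations$major_type == t & annotations$arm_label == a
        if (!any(cells)) return(NA_real_)
        mean(clr_adt[ab, cells])
      }, 0)
      fit <- fit_dose_response(means, arms$factor)
      row <- data.frame(antibody_id = ab, major_type = t,
                        b0 = fit$b0, b1 = fit$b1, flat = fit$flat,
                        stringsAsFactors = FALSE)
      fitted <- as.data.frame(as.list(stats::setNames(fit$fitted,
                                                      paste0("fit_", arms$label))))
      res[[length(res) + 1L]] <- cbind(row, fitted)
    }
  }
  do.call(rbind, res)
}

#' Antigen sharing across major cell types
#'
#' For every antibody detectable at the chosen arm, determines the set of
#' major types "expressing" its antigen (at least `positivity_fraction` of
#' the type's cells thresholded positive) and tallies the sharing
#' categories: detected in all five types, exclusively in B / CM / NK,
#' exclusively in one other type, or in several (multi).
#'
#' @param binary_calls Logical antibodies x droplets matrix.
#' @param annotations Gated annotations.
#' @param calls A `detect_calls` table.
#' @param arm_label Arm at which sharing is assessed (default `"1x"`).
#' @param positivity_fraction Minimum positive fraction per type
#'   (default 0.10).
#' @return List with `profiles` (antibody_id, expressing_types, category)
#'   and `counts` (category tally).
#' @export
antigen_sharing <- function(binary_calls, annotations, calls,
                            arm_label = "1x", positivity_fraction = 0.10) {
  types <- setdiff(MAJOR_TYPES, "remaining")
  det_ids <- calls$antibody_id[calls$arm_label == arm_label & calls$detectable]
  cells_of <- lapply(types, function(t) {
    which(annotations$qc_pass & !is.na(annotations$major_type) &
            annotations$major_type == t & annotations$arm_label == arm_label)
  })
  names(cells_of) <- types
  profiles <- lapply(det_ids, function(ab) {
    frac <- vapply(types, function(t) {
      idx <- cells_of[[t]]
      if (length(idx) == 0L) return(0)
      mean(binary_calls[ab, idx])
    }, 0)
    expressed <- types[frac >= positivity_fraction]
    category <- if (length(expressed) == 5L) "all_five"
      else if (identical(expressed, "B")) "exclusive_B"
      else if (identical(expressed, "CM")) "exclusive_CM"
      else if (identical(expressed, "NK")) "exclusive_NK"
      else if (length(expressed) == 1L) "exclusive_other"
      else if (length(expressed) == 0L) "none"
      else "multi"
    data.frame(antibody_id = ab,
               expressing_types = paste(expressed, collapse = ","),
               category = category, stringsAsFactors = FALSE)
  })
  profiles <- do.call(rbind, profiles)
  counts <- table(factor(profiles$category,
                         levels = c("all_five", "exclusive_B", "exclusive_CM",
                                    "exclusive_NK", "exclusive_other",
                                    "multi", "none")))
  list(profiles = profiles, counts = counts)
}

#' One-vs-rest marker genes per major type
#'
#' Wilcoxon rank-sum test of each gene in each type against all other gated
#' cells, Bonferroni-corrected by the number of genes tested; significant at
#' adjusted p < 0.05 with no fold-change floor. Genes are ranked by adjusted
#' p, then by effect size (difference of mean log-normalized expression,
#' expressed in log2 units).
#'
#' @param lognorm Log-normalized genes x droplets matrix.
#' @param annotations Gated annotations.
#' @param types Types to profile (default the five major populations).
#' @param top_k Markers exported per type in `top` (default 10).
#' @param min_cells Minimum cells per type (smaller types are skipped with a
#'   warning).
#' @return List with `table` (all tested genes, ranked within type) and
#'   `top` (top_k rows per type).
#' @export
marker_genes <- function(lognorm, annotations,
                         types = setdiff(MAJOR_TYPES, "remaining"),
                         top_k = 10L, min_cells = 3L) {
  keep <- annotations$qc_pass & !is.na(annotations$major_type) &
    annotations$major_type %in% types
  m <- lognorm[, keep, drop = FALSE]
  lab <- annotations$major_type[keep]
  n_genes <- nrow(m)
  res <- list()
  for (t in types) {
    in_t <- lab == t
    if (sum(in_t) < min_cells) {
      warning("type ", t, " has fewer than ", min_cells, " cells; skipped")
      next
    }
    p <- vapply(seq_len(n_genes), function(g) {
      x <- m[g, in_t]; y <- m[g, !in_t]
      if (stats::sd(c(x, y)) == 0) return(1)
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    }, 0)
    lfc <- (rowMeans(m[, in_t, drop = FALSE]) -
              rowMeans(m[, !in_t, drop = FALSE])) / log(2)
    tab <- data.frame(major_type = t, gene = rownames(m),
                      p = p, p_adj = pmin(1, p * n_genes),
                      avg_log2FC = lfc,
                      significant = pmin(1, p * n_genes) < 0.05,
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$p_adj, -tab$avg_log2FC), ]
    tab$rank <- seq_len(nrow(tab))
    res[[t]] <- tab
  }
  table <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  top <- do.call(rbind, lapply(res, function(tab) utils::head(tab, top_k)))
  rownames(top) <- NULL
  list(table = table, top = top)
}
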