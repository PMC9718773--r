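#' Derive per-arm gating thresholds for the major-type markers
#'
#' For each concentration arm and each of the seven gating markers (CD3,
#' CD19, CD4, CD8, CD14, CD16, CD56), fits a two-component Gaussian mixture
#' to the arm's CLR values over QC-passing singlets and places the threshold
#' at the minimum-misclassification boundary between the two components (the
#' point between the component means where their weighted densities cross).
#' Unlike a rank-based percentile of the negative population — which by
#' construction leaves a fixed share of negative cells above it and thereby
#' inflates rare gated populations — the density crossing has near-zero
#' error in both directions when the populations are well separated. If
#' either component attracts fewer than `min_component` cells the threshold
#' falls back to the midpoint between the component means. Thresholding is
#' done separately for each arm because lower antibody concentrations shift
#' the positive populations.
#'
#' @param clr_adt CLR-normalized ADT matrix (antibodies x droplets, rownames
#'   = antibody ids, columns aligned with `annotations`).
#' @param annotations QC annotation data.frame from [run_qc()].
#' @param panel A [panel_definition()]; markers are looked up by
#'   `target_name`.
#' @param markers Character marker names (default the seven gating markers).
#' @param seed Seed forwarded to the mixture fits.
#' @param min_component Minimum negative-component size before the midpoint
#'   fallback (default 20).
#' @return A data.frame (`gate_thresholds`) with columns `arm_label`,
#'   `marker`, `threshold`.
#' @export
derive_gate_thresholds <- function(clr_adt, annotations, panel,
                                   markers = GATING_MARKERS, seed = 1L,
                                   min_component = 20L) {
  idx <- match(markers, panel$target_name)
  if (anyNA(idx)) {
    stop("gating marker(s) absent from panel: ",
         paste(markers[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  marker_ids <- panel$antibody_id[idx]
  arm_labels <- unique(stats::na.omit(annotations$arm_label))
  out <- expand.grid(arm_label = arm_labels, marker = markers,
                     stringsAsFactors = FALSE)
  out$threshold <- NA_real_
  for (r in seq_len(nrow(out))) {
    cells <- which(annotations$qc_pass &
                     !is.na(annotations$arm_label) &
                     annotations$arm_label == out$arm_label[r])
    vals <- clr_adt[marker_ids[match(out$marker[r], markers)], cells]
    fit <- fit_population_model(vals, seed = seed)
    out$threshold[r] <- mixture_boundary(fit, min_component)
  }
  class(out) <- c("gate_thresholds", "data.frame")
  out
}

#' Assign a major PBMC cell type from marker positivity
#'
#' Hierarchical biaxial gating scheme: CD3+ cells split into CD4 T
#' (CD4+CD8-) and CD8 T (CD4-CD8+); CD3- cells into B (CD19+), classical
#' monocytes (CD19-CD14+CD16-) and NK (CD19-CD14-CD56+). Double-positive or
#' otherwise contradictory combinations map to "remaining", the conservative
#' reading (such cells are excluded from downstream analyses).
#'
#' @param marker_positivity Named logical vector over the seven gating
#'   markers.
#' @return One of `"B"`, `"CD4T"`, `"CD8T"`, `"CM"`, `"NK"`, `"remaining"`.
#' @examples
#' assign_major_type(c(CD3 = TRUE, CD19 = FALSE, CD4 = TRUE, CD8 = FALSE,
#'                     CD14 = FALSE, CD16 = FALSE, CD56 = FALSE))
#' @export
assign_major_type <- function(marker_positivity) {
  missing <- setdiff(GATING_MARKERS, names(marker_positivity))
  if (length(missing) > 0L) {
    stop("marker positivity is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- marker_positivity
  if (p[["CD3"]]) {
    if (p[["CD4"]] && !p[["CD8"]]) return("CD4T")
    if (!p[["CD4"]] && p[["CD8"]]) return("CD8T")
    return("remaining")
  }
  if (p[["CD19"]]) return("B")
  if (p[["CD14"]] && !p[["CD16"]]) return("CM")
  if (!p[["CD14"]] && p[["CD56"]]) return("NK")
  "remaining"
}

#' Gate all QC-passing singlets into major cell types
#'
#' Applies the per-arm marker thresholds and the hierarchical gating scheme
#' of [assign_major_type()] to every QC-passing singlet; each such cell
#' receives exactly one label from B/CD4T/CD8T/CM/NK/remaining.
#'
#' @inheritParams derive_gate_thresholds
#' @param thresholds A `gate_thresholds` table from
#'   [derive_gate_thresholds()].
#' @return The `annotations` data.frame with `major_type` filled in for
#'   QC-passing cells.
#' @export
gate_all <- function(clr_adt, annotations, thresholds, panel) {
  if (ncol(clr_adt) != nrow(annotations)) {
    stop("clr_adt has ", ncol(clr_adt), " columns but annotations has ",
         nrow(annotations), " rows", call. = FALSE)
  }
  marker_ids <- panel$antibody_id[match(GATING_MARKERS, panel$target_name)]
  annotations$major_type <- NA_character_
  for (arm in unique(stats::na.omit(annotations$arm_label))) {
    cells <- which(annotations$qc_pass & !is.na(annotations$arm_label) &
                     annotations$arm_label == arm)
    if (length(cells) == 0L) next
    thr_arm <- thresholds[thresholds$arm_label == arm, ]
    thr <- stats::setNames(thr_arm$threshold, thr_arm$marker)[GATING_MARKERS]
    if (anyNA(thr)) {
      stop("thresholds do not cover all gating markers for arm ", arm,
           call. = FALSE)
    }
    pos <- clr_adt[marker_ids, cells, drop = FALSE] > thr  # markers x cells
    rownames(pos) <- GATING_MARKERS
    cd3 <- pos["CD3", ]; cd4 <- pos["CD4", ]; cd8 <- pos["CD8", ]
    cd19 <- pos["CD19", ]; cd14 <- pos["CD14", ]; cd16 <- pos["CD16", ]
    cd56 <- pos["CD56", ]
    lab <- ifelse(cd3,
                  ifelse(cd4 & !cd8, "CD4T",
                         ifelse(!cd4 & cd8, "CD8T", "remaining")),
                  ifelse(cd19, "B",
                         ifelse(cd14 & !cd16, "CM",
                                ifelse(!cd14 & cd56, "NK", "remaining"))))
    annotations$major_type[cells] <- lab
  }
  annotations
}
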