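#' Quality-control parameters
#'
#' Droplet-level filters applied before any downstream analysis, with the
#' defaults of the titration protocol: low viability = mitochondrial UMI
#' fraction strictly above `mito_max_fraction`; low staining quality = total
#' ADT strictly below `adt_min_per_cell` or strictly above
#' `adt_max_per_cell`; HTO doublet = max hashtag count / mean hashtag count
#' strictly above `hto_doublet_ratio`; HTO negative = max hashtag count at or
#' below `hto_negative_max`. Boundary values are kept (the rules are strict
#' inequalities).
#'
#' @param mito_max_fraction Maximum tolerated mitochondrial fraction
#'   (default 0.10).
#' @param adt_min_per_cell Minimum total ADT per droplet (default 200).
#' @param adt_max_per_cell Maximum total ADT per droplet (default 100000).
#' @param hto_doublet_ratio Max/mean hashtag ratio above which a droplet is a
#'   doublet (default 3).
#' @param hto_negative_max Hashtag count at or below which a droplet is
#'   HTO-negative (default 20).
#' @return A `qc_params` list.
#' @export
qc_params <- function(mito_max_fraction = 0.10,
                      adt_min_per_cell = 200,
                      adt_max_per_cell = 100000,
                      hto_doublet_ratio = 3,
                      hto_negative_max = 20) {
  stopifnot(mito_max_fraction > 0, mito_max_fraction < 1,
            adt_min_per_cell < adt_max_per_cell,
            hto_doublet_ratio > 1)
  structure(list(mito_max_fraction = mito_max_fraction,
                 adt_min_per_cell = adt_min_per_cell,
                 adt_max_per_cell = adt_max_per_cell,
                 hto_doublet_ratio = hto_doublet_ratio,
                 hto_negative_max = hto_negative_max),
            class = "qc_params")
}

#' Viability filter from mitochondrial content
#'
#' A droplet is kept iff its mitochondrial UMI fraction is at or below
#' `mito_max_fraction` (the removal rule is strictly greater-than). Droplets
#' with zero total RNA are removed.
#'
#' @param rna_counts Genes x droplets count matrix with gene rownames.
#' @param mito_gene_ids Non-empty subset of the gene rownames.
#' @param params A [qc_params()].
#' @return Logical vector, TRUE = droplet kept.
#' @export
viability_mask <- function(rna_counts, mito_gene_ids, params = qc_params()) {
  if (length(mito_gene_ids) == 0L) {
    stop("mito_gene_ids is empty: the viability filter needs at least one ",
         "mitochondrial gene", call. = FALSE)
  }
  if (!all(mito_gene_ids %in% rownames(rna_counts))) {
    stop("mito_gene_ids must be a subset of the RNA gene registry", call. = FALSE)
  }
  total <- Matrix::colSums(rna_counts)
  mito <- Matrix::colSums(rna_counts[mito_gene_ids, , drop = FALSE])
  frac <- ifelse(total > 0, mito / total, 1)
  total > 0 & frac <= params$mito_max_fraction
}

#' Staining-quality filter from total ADT per droplet
#'
#' Kept iff `adt_min_per_cell <= total ADT <= adt_max_per_cell` (boundaries
#' kept; the removal rules are strict `<` / `>`).
#'
#' @inheritParams viability_mask
#' @param adt_counts Antibodies x droplets count matrix.
#' @return Logical vector, TRUE = droplet kept.
#' @export
staining_quality_mask <- function(adt_counts, params = qc_params()) {
  total <- Matrix::colSums(adt_counts)
  total >= params$adt_min_per_cell & total <= params$adt_max_per_cell
}

#' Classify one droplet's hashtag profile
#'
#' Negative if the maximum hashtag count is at or below `hto_negative_max`
#' (an all-zero profile is negative, not an error); otherwise doublet if
#' max/mean is strictly above `hto_doublet_ratio`; otherwise a singlet
#' assigned to the arg-max hashtag (ties broken by lowest hashtag index, so
#' the call is deterministic).
#'
#' @param hto_vector Named or unnamed non-negative counts, one per hashtag
#'   (at least 2 hashtags).
#' @param params A [qc_params()].
#' @return A list with `verdict` ("negative", "singlet" or "doublet"),
#'   `hashtag_id` (index or name, singlets only, otherwise `NA`) and `ratio`
#'   (max/mean).
#' @examples
#' classify_hto(c(400, 50, 30, 20))  # doublet: ratio 3.2
#' classify_hto(c(90, 10, 10, 10))   # singlet: ratio exactly 3 is not > 3
#' @export
classify_hto <- function(hto_vector, params = qc_params()) {
  if (length(hto_vector) < 2L) {
    stop("classify_hto needs at least two hashtags", call. = FALSE)
  }
  mx <- max(hto_vector)
  ratio <- if (mx == 0) 0 else mx / mean(hto_vector)
  if (mx <= params$hto_negative_max) {
    return(list(verdict = "negative", hashtag_id = NA, ratio = ratio))
  }
  if (ratio > params$hto_doublet_ratio) {
    return(list(verdict = "doublet", hashtag_id = NA, ratio = ratio))
  }
  idx <- which.max(hto_vector)  # which.max takes the first maximum: lowest index wins ties
  id <- if (!is.null(names(hto_vector))) names(hto_vector)[idx] else idx
  list(verdict = "singlet", hashtag_id = id, ratio = ratio)
}

# Vectorized hashtag classification over a hashtags x droplets matrix.
classify_hto_matrix <- function(hto_counts, params = qc_params()) {
  m <- as.matrix(hto_counts)
  mx <- apply(m, 2L, max)
  mean_ <- colMeans(m)
  ratio <- ifelse(mx == 0, 0, mx / mean_)
  verdict <- ifelse(mx <= params$hto_negative_max, "negative",
                    ifelse(ratio > params$hto_doublet_ratio, "doublet", "singlet"))
  top <- rownames(m)[apply(m, 2L, which.max)]
  data.frame(verdict = verdict,
             hashtag_id = ifelse(verdict == "singlet", top, NA_character_),
             ratio = ratio, stringsAsFactors = FALSE)
}

#' Run droplet quality control and hashtag demultiplexing
#'
#' Applies the viability, staining-quality and hashtag filters (plus an
#' optional external doublet flag standing in for a transcriptome-based
#' doublet caller) and demultiplexes singlets into concentration arms. The
#' four masks are computed independently; a droplet passes iff it passes all
#' of them and is an HTO singlet. Removal attribution follows the fixed order
#' viability, staining_quality, doublet, hto_negative, and a droplet failing
#' several filters is counted once under the first.
#'
#' @param dataset A [titration_dataset()].
#' @param params A [qc_params()].
#' @param external_doublet_flags Optional logical vector (TRUE = doublet)
#'   aligned to the droplets, e.g. from a transcriptome doublet caller.
#' @return A list with `annotations` (data.frame: barcode, qc_pass,
#'   qc_fail_reason, arm_label, major_type placeholder) and `report` (list:
#'   n_input, n_removed_per_reason, n_remaining).
#' @export
run_qc <- function(dataset, params = qc_params(),
                   external_doublet_flags = NULL) {
  stopifnot(inherits(dataset, "titration_dataset"))
  n <- n_droplets(dataset)
  if (!is.null(external_doublet_flags) && length(external_doublet_flags) != n) {
    stop("external_doublet_flags has length ", length(external_doublet_flags),
         " but the dataset has ", n, " droplets", call. = FALSE)
  }
  viable <- viability_mask(dataset$rna_counts, dataset$mito_gene_ids, params)
  stained <- staining_quality_mask(dataset$adt_counts, params)
  hto <- classify_hto_matrix(dataset$hto_counts, params)
  is_doublet <- hto$verdict == "doublet"
  if (!is.null(external_doublet_flags)) {
    is_doublet <- is_doublet | external_doublet_flags
  }
  is_negative <- hto$verdict == "negative"

  reason <- rep("none", n)
  reason[!viable] <- "viability"
  reason[reason == "none" & !stained] <- "staining_quality"
  reason[reason == "none" & is_doublet] <- "doublet"
  reason[reason == "none" & is_negative] <- "hto_negative"
  qc_pass <- reason == "none"

  arm_label <- rep(NA_character_, n)
  singlet <- hto$verdict == "singlet" & !is_doublet
  arm_label[singlet] <- dataset$arms$label[
    match(hto$hashtag_id[singlet], dataset$arms$hashtag_id)]

  annotations <- data.frame(
    barcode = dataset$barcodes,
    qc_pass = qc_pass,
    qc_fail_reason = reason,
    arm_label = arm_label,
    major_type = NA_character_,
    stringsAsFactors = FALSE
  )
  removed <- table(factor(reason[!qc_pass],
                          levels = c("viability", "staining_quality",
                                     "doublet", "hto_negative")))
  report <- list(n_input = n,
                 n_removed_per_reason = as.list(as.integer(removed) |>
                                                  stats::setNames(names(removed))),
                 n_remaining = sum(qc_pass))
  stopifnot(report$n_input - sum(unlist(report$n_removed_per_reason)) ==
              report$n_remaining)
  list(annotations = annotations, report = report)
}
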