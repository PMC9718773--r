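#' Construct a titration dataset
#'
#' Bundles the three aligned feature-class count matrices of a hashed
#' CITE-Seq titration run: gene expression (RNA), antibody capture (ADT) and
#' multiplexing capture (HTO). All matrices are features x droplets and share
#' the droplet axis.
#'
#' @param rna_counts Non-negative integer matrix, genes x droplets.
#' @param adt_counts Non-negative integer matrix, antibodies x droplets; row
#'   count must equal the panel size.
#' @param hto_counts Non-negative integer matrix, hashtags x droplets; row
#'   count must equal the number of arms.
#' @param gene_ids Character vector of gene identifiers (rownames of
#'   `rna_counts`).
#' @param mito_gene_ids Subset of `gene_ids` flagged as mitochondrial.
#' @param barcodes Character droplet barcodes (column names, input order is
#'   canonical).
#' @param panel A [panel_definition()].
#' @param arms A [concentration_arms()] table.
#' @return A `titration_dataset` object (list with the validated components;
#'   matrices stored sparse).
#' @export
titration_dataset <- function(rna_counts, adt_counts, hto_counts,
                              gene_ids, mito_gene_ids, barcodes,
                              panel, arms) {
  stopifnot(inherits(panel, "panel_definition"),
            inherits(arms, "concentration_arms"))
  rna <- as_count_matrix(rna_counts, "rna_counts")
  adt <- as_count_matrix(adt_counts, "adt_counts")
  hto <- as_count_matrix(hto_counts, "hto_counts")
  n <- length(barcodes)
  if (ncol(rna) != n || ncol(adt) != n || ncol(hto) != n) {
    stop("matrix dimension mismatch: all matrices must share the droplet axis (",
         n, " barcodes)", call. = FALSE)
  }
  if (nrow(rna) != length(gene_ids)) {
    stop("rna_counts has ", nrow(rna), " rows but ", length(gene_ids),
         " gene_ids", call. = FALSE)
  }
  if (nrow(adt) != nrow(panel)) {
    stop("adt_counts has ", nrow(adt), " rows but the panel has ",
         nrow(panel), " antibodies", call. = FALSE)
  }
  if (nrow(hto) != nrow(arms)) {
    stop("hto_counts has ", nrow(hto), " rows but there are ",
         nrow(arms), " arms", call. = FALSE)
  }
  if (!all(mito_gene_ids %in% gene_ids)) {
    stop("mito_gene_ids must be a subset of gene_ids", call. = FALSE)
  }
  dimnames(rna) <- list(gene_ids, barcodes)
  dimnames(adt) <- list(panel$antibody_id, barcodes)
  dimnames(hto) <- list(arms$hashtag_id, barcodes)
  structure(
    list(rna_counts = rna, adt_counts = adt, hto_counts = hto,
         gene_ids = as.character(gene_ids),
         mito_gene_ids = as.character(mito_gene_ids),
         barcodes = as.character(barcodes),
         panel = panel, arms = arms),
    class = "titration_dataset"
  )
}

# Coerce to a sparse dgCMatrix of non-negative integers; non-integer or
# negative entries are hard errors (no silent rounding).
as_count_matrix <- function(m, what) {
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  x <- m@x
  if (any(x < 0)) stop(what, " contains negative counts", call. = FALSE)
  if (any(x != round(x))) {
    stop(what, " contains non-integer values; counts must be integers",
         call. = FALSE)
  }
  m
}

#' @export
print.titration_dataset <- function(x, ...) {
  cat("CITE-Seq titration dataset\n")
  cat(sprintf("  %d droplets | %d genes (%d mitochondrial) | %d ADT features | %d hashtags\n",
              length(x$barcodes), length(x$gene_ids), length(x$mito_gene_ids),
              nrow(x$adt_counts), nrow(x$hto_counts)))
  cat(sprintf("  arms: %s\n", paste(x$arms$label, collapse = ", ")))
  invisible(x)
}

#' Number of droplets in a titration dataset
#' @param dataset A `titration_dataset`.
#' @return Integer droplet count.
#' @export
n_droplets <- function(dataset) {
  stopifnot(inherits(dataset, "titration_dataset"))
  length(dataset$barcodes)
}
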