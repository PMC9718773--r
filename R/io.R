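## Count-bundle reader/writer: the 10x-style triplet layout
## (matrix.mtx + features.tsv + barcodes.tsv) with all three feature classes
## stacked in one matrix and distinguished by the feature_type column.
## Two sidecar tables (panel.tsv, arms.tsv) carry panel metadata that the
## bare 10x layout has no place for; they are optional on read.

FEATURE_TYPE_GEX <- "Gene Expression"
FEATURE_TYPE_ADT <- "Antibody Capture"
FEATURE_TYPE_HTO <- "Multiplexing Capture"

#' Write a titration dataset as a 10x-style count bundle
#'
#' Writes `matrix.mtx` (Matrix Market, all feature classes stacked
#' RNA/ADT/HTO), `features.tsv` (id, name, feature_type), `barcodes.tsv`,
#' plus `panel.tsv` and `arms.tsv` sidecars so that a read round-trips to an
#' identical dataset. Integer counts are preserved exactly.
#'
#' @param dataset A [titration_dataset()].
#' @param directory_path Output directory (created if missing).
#' @return Invisibly, `directory_path`.
#' @export
write_count_bundle <- function(dataset, directory_path) {
  stopifnot(inherits(dataset, "titration_dataset"))
  ok <- dir.exists(directory_path) || dir.create(directory_path, recursive = TRUE)
  if (!ok) stop("cannot create directory: ", directory_path, call. = FALSE)
  panel <- dataset$panel
  features <- data.frame(
    id = c(dataset$gene_ids, panel$antibody_id, dataset$arms$hashtag_id),
    name = c(dataset$gene_ids, panel$target_name, dataset$arms$hashtag_id),
    feature_type = c(rep(FEATURE_TYPE_GEX, length(dataset$gene_ids)),
                     rep(FEATURE_TYPE_ADT, nrow(panel)),
                     rep(FEATURE_TYPE_HTO, nrow(dataset$arms))),
    stringsAsFactors = FALSE
  )
  stacked <- rbind(dataset$rna_counts, dataset$adt_counts, dataset$hto_counts)
  Matrix::writeMM(stacked, file.path(directory_path, "matrix.mtx"))
  utils::write.table(features, file.path(directory_path, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(dataset$barcodes, file.path(directory_path, "barcodes.tsv"))
  write_panel(panel, file.path(directory_path, "panel.tsv"))
  utils::write.table(as.data.frame(dataset$arms),
                     file.path(directory_path, "arms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory_path)
}

#' Read a 10x-style count bundle into a titration dataset
#'
#' Expects the triplet layout written by [write_count_bundle()] (or any 10x
#' triplet whose features table carries the three feature classes). Feature
#' rows are split by `feature_type` into the RNA, ADT and HTO matrices.
#'
#' @param directory_path Directory containing `matrix.mtx`, `features.tsv`
#'   and `barcodes.tsv` (optionally gzipped).
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @param panel Optional [panel_definition()]; if absent, a `panel.tsv`
#'   sidecar is used, and failing that the panel is built from the
#'   antibody-capture features (isotype controls guessed from names
#'   containing "isotype", case-insensitive).
#' @param arms Optional [concentration_arms()]; if absent, an `arms.tsv`
#'   sidecar is required.
#' @return A [titration_dataset()].
#' @export
read_count_bundle <- function(directory_path, mito_prefix = "MT-",
                              panel = NULL, arms = NULL) {
  path_of <- function(base) {
    for (cand in c(base, paste0(base, ".gz"))) {
      p <- file.path(directory_path, cand)
      if (file.exists(p)) return(p)
    }
    stop("missing file in count bundle: ", file.path(directory_path, base),
         call. = FALSE)
  }
  mat <- methods::as(methods::as(Matrix::readMM(path_of("matrix.mtx")),
                                 "generalMatrix"), "CsparseMatrix")
  features <- utils::read.table(path_of("features.tsv"), sep = "\t",
                                stringsAsFactors = FALSE, quote = "",
                                col.names = c("id", "name", "feature_type"))
  barcodes <- readLines(path_of("barcodes.tsv"))
  if (nrow(features) != nrow(mat)) {
    stop("matrix has ", nrow(mat), " rows but features table has ",
         nrow(features), call. = FALSE)
  }
  if (length(barcodes) != ncol(mat)) {
    stop("matrix has ", ncol(mat), " columns but barcodes table has ",
         length(barcodes), call. = FALSE)
  }
  known <- c(FEATURE_TYPE_GEX, FEATURE_TYPE_ADT, FEATURE_TYPE_HTO)
  unknown <- setdiff(unique(features$feature_type), known)
  if (length(unknown) > 0L) {
    stop("unknown feature_type in features table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  is_gex <- features$feature_type == FEATURE_TYPE_GEX
  is_adt <- features$feature_type == FEATURE_TYPE_ADT
  is_hto <- features$feature_type == FEATURE_TYPE_HTO
  if (!any(is_adt)) {
    stop("count bundle has no antibody-capture rows (panel would be empty)",
         call. = FALSE)
  }
  if (is.null(panel)) {
    sidecar <- file.path(directory_path, "panel.tsv")
    panel <- if (file.exists(sidecar)) {
      load_panel(sidecar)
    } else {
      panel_definition(
        antibody_id = features$id[is_adt],
        target_name = features$name[is_adt],
        is_isotype_control = grepl("isotype", features$name[is_adt],
                                   ignore.case = TRUE)
      )
    }
  }
  if (is.null(arms)) {
    sidecar <- file.path(directory_path, "arms.tsv")
    if (!file.exists(sidecar)) {
      stop("no arms table: pass `arms` or provide an arms.tsv sidecar",
           call. = FALSE)
    }
    tab <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    arms <- concentration_arms(tab$label, tab$factor, tab$hashtag_id)
  }
  gene_ids <- features$id[is_gex]
  titration_dataset(
    rna_counts = mat[is_gex, , drop = FALSE],
    adt_counts = mat[is_adt, , drop = FALSE],
    hto_counts = mat[is_hto, , drop = FALSE],
    gene_ids = gene_ids,
    mito_gene_ids = gene_ids[startsWith(gene_ids, mito_prefix)],
    barcodes = barcodes,
    panel = panel,
    arms = arms
  )
}
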