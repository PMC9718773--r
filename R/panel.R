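#' Construct an antibody panel definition
#'
#' A panel is the registry of oligo-tagged antibodies in a CITE-Seq
#' experiment: target-detecting antibodies plus isotype controls, which carry
#' no target-detection expectation and serve only to estimate nonspecific
#' (ambient) binding.
#'
#' @param antibody_id Character vector of unique antibody identifiers.
#' @param target_name Character vector of target antigen names (defaults to
#'   the antibody id).
#' @param is_isotype_control Logical vector flagging isotype controls.
#' @param barcode_tag Opaque oligo tag identifiers (defaults to the id).
#' @return A `panel_definition`: a data.frame with one row per antibody and
#'   columns `antibody_id`, `target_name`, `is_isotype_control`,
#'   `barcode_tag`.
#' @examples
#' panel_definition(c("CD3", "ISO1"), is_isotype_control = c(FALSE, TRUE))
#' @export
panel_definition <- function(antibody_id,
                             target_name = antibody_id,
                             is_isotype_control = FALSE,
                             barcode_tag = antibody_id) {
  antibody_id <- as.character(antibody_id)
  if (length(antibody_id) == 0L) {
    stop("panel is empty: at least one antibody is required", call. = FALSE)
  }
  dup <- antibody_id[duplicated(antibody_id)]
  if (length(dup) > 0L) {
    stop("duplicated antibody_id in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    antibody_id = antibody_id,
    target_name = as.character(target_name),
    is_isotype_control = rep_len(as.logical(is_isotype_control), length(antibody_id)),
    barcode_tag = rep_len(as.character(barcode_tag), length(antibody_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("panel_definition", "data.frame")
  out
}

#' Number of antibodies in a panel
#' @param panel A `panel_definition`.
#' @return Integer panel size (isotype controls included).
#' @export
panel_size <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  nrow(panel)
}

#' Read a panel definition from a delimited table
#'
#' The table must have a header with at least `antibody_id`, `target_name`
#' and `is_isotype_control` columns; an optional `barcode_tag` column is kept.
#' Comma- or tab-delimited files are detected from the extension (`.csv` is
#' comma, anything else tab).
#'
#' @param path Path to the table.
#' @return A [panel_definition()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) {
    stop("panel file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  required <- c("antibody_id", "target_name", "is_isotype_control")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("panel table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop("panel table has no rows", call. = FALSE)
  }
  iso <- tab$is_isotype_control
  if (is.character(iso)) iso <- toupper(iso) %in% c("TRUE", "T", "1", "YES")
  panel_definition(
    antibody_id = tab$antibody_id,
    target_name = tab$target_name,
    is_isotype_control = as.logical(iso),
    barcode_tag = if ("barcode_tag" %in% names(tab)) tab$barcode_tag else tab$antibody_id
  )
}

#' Write a panel definition to a tab-delimited table
#' @param panel A `panel_definition`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_definition"))
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.panel_definition <- function(x, ...) {
  n_iso <- sum(x$is_isotype_control)
  cat(sprintf("%dplex antibody panel (%d antibodies + %d isotype controls)\n",
              nrow(x), nrow(x) - n_iso, n_iso))
  invisible(x)
}

#' Construct the table of antibody concentration arms
#'
#' Each arm is one staining condition: a concentration factor relative to the
#' manufacturer-recommended concentration, tagged with its own hashtag
#' oligonucleotide so the arms can be pooled and later demultiplexed.
#'
#' @param label Character arm labels, e.g. `"1x"`.
#' @param factor Positive concentration factors; exactly one must equal 1.
#' @param hashtag_id Hashtag identifiers, one per arm.
#' @return A `concentration_arms` data.frame.
#' @export
concentration_arms <- function(label, factor, hashtag_id) {
  if (any(duplicated(label))) stop("arm labels must be unique", call. = FALSE)
  if (any(factor <= 0)) stop("concentration factors must be positive", call. = FALSE)
  if (sum(factor == 1) != 1L) {
    stop("exactly one arm must be the recommended concentration (factor 1)",
         call. = FALSE)
  }
  out <- data.frame(label = as.character(label), factor = as.numeric(factor),
                    hashtag_id = as.character(hashtag_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("concentration_arms", "data.frame")
  out
}

#' Default four-arm titration design
#'
#' The four-point dilution series used throughout: double, recommended,
#' one-fifth and one-twenty-fifth of the recommended antibody concentration,
#' hashed as HTO1-HTO4.
#'
#' @return A [concentration_arms()] table with arms 2x, 1x, 0.2x, 0.04x.
#' @export
default_arms <- function() {
  concentration_arms(
    label = c("2x", "1x", "0.2x", "0.04x"),
    factor = c(2, 1, 0.2, 0.04),
    hashtag_id = c("HTO1", "HTO2", "HTO3", "HTO4")
  )
}
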