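#' Centered log-ratio normalization of ADT counts
#'
#' Per droplet (column-wise margin, i.e. across the panel features of each
#' droplet): `clr_i = ln(x_i + 1) - mean_j ln(x_j + 1)`. Centering across
#' features removes per-droplet differences in ADT depth. The
#' pseudocount-one centered form over all panel features is used; popular
#' toolkit variants differ (some take the geometric mean over positive
#' entries only), so the formula here is frozen for reproducibility.
#'
#' @param adt_counts Non-negative count matrix, antibodies x droplets
#'   (sparse or dense).
#' @return Dense numeric matrix of the same shape; every column sums to zero.
#' @examples
#' clr_normalize(matrix(c(0, 3, 7), ncol = 1))
#' @export
clr_normalize <- function(adt_counts) {
  m <- log1p(as.matrix(adt_counts))
  sweep(m, 2L, colMeans(m), "-")
}

#' Log-normalize RNA counts
#'
#' Per droplet: `ln(1 + count * scale_total / droplet_total)`, the standard
#' depth-normalized log transform for droplet transcriptomes.
#'
#' @param rna_counts Non-negative count matrix, genes x droplets.
#' @param scale_total Library-size scaling constant (default 10000).
#' @return Dense numeric matrix of the same shape.
#' @export
lognorm_rna <- function(rna_counts, scale_total = 10000) {
  m <- as.matrix(rna_counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("zero-total RNA droplet reached lognorm_rna; such droplets must be ",
         "removed by quality control first", call. = FALSE)
  }
  log1p(sweep(m, 2L, scale_total / totals, "*"))
}
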