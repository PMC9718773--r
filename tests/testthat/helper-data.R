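# Small hand-built fixtures used across test files.

tiny_panel <- function(n = 3, n_iso = 0) {
  ids <- c(sprintf("AB%d", seq_len(n - n_iso)),
           if (n_iso > 0) sprintf("ISO%d", seq_len(n_iso)))
  panel_definition(ids, is_isotype_control = c(rep(FALSE, n - n_iso),
                                               rep(TRUE, n_iso)))
}

# A 10-droplet dataset with known QC outcomes (all droplets are singlets of
# the 1x hashtag unless stated): droplets 1-2 high mito, droplet 3 low total
# ADT, droplet 4 an HTO doublet profile, droplet 5 HTO-negative, 6-10 clean.
qc_fixture_dataset <- function() {
  n <- 10
  arms <- default_arms()
  rna <- rbind(`MT-1` = rep(1, n), G1 = rep(99, n))
  rna[, 1:2] <- c(50, 50)  # mito fraction 0.5
  adt <- matrix(2000, 3, n)
  adt[, 3] <- 50  # total ADT 150 < 200
  hto <- matrix(10, 4, n)
  hto[2, ] <- 90                 # singlet of HTO2 (1x): ratio 90/30 = 3, not > 3
  hto[, 4] <- c(400, 50, 30, 20) # ratio 3.2 -> doublet
  hto[, 5] <- c(15, 5, 5, 5)     # max 15 <= 20 -> negative
  titration_dataset(rna, adt, hto,
                    gene_ids = c("MT-1", "G1"), mito_gene_ids = "MT-1",
                    barcodes = sprintf("BC%02d", seq_len(n)),
                    panel = tiny_panel(3), arms = arms)
}

random_tiny_dataset <- function(seed = 42, n = 6) {
  set.seed(seed)
  rna <- matrix(rpois(5 * n, 10), 5, n)
  adt <- matrix(rpois(3 * n, 50), 3, n)
  hto <- matrix(rpois(4 * n, 20), 4, n)
  titration_dataset(rna, adt, hto,
                    gene_ids = c("MT-1", sprintf("G%d", 1:4)),
                    mito_gene_ids = "MT-1",
                    barcodes = sprintf("BC%02d", seq_len(n)),
                    panel = tiny_panel(3), arms = default_arms())
}
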