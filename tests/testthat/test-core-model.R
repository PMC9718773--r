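test_that("panel construction enforces uniqueness and non-emptiness", {
  p <- panel_definition(c("CD3", "ISO1"), is_isotype_control = c(FALSE, TRUE))
  expect_s3_class(p, "panel_definition")
  expect_equal(panel_size(p), 2L)
  expect_error(panel_definition(character(0)), "empty")
  expect_error(panel_definition(c("a", "a")), "duplicated.*a")
})

test_that("load_panel reads a 192-row table and rejects bad schemas", {
  tab <- data.frame(
    antibody_id = c(sprintf("AB%03d", 1:188), sprintf("ISO%d", 1:4)),
    target_name = c(sprintf("antigen-%03d", 1:188), sprintf("iso-%d", 1:4)),
    is_isotype_control = c(rep(FALSE, 188), rep(TRUE, 4))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  p <- load_panel(path)
  expect_equal(panel_size(p), 192L)
  expect_equal(sum(p$is_isotype_control), 4L)

  empty <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[0, ], empty, row.names = FALSE)
  expect_error(load_panel(empty), "no rows")

  dup <- withr::local_tempfile(fileext = ".csv")
  write.csv(rbind(tab[1:2, ], tab[1, ]), dup, row.names = FALSE)
  expect_error(load_panel(dup), "AB001")

  noschema <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[, 1:2], noschema, row.names = FALSE)
  expect_error(load_panel(noschema), "is_isotype_control")
})

test_that("concentration arms require a unique recommended arm", {
  a <- default_arms()
  expect_equal(sum(a$factor == 1), 1L)
  expect_error(concentration_arms(c("a", "b"), c(2, 0.5), c("H1", "H2")),
               "factor 1")
  expect_error(concentration_arms(c("a", "a"), c(1, 2), c("H1", "H2")),
               "unique")
})

test_that("dataset constructor validates alignment and integer counts", {
  ds <- random_tiny_dataset()
  expect_equal(n_droplets(ds), 6L)
  expect_error(
    titration_dataset(matrix(1, 2, 5), matrix(1, 3, 6), matrix(1, 4, 6),
                      gene_ids = c("MT-1", "g2"), mito_gene_ids = "MT-1",
                      barcodes = sprintf("b%d", 1:6),
                      panel = tiny_panel(3), arms = default_arms()),
    "droplet axis")
  expect_error(
    titration_dataset(matrix(1.5, 2, 6), matrix(1, 3, 6), matrix(1, 4, 6),
                      gene_ids = c("MT-1", "g2"), mito_gene_ids = "MT-1",
                      barcodes = sprintf("b%d", 1:6),
                      panel = tiny_panel(3), arms = default_arms()),
    "non-integer")
  expect_error(
    titration_dataset(matrix(1, 2, 6), matrix(1, 2, 6), matrix(1, 4, 6),
                      gene_ids = c("MT-1", "g2"), mito_gene_ids = "MT-1",
                      barcodes = sprintf("b%d", 1:6),
                      panel = tiny_panel(3), arms = default_arms()),
    "panel")
})

test_that("count bundle round-trips exactly and writes are idempotent", {
  ds <- random_tiny_dataset()
  dir1 <- withr::local_tempdir()
  write_count_bundle(ds, dir1)
  back <- read_count_bundle(dir1)
  expect_equal(as.matrix(back$rna_counts), as.matrix(ds$rna_counts))
  expect_equal(as.matrix(back$adt_counts), as.matrix(ds$adt_counts))
  expect_equal(as.matrix(back$hto_counts), as.matrix(ds$hto_counts))
  expect_equal(back$barcodes, ds$barcodes)
  expect_equal(back$mito_gene_ids, "MT-1")
  expect_equal(as.data.frame(back$panel), as.data.frame(ds$panel))

  dir2 <- withr::local_tempdir()
  write_count_bundle(back, dir2)
  expect_identical(readLines(file.path(dir1, "matrix.mtx")),
                   readLines(file.path(dir2, "matrix.mtx")))
})

test_that("bundle reader splits feature classes by shape", {
  # 5 genes / 3 ADT / 2 HTO x 4 droplets
  arms2 <- concentration_arms(c("1x", "0.2x"), c(1, 0.2), c("H1", "H2"))
  ds <- titration_dataset(matrix(1:20, 5, 4), matrix(1:12, 3, 4),
                          matrix(1:8, 2, 4),
                          gene_ids = sprintf("G%d", 1:5),
                          mito_gene_ids = character(0),
                          barcodes = sprintf("b%d", 1:4),
                          panel = tiny_panel(3), arms = arms2)
  dir <- withr::local_tempdir()
  write_count_bundle(ds, dir)
  back <- read_count_bundle(dir)
  expect_equal(dim(back$rna_counts), c(5L, 4L))
  expect_equal(dim(back$adt_counts), c(3L, 4L))
  expect_equal(dim(back$hto_counts), c(2L, 4L))
})

test_that("bundle reader rejects missing files, empty panels and unknown types", {
  dir <- withr::local_tempdir()
  expect_error(read_count_bundle(dir), "missing file")

  # hand-written bundle with no antibody-capture rows
  m <- Matrix::Matrix(matrix(1:4, 2, 2), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(c("G1\tG1\tGene Expression", "H1\tH1\tMultiplexing Capture"),
             file.path(dir, "features.tsv"))
  writeLines(c("b1", "b2"), file.path(dir, "barcodes.tsv"))
  expect_error(read_count_bundle(dir), "no antibody-capture rows")

  writeLines(c("G1\tG1\tGene Expression", "X1\tX1\tMystery Capture"),
             file.path(dir, "features.tsv"))
  expect_error(read_count_bundle(dir), "unknown feature_type")
})
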