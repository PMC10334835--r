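test_that("dense CSV parsing, duplicate symbol disambiguation and error paths", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2", "ACTB,1,0", "VEGFA,2,3", "ACTB,0,0"), csv)
  m <- read_expression(csv, "csv")
  expect_s3_class(m, "ExpressionMatrix")
  expect_equal(m$layer, "raw_counts")
  expect_equal(m$gene_ids, c("ACTB", "VEGFA", "ACTB.1"))
  expect_equal(unname(as.matrix(m$values)), rbind(c(1, 0), c(2, 3), c(0, 0)))

  expect_error(read_expression(tempfile(), "csv"), "does not exist")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("gene,c1", "ACTB,x"), bad)
  expect_error(read_expression(bad, "csv"), "non-numeric")
})

test_that("MTX triplet round-trips and dimension mismatch is a format error", {
  d <- generate_dataset(generator_config(n_cells = 20, n_genes = 30,
                                         n_program_genes = 5,
                                         signature_size = 4, seed = 3))
  dir <- tempfile(); write_dataset(d, dir)
  m <- read_expression(dir, "mtx_dir")
  expect_equal(m$gene_ids, d$matrix$gene_ids)
  expect_equal(m$cell_ids, d$matrix$cell_ids)
  expect_equal(unname(as.matrix(m$values)), unname(unclass(d$matrix$values)))

  # drop one feature line -> declared gene count no longer matches
  feats <- readLines(file.path(dir, "features.tsv"))
  writeLines(feats[-1], file.path(dir, "features.tsv"))
  expect_error(read_expression(dir, "mtx_dir"), "format error")
})

test_that("GMT reader preserves order and rejects malformed lines", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("HYPOXIA_A\tdesc\tVEGFA\tLDHA", "", "HYPOXIA_B\tdesc\tPGK1"), gmt)
  sets <- read_gene_sets(gmt)
  expect_equal(names(sets), c("HYPOXIA_A", "HYPOXIA_B"))
  expect_equal(sets$HYPOXIA_A, c("VEGFA", "LDHA"))

  empty <- tempfile(); writeLines(character(), empty)
  expect_warning(e <- read_gene_sets(empty), "empty")
  expect_length(e, 0)

  short <- tempfile(); writeLines(c("OK\td\tG1", "BAD\tdesc"), short)
  expect_error(read_gene_sets(short), "line 2")

  dup <- tempfile(); writeLines(c("S1\td\tG1", "S1\td\tG2"), dup)
  expect_error(read_gene_sets(dup), "duplicate")
})

test_that("gene filter keeps the exact boundary fraction and is idempotent", {
  counts <- matrix(0, nrow = 3, ncol = 1000,
                   dimnames = list(c("absent", "boundary", "everywhere"),
                                   sprintf("c%04d", 1:1000)))
  counts["boundary", 1] <- 5          # expressed in exactly 0.1% of cells
  counts["everywhere", ] <- 1
  m <- ExpressionMatrix(counts, layer = "raw_counts")
  f <- filter_genes(m, 0.001)
  expect_equal(f$gene_ids, c("boundary", "everywhere"))
  expect_equal(filter_genes(f, 0.001)$gene_ids, f$gene_ids)  # idempotent
  expect_equal(f$cell_ids, m$cell_ids)
  partial <- ExpressionMatrix(counts[, 1:999][, , drop = FALSE],
                              gene_ids = rownames(counts),
                              cell_ids = sprintf("c%04d", 1:999),
                              layer = "raw_counts")
  partial$values["everywhere", 1] <- 0   # now no gene covers every cell
  expect_error(filter_genes(ExpressionMatrix(partial$values, layer = "raw_counts"), 1),
               "all genes removed")
})

test_that("normalization: forced arithmetic, conservation, zero pattern, errors", {
  counts <- matrix(c(1, 1, 0, 4), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  m <- ExpressionMatrix(counts, layer = "raw_counts")
  n <- normalize_expression(m, scale_factor = 2)
  expect_equal(as.numeric(n$values[, "c1"]), c(log(2), log(2)))
  # conservation identity: per cell, sum(expm1(values)) == scale_factor
  n2 <- normalize_expression(m, scale_factor = 1e4)
  expect_equal(unname(colSums(expm1(as.matrix(n2$values)))), c(1e4, 1e4))
  expect_equal(as.matrix(n2$values) == 0, counts == 0)  # zero pattern

  zc <- ExpressionMatrix(matrix(c(1, 1, 0, 0), 2,
                                dimnames = list(c("g1", "g2"), c("ok", "empty"))),
                         layer = "raw_counts")
  expect_error(normalize_expression(zc), "empty")

  # sparse path agrees with dense path
  set.seed(42)
  big <- matrix(rpois(600, 0.8), nrow = 30,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:20)))
  big[, 1] <- pmax(big[, 1], 1)
  dn <- normalize_expression(ExpressionMatrix(big + 0, layer = "raw_counts"))
  sp <- normalize_expression(
    ExpressionMatrix(Matrix::Matrix(big, sparse = TRUE), layer = "raw_counts"))
  expect_equal(as.matrix(sp$values), as.matrix(dn$values), tolerance = 1e-12)
})

test_that("label tables round-trip through TSV", {
  tab <- data.frame(cell_id = c("c1", "c2"), status = c("hypoxic", "normoxic"),
                    score = c(0.9, 0.1), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_labels(tab, path)
  expect_equal(length(readLines(path)), 3L)   # header + 2 rows
  expect_equal(read_labels(path), tab)
  expect_warning(write_labels(tab[0, ], tempfile()), "header-only")
})

test_that("ExpressionMatrix invariants are enforced", {
  v <- matrix(1:4, 2)
  expect_error(ExpressionMatrix(v, c("a", "a"), c("c1", "c2")), "duplicate gene")
  expect_error(ExpressionMatrix(v, c("a", "b"), c("c1", "c1")), "duplicate cell")
  expect_error(ExpressionMatrix(v, c("a", "b", "c"), c("c1", "c2")), "dimension")
  expect_error(ExpressionMatrix(-v, c("a", "b"), c("c1", "c2")), "negative")
})
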