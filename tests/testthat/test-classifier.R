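# shared small fixture: planted two-class dataset with known DE genes
make_planted <- function(seed = 21, n_cells = 160, n_genes = 120,
                         n_de = 30, lfc = 2, separator = FALSE) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  cells <- sprintf("C%03d", seq_len(n_cells))
  status <- rep(c("hypoxic", "normoxic"), length.out = n_cells)
  base <- rlnorm(n_genes, 0, 0.5) + 0.5
  counts <- matrix(0, n_genes, n_cells, dimnames = list(genes, cells))
  for (ci in seq_len(n_cells)) {
    mu <- base
    if (status[ci] == "hypoxic") mu[1:n_de] <- mu[1:n_de] * 2^lfc
    counts[, ci] <- rnbinom(n_genes, mu = mu * 400 / mean(mu), size = 5)
  }
  counts[, colSums(counts) == 0] <- 1
  if (separator) {  # make the classes perfectly separable on one marker gene
    counts[1, status == "hypoxic"] <- counts[1, status == "hypoxic"] + 400
    counts[1, status == "normoxic"] <- 0
  }
  labels <- structure(
    data.frame(cell_id = cells,
               status = factor(status,
                               levels = c("hypoxic", "normoxic", "unclassified")),
               n_high = 0L, stringsAsFactors = FALSE),
    class = c("HighConfidenceLabels", "data.frame"))
  list(m = normalize_expression(ExpressionMatrix(counts, layer = "raw_counts")),
       labels = labels, de_genes = genes[1:n_de])
}

test_that("feature selection recovers planted DE genes and clamps panel size", {
  fx <- make_planted()
  panel <- select_deg_features(fx$m, fx$labels, n_features = 60)
  expect_s3_class(panel, "FeaturePanel")
  expect_equal(nrow(panel), 60L)
  expect_true(all(fx$de_genes %in% panel$gene))
  # ranked by ascending p-value
  expect_true(!is.unsorted(panel$p_value))
  expect_warning(all_p <- select_deg_features(fx$m, fx$labels, 500),
                 "exceeds gene count")
  expect_equal(nrow(all_p), length(fx$m$gene_ids))
  expect_error(select_deg_features(fx$m, fx$labels, 0), "positive")
  one <- fx$labels; one$status[one$status == "normoxic"] <- "unclassified"
  expect_error(select_deg_features(fx$m, one), "2 cells per class")
})

test_that("per-gene test agrees with stats::wilcox.test and ranking tie-break is deterministic", {
  fx <- make_planted(seed = 4, n_cells = 40, n_genes = 25, n_de = 5)
  X <- as.matrix(fx$m$values)
  is_h <- fx$labels$status == "hypoxic"
  res <- chpf:::wilcox_by_gene(X, is_h)
  for (g in c(1, 7, 20)) {
    ref <- wilcox.test(X[g, is_h], X[g, !is_h], exact = FALSE)
    expect_equal(res$p_value[g], ref$p.value)
  }
  p1 <- select_deg_features(fx$m, fx$labels, 10)
  p2 <- select_deg_features(fx$m, fx$labels, 10)
  expect_identical(p1, p2)
})

test_that("ensemble honors fold structure, balance, and perfect-recall weights", {
  # perfectly separable by construction: every hypoxic cell shares one
  # profile, every normoxic cell another, with a wide margin on 10 genes
  set.seed(71)
  n_genes <- 50; n_cells <- 120
  genes <- sprintf("G%03d", 1:n_genes); cells <- sprintf("C%03d", 1:n_cells)
  status <- rep(c("hypoxic", "normoxic"), length.out = n_cells)
  vals <- matrix(rep(runif(n_genes, 0.5, 1.5), n_cells), n_genes, n_cells,
                 dimnames = list(genes, cells))
  vals[1:10, status == "hypoxic"] <- 5
  vals[1:10, status == "normoxic"] <- 0
  m <- ExpressionMatrix(vals, layer = "lognorm")
  labels <- structure(
    data.frame(cell_id = cells,
               status = factor(status,
                               levels = c("hypoxic", "normoxic", "unclassified")),
               n_high = 0L, stringsAsFactors = FALSE),
    class = c("HighConfidenceLabels", "data.frame"))
  panel <- select_deg_features(m, labels, 20)
  expect_true(all(genes[1:10] %in% panel$gene[1:10]))
  model <- train_ensemble(m, labels, panel, n_members = 10, k_folds = 5,
                          seed = 5, nrounds = 20)
  expect_equal(model$n_members, 10L)
  expect_equal(as.vector(table(model$fold_map)), rep(2L, 5))  # members per fold
  expect_true(all(model$weights == 1))                     # perfect recall
  expect_error(train_ensemble(m, labels, panel, n_members = 7,
                              k_folds = 5, seed = 1), "divisible")
})

test_that("every member trains on equal class counts", {
  fx <- make_planted(seed = 31)
  # make hypoxic the minority class: drop a quarter of the hypoxic cells
  lab <- fx$labels
  hyp <- which(lab$status == "hypoxic")
  lab$status[hyp[1:20]] <- "unclassified"
  panel <- select_deg_features(fx$m, lab, 40)
  # re-derive each member's undersample from its stored seed and assert the
  # training set it saw had equal class counts
  model <- train_ensemble(fx$m, lab, panel, n_members = 5, k_folds = 5,
                          seed = 11, nrounds = 10)
  y <- model$train_label; fold <- model$fold_of
  for (t in seq_len(model$n_members)) {
    f <- model$fold_map[t]
    h_tr <- which(fold != f & y == 1)
    n_tr <- which(fold != f & y == 0)
    expect_gte(length(n_tr), length(h_tr))
    set.seed(model$seeds[t] %% .Machine$integer.max)
    n_sub <- sample(n_tr, length(h_tr))
    use <- c(h_tr, n_sub)
    expect_equal(sum(y[use] == 1), sum(y[use] == 0))
  }
})

test_that("voting rate formula is exact and boundary goes to hypoxic", {
  # equal weights reduce to the fraction of members voting hypoxic
  I <- matrix(rep(c(1, 0), c(60, 40)), nrow = 1)
  expect_equal(voting_rate(I, rep(1, 100)), 0.6)
  # weighted two-member case: 0.5/1.5
  expect_equal(voting_rate(matrix(c(1, 0), 1), c(0.5, 1.0)), 1 / 3)
  expect_error(voting_rate(matrix(1, 1, 2), c(0, 0)), "uninformative")
  # reproducibility of full training: identical data + seed => identical model
  fx <- make_planted(seed = 31)
  panel <- select_deg_features(fx$m, fx$labels, 30)
  m1 <- train_ensemble(fx$m, fx$labels, panel, n_members = 5, k_folds = 5,
                       seed = 3, nrounds = 10)
  m2 <- train_ensemble(fx$m, fx$labels, panel, n_members = 5, k_folds = 5,
                       seed = 3, nrounds = 10)
  expect_identical(m1$members, m2$members)
  expect_identical(m1$weights, m2$weights)
  v1 <- vote(m1, fx$m); v2 <- vote(m2, fx$m)
  expect_identical(v1, v2)
  expect_true(all(v1$voting_rate >= 0 & v1$voting_rate <= 1))
  expect_equal(as.character(v1$status),
               ifelse(v1$voting_rate >= 0.5, "hypoxic", "normoxic"))
})

test_that("label shuffling drives member recall toward chance", {
  fx <- make_planted(seed = 13, n_cells = 200)
  shuffled <- fx$labels
  set.seed(99)
  shuffled$status <- sample(shuffled$status)
  panel <- select_deg_features(fx$m, shuffled, 40)
  model <- train_ensemble(fx$m, shuffled, panel, n_members = 10, k_folds = 5,
                          seed = 2, nrounds = 20)
  # hypoxic prevalence in balanced training is 1/2; held-out recall of an
  # uninformative member should hover near the chance level, far below the
  # near-1 recall of truly separable classes
  expect_lt(median(model$weights), 0.8)
  expect_gt(median(model$weights), 0.2)
})

test_that("stable-feature counting applies a strict member-fraction threshold", {
  used <- c(g_all = 100L, g95 = 95L, g90 = 90L, g10 = 10L)
  expect_equal(chpf:::stable_from_counts(used, 100L, 0.9), c("g_all", "g95"))
  fx <- make_planted(seed = 31, lfc = 4, separator = TRUE)
  panel <- select_deg_features(fx$m, fx$labels, 40)
  model <- train_ensemble(fx$m, fx$labels, panel, n_members = 5, k_folds = 5,
                          seed = 5, nrounds = 20)
  sf <- stable_features(model, fraction = 0)    # genes used in >0 members
  expect_true(length(sf) > 0 && all(sf %in% panel$gene))
  expect_warning(stable_features(model, fraction = 1), "no gene")
})

test_that("cell-type signatures honor strict FDR and log2FC thresholds", {
  fx <- make_planted(seed = 61, n_cells = 120, n_genes = 60, n_de = 10, lfc = 3)
  status <- data.frame(cell_id = fx$labels$cell_id,
                       status = as.character(fx$labels$status),
                       stringsAsFactors = FALSE)
  meta <- data.frame(cell_id = fx$labels$cell_id,
                     cell_type = rep(c("tumor", "immune"), each = 60),
                     stringsAsFactors = FALSE)
  tbl <- cell_type_signatures(fx$m, status, meta, genes = fx$m$gene_ids)
  expect_s3_class(tbl, "SignatureTable")
  expect_true(all(tbl$fdr < 0.05) && all(tbl$log2fc > 1.5))
  expect_true(all(tbl$gene %in% fx$de_genes))

  # boundary: a gene whose log2FC equals the threshold exactly is excluded.
  # Restrict to one cell type so the threshold is computed on exactly the
  # cells the per-type test will see.
  tumor <- meta$cell_id[meta$cell_type == "tumor"]
  X <- as.matrix(fx$m$values[, tumor])
  is_h <- status$status[match(tumor, status$cell_id)] == "hypoxic"
  res <- chpf:::wilcox_by_gene(X, is_h)
  strongest <- res[which.min(res$p_value), ]
  at_boundary <- cell_type_signatures(fx$m, status,
                                      meta[meta$cell_type == "tumor", ],
                                      genes = strongest$gene,
                                      lfc = strongest$log2fc) |>
    suppressWarnings()
  expect_false(strongest$gene %in% at_boundary$gene)

  # a cell type present only among normoxic cells is skipped with a warning
  meta2 <- meta
  meta2$cell_type[status$status == "hypoxic" & meta$cell_type == "immune"] <- "tumor"
  expect_warning(cell_type_signatures(fx$m, status, meta2, genes = fx$m$gene_ids),
                 "skipped")
})

test_that("final status merges consensus labels with predictions", {
  lab <- structure(
    data.frame(cell_id = c("a", "b", "c"),
               status = factor(c("hypoxic", "unclassified", "normoxic"),
                               levels = c("hypoxic", "normoxic", "unclassified")),
               n_high = c(7L, 3L, 0L), stringsAsFactors = FALSE),
    class = c("HighConfidenceLabels", "data.frame"))
  voting <- data.frame(cell_id = "b", voting_rate = 0.8,
                       status = factor("hypoxic",
                                       levels = c("hypoxic", "normoxic")))
  fs <- final_status(lab, voting)
  expect_equal(as.character(fs$status), c("hypoxic", "hypoxic", "normoxic"))
  expect_equal(fs$source, c("consensus", "predicted", "consensus"))
  expect_error(final_status(lab, voting[0, ]), "without a vote")
})
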