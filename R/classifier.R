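#' Select differential-expression features between high-confidence classes
#'
#' Two-sided Wilcoxon rank-sum test per gene, high-confidence hypoxic versus
#' high-confidence normoxic cells; genes are ranked by ascending raw p-value
#' (ties broken by larger absolute log2 fold change, then gene identifier)
#' and the top `n_features` are returned as the classifier's feature panel.
#' log2FC is computed on mean(expm1(lognorm)) + 1 per class.
#'
#' @param m lognorm [ExpressionMatrix()].
#' @param labels `HighConfidenceLabels` data frame (from [consensus_labels()]).
#' @param n_features panel size (default 500); clamped to the gene count with
#'   a warning.
#' @return A `FeaturePanel` data frame: `gene`, `p_value`, `statistic`,
#'   `log2fc`, ordered as ranked.
#' @export
select_deg_features <- function(m, labels, n_features = 500L) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  if (n_features <= 0) stop("n_features must be positive")
  hyp <- labels$cell_id[labels$status == "hypoxic"]
  nor <- labels$cell_id[labels$status == "normoxic"]
  if (length(hyp) < 2 || length(nor) < 2)
    stop(sprintf("need >= 2 cells per class; got %d hypoxic, %d normoxic",
                 length(hyp), length(nor)))
  X <- as.matrix(m$values[, c(hyp, nor), drop = FALSE])
  is_h <- c(rep(TRUE, length(hyp)), rep(FALSE, length(nor)))
  res <- wilcox_by_gene(X, is_h)
  if (n_features > nrow(res)) {
    warning(sprintf("n_features = %d exceeds gene count %d; returning all genes",
                    n_features, nrow(res)))
    n_features <- nrow(res)
  }
  ord <- order(res$p_value, -abs(res$log2fc), res$gene)
  panel <- res[ord, , drop = FALSE][seq_len(n_features), ]
  rownames(panel) <- NULL
  structure(panel, class = c("FeaturePanel", "data.frame"))
}

# per-gene two-sided Wilcoxon rank-sum plus log2FC on de-logged means
wilcox_by_gene <- function(X, is_h) {
  p <- numeric(nrow(X)); stat <- numeric(nrow(X))
  for (g in seq_len(nrow(X))) {
    wt <- suppressWarnings(
      stats::wilcox.test(X[g, is_h], X[g, !is_h], exact = FALSE, correct = TRUE))
    p[g] <- wt$p.value
    stat[g] <- unname(wt$statistic)
  }
  p[is.na(p)] <- 1   # constant gene across both classes
  mh <- rowMeans(expm1(X[, is_h, drop = FALSE]))
  mn <- rowMeans(expm1(X[, !is_h, drop = FALSE]))
  data.frame(gene = rownames(X), p_value = p, statistic = stat,
             log2fc = log2((mh + 1) / (mn + 1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Train the recall-weighted gradient-boosted tree ensemble
#'
#' High-confidence cells are split into `k_folds` stratified folds. Each
#' ensemble member picks one fold as its held-out test set; from the
#' remaining training cells it takes every hypoxic cell plus an equal-size
#' random undersample of normoxic cells, and fits a gradient-boosted tree
#' classifier (xgboost, binary logistic) on the panel genes. The member's
#' voting weight is its recall for the hypoxic class on the held-out fold.
#' With the defaults (100 members, 5 folds) every fold anchors 20 members,
#' each re-drawing the normoxic undersample.
#'
#' @param m lognorm [ExpressionMatrix()].
#' @param labels `HighConfidenceLabels`.
#' @param panel `FeaturePanel` from [select_deg_features()].
#' @param n_members ensemble size (default 100); must be divisible by
#'   `k_folds`.
#' @param k_folds cross-validation folds (default 5).
#' @param seed integer seed governing fold assignment and undersampling.
#' @param params xgboost booster parameters; defaults: `max_depth = 6`,
#'   `eta = 0.1`, single-threaded for bit reproducibility.
#' @param nrounds boosting rounds per member (default 100).
#' @return An `EnsembleModel`: list with `members` (serialized xgboost
#'   boosters as raw vectors), `weights`, `fold_map`, `seeds`,
#'   `feature_genes`, `k_folds`, `n_members`.
#' @export
train_ensemble <- function(m, labels, panel, n_members = 100L, k_folds = 5L,
                           seed = 1L, params = list(), nrounds = 100L) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  if (n_members %% k_folds != 0)
    stop("n_members must be divisible by k_folds")
  genes <- panel$gene
  missing <- setdiff(genes, m$gene_ids)
  if (length(missing))
    stop("panel genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  hyp <- labels$cell_id[labels$status == "hypoxic"]
  nor <- labels$cell_id[labels$status == "normoxic"]
  if (!length(hyp) || !length(nor))
    stop("both high-confidence classes must be non-empty")

  X <- t(as.matrix(m$values[genes, c(hyp, nor), drop = FALSE]))
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- c(rep(1, length(hyp)), rep(0, length(nor)))  # 1 = hypoxic
  cells <- rownames(X)

  set.seed(as.integer(seed))
  fold_of <- integer(length(y))
  for (cls in c(0, 1)) {   # stratified fold assignment
    idx <- sample(which(y == cls))
    fold_of[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  for (f in seq_len(k_folds))
    if (sum(y == 1 & fold_of != f) == 0)
      stop("fold ", f, " leaves no hypoxic training cells")

  defaults <- list(objective = "binary:logistic", max_depth = 6, eta = 0.1,
                   nthread = 1, tree_method = "hist")
  params <- utils::modifyList(defaults, params)

  repeats <- n_members %/% k_folds
  member_seeds <- sample.int(.Machine$integer.max, n_members)
  members <- vector("list", n_members)
  weights <- numeric(n_members)
  fold_map <- integer(n_members)
  t <- 0L
  for (rep_i in seq_len(repeats)) {
    for (f in seq_len(k_folds)) {
      t <- t + 1L
      fold_map[t] <- f
      train_idx <- which(fold_of != f)
      test_idx <- which(fold_of == f)
      h_tr <- train_idx[y[train_idx] == 1]
      n_tr <- train_idx[y[train_idx] == 0]
      set.seed(member_seeds[t] %% .Machine$integer.max)
      n_sub <- if (length(n_tr) >= length(h_tr))
        sample(n_tr, length(h_tr)) else n_tr
      use <- c(h_tr, n_sub)
      pars <- c(params, list(seed = member_seeds[t] %% 100000L))
      dtrain <- xgboost::xgb.DMatrix(X[use, , drop = FALSE], label = y[use],
                                     nthread = 1)
      booster <- xgboost::xgb.train(params = pars, data = dtrain,
                                    nrounds = nrounds, verbose = 0)
      # recall of the hypoxic class on the held-out fold
      ho_h <- test_idx[y[test_idx] == 1]
      if (length(ho_h)) {
        pr <- stats::predict(booster,
                             xgboost::xgb.DMatrix(X[ho_h, , drop = FALSE],
                                                  nthread = 1))
        weights[t] <- mean(pr >= 0.5)
      } else weights[t] <- 0
      # keep only the serialized booster: a live handle pins its training
      # cache (~60 MB/member), which does not survive 100 members
      members[[t]] <- xgboost::xgb.save.raw(booster)
      rm(booster, dtrain)
      if (t %% 10L == 0L) gc(FALSE)
    }
  }
  gc(FALSE)
  structure(list(members = members, weights = weights, fold_map = fold_map,
                 seeds = member_seeds, feature_genes = panel,
                 k_folds = k_folds, n_members = n_members,
                 params = params, nrounds = nrounds,
                 train_cells = cells, train_label = y, fold_of = fold_of),
            class = "EnsembleModel")
}

#' @export
print.EnsembleModel <- function(x, ...) {
  cat(sprintf("EnsembleModel: %d members, %d folds, %d feature genes\n",
              x$n_members, x$k_folds, nrow(x$feature_genes)))
  cat(sprintf("  recall weights: median %.3f [%.3f, %.3f]\n",
              stats::median(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Recall-weighted ensemble vote
#'
#' For cell i the voting rate is v_i = sum_t w_t I_t(i) / sum_t w_t, where
#' I_t(i) = 1 when member t predicts the cell hypoxic and w_t is the member's
#' hypoxic-class recall on its held-out fold. A cell is called hypoxic when
#' v_i >= 0.5 (the boundary goes to hypoxic).
#'
#' @param model `EnsembleModel`.
#' @param m lognorm [ExpressionMatrix()]; panel genes missing from it are
#'   imputed as zero with a warning.
#' @param cells cell ids to score (default: all cells of `m`).
#' @return A `VotingResult` data frame: `cell_id`, `voting_rate`, `status`.
#' @export
vote <- function(model, m, cells = m$cell_ids) {
  stopifnot(inherits(model, "EnsembleModel"),
            inherits(m, "ExpressionMatrix"))
  if (sum(model$weights) == 0)
    stop("all member weights are zero: uninformative ensemble")
  genes <- model$feature_genes$gene
  present <- genes %in% m$gene_ids
  if (!all(present))
    warning(sum(!present), " panel gene(s) missing from matrix; imputed as 0")
  X <- matrix(0, nrow = length(cells), ncol = length(genes),
              dimnames = list(cells, genes))
  X[, genes[present]] <- t(as.matrix(m$values[genes[present], cells, drop = FALSE]))
  dm <- xgboost::xgb.DMatrix(X, nthread = 1)
  I <- matrix(0, nrow = length(cells), ncol = length(model$members))
  for (t in seq_along(model$members)) {
    booster <- xgboost::xgb.load.raw(model$members[[t]])
    I[, t] <- as.numeric(stats::predict(booster, dm) >= 0.5)
    rm(booster)
    if (t %% 25L == 0L) gc(FALSE)
  }
  v <- voting_rate(I, model$weights)
  structure(data.frame(cell_id = cells, voting_rate = v,
                       status = factor(ifelse(v >= 0.5, "hypoxic", "normoxic"),
                                       levels = c("hypoxic", "normoxic")),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("VotingResult", "data.frame"))
}

#' Recall-weighted voting rate
#'
#' v_i = sum_t w_t I[i, t] / sum_t w_t. Exposed separately so the decision
#' statistic can be audited against hand-constructed member predictions.
#'
#' @param I cells x members 0/1 indicator matrix (1 = member predicts
#'   hypoxic).
#' @param w per-member weights in [0, 1], not all zero.
#' @return Numeric vector of voting rates in [0, 1].
#' @export
voting_rate <- function(I, w) {
  I <- as.matrix(I)
  if (ncol(I) != length(w)) stop("one weight per member required")
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  if (sum(w) == 0) stop("all member weights are zero: uninformative ensemble")
  as.numeric(I %*% w) / sum(w)
}

# strictly more than fraction * n_members members must use the gene
stable_from_counts <- function(used, n_members, fraction) {
  names(used)[used > fraction * n_members]
}

#' Features used by more than a fraction of ensemble members
#'
#' A gene is "used" by a member when its split importance (gain) in that
#' member's booster is positive; genes used in strictly more than
#' `fraction * n_members` members are returned (a gene used in exactly 90 of
#' 100 members with the default fraction is excluded).
#'
#' @param model `EnsembleModel`.
#' @param fraction member fraction threshold (default 0.9).
#' @return Character vector of stable feature genes (possibly empty, with a
#'   warning).
#' @export
stable_features <- function(model, fraction = 0.9) {
  stopifnot(inherits(model, "EnsembleModel"))
  genes <- model$feature_genes$gene
  used <- integer(length(genes)); names(used) <- genes
  for (t in seq_along(model$members)) {
    b <- xgboost::xgb.load.raw(model$members[[t]])
    imp <- xgboost::xgb.importance(model = b)
    hit <- imp$Feature[imp$Gain > 0]
    used[hit] <- used[hit] + 1L
    rm(b)
    if (t %% 25L == 0L) gc(FALSE)
  }
  out <- stable_from_counts(used, model$n_members, fraction)
  if (!length(out))
    warning("no gene is used in more than ", fraction * 100, "% of members")
  out
}

#' Cell-type-specific hypoxia gene signatures
#'
#' Within each cell type with enough cells of both statuses, a two-sided
#' Wilcoxon rank-sum test (hypoxic vs normoxic) is run per gene, p-values are
#' Benjamini-Hochberg adjusted within the cell type, and rows with
#' FDR < `fdr` AND log2FC > `lfc` are retained (both strict). log2FC is
#' computed on mean(expm1(lognorm)) + 1.
#'
#' @param m lognorm [ExpressionMatrix()].
#' @param status data frame with `cell_id` and `status` (hypoxic/normoxic),
#'   e.g. from [final_status()] or [vote()].
#' @param meta data frame with `cell_id` and `cell_type`.
#' @param genes genes to test; typically the [stable_features()] output.
#' @param fdr,lfc retention thresholds (defaults 0.05 and 1.5, both strict).
#' @param min_cells minimum cells per status within a cell type (default 3).
#' @return A `SignatureTable` data frame: `cell_type`, `gene`, `log2fc`,
#'   `p_value`, `fdr`, `direction`.
#' @export
cell_type_signatures <- function(m, status, meta, genes = m$gene_ids,
                                 fdr = 0.05, lfc = 1.5, min_cells = 3L) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  genes <- intersect(genes, m$gene_ids)
  if (!length(genes)) stop("none of the requested genes are in the matrix")
  st <- stats::setNames(as.character(status$status), status$cell_id)
  ct <- stats::setNames(as.character(meta$cell_type), meta$cell_id)
  out <- list()
  for (type in sort(unique(ct))) {
    cells <- names(ct)[ct == type]
    cells <- cells[cells %in% names(st) & cells %in% m$cell_ids]
    h <- cells[st[cells] == "hypoxic"]
    n <- cells[st[cells] == "normoxic"]
    if (length(h) < min_cells || length(n) < min_cells) {
      warning(sprintf("cell type '%s' skipped: %d hypoxic / %d normoxic cells",
                      type, length(h), length(n)))
      next
    }
    X <- as.matrix(m$values[genes, c(h, n), drop = FALSE])
    res <- wilcox_by_gene(X, c(rep(TRUE, length(h)), rep(FALSE, length(n))))
    res$fdr <- stats::p.adjust(res$p_value, method = "BH")
    keep <- res$fdr < fdr & res$log2fc > lfc
    if (any(keep)) {
      hit <- res[keep, , drop = FALSE]
      out[[type]] <- data.frame(cell_type = type, gene = hit$gene,
                                log2fc = hit$log2fc, p_value = hit$p_value,
                                fdr = hit$fdr, direction = "up",
                                stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    warning("no cell-type-specific signature genes pass the thresholds")
    return(structure(data.frame(cell_type = character(), gene = character(),
                                log2fc = numeric(), p_value = numeric(),
                                fdr = numeric(), direction = character(),
                                stringsAsFactors = FALSE),
                     class = c("SignatureTable", "data.frame")))
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  structure(tbl, class = c("SignatureTable", "data.frame"))
}

#' Serialize a trained ensemble to a directory
#'
#' Writes `model.json` (weights, fold map, seeds, feature panel, training
#' parameters) plus one UBJSON booster file per member.
#'
#' @param model `EnsembleModel`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "EnsembleModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(n_members = model$n_members, k_folds = model$k_folds,
               weights = model$weights, fold_map = model$fold_map,
               seeds = model$seeds, params = model$params,
               nrounds = model$nrounds,
               feature_genes = model$feature_genes)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"),
             file.path(dir, "model.json"))
  for (t in seq_along(model$members))
    writeBin(model$members[[t]], file.path(dir, sprintf("member_%03d.ubj", t)))
  invisible(dir)
}

#' Load an ensemble serialized by [save_ensemble()]
#' @param dir model directory.
#' @return `EnsembleModel`.
#' @export
load_ensemble <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) stop("no model.json under ", dir)
  meta <- jsonlite::fromJSON(readLines(meta_path))
  members <- lapply(seq_len(meta$n_members), function(t) {
    f <- file.path(dir, sprintf("member_%03d.ubj", t))
    readBin(f, "raw", n = file.size(f))
  })
  panel <- as.data.frame(meta$feature_genes, stringsAsFactors = FALSE)
  structure(list(members = members, weights = meta$weights,
                 fold_map = meta$fold_map, seeds = meta$seeds,
                 feature_genes = structure(panel,
                                           class = c("FeaturePanel", "data.frame")),
                 k_folds = meta$k_folds, n_members = meta$n_members,
                 params = meta$params, nrounds = meta$nrounds),
            class = "EnsembleModel")
}

#' Combine consensus labels with ensemble predictions
#'
#' High-confidence cells keep their consensus label; cells the consensus left
#' unclassified take the ensemble's vote.
#'
#' @param labels `HighConfidenceLabels`.
#' @param voting `VotingResult` covering (at least) the unclassified cells.
#' @return data frame `cell_id`, `status` (hypoxic/normoxic), `source`
#'   (consensus/predicted), `voting_rate` (NA for consensus cells).
#' @export
final_status <- function(labels, voting) {
  v <- stats::setNames(voting$voting_rate, voting$cell_id)
  ps <- stats::setNames(as.character(voting$status), voting$cell_id)
  unc <- labels$status == "unclassified"
  missing <- labels$cell_id[unc][!labels$cell_id[unc] %in% names(ps)]
  if (length(missing))
    stop("unclassified cells without a vote: ",
         paste(utils::head(missing, 5), collapse = ", "))
  status <- as.character(labels$status)
  status[unc] <- ps[labels$cell_id[unc]]
  data.frame(cell_id = labels$cell_id,
             status = factor(status, levels = c("hypoxic", "normoxic")),
             source = ifelse(unc, "predicted", "consensus"),
             voting_rate = ifelse(unc, v[labels$cell_id], NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}
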