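#' Per-cell hypoxia score from a gene signature
#'
#' Mean of per-gene z-scored log-normalized expression over the signature
#' genes. A gene constant across cells has no z-score; it contributes 0 to
#' every cell. When all signature genes are non-degenerate the scores average
#' to 0 across cells by construction.
#'
#' @param m lognorm [ExpressionMatrix()].
#' @param genes signature gene symbols (matched after uppercasing).
#' @return Named numeric vector, one score per cell.
#' @export
hypoxia_score <- function(m, genes) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  hit <- m$gene_ids[toupper(m$gene_ids) %in% toupper(genes)]
  if (!length(hit))
    stop("no signature gene present in the expression matrix")
  X <- as.matrix(m$values[hit, , drop = FALSE])
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  Z <- (X - mu) / ifelse(s == 0, 1, s)
  Z[s == 0, ] <- 0
  stats::setNames(colMeans(Z), m$cell_ids)
}

#' Copy-number-alteration score per cell
#'
#' The quadratic sum over regions of each cell's inferred CNV values:
#' score(cell) = sum_r value[r, cell]^2. Non-negative, zero only for an
#' all-zero profile, invariant to region order.
#'
#' @param cnv regions x cells numeric matrix.
#' @return Named numeric vector of per-cell scores.
#' @export
cna_score <- function(cnv) {
  cnv <- as.matrix(cnv)
  if (nrow(cnv) == 0) stop("empty region set")
  if (any(!is.finite(cnv))) stop("CNV values must be finite")
  stats::setNames(colSums(cnv^2), colnames(cnv))
}

#' Prognostic risk score
#'
#' Linear combination of per-patient gene expression weighted by externally
#' fitted survival-regression coefficients:
#' risk(patient) = sum_i coef_i * expr[gene_i, patient].
#'
#' @param expr genes x patients numeric matrix.
#' @param model list with `genes` (character) and `coefficients` (numeric,
#'   same length, finite).
#' @return Named numeric vector of per-patient risk scores.
#' @export
risk_score <- function(expr, model) {
  stopifnot(is.list(model), length(model$genes) == length(model$coefficients))
  if (anyDuplicated(model$genes)) stop("duplicate model genes")
  if (any(!is.finite(model$coefficients))) stop("non-finite coefficients")
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing))
    stop("model gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(expr[model$genes, , drop = FALSE])
  stats::setNames(as.numeric(crossprod(X, model$coefficients)), colnames(expr))
}

#' Split patients into risk groups at the median score
#'
#' `high_risk` iff score > median; a score exactly equal to the median goes to
#' `low_risk`. With an even number of distinct scores the split is exactly
#' half/half (e.g. 518 distinct scores give 259 per group).
#'
#' @param scores named numeric vector of per-patient risk scores (>= 2).
#' @return Named factor with levels `high_risk`, `low_risk`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 patients")
  med <- stats::median(scores)
  grp <- ifelse(scores > med, "high_risk", "low_risk")
  if (all(grp == "low_risk") && length(unique(scores)) == 1)
    warning("all scores equal: every patient assigned low_risk")
  factor(grp, levels = c("high_risk", "low_risk"))
}

# signed maximum deviation of the weighted-KS enrichment walk
ks_enrichment <- function(ranked_genes, weights, set) {
  member <- toupper(ranked_genes) %in% toupper(set)
  n_in <- sum(member)
  G <- length(ranked_genes)
  if (n_in == 0) stop("set has no gene in the ranking")
  if (n_in == G) stop("set covers the whole ranking")
  w <- abs(weights)
  p_hit <- cumsum(w * member) / sum(w * member)
  p_miss <- cumsum(!member) / (G - n_in)
  d <- p_hit - p_miss
  d[which.max(abs(d))]
}

#' Weighted connectivity score (WTCS)
#'
#' Enrichment of an up-set and a down-set against a ranked signature using
#' the weighted Kolmogorov-Smirnov statistic (weights = |rank statistic|, or
#' rank magnitude G..1 when only an ordering is supplied). When the two
#' enrichment scores have opposite signs, WTCS = (ES_up - ES_down) / 2;
#' when they share a sign the signature is called unrelated and WTCS = 0.
#' Always in [-1, 1] and antisymmetric under swapping the two sets.
#'
#' @param ranking character vector of genes ordered most up-regulated first,
#'   or a data frame with columns `gene` and `statistic` (descending).
#' @param up_set,down_set disjoint gene sets, each non-empty after
#'   intersection with the ranking.
#' @return Single numeric score in [-1, 1].
#' @export
wtcs <- function(ranking, up_set, down_set) {
  if (is.data.frame(ranking)) {
    genes <- as.character(ranking$gene)
    weights <- as.numeric(ranking$statistic)
  } else {
    genes <- as.character(ranking)
    weights <- rev(seq_along(genes))   # rank magnitude G..1
  }
  if (length(intersect(toupper(up_set), toupper(down_set))))
    stop("up_set and down_set overlap")
  es_up <- ks_enrichment(genes, weights, up_set)
  es_down <- ks_enrichment(genes, weights, down_set)
  if (sign(es_up) == sign(es_down)) return(0)
  (es_up - es_down) / 2
}

#' Drug-TF association filter
#'
#' Spearman correlation between each transcription factor's expression and
#' each drug's AUC across shared cell lines, Benjamini-Hochberg FDR over all
#' tested pairs, retaining |rho| > `cor_min` AND FDR < `fdr_max` (both
#' strict). With the AUC convention (lower AUC = more sensitive), rho < 0 is
#' reported as `sensitivity` and rho > 0 as `resistance`.
#'
#' @param tf_expr TFs x cell-lines numeric matrix.
#' @param drug_auc drugs x cell-lines numeric matrix.
#' @param cor_min,fdr_max retention thresholds (defaults 0.3 and 0.05).
#' @param min_lines minimum shared cell lines per pair (default 3).
#' @return data frame `tf`, `drug`, `rho`, `p_value`, `fdr`, `direction`.
#' @export
drug_tf_associations <- function(tf_expr, drug_auc, cor_min = 0.3,
                                 fdr_max = 0.05, min_lines = 3L) {
  shared <- intersect(colnames(tf_expr), colnames(drug_auc))
  if (length(shared) < min_lines)
    stop("fewer than ", min_lines, " shared cell lines")
  tf_expr <- as.matrix(tf_expr[, shared, drop = FALSE])
  drug_auc <- as.matrix(drug_auc[, shared, drop = FALSE])
  rows <- list(); skipped <- 0L
  for (tf in rownames(tf_expr)) {
    for (dr in rownames(drug_auc)) {
      x <- tf_expr[tf, ]; y <- drug_auc[dr, ]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_lines || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        skipped <- skipped + 1L
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rows[[paste(tf, dr)]] <- data.frame(tf = tf, drug = dr,
                                          rho = unname(ct$estimate),
                                          p_value = ct$p.value,
                                          stringsAsFactors = FALSE)
    }
  }
  if (skipped) warning(skipped, " pair(s) skipped (constant or too few values)")
  if (!length(rows)) {
    warning("no testable TF-drug pair")
    return(data.frame(tf = character(), drug = character(), rho = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  tbl <- do.call(rbind, rows)
  tbl$fdr <- stats::p.adjust(tbl$p_value, method = "BH")
  keep <- abs(tbl$rho) > cor_min & tbl$fdr < fdr_max
  tbl <- tbl[keep, , drop = FALSE]
  tbl$direction <- ifelse(tbl$rho < 0, "sensitivity", "resistance")
  rownames(tbl) <- NULL
  tbl
}
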