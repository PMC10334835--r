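#' ssGSEA score of one gene set in one cell
#'
#' Single-sample gene set enrichment: genes are ranked by expression in
#' descending order (ties broken by lexicographically smaller gene identifier
#' first, so the walk is deterministic); walking down the ranking, the in-set
#' empirical distribution accumulates rank-position weights (G, G-1, ..., 1
#' raised to `alpha`, normalized to 1) while the out-of-set distribution
#' accumulates uniform steps; the score is the sum over ranking positions of
#' the difference between the two running distributions. Because only ranks
#' enter, the score is invariant to any strictly monotone transform of the
#' expression vector.
#'
#' @param expr named numeric vector of expression over all genes of one cell.
#' @param gene_set character vector of gene symbols; matching against
#'   `names(expr)` is exact after uppercasing both sides. The effective set
#'   must be non-empty and must not cover all genes.
#' @param alpha weighting exponent (default 0.25, the canonical ssGSEA value;
#'   `alpha = 0` gives the unweighted Kolmogorov-Smirnov-style walk).
#' @return A single numeric score.
#' @export
ssgsea_cell <- function(expr, gene_set, alpha = 0.25) {
  if (is.null(names(expr))) stop("expr must be a named vector (gene names)")
  member <- toupper(names(expr)) %in% toupper(gene_set)
  n_in <- sum(member)
  G <- length(expr)
  if (n_in == 0) stop("no gene of the set is present in the expression vector")
  if (n_in == G) stop("gene set covers all genes; out-of-set ECDF undefined")
  ord <- order(-expr, names(expr))
  in_walk <- member[ord]
  w <- (G - seq_len(G) + 1)^alpha
  p_in <- cumsum(w * in_walk) / sum(w * in_walk)
  p_out <- cumsum(!in_walk) / (G - n_in)
  sum(p_in - p_out)
}

#' ssGSEA activity scores of every gene set in every cell
#'
#' Applies [ssgsea_cell()] column by column; cells are scored independently
#' (no cross-cell normalization by default).
#'
#' @param m lognorm [ExpressionMatrix()].
#' @param sets [GeneSetCollection()].
#' @param alpha weighting exponent, see [ssgsea_cell()].
#' @param rescale if `TRUE`, min-max rescale each signature's scores to [0, 1]
#'   across cells (parity flag with common implementations; off by default).
#' @return An `ActivityScoreMatrix`: sets x cells numeric matrix with
#'   attribute `alpha`.
#' @export
ssgsea_scores <- function(m, sets, alpha = 0.25, rescale = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm")
    stop("ssgsea_scores expects the lognorm layer; run normalize_expression first")
  if (!length(sets)) stop("empty gene-set collection")
  G <- length(m$gene_ids)
  up_genes <- toupper(m$gene_ids)
  # per-set membership and validity, checked once
  members <- lapply(names(sets), function(nm) {
    mem <- up_genes %in% toupper(sets[[nm]])
    dropped <- sum(!toupper(sets[[nm]]) %in% up_genes)
    if (dropped > 0)
      message(sprintf("set %s: %d signature gene(s) absent from the matrix", nm, dropped))
    if (!any(mem)) stop("set ", nm, ": no gene present in the expression matrix")
    if (all(mem)) stop("set ", nm, ": covers all genes; score undefined")
    mem
  })
  names(members) <- names(sets)
  w_pos <- (G - seq_len(G) + 1)^alpha
  scores <- matrix(NA_real_, nrow = length(sets), ncol = length(m$cell_ids),
                   dimnames = list(names(sets), m$cell_ids))
  for (ci in seq_along(m$cell_ids)) {
    expr <- as.numeric(m$values[, ci])
    ord <- order(-expr, m$gene_ids)
    for (si in seq_along(members)) {
      in_walk <- members[[si]][ord]
      p_in <- cumsum(w_pos * in_walk) / sum(w_pos * in_walk)
      p_out <- cumsum(!in_walk) / (G - sum(in_walk))
      scores[si, ci] <- sum(p_in - p_out)
    }
  }
  if (rescale) {
    rng <- apply(scores, 1, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    scores <- (scores - rng[1, ]) / span
  }
  structure(scores, alpha = alpha, class = c("ActivityScoreMatrix", "matrix", "array"))
}
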