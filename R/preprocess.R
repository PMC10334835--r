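#' Remove genes expressed in too few cells
#'
#' A gene is "expressed" in a cell when its raw count is strictly positive.
#' Genes whose expressing-cell fraction is below `min_cell_fraction` are
#' dropped; a gene expressed in exactly that fraction of cells is retained.
#' Gene order and the cell set are unchanged; the operation is idempotent.
#'
#' @param m raw-counts [ExpressionMatrix()].
#' @param min_cell_fraction minimum fraction of cells (default 0.001, i.e.
#'   genes seen in < 0.1% of cells are removed).
#' @export
filter_genes <- function(m, min_cell_fraction = 0.001) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw_counts")
    stop("filter_genes expects the raw_counts layer, got ", m$layer)
  if (min_cell_fraction < 0 || min_cell_fraction > 1)
    stop("min_cell_fraction must be in [0, 1]")
  n_cells <- length(m$cell_ids)
  n_expr <- if (inherits(m$values, "sparseMatrix"))
    Matrix::rowSums(m$values > 0) else rowSums(m$values > 0)
  keep <- (n_expr / n_cells) >= min_cell_fraction
  if (!any(keep))
    stop("all genes removed at min_cell_fraction = ", min_cell_fraction,
         "; review the threshold")
  ExpressionMatrix(m$values[keep, , drop = FALSE],
                   gene_ids = m$gene_ids[keep], cell_ids = m$cell_ids,
                   layer = "raw_counts")
}

#' Library-size normalization with log transform
#'
#' Per cell, counts are divided by the cell's total count, multiplied by
#' `scale_factor`, then transformed with log(1 + x) (natural log). The zero
#' pattern is preserved exactly and, for every cell, the transformed column
#' satisfies sum(expm1(values)) == scale_factor.
#'
#' @param m raw-counts [ExpressionMatrix()].
#' @param scale_factor library-size target (default 1e4).
#' @return A lognorm-layer [ExpressionMatrix()].
#' @export
normalize_expression <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw_counts")
    stop("normalize_expression expects the raw_counts layer, got ", m$layer)
  totals <- if (inherits(m$values, "sparseMatrix"))
    Matrix::colSums(m$values) else colSums(m$values)
  zero <- totals == 0
  if (any(zero))
    stop("cell(s) with zero total count cannot be normalized: ",
         paste(m$cell_ids[zero], collapse = ", "))
  if (inherits(m$values, "sparseMatrix")) {
    v <- m$values
    # scale columns, then log1p on the non-zero entries (0 maps to 0)
    v@x <- v@x * rep.int(scale_factor / totals, diff(v@p))
    v@x <- log1p(v@x)
  } else {
    v <- log1p(sweep(m$values, 2, totals / scale_factor, "/"))
  }
  ExpressionMatrix(v, gene_ids = m$gene_ids, cell_ids = m$cell_ids,
                   layer = "lognorm")
}
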