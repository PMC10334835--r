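#' Construct an ExpressionMatrix
#'
#' The substrate of every scoring step: a genes x cells numeric matrix with
#' unique gene and cell identifiers and a layer flag recording whether the
#' values are raw counts or log-normalized expression.
#'
#' @param values genes x cells numeric matrix (base matrix or sparse
#'   [Matrix::dgCMatrix-class]). Row/column names, if present, must agree with
#'   `gene_ids` / `cell_ids`.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param layer `"raw_counts"` (non-negative integers/doubles) or `"lognorm"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `gene_ids`, `cell_ids`, `values`, `layer`.
#' @export
ExpressionMatrix <- function(values, gene_ids = rownames(values),
                             cell_ids = colnames(values),
                             layer = c("raw_counts", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (as arguments or dimnames)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids))
    stop(sprintf("dimension mismatch: values is %d x %d but %d gene ids and %d cell ids given",
                 nrow(values), ncol(values), length(gene_ids), length(cell_ids)))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  vals <- if (inherits(values, "sparseMatrix")) values@x else values
  if (layer == "raw_counts" && any(vals < 0))
    stop("raw_counts layer contains negative values")
  if (layer == "lognorm" && any(!is.finite(vals)))
    stop("lognorm layer contains non-finite values")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(gene_ids = gene_ids, cell_ids = cell_ids,
                 values = values, layer = layer),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [%s]%s\n",
              length(x$gene_ids), length(x$cell_ids), x$layer,
              if (inherits(x$values, "sparseMatrix")) " (sparse)" else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# dense numeric column for one cell, named by gene
cell_vector <- function(m, cell) {
  v <- as.numeric(m$values[, cell])
  names(v) <- m$gene_ids
  v
}
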