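#' Read an expression matrix from disk
#'
#' Supports the 10x MatrixMarket triplet layout (a directory holding
#' `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`) and dense
#' CSV/TSV with gene rows, cell columns and a header line of cell identifiers.
#' Duplicated gene symbols are disambiguated deterministically in file order
#' by suffixing `.1`, `.2`, ...
#'
#' @param path directory (for `mtx_dir`) or file path.
#' @param format `"mtx_dir"`, `"csv"` or `"tsv"`.
#' @return A raw-counts [ExpressionMatrix()].
#' @export
read_expression <- function(path, format = c("mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path)
  if (format == "mtx_dir") {
    read_expression_mtx(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    genes <- as.character(tab[[1]])
    num <- tab[, -1, drop = FALSE]
    bad <- which(!vapply(num, is.numeric, logical(1)))
    if (length(bad)) {
      col <- bad[1]
      row <- which(is.na(suppressWarnings(as.numeric(num[[col]]))))[1]
      stop(sprintf("non-numeric value at data row %s, column '%s' of %s",
                   ifelse(is.na(row), "?", row), names(num)[col], path))
    }
    values <- as.matrix(num)
    ExpressionMatrix(values, gene_ids = dedupe_ids(genes),
                     cell_ids = colnames(num), layer = "raw_counts")
  }
}

read_expression_mtx <- function(dir) {
  pick <- function(cands) {
    for (f in cands) if (file.exists(file.path(dir, f))) return(file.path(dir, f))
    stop("MTX triplet incomplete in ", dir, ": none of ",
         paste(cands, collapse = "/"), " found")
  }
  mtx <- pick(c("matrix.mtx", "matrix.mtx.gz"))
  feat <- pick(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  bc <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))
  values <- as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE, stringsAsFactors = FALSE)[[1]]
  # 10x features files carry id, symbol[, type]; score on the symbol if present
  genes <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  if (nrow(values) != length(genes))
    stop(sprintf("MTX format error: matrix declares %d genes but features file lists %d",
                 nrow(values), length(genes)))
  if (ncol(values) != length(barcodes))
    stop(sprintf("MTX format error: matrix declares %d cells but barcodes file lists %d",
                 ncol(values), length(barcodes)))
  ExpressionMatrix(values, gene_ids = dedupe_ids(genes),
                   cell_ids = as.character(barcodes), layer = "raw_counts")
}

# first occurrence keeps its name; later ones get .1, .2 ... in file order
dedupe_ids <- function(ids) {
  ids <- as.character(ids)
  dup <- duplicated(ids)
  if (!any(dup)) return(ids)
  counts <- new.env(parent = emptyenv())
  out <- ids
  for (i in which(dup)) {
    k <- (if (is.null(counts[[ids[i]]])) 0L else counts[[ids[i]]]) + 1L
    counts[[ids[i]]] <- k
    out[i] <- paste0(ids[i], ".", k)
  }
  out
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then gene symbols, all tab-separated.
#' Within-set gene order is preserved; blank lines are skipped.
#'
#' @param path GMT file path.
#' @return A `GeneSetCollection`: a named list of character vectors with a
#'   `provenance` attribute holding each set's description field.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path))
    stop("GMT file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    warning("empty GMT file: ", path)
    return(GeneSetCollection(stats::setNames(list(), character())))
  }
  sets <- list(); prov <- character()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT format error at line %d: %d field(s), need name, description and >= 1 gene",
                   i, length(fields)))
    nm <- fields[1]
    if (nm %in% names(sets))
      stop("duplicate gene-set name in GMT: ", nm)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[nm]] <- unique(genes)
    prov[nm] <- fields[2]
  }
  GeneSetCollection(sets, provenance = prov)
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of character gene vectors; names unique, sets
#'   non-empty, genes unique within a set.
#' @param provenance optional per-set free-text (e.g. GMT description field).
#' @export
GeneSetCollection <- function(sets, provenance = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("gene-set names must be present and unique")
    empty <- names(sets)[lengths(sets) == 0]
    if (length(empty)) stop("empty gene set(s): ", paste(empty, collapse = ", "))
    for (nm in names(sets))
      if (anyDuplicated(sets[[nm]]))
        stop("duplicate genes within set ", nm)
  }
  structure(sets, provenance = provenance, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s)\n", length(x)))
  for (nm in names(x)) cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Write a per-cell label/score table as TSV
#'
#' @param labels data frame with a `cell_id` column plus any label/score
#'   columns; rows are written in input order.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  stopifnot(is.data.frame(labels), "cell_id" %in% names(labels))
  if (nrow(labels) == 0) warning("writing header-only label table: no cells")
  ok <- tryCatch({
    utils::write.table(labels, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write label table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a label/score table written by [write_labels()]
#' @param path TSV file with header.
#' @return data frame in file order.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label table does not exist: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
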