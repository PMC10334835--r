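#' Configuration for the synthetic scRNA-seq generator
#'
#' Defaults describe the study conditions the package is exercised under: a
#' 2,000-cell, 2,000-gene tumor-like dataset over 4 cell types in which 20%
#' of the cells run a 200-gene hypoxia program at log2 fold change 2,
#' negative-binomial counts with moderate overdispersion and log-normal
#' library sizes around 5,000, and 7 hypoxia signatures of 50 genes each
#' drawing 80% of their genes from the planted program.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param n_celltypes number of cell types in the metadata.
#' @param hypoxic_fraction fraction of cells carrying the hypoxia program.
#' @param n_program_genes size of the planted program.
#' @param program_log2fc log2 fold change of program genes in hypoxic cells.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param library_size_mean mean total counts per cell.
#' @param n_signatures,signature_size,signature_program_overlap hypoxia
#'   signature collection shape.
#' @param seed integer seed; identical configs give bit-identical outputs.
#' @return A `GeneratorConfig` list.
#' @export
generator_config <- function(n_cells = 2000L, n_genes = 2000L,
                             n_celltypes = 4L, hypoxic_fraction = 0.2,
                             n_program_genes = 200L, program_log2fc = 2,
                             nb_dispersion = 0.5, library_size_mean = 5000,
                             n_signatures = 7L, signature_size = 50L,
                             signature_program_overlap = 0.8, seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_celltypes = as.integer(n_celltypes),
              hypoxic_fraction = hypoxic_fraction,
              n_program_genes = as.integer(n_program_genes),
              program_log2fc = program_log2fc,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              n_signatures = as.integer(n_signatures),
              signature_size = as.integer(signature_size),
              signature_program_overlap = signature_program_overlap,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cells > 0, n_genes > 0, n_celltypes > 0,
              hypoxic_fraction >= 0, hypoxic_fraction <= 1,
              signature_program_overlap >= 0, signature_program_overlap <= 1,
              nb_dispersion > 0, library_size_mean > 0)
  })
  if (cfg$n_program_genes > cfg$n_genes)
    stop("n_program_genes exceeds n_genes")
  need_nonprog <- cfg$signature_size -
    round(cfg$signature_program_overlap * cfg$signature_size)
  if (need_nonprog > cfg$n_genes - cfg$n_program_genes)
    stop(sprintf(paste("signatures need %d non-program gene(s) but only %d exist;",
                       "increase n_genes or signature_program_overlap"),
                 need_nonprog, cfg$n_genes - cfg$n_program_genes))
  structure(cfg, class = c("GeneratorConfig", "list"))
}

#' Generate a synthetic scRNA-seq dataset with a planted hypoxia program
#'
#' Counts follow a negative-binomial model: per-gene relative abundances are
#' log-normal, per-cell library sizes are log-normal around
#' `library_size_mean`, and in hypoxic cells the program genes' abundances
#' are multiplied by 2^program_log2fc (with renormalization, giving the
#' composition shift real differential programs cause). Hypoxic cells are
#' confined to the "core" region of the metadata; normoxic cells split
#' between core and periphery. Gene signatures draw
#' `signature_program_overlap` of their genes from the program and the rest
#' from non-program genes.
#'
#' @param cfg [generator_config()].
#' @return list with `matrix` (raw-counts [ExpressionMatrix()]), `meta`
#'   (data frame `cell_id`, `cell_type`, `region`, `patient`), `true_status`
#'   (named factor hypoxic/normoxic), `signatures` ([GeneSetCollection()]),
#'   `program_genes`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  cells <- sprintf("CELL%05d", seq_len(cfg$n_cells))

  n_hyp <- round(cfg$hypoxic_fraction * cfg$n_cells)
  status <- rep("normoxic", cfg$n_cells)
  status[sample.int(cfg$n_cells, n_hyp)] <- "hypoxic"
  true_status <- stats::setNames(factor(status, levels = c("hypoxic", "normoxic")),
                                 cells)

  program <- sample(genes, cfg$n_program_genes)
  base_abund <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.2)
  names(base_abund) <- genes
  p_norm <- base_abund / sum(base_abund)
  boosted <- base_abund
  boosted[program] <- boosted[program] * 2^cfg$program_log2fc
  p_hyp <- boosted / sum(boosted)

  lib <- stats::rlnorm(cfg$n_cells,
                       meanlog = log(cfg$library_size_mean) - 0.3^2 / 2,
                       sdlog = 0.3)
  size <- 1 / cfg$nb_dispersion
  counts <- matrix(0L, nrow = cfg$n_genes, ncol = cfg$n_cells,
                   dimnames = list(genes, cells))
  for (ci in seq_len(cfg$n_cells)) {
    p <- if (status[ci] == "hypoxic") p_hyp else p_norm
    counts[, ci] <- stats::rnbinom(cfg$n_genes, mu = lib[ci] * p, size = size)
  }

  types <- sprintf("type%d", sample.int(cfg$n_celltypes, cfg$n_cells, replace = TRUE))
  region <- ifelse(status == "hypoxic", "core",
                   sample(c("core", "periphery"), cfg$n_cells, replace = TRUE))
  patient <- sprintf("P%d", 1 + (seq_len(cfg$n_cells) %% 3))
  meta <- data.frame(cell_id = cells, cell_type = types, region = region,
                     patient = patient, stringsAsFactors = FALSE)

  non_program <- setdiff(genes, program)
  n_from_prog <- round(cfg$signature_program_overlap * cfg$signature_size)
  sets <- lapply(seq_len(cfg$n_signatures), function(i) {
    c(sample(program, min(n_from_prog, length(program))),
      sample(non_program, cfg$signature_size - min(n_from_prog, length(program))))
  })
  names(sets) <- sprintf("HYPOXIA_SIG_%d", seq_len(cfg$n_signatures))

  list(matrix = ExpressionMatrix(counts, layer = "raw_counts"),
       meta = meta, true_status = true_status,
       signatures = GeneSetCollection(sets), program_genes = program)
}

#' Generate a directed TF->target network with planted hub regulators
#'
#' Preferential-attachment-style growth: target nodes arrive one at a time
#' and receive `edges_per_node` incoming edges from TF nodes chosen with
#' probability proportional to current out-degree, with the designated hub
#' TFs given a strong initial attractiveness boost. Hubs therefore end with
#' inflated out-degree and dominate every centrality.
#'
#' @param n_nodes total node count.
#' @param n_hubs number of planted hub TFs (must be < n_nodes).
#' @param edges_per_node incoming edges per target node.
#' @param seed integer seed.
#' @return A `GeneNetwork` with attribute `hubs` naming the planted hubs.
#' @export
generate_network <- function(n_nodes, n_hubs, edges_per_node = 3L, seed = 1L) {
  if (n_hubs >= n_nodes) stop("n_hubs must be smaller than n_nodes")
  set.seed(as.integer(seed))
  genes <- sprintf("TF%03d", seq_len(n_nodes))
  n_tf <- max(n_hubs, ceiling(0.1 * n_nodes), 2L)
  tfs <- genes[seq_len(n_tf)]
  hubs <- if (n_hubs > 0) genes[seq_len(n_hubs)] else character()
  attract <- rep(1, n_tf)
  if (n_hubs > 0) attract[seq_len(n_hubs)] <- 20
  from <- character(0); to <- character(0)
  for (node in genes[-seq_len(n_tf)]) {
    k <- min(edges_per_node, n_tf)
    src <- sample(tfs, k, prob = attract)
    from <- c(from, src); to <- c(to, rep(node, k))
    attract[match(src, tfs)] <- attract[match(src, tfs)] + 1
  }
  net <- gene_network(data.frame(from = from, to = to,
                                 stringsAsFactors = FALSE),
                      tfs = tfs, isolates = genes)
  attr(net, "hubs") <- hubs
  net
}

#' Generate a ranked signature with planted up/down blocks
#'
#' Builds a descending differential statistic over `n_genes` genes, places
#' the up-set at the very top and the down-set at the very bottom of the
#' ranking — the extremal configuration for WTCS tests.
#'
#' @param n_genes ranking length.
#' @param up_block,down_block block sizes; they must fit without overlap.
#' @param seed integer seed.
#' @return list with `ranking` (data frame `gene`, `statistic`), `up_set`,
#'   `down_set`.
#' @export
generate_ranked_signature <- function(n_genes, up_block, down_block, seed = 1L) {
  if (up_block + down_block > n_genes)
    stop("up and down blocks overlap: up_block + down_block > n_genes")
  if (up_block < 1 || down_block < 1) stop("blocks must be non-empty")
  set.seed(as.integer(seed))
  genes <- sprintf("R%04d", seq_len(n_genes))
  stat <- sort(stats::rnorm(n_genes, sd = 2), decreasing = TRUE)
  ranking <- data.frame(gene = genes, statistic = stat,
                        stringsAsFactors = FALSE)
  list(ranking = ranking,
       up_set = genes[seq_len(up_block)],
       down_set = genes[(n_genes - down_block + 1):n_genes])
}

#' Write a generated dataset to disk as MTX + TSV + GMT
#'
#' @param data list from [generate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(data, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sp <- as(Matrix::Matrix(data$matrix$values, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(outdir, "matrix.mtx"))
  writeLines(paste(data$matrix$gene_ids, data$matrix$gene_ids,
                   "Gene Expression", sep = "\t"),
             file.path(outdir, "features.tsv"))
  writeLines(data$matrix$cell_ids, file.path(outdir, "barcodes.tsv"))
  utils::write.table(data$meta, file.path(outdir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_labels(data.frame(cell_id = names(data$true_status),
                          status = as.character(data$true_status),
                          stringsAsFactors = FALSE),
               file.path(outdir, "true_status.tsv"))
  gmt <- vapply(names(data$signatures), function(nm) {
    paste(c(nm, "synthetic hypoxia signature", data$signatures[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(outdir, "signatures.gmt"))
  invisible(outdir)
}
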