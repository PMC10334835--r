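#' Assemble a pipeline run configuration
#'
#' @param matrix_path expression input (MTX directory or dense CSV/TSV); or
#'   NULL when an in-memory `ExpressionMatrix` is passed to [run_pipeline()].
#' @param format expression input format, see [read_expression()].
#' @param gmt_path hypoxia signature GMT file.
#' @param meta_path optional cell metadata TSV (`cell_id`, `cell_type`, ...).
#' @param out_dir output directory.
#' @param min_cell_fraction,scale_factor preprocessing controls.
#' @param alpha ssGSEA exponent.
#' @param seed base seed for GMM fits, fold assignment and undersampling.
#' @param n_features,n_members,k_folds,vote_threshold classifier controls.
#' @param stable_fraction stable-feature member fraction.
#' @param sig_fdr,sig_lfc cell-type signature thresholds.
#' @return A `RunConfig` list.
#' @export
run_config <- function(matrix_path = NULL, format = "mtx_dir",
                       gmt_path = NULL, meta_path = NULL,
                       out_dir = "chpf_out", min_cell_fraction = 0.001,
                       scale_factor = 1e4, alpha = 0.25, seed = 1L,
                       n_features = 500L, n_members = 100L, k_folds = 5L,
                       vote_threshold = 0.5, stable_fraction = 0.9,
                       sig_fdr = 0.05, sig_lfc = 1.5) {
  stopifnot(alpha >= 0, vote_threshold >= 0, vote_threshold <= 1,
            stable_fraction >= 0, stable_fraction <= 1,
            sig_fdr > 0, sig_fdr < 1, n_features > 0,
            n_members > 0, k_folds > 1)
  structure(list(matrix_path = matrix_path, format = format,
                 gmt_path = gmt_path, meta_path = meta_path,
                 out_dir = out_dir, min_cell_fraction = min_cell_fraction,
                 scale_factor = scale_factor, alpha = alpha,
                 seed = as.integer(seed), n_features = as.integer(n_features),
                 n_members = as.integer(n_members),
                 k_folds = as.integer(k_folds),
                 vote_threshold = vote_threshold,
                 stable_fraction = stable_fraction,
                 sig_fdr = sig_fdr, sig_lfc = sig_lfc),
            class = c("RunConfig", "list"))
}

config_hash <- function(cfg) {
  # the hash keys the computation, not its destination: out_dir is excluded
  # so reruns into different directories compare byte-identical
  keyed <- unclass(cfg)
  keyed$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(keyed, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full hypoxia classification pipeline
#'
#' Stages: gene filter, library-size log-normalization, ssGSEA scoring of
#' every signature, per-signature Gaussian-mixture assignment with strict
#' consensus, differential-expression feature selection, recall-weighted
#' ensemble training, voting on the unclassified cells, stable-feature
#' extraction, and (when cell-type metadata is available) cell-type-specific
#' signature tables. Every output TSV carries the config hash in a header
#' comment; a JSON manifest records config, versions and seeds.
#'
#' @param cfg [run_config()].
#' @param matrix optional in-memory raw-counts [ExpressionMatrix()]
#'   (overrides `cfg$matrix_path`).
#' @param sets optional in-memory [GeneSetCollection()] (overrides
#'   `cfg$gmt_path`).
#' @param meta optional in-memory metadata data frame.
#' @param write if `FALSE`, skip writing files and return results only.
#' @return Invisibly, a list with all stage results: `matrix` (lognorm),
#'   `scores`, `hc_labels`, `panel`, `model`, `voting`, `status`,
#'   `stable_genes`, `signatures_table`, `hash`.
#' @export
run_pipeline <- function(cfg, matrix = NULL, sets = NULL, meta = NULL,
                         write = TRUE) {
  stopifnot(inherits(cfg, "RunConfig"))
  hash <- config_hash(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(matrix))
    matrix <- stage("read", read_expression(cfg$matrix_path, cfg$format))
  if (is.null(sets))
    sets <- stage("gene_sets", read_gene_sets(cfg$gmt_path))
  if (is.null(meta) && !is.null(cfg$meta_path))
    meta <- stage("metadata", read_labels(cfg$meta_path))

  filtered <- stage("filter", filter_genes(matrix, cfg$min_cell_fraction))
  norm <- stage("normalize", normalize_expression(filtered, cfg$scale_factor))
  scores <- stage("score", ssgsea_scores(norm, sets, alpha = cfg$alpha))
  hc <- stage("consensus", label_high_confidence(scores, seed = cfg$seed))
  panel <- stage("features", select_deg_features(norm, hc, cfg$n_features))
  model <- stage("train", train_ensemble(norm, hc, panel,
                                         n_members = cfg$n_members,
                                         k_folds = cfg$k_folds,
                                         seed = cfg$seed))
  unclassified <- hc$cell_id[hc$status == "unclassified"]
  voting <- stage("vote",
                  vote(model, norm,
                       cells = if (length(unclassified)) unclassified else norm$cell_ids))
  status <- stage("final_status", final_status(hc, voting))
  stable <- stage("stable_features",
                  withCallingHandlers(
                    stable_features(model, cfg$stable_fraction),
                    warning = function(w) invokeRestart("muffleWarning")))
  sig_tbl <- NULL
  if (!is.null(meta) && "cell_type" %in% names(meta) && length(stable))
    sig_tbl <- stage("signatures",
                     suppressWarnings(
                       cell_type_signatures(norm, status, meta, genes = stable,
                                            fdr = cfg$sig_fdr, lfc = cfg$sig_lfc)))

  res <- list(matrix = norm, scores = scores, hc_labels = hc, panel = panel,
              model = model, voting = voting, status = status,
              stable_genes = stable, signatures_table = sig_tbl, hash = hash,
              config = cfg)
  if (write) write_pipeline_outputs(res, cfg)
  invisible(res)
}

write_tsv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# chpf config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a stage TSV and check its config hash
#' @param path stage TSV written by [run_pipeline()].
#' @param expect_hash if non-NULL, refuse a file whose hash differs.
#' @return data frame.
#' @export
read_stage_tsv <- function(path, expect_hash = NULL) {
  first <- readLines(path, n = 1)
  hash <- sub("^# chpf config_hash=", "", first)
  if (!is.null(expect_hash) && !identical(hash, expect_hash))
    stop("config hash mismatch for ", path, ": output from a different run")
  utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- res$hash
  out <- function(f) file.path(cfg$out_dir, f)
  sc <- data.frame(set = rownames(res$scores),
                   as.data.frame(unclass(res$scores)), check.names = FALSE)
  write_tsv_stamped(sc, out("scores.tsv"), h)
  write_tsv_stamped(res$hc_labels, out("hc_labels.tsv"), h)
  write_tsv_stamped(res$panel, out("features.tsv"), h)
  write_tsv_stamped(res$voting, out("voting.tsv"), h)
  write_tsv_stamped(res$status, out("status.tsv"), h)
  writeLines(res$stable_genes, out("stable_features.txt"))
  if (!is.null(res$signatures_table))
    write_tsv_stamped(res$signatures_table, out("signatures.tsv"), h)
  save_ensemble(res$model, out("model"))
  cfg_rec <- unclass(cfg)
  cfg_rec$out_dir <- NULL   # destination is not part of the keyed computation
  manifest <- list(config = cfg_rec, config_hash = h,
                   n_cells = length(res$matrix$cell_ids),
                   n_genes = length(res$matrix$gene_ids),
                   n_hypoxic_hc = sum(res$hc_labels$status == "hypoxic"),
                   n_normoxic_hc = sum(res$hc_labels$status == "normoxic"),
                   n_unclassified = sum(res$hc_labels$status == "unclassified"),
                   weights = res$model$weights,
                   versions = list(
                     chpf = as.character(utils::packageVersion("chpf")),
                     xgboost = as.character(utils::packageVersion("xgboost")),
                     R = paste(R.version$major, R.version$minor, sep = ".")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             out("manifest.json"))
  invisible(cfg$out_dir)
}
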