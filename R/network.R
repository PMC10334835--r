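#' Construct a gene regulatory network from a TF->target edge list
#'
#' @param edges data frame with columns `from` (TF), `to` (target) and
#'   optionally `weight`; or a TSV path with those columns (header optional
#'   when exactly 2-3 columns).
#' @param tfs optional character vector of genes to flag as transcription
#'   factors; defaults to every gene appearing as an edge source.
#' @param isolates optional genes with no edges to include as nodes.
#' @return A `GeneNetwork`: list with `edges` (data frame) and `nodes`
#'   (data frame `gene`, `is_tf`).
#' @export
gene_network <- function(edges, tfs = NULL, isolates = character()) {
  if (is.character(edges) && length(edges) == 1) {
    if (!file.exists(edges)) stop("edge list does not exist: ", edges)
    if (grepl("\\.graphml$", edges, ignore.case = TRUE)) {
      g <- igraph::read_graph(edges, format = "graphml")
      tab <- igraph::as_data_frame(g, what = "edges")
      names(tab)[1:2] <- c("from", "to")
    } else {
      tab <- utils::read.delim(edges, stringsAsFactors = FALSE)
      if (!all(c("from", "to") %in% names(tab))) {
        tab <- utils::read.delim(edges, header = FALSE, stringsAsFactors = FALSE)
        names(tab) <- c("from", "to", "weight")[seq_len(ncol(tab))]
      }
    }
    edges <- tab
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) removed")
    edges <- edges[!loops, , drop = FALSE]
  }
  genes <- unique(c(edges$from, edges$to, isolates))
  if (is.null(tfs)) tfs <- unique(edges$from)
  structure(list(edges = edges,
                 nodes = data.frame(gene = genes, is_tf = genes %in% tfs,
                                    stringsAsFactors = FALSE)),
            class = "GeneNetwork")
}

as_igraph <- function(net, directed = TRUE) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = net$nodes$gene)
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  g
}

#' Five node-centrality metrics of a gene regulatory network
#'
#' Degree is total (in + out) degree on the directed graph; betweenness and
#' harmonic closeness are computed on the undirected view (harmonic closeness
#' handles disconnected graphs); eigenvector centrality on the undirected
#' view of the largest connected component (0 elsewhere); PageRank on the
#' directed graph with damping 0.85. Edge weights, if present, are ignored:
#' regulatory confidence weights are not shortest-path distances.
#'
#' @param net `GeneNetwork`.
#' @return A `CentralityTable` data frame: `gene`, `is_tf`, `degree`,
#'   `betweenness`, `closeness`, `eigenvector`, `pagerank`.
#' @export
compute_centralities <- function(net) {
  stopifnot(inherits(net, "GeneNetwork"))
  genes <- net$nodes$gene
  if (length(genes) < 2) stop("need at least 2 nodes")
  if (nrow(net$edges) == 0) {
    warning("empty edge set: all centralities are zero")
    tbl <- data.frame(gene = genes, is_tf = net$nodes$is_tf,
                      degree = 0, betweenness = 0, closeness = 0,
                      eigenvector = 0, pagerank = 1 / length(genes),
                      stringsAsFactors = FALSE)
    return(structure(tbl, class = c("CentralityTable", "data.frame")))
  }
  gd <- as_igraph(net, directed = TRUE)
  gu <- as_igraph(net, directed = FALSE)
  deg <- igraph::degree(gd, mode = "all")
  btw <- igraph::betweenness(gu, directed = FALSE)
  clo <- igraph::harmonic_centrality(gu, normalized = TRUE)
  comp <- igraph::components(gu)
  big <- which.max(comp$csize)
  eig <- stats::setNames(numeric(length(genes)), genes)
  sub <- igraph::induced_subgraph(gu, which(comp$membership == big))
  ev <- igraph::eigen_centrality(sub, directed = FALSE)$vector
  eig[names(ev)] <- ev
  pr <- igraph::page_rank(gd, damping = 0.85)$vector
  tbl <- data.frame(gene = genes, is_tf = net$nodes$is_tf,
                    degree = as.numeric(deg[genes]),
                    betweenness = as.numeric(btw[genes]),
                    closeness = as.numeric(clo[genes]),
                    eigenvector = as.numeric(eig[genes]),
                    pagerank = as.numeric(pr[genes]),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(tbl, class = c("CentralityTable", "data.frame"))
}

#' Joint order-statistic probability of sorted rank ratios
#'
#' Given k rank ratios in (0, 1], returns the probability that the order
#' statistics of k independent Uniform(0,1) draws fall jointly below the
#' sorted observed ratios, evaluated by the classical recursion
#' Q = k! * v_k with v_j = sum_i (-1)^(i-1) v_(j-i) r_(k-j+1)^i / i!.
#' Smaller Q means the profile of ranks is jointly more extreme (more
#' central across metrics).
#'
#' @param r numeric vector of rank ratios in (0, 1].
#' @return Probability in (0, 1].
#' @export
q_statistic <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1))
    stop("rank ratios must be finite and in (0, 1]")
  r <- sort(r)
  k <- length(r)
  v <- numeric(k + 1); v[1] <- 1
  for (j in seq_len(k)) {
    i <- seq_len(j)
    v[j + 1] <- sum((-1)^(i - 1) * v[j - i + 1] * r[k - j + 1]^i / factorial(i))
  }
  q <- factorial(k) * v[k + 1]
  min(max(q, .Machine$double.xmin), 1)
}

#' Integrate the five centralities into a Q statistic per node
#'
#' Each metric is converted to a rank (1 = most central, average ranks for
#' ties) and scaled to a rank ratio rank/N; the five ratios per node are
#' integrated with [q_statistic()]. `q_rank` ranks nodes by ascending Q
#' (rank 1 = jointly most central).
#'
#' @param tbl `CentralityTable` from [compute_centralities()].
#' @return The table with added per-metric rank columns plus `q_value` and
#'   `q_rank`.
#' @export
q_statistic_aggregate <- function(tbl) {
  metrics <- c("degree", "betweenness", "closeness", "eigenvector", "pagerank")
  if (!all(metrics %in% names(tbl)))
    stop("centrality columns missing: ",
         paste(setdiff(metrics, names(tbl)), collapse = ", "))
  if (any(!is.finite(as.matrix(tbl[metrics]))))
    stop("non-finite centrality values")
  N <- nrow(tbl)
  ratios <- sapply(metrics, function(mc) rank(-tbl[[mc]], ties.method = "average") / N)
  if (N == 1) ratios <- matrix(ratios, nrow = 1, dimnames = list(NULL, metrics))
  for (mc in metrics) tbl[[paste0("rank_", mc)]] <- ratios[, mc] * N
  tbl$q_value <- apply(ratios, 1, q_statistic)
  tbl$q_rank <- rank(tbl$q_value, ties.method = "average")
  structure(tbl, class = c("CentralityTable", "data.frame"))
}

#' Top-1% critical genes of a network
#'
#' Selects the ceil(top_frac * N) genes with the smallest integrated Q;
#' genes tied at the boundary Q value are all included.
#'
#' @param tbl `CentralityTable` with `q_value` (see [q_statistic_aggregate()]).
#' @param top_frac fraction of nodes to call critical (default 0.01).
#' @param label free-text network label carried into the result.
#' @return A `CriticalGeneSet`: list with `label`, `genes`, `tf_subset`,
#'   `q_values`.
#' @export
critical_genes <- function(tbl, top_frac = 0.01, label = NA_character_) {
  if (!"q_value" %in% names(tbl))
    stop("q_value column missing; run q_statistic_aggregate first")
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  N <- nrow(tbl)
  k <- ceiling(top_frac * N)
  thr <- sort(tbl$q_value)[k]
  sel <- tbl$q_value <= thr
  ord <- order(tbl$q_value[sel], tbl$gene[sel])
  genes <- tbl$gene[sel][ord]
  structure(list(label = label, genes = genes,
                 tf_subset = genes[tbl$is_tf[sel][ord]],
                 q_values = stats::setNames(tbl$q_value[sel][ord], genes)),
            class = "CriticalGeneSet")
}

#' Transcription factors critical in one status but not the other
#'
#' Returns the TFs of the first (e.g. hypoxic-network) critical set that do
#' not appear among the second (reference-network) critical genes.
#'
#' @param critical_h,critical_n `CriticalGeneSet` objects computed with the
#'   same `top_frac`.
#' @return Character vector of status-specific TFs.
#' @export
status_specific_tfs <- function(critical_h, critical_n) {
  stopifnot(inherits(critical_h, "CriticalGeneSet"),
            inherits(critical_n, "CriticalGeneSet"))
  setdiff(critical_h$tf_subset, critical_n$genes)
}
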