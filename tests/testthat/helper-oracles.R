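# Independent oracles and small fixture builders shared across tests.
# Each oracle is written from the definition, not from the package code.

# Brute-force ssGSEA: explicit weighted-ECDF walk down the descending
# ranking, ties broken by lexicographically smaller gene id.
oracle_ssgsea <- function(expr, gene_set, alpha) {
  stopifnot(!is.null(names(expr)))
  df <- data.frame(gene = names(expr), x = as.numeric(expr),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$x, df$gene), ]
  G <- nrow(df)
  inset <- toupper(df$gene) %in% toupper(gene_set)
  score <- 0
  ecdf_in <- 0; ecdf_out <- 0
  w_total <- 0
  for (i in seq_len(G)) if (inset[i]) w_total <- w_total + (G - i + 1)^alpha
  n_out <- sum(!inset)
  for (i in seq_len(G)) {
    if (inset[i]) ecdf_in <- ecdf_in + (G - i + 1)^alpha / w_total
    else ecdf_out <- ecdf_out + 1 / n_out
    score <- score + (ecdf_in - ecdf_out)
  }
  score
}

# Exhaustive betweenness by shortest-path enumeration (unweighted,
# undirected): for every ordered pair (s, t), enumerate ALL shortest paths
# with a depth-limited DFS and credit interior vertices fractionally.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  for (v in 1:n) {  # BFS distances
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in which(adj[u, ] == 1))
        if (dist[v, w] > dist[v, u] + 1) {
          dist[v, w] <- dist[v, u] + 1
          queue <- c(queue, w)
        }
    }
  }
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) { out[[length(out) + 1]] <<- path; return() }
      for (w in which(adj[u, ] == 1))
        if (dist[s, w] == dist[s, u] + 1 && dist[w, t] == dist[u, t] - 1)
          walk(c(path, w))
    }
    if (is.finite(dist[s, t])) walk(s)
    out
  }
  btw <- numeric(n)
  for (s in 1:n) for (t in 1:n) {
    if (s == t || !is.finite(dist[s, t])) next
    paths <- paths_between(s, t)
    if (!length(paths)) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(paths)
    }
  }
  btw / 2  # each unordered pair counted twice
}

# Harmonic closeness (normalized): mean of 1/d(v, u) over u != v.
oracle_harmonic_closeness <- function(adj) {
  n <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  vapply(1:n, function(v) sum(1 / d[v, -v]) / (n - 1), numeric(1))
}

random_connected_graph <- function(n) {
  repeat {
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (stats::runif(1) < 0.4) adj[i, j] <- adj[j, i] <- 1
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g) && sum(adj) > 0) return(adj)
  }
}

# Mann-Whitney AUROC of a score against binary truth
rank_auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  (mean(r[truth == 1]) - (n1 + 1) / 2) / n0
}

# small lognorm ExpressionMatrix from a dense matrix of counts
tiny_lognorm <- function(counts, genes = sprintf("G%02d", seq_len(nrow(counts))),
                         cells = sprintf("C%02d", seq_len(ncol(counts)))) {
  dimnames(counts) <- list(genes, cells)
  normalize_expression(ExpressionMatrix(counts, layer = "raw_counts"))
}

# fabricate a GmmAssignment with prescribed high/low groups
fake_assignment <- function(groups, set_name = "S") {
  structure(list(set_name = set_name,
                 means = c(low = 0, high = 1),
                 variances = c(low = 1, high = 1),
                 mixing_weights = c(low = 0.5, high = 0.5),
                 cell_group = factor(groups, levels = c("high", "low")),
                 posterior_high = ifelse(groups == "high", 0.9, 0.1),
                 loglik = 0, converged = TRUE),
            class = "GmmAssignment")
}

# reduced-scale generator + pipeline config used by most integration tests;
# small enough that one pipeline run takes seconds
small_generator <- function(seed = 1L)
  generator_config(n_cells = 500L, n_genes = 600L, n_celltypes = 3L,
                   n_program_genes = 80L, signature_size = 30L, seed = seed)

small_pipeline <- function(seed = 1L, out_dir = tempfile("chpf")) {
  cfg <- run_config(out_dir = out_dir, seed = seed,
                    n_features = 150L, n_members = 20L, k_folds = 5L)
  d <- generate_dataset(small_generator(seed))
  list(cfg = cfg, data = d,
       res = run_pipeline(cfg, matrix = d$matrix, sets = d$signatures,
                          meta = d$meta, write = !is.null(out_dir)))
}
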