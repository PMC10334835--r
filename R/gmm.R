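#' Two-component Gaussian mixture assignment of activity scores
#'
#' Fits a 1-D two-component Gaussian mixture by expectation-maximization and
#' splits the cells into a high-score and a low-score group. Initialization is
#' k-means-style from the given seed; EM stops when the log-likelihood changes
#' by less than `tol` or after `max_iter` iterations (non-convergence yields a
#' warning and the best iterate, flagged). The "high" component is the one
#' with the larger mean; a cell is assigned "high" when its posterior
#' probability for that component is >= 0.5 (ties to "high").
#'
#' @param scores numeric vector of per-cell scores (>= 4 cells, finite),
#'   optionally named by cell id.
#' @param seed integer seed controlling the initialization.
#' @param set_name optional label carried through to the result.
#' @param tol,max_iter EM stopping controls.
#' @return A `GmmAssignment`: list with `set_name`, `means`, `variances`,
#'   `mixing_weights` (each ordered low, high), `cell_group` (factor
#'   high/low), `posterior_high`, `loglik`, `converged`.
#' @export
fit_gmm_1d <- function(scores, seed, set_name = NA_character_,
                       tol = 1e-6, max_iter = 500L) {
  x <- as.numeric(scores)
  if (length(x) < 4) stop("need at least 4 cells to fit the mixture")
  if (any(!is.finite(x))) stop("scores must be finite")
  if (max(x) == min(x))
    stop("degenerate input: all scores identical; no high/low split exists")
  ids <- if (!is.null(names(scores))) names(scores) else as.character(seq_along(x))

  set.seed(as.integer(seed))
  km <- suppressWarnings(stats::kmeans(x, centers = 2, nstart = 5))
  mu <- as.numeric(km$centers)
  var_floor <- max(stats::sd(x)^2 * 1e-8, .Machine$double.eps)
  s2 <- vapply(1:2, function(k) {
    v <- stats::sd(x[km$cluster == k])^2
    if (!is.finite(v) || v < var_floor) var_floor else v
  }, numeric(1))
  pi_k <- tabulate(km$cluster, 2) / length(x)
  pi_k[pi_k == 0] <- 1e-6
  pi_k <- pi_k / sum(pi_k)

  loglik <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ld <- cbind(log(pi_k[1]) + stats::dnorm(x, mu[1], sqrt(s2[1]), log = TRUE),
                log(pi_k[2]) + stats::dnorm(x, mu[2], sqrt(s2[2]), log = TRUE))
    mx <- pmax(ld[, 1], ld[, 2])
    lse <- mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx))
    ll <- sum(lse)
    resp <- exp(ld - lse)   # n x 2 responsibilities
    if (is.finite(loglik) && abs(ll - loglik) < tol) { converged <- TRUE; loglik <- ll; break }
    loglik <- ll
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(resp * x) / nk
    s2 <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, var_floor)
    pi_k <- nk / length(x)
  }
  if (!converged)
    warning("EM did not converge within ", max_iter,
            " iterations; returning best iterate")

  hi <- which.max(mu); lo <- 3L - hi
  posterior_high <- resp[, hi]
  group <- factor(ifelse(posterior_high >= 0.5, "high", "low"),
                  levels = c("high", "low"))
  names(group) <- ids; names(posterior_high) <- ids
  structure(list(set_name = set_name,
                 means = c(low = mu[lo], high = mu[hi]),
                 variances = c(low = s2[lo], high = s2[hi]),
                 mixing_weights = c(low = pi_k[lo], high = pi_k[hi]),
                 cell_group = group, posterior_high = posterior_high,
                 loglik = loglik, converged = converged),
            class = "GmmAssignment")
}

#' Consensus high-confidence labels across signatures
#'
#' A cell is high-confidence hypoxic only when every signature's mixture
#' assigns it to the high-score group, high-confidence normoxic only when
#' every signature assigns it to the low-score group; any disagreement leaves
#' it unclassified.
#'
#' @param assignments list of `GmmAssignment` objects over identical cell sets
#'   (typically one per hypoxia signature).
#' @return A `HighConfidenceLabels` data frame: `cell_id`, `status` (factor
#'   hypoxic/normoxic/unclassified), `n_high` (signatures voting high).
#' @export
consensus_labels <- function(assignments) {
  if (!length(assignments)) stop("need at least one GmmAssignment")
  cells <- names(assignments[[1]]$cell_group)
  for (a in assignments[-1]) {
    other <- names(a$cell_group)
    if (!setequal(cells, other)) {
      diff <- union(setdiff(cells, other), setdiff(other, cells))
      stop("assignments cover different cell sets; symmetric difference: ",
           paste(utils::head(diff, 10), collapse = ", "),
           if (length(diff) > 10) " ..." else "")
    }
  }
  high <- vapply(assignments,
                 function(a) unname(a$cell_group[cells] == "high"),
                 logical(length(cells)))
  if (is.null(dim(high))) high <- matrix(high, nrow = length(cells))
  n_high <- rowSums(high)
  k <- length(assignments)
  status <- factor(ifelse(n_high == k, "hypoxic",
                          ifelse(n_high == 0, "normoxic", "unclassified")),
                   levels = c("hypoxic", "normoxic", "unclassified"))
  structure(data.frame(cell_id = cells, status = status, n_high = n_high,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("HighConfidenceLabels", "data.frame"))
}

#' Fit one mixture per signature and take the consensus
#'
#' Convenience wrapper: applies [fit_gmm_1d()] to every row of an activity
#' score matrix (one derived seed per signature) and returns
#' [consensus_labels()] of the assignments.
#'
#' @param scores sets x cells matrix from [ssgsea_scores()].
#' @param seed base integer seed; signature i uses `seed + i - 1`.
#' @return A `HighConfidenceLabels` data frame.
#' @export
label_high_confidence <- function(scores, seed) {
  assignments <- lapply(seq_len(nrow(scores)), function(i) {
    fit_gmm_1d(scores[i, ], seed = seed + i - 1L,
               set_name = rownames(scores)[i])
  })
  consensus_labels(assignments)
}
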