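## Markov clustering (MCL). Flow on the graph is simulated on a
## column-stochastic matrix by alternating expansion (matrix powers) and
## inflation (entrywise powers followed by column renormalisation), with
## pruning of tiny entries for sparsity, until the flow matrix stops
## changing. Clusters are read off the limit matrix as the column
## support of each attractor row. Fully deterministic: no randomness,
## fixed iteration order.

#' Markov clustering of a graph
#'
#' @param graph Non-empty undirected [igraph][igraph::graph].
#' @param inflation Inflation exponent (> 1, default 2): larger values
#'   give finer clusters.
#' @param expansion Expansion power (integer >= 2, default 2).
#' @param self_loop_weight Weight added to each diagonal entry before
#'   normalisation (default 1); self-loops stabilise the flow and avoid
#'   period-2 oscillation on bipartite structures.
#' @param prune_threshold Entries below this are zeroed after each
#'   inflation (default 1e-5), then columns are renormalised.
#' @param max_iter Iteration cap (default 200); non-convergence is
#'   reported as a warning and the current matrix interpreted anyway.
#' @param tol Convergence tolerance on the max absolute change of the
#'   flow matrix (default 1e-6).
#' @param min_cluster_size Clusters smaller than this are discarded
#'   (default 2; a single protein is not a complex).
#' @return A list of clusters, each a character vector of protein
#'   identifiers. Overlapping clusters are retained; duplicates removed.
#'   The attribute `colsum_dev` records the largest deviation of any
#'   column sum from 1 observed right after a normalisation step.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2L,
                        self_loop_weight = 1, prune_threshold = 1e-5,
                        max_iter = 200L, tol = 1e-6,
                        min_cluster_size = 2L) {
  if (!igraph::is_igraph(graph) || igraph::vcount(graph) == 0L)
    stop("MCL needs a non-empty graph", call. = FALSE)
  stopifnot(inflation > 1, expansion >= 2L, self_loop_weight >= 0,
            prune_threshold >= 0, max_iter >= 1L, tol > 0)
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))

  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE) * 1.0
  A <- A + Matrix::Diagonal(n, self_loop_weight)
  M <- normalize_columns(A)
  colsum_dev <- attr(M, "colsum_dev")

  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Me <- M
    for (i in seq_len(expansion - 1L)) Me <- Me %*% M
    Me <- methods::as(Me, "CsparseMatrix")
    Me@x <- Me@x^inflation
    Me <- normalize_columns(Me)
    colsum_dev <- max(colsum_dev, attr(Me, "colsum_dev"))
    if (prune_threshold > 0) {
      Me@x[Me@x < prune_threshold] <- 0
      Me <- Matrix::drop0(Me)
      Me <- normalize_columns(Me)
      colsum_dev <- max(colsum_dev, attr(Me, "colsum_dev"))
    }
    delta <- max(abs(Me - M))
    M <- Me
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations; interpreting the current flow matrix",
                    max_iter), call. = FALSE)

  clusters <- interpret_flow(M, nodes, min_cluster_size)
  attr(clusters, "colsum_dev") <- colsum_dev
  attr(clusters, "iterations") <- iter
  clusters
}

## Column-normalise a sparse non-negative matrix; a column that has
## become all-zero (possible after pruning) is reset to its diagonal.
## Records how far column sums were from 1 after the operation.
normalize_columns <- function(m) {
  cs <- Matrix::colSums(m)
  zero <- which(cs == 0)
  if (length(zero)) {
    m[cbind(zero, zero)] <- 1
    cs[zero] <- 1
  }
  m <- m %*% Matrix::Diagonal(x = 1 / cs)
  m <- methods::as(m, "CsparseMatrix")
  attr(m, "colsum_dev") <- max(abs(Matrix::colSums(m) - 1))
  m
}

## Read clusters from the limit flow matrix: each nonzero row is an
## attractor system; its cluster is the set of columns (nodes) whose
## flow ends there. Node order within a cluster is sorted for
## determinism; duplicate clusters collapsed.
interpret_flow <- function(M, nodes, min_cluster_size) {
  Mt <- methods::as(Matrix::t(M), "CsparseMatrix")  # row i support = column i of t(M)
  rs <- Matrix::rowSums(M)
  out <- list()
  for (i in which(rs > 0)) {
    members <- sort(nodes[Mt[, i] != 0])
    if (length(members) < min_cluster_size) next
    key <- paste(members, collapse = "\r")
    if (is.null(out[[key]])) out[[key]] <- members
  }
  unname(out)
}

#' Cluster every subnetwork of a dynamic network
#'
#' Runs [mcl_cluster()] on each non-empty time-point subnetwork and tags
#' each cluster with its source time point.
#'
#' @param dyn A `dynamic_network` from [build_dynamic()].
#' @param ... Passed to [mcl_cluster()].
#' @return A list of length `T`; element `t` is the cluster list of
#'   subnetwork `t` (empty subnetworks give an empty list).
#' @export
cluster_dynamic <- function(dyn, ...) {
  stopifnot(inherits(dyn, "dynamic_network"))
  out <- lapply(seq_along(dyn$subnetworks), function(t) {
    g <- dyn$subnetworks[[t]]
    if (igraph::vcount(g) == 0L) return(list())
    cl <- mcl_cluster(g, ...)
    attr(cl, "source_time") <- dyn$time_labels[t]
    cl
  })
  names(out) <- dyn$time_labels
  out
}

#' Write clusters as a one-complex-per-line file
#'
#' Each line: an optional time label prefix, then tab-separated member
#' identifiers.
#' @param per_time List of cluster lists (as from [cluster_dynamic()]),
#'   or a flat cluster list.
#' @param path Output path.
#' @export
write_clusters <- function(per_time, path) {
  if (length(per_time) && is.character(per_time[[1L]]))
    per_time <- list(per_time)
  lines <- character()
  for (t in seq_along(per_time)) {
    lab <- attr(per_time[[t]], "source_time")
    if (is.null(lab)) lab <- names(per_time)[t]
    if (is.null(lab) || !nzchar(lab)) lab <- sprintf("t%d", t)
    for (cl in per_time[[t]])
      lines <- c(lines, paste(c(lab, cl), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
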