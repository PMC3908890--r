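# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths: plain dense
# matrices, lm(), and explicit loops.

# build an undirected igraph from a 2-column character matrix
graph_from_pairs <- function(pairs) {
  igraph::graph_from_edgelist(pairs, directed = FALSE)
}

# least-squares oracle for the AR design: lm() on the embedded lags
oracle_ar_lm <- function(x, p) {
  E <- stats::embed(x, p + 1L)
  y <- E[, 1L]
  L <- E[, 2L:(p + 1L), drop = FALSE]
  fit <- stats::lm(y ~ L)
  list(coefficients = unname(stats::coef(fit)),
       residual_variance = sum(stats::resid(fit)^2) / length(y))
}

# dense brute-force Markov-flow oracle: same parameters as mcl_cluster
# but base-R dense arithmetic and explicit column loops
oracle_mcl <- function(adj, nodes, inflation = 2, expansion = 2,
                       self_loop = 1, prune = 1e-5, max_iter = 200,
                       tol = 1e-6, min_size = 2) {
  n <- nrow(adj)
  A <- adj + diag(self_loop, n)
  colnorm <- function(m) {
    for (j in seq_len(n)) {
      s <- sum(m[, j])
      if (s == 0) { m[j, j] <- 1; s <- 1 }
      m[, j] <- m[, j] / s
    }
    m
  }
  M <- colnorm(A)
  for (it in seq_len(max_iter)) {
    Me <- M
    for (i in seq_len(expansion - 1)) Me <- Me %*% M
    Me <- Me^inflation
    Me <- colnorm(Me)
    Me[Me < prune] <- 0
    Me <- colnorm(Me)
    d <- max(abs(Me - M))
    M <- Me
    if (d < tol) break
  }
  out <- list()
  for (i in seq_len(n)) {
    if (sum(M[i, ]) == 0) next
    mem <- sort(nodes[M[i, ] > 0])
    if (length(mem) < min_size) next
    out[[paste(mem, collapse = "|")]] <- mem
  }
  unname(out)
}

# canonical form of a cluster list for set-wise comparison
canon_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, paste, character(1L), collapse = "|"))]
}

# graph catalogue for MCL oracle comparison: everything up to 6 nodes
# that exercises the interesting regimes (cliques, paths, cycles, stars,
# bridges, disconnected unions)
graph_catalogue <- function() {
  E <- function(...) do.call(rbind, list(...))
  list(
    single_edge   = E(c("a", "b")),
    path3         = E(c("a", "b"), c("b", "c")),
    path4         = E(c("a", "b"), c("b", "c"), c("c", "d")),
    path6         = E(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"), c("e", "f")),
    triangle      = E(c("a", "b"), c("b", "c"), c("a", "c")),
    square        = E(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")),
    pentagon      = E(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"), c("e", "a")),
    hexagon       = E(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"), c("e", "f"), c("f", "a")),
    star5         = E(c("h", "a"), c("h", "b"), c("h", "c"), c("h", "d"), c("h", "e")),
    k4            = t(combn(letters[1:4], 2)),
    k5            = t(combn(letters[1:5], 2)),
    k23           = E(c("a", "x"), c("a", "y"), c("a", "z"), c("b", "x"), c("b", "y"), c("b", "z")),
    two_triangles = E(c("a", "b"), c("b", "c"), c("a", "c"),
                      c("d", "e"), c("e", "f"), c("d", "f")),
    bridged_triangles = E(c("a", "b"), c("b", "c"), c("a", "c"),
                          c("d", "e"), c("e", "f"), c("d", "f"), c("c", "d")),
    k4_plus_edge  = rbind(t(combn(letters[1:4], 2)), c("e", "f")),
    triangle_tail = E(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d"))
  )
}

# tiny expression matrix builder
expr_matrix <- function(rows, ids = sprintf("g%d", seq_along(rows))) {
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  colnames(m) <- paste0("m", seq_len(ncol(m)))
  m
}
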