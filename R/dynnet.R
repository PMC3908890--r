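## Static PIN handling and the dynamic (per-time-point) subnetworks.
## The subnetwork at time t keeps an interaction (a, b) iff both a and b
## are active at t; proteins with no incident edge at t are excluded.
## Proteins without an expression profile are treated as never active.

#' Read a static protein interaction network from an edge list
#'
#' Accepts two-column TSV/whitespace edge lists (`a b`) or three-column
#' SIF lines (`a type b`). Self-interactions are dropped and duplicated
#' interactions (including reversed pairs) collapsed, as is customary
#' when cleaning PPI downloads.
#'
#' @param path Path to the edge-list file.
#' @param quiet Suppress the count message.
#' @return An undirected simple [igraph][igraph::graph] with protein
#'   identifiers as vertex names.
#' @export
read_pin <- function(path, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty interaction file: returning an empty network", call. = FALSE)
    return(igraph::make_empty_graph(directed = FALSE))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(!lengths(toks) %in% c(2L, 3L))
  if (length(bad))
    stop(sprintf("malformed interaction line %d: %s", bad[1L], lines[bad[1L]]),
         call. = FALSE)
  a <- vapply(toks, `[[`, character(1L), 1L)
  b <- vapply(toks, function(x) x[[length(x)]], character(1L))  # SIF: a type b
  g <- igraph::graph_from_data_frame(data.frame(a, b, stringsAsFactors = FALSE),
                                     directed = FALSE)
  n_raw <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!quiet)
    message(sprintf("PIN: %d proteins, %d interactions (%d self/duplicate lines discarded)",
                    igraph::vcount(g), igraph::ecount(g), n_raw - igraph::ecount(g)))
  g
}

#' Write a network as a two-column edge list
#' @param graph An igraph object with vertex names.
#' @param path Output path.
#' @export
write_pin <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the per-time-point active subnetworks
#'
#' For each time point, keeps the interactions of the static PIN whose
#' two proteins are both active, then drops isolated proteins. Proteins
#' absent from the activity table never appear.
#'
#' @param pin Static PIN ([igraph][igraph::graph]), non-empty.
#' @param activity An `activity_profiles` object from
#'   [activity_matrix()].
#' @return An object of class `dynamic_network`: list with
#'   `subnetworks` (list of `T` igraphs) and `time_labels`.
#' @export
build_dynamic <- function(pin, activity) {
  if (!igraph::is_igraph(pin) || igraph::vcount(pin) == 0L)
    stop("static PIN is empty", call. = FALSE)
  stopifnot(inherits(activity, "activity_profiles"))
  act <- activity$active
  genes <- rownames(act)
  subnets <- lapply(seq_len(ncol(act)), function(t) {
    on_t <- intersect(genes[act[, t]], igraph::V(pin)$name)
    g <- igraph::induced_subgraph(pin, on_t)
    igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  })
  structure(list(subnetworks = subnets,
                 time_labels = colnames(act)),
            class = "dynamic_network")
}

#' @exportS3Method print dynamic_network
print.dynamic_network <- function(x, ...) {
  nv <- vapply(x$subnetworks, function(g) as.integer(igraph::vcount(g)), integer(1L))
  ne <- vapply(x$subnetworks, function(g) as.integer(igraph::ecount(g)), integer(1L))
  cat(sprintf("dynamic_network: %d time-point subnetworks\n", length(nv)))
  cat(sprintf("  nodes: mean %.1f (range %d-%d); edges: mean %.1f (range %d-%d)\n",
              mean(nv), min(nv), max(nv), mean(ne), min(ne), max(ne)))
  invisible(x)
}

#' Summarise a dynamic network as a per-time-point count table
#' @param object A `dynamic_network`.
#' @param ... Unused.
#' @return Data frame `time`, `nodes`, `edges`.
#' @exportS3Method summary dynamic_network
summary.dynamic_network <- function(object, ...) {
  data.frame(time = object$time_labels,
             nodes = vapply(object$subnetworks, function(g) as.integer(igraph::vcount(g)), integer(1L)),
             edges = vapply(object$subnetworks, function(g) as.integer(igraph::ecount(g)), integer(1L)),
             stringsAsFactors = FALSE)
}

#' Write a dynamic network to a directory
#'
#' One edge-list file per time point plus a `summary.tsv` of node/edge
#' counts.
#' @param dyn A `dynamic_network`.
#' @param dir Output directory (created if needed).
#' @export
write_dynamic <- function(dyn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dyn$subnetworks))
    write_pin(dyn$subnetworks[[i]],
              file.path(dir, sprintf("subnetwork_%s.tsv", dyn$time_labels[i])))
  utils::write.table(summary(dyn), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
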