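## Complex evaluation: overlap score, cross-time merging of predicted
## clusters, and sensitivity / specificity / f-measure against a
## benchmark complex set.

#' Overlap score between two protein sets
#'
#' The neighbourhood-affinity score `OS(A, B) = |A n B|^2 / (|A| |B|)`,
#' the standard match criterion for complex prediction: 1 iff the sets
#' are equal, 0 iff disjoint, symmetric. `OS >= 0.2` is the conventional
#' threshold for declaring a prediction to match a known complex.
#'
#' @param a,b Non-empty vectors of protein identifiers (duplicates
#'   ignored).
#' @return A number in `[0, 1]`.
#' @export
overlap_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("overlap score of an empty set is undefined", call. = FALSE)
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Read a benchmark (or predicted) complex file
#'
#' One complex per line, members whitespace- or tab-separated
#' (CYC2008-style). Empty lines skipped; duplicate complexes collapsed.
#'
#' @param path Path to the complex file.
#' @return List of character vectors (sorted members).
#' @export
read_complexes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sets <- lapply(strsplit(trimws(lines), "[ \t]+"), function(x)
    sort(unique(x[nzchar(x)])))
  sets <- sets[lengths(sets) > 0L]
  keys <- vapply(sets, paste, character(1L), collapse = "\r")
  unname(sets[!duplicated(keys)])
}

#' Write a complex set, one complex per line
#' @param complexes List of member vectors.
#' @param path Output path.
#' @export
write_complexes <- function(complexes, path) {
  writeLines(vapply(complexes, paste, character(1L), collapse = "\t"), path)
  invisible(path)
}

#' Merge per-time-point clusters into a single predicted complex set
#'
#' Pools the clusters of all time points, removes exact duplicates, then
#' greedily replaces the pair with the highest overlap score (ties: the
#' earliest pair in pool order) by its union, as long as some pair has
#' `OS >= merge_os`, iterating to a fixpoint. The result has no
#' duplicate complexes and no pair at or above `merge_os`.
#'
#' @param per_time List of cluster lists (one per time point), or a flat
#'   list of clusters.
#' @param merge_os Overlap-score threshold for merging, in (0, 1]
#'   (default 0.8).
#' @return List of character vectors (sorted members).
#' @export
merge_time_clusters <- function(per_time, merge_os = 0.8) {
  stopifnot(merge_os > 0, merge_os <= 1)
  if (length(per_time) && is.character(per_time[[1L]]))
    per_time <- list(per_time)
  pool <- lapply(unlist(per_time, recursive = FALSE), function(x) sort(unique(x)))
  pool <- pool[lengths(pool) > 0L]
  pool <- dedupe_sets(pool)
  if (length(pool) < 2L) return(unname(pool))
  os <- pairwise_os(pool)
  repeat {
    best <- max(os)
    if (best < merge_os) break
    hit <- which(os == best, arr.ind = TRUE)[1L, ]        # earliest pair wins ties
    i <- min(hit); j <- max(hit)
    merged <- sort(union(pool[[i]], pool[[j]]))
    pool <- pool[-c(i, j)]
    os <- os[-c(i, j), -c(i, j), drop = FALSE]
    pool <- c(pool, list(merged))
    pool <- dedupe_sets(pool)
    n <- length(pool)
    if (n < 2L) break
    if (identical(pool[[n]], merged)) {                   # union was new: grow os
      newcol <- vapply(pool[-n], overlap_score, double(1L), merged)
      os <- rbind(cbind(os, newcol), 0)
    } else {
      os <- pairwise_os(pool)                             # union duplicated an entry
    }
  }
  unname(pool)
}

dedupe_sets <- function(sets) {
  keys <- vapply(sets, paste, character(1L), collapse = "\r")
  sets[!duplicated(keys)]
}

## Lower-triangular-filled symmetric OS matrix (diagonal 0 so a set
## never merges with itself).
pairwise_os <- function(sets) {
  n <- length(sets)
  os <- matrix(0, n, n)
  for (j in seq_len(n - 1L))
    for (i in (j + 1L):n)
      os[i, j] <- os[j, i] <- overlap_score(sets[[i]], sets[[j]])
  os
}

#' Evaluate predicted complexes against a benchmark set
#'
#' A known complex is matched when some prediction reaches
#' `OS >= os_threshold`; the count of exactly recovered complexes
#' (`OS = 1`) is also reported. Two metric conventions are available:
#' \describe{
#'   \item{`match_fraction`}{`sn` = matched known / number known;
#'     `sp` = matched predictions / number predicted.}
#'   \item{`brohee`}{complex-wise sensitivity
#'     `sn = sum_c max_p |c n p| / sum_c |c|` and positive predictive
#'     value `sp = sum_p max_c |c n p| / sum_p sum_c |c n p|`.}
#' }
#' `f_measure` is the harmonic mean of `sn` and `sp` (0 when both are 0,
#' or when there are no predictions).
#'
#' @param pred List of predicted complexes (character vectors).
#' @param known List of benchmark complexes; must be non-empty.
#' @param os_threshold Overlap-score match threshold in (0, 1]
#'   (default 0.2).
#' @param metric_mode `"brohee"` (default) or `"match_fraction"`.
#' @return An object of class `eval_report`: `n_predicted`, `n_known`,
#'   `n_matched_known`, `n_matched_known_exact`, `n_matched_predicted`,
#'   `sn`, `sp`, `f_measure`, `os_threshold`, `metric_mode`.
#' @export
evaluate <- function(pred, known, os_threshold = 0.2,
                     metric_mode = c("brohee", "match_fraction")) {
  metric_mode <- match.arg(metric_mode)
  stopifnot(os_threshold > 0, os_threshold <= 1)
  known <- lapply(known, unique)
  pred <- lapply(pred, unique)
  if (length(known) == 0L) stop("benchmark complex set is empty", call. = FALSE)
  if (any(lengths(known) == 0L) || any(lengths(pred) == 0L))
    stop("empty complex in input", call. = FALSE)
  n_p <- length(pred); n_k <- length(known)

  if (n_p == 0L) {
    rep_ <- list(n_predicted = 0L, n_known = n_k, n_matched_known = 0L,
                 n_matched_known_exact = 0L, n_matched_predicted = 0L,
                 sn = 0, sp = 0, f_measure = 0,
                 os_threshold = os_threshold, metric_mode = metric_mode)
    return(structure(rep_, class = "eval_report"))
  }

  inter <- matrix(0L, n_p, n_k)
  for (i in seq_len(n_p))
    for (j in seq_len(n_k))
      inter[i, j] <- length(intersect(pred[[i]], known[[j]]))
  os <- inter^2 / outer(lengths(pred), lengths(known))

  known_best <- apply(os, 2L, max)
  pred_best <- apply(os, 1L, max)
  n_mk <- sum(known_best >= os_threshold)
  n_mk1 <- sum(known_best >= 1 - 1e-12)
  n_mp <- sum(pred_best >= os_threshold)

  if (metric_mode == "match_fraction") {
    sn <- n_mk / n_k
    sp <- n_mp / n_p
  } else {
    sn <- sum(apply(inter, 2L, max)) / sum(lengths(known))
    tot <- sum(inter)
    sp <- if (tot > 0) sum(apply(inter, 1L, max)) / tot else 0
  }
  f <- if (sn + sp > 0) 2 * sn * sp / (sn + sp) else 0
  structure(list(n_predicted = n_p, n_known = n_k,
                 n_matched_known = n_mk, n_matched_known_exact = n_mk1,
                 n_matched_predicted = n_mp,
                 sn = sn, sp = sp, f_measure = f,
                 os_threshold = os_threshold, metric_mode = metric_mode),
            class = "eval_report")
}

#' @exportS3Method print eval_report
print.eval_report <- function(x, ...) {
  cat(sprintf("complex prediction report (%s, OS >= %g)\n",
              x$metric_mode, x$os_threshold))
  cat(sprintf("  predicted: %d   known: %d   matched known: %d (exact: %d)\n",
              x$n_predicted, x$n_known, x$n_matched_known,
              x$n_matched_known_exact))
  cat(sprintf("  Sn = %.3f   Sp = %.3f   f-measure = %.3f\n",
              x$sn, x$sp, x$f_measure))
  invisible(x)
}

#' Write an evaluation report as a one-row TSV
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(unclass(report), stringsAsFactors = FALSE)
  df[c("sn", "sp", "f_measure")] <- lapply(df[c("sn", "sp", "f_measure")],
                                           signif, 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
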