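## Noise filter: a gene is noise when its profile is time-independent
## AND its mean expression is small. Time-dependent genes are never
## flagged, whatever their mean.

#' Flag noisy genes
#'
#' In `absolute` mode a time-independent gene is noise when its mean
#' over all raw time points is strictly below `threshold` (default 0.5,
#' on the scale of the input intensities). In `quantile` mode the
#' time-independent genes are sorted ascending by mean and the lowest
#' `threshold` fraction (default 0.15) is flagged; ties at the boundary
#' are all included.
#'
#' @param screen Data frame from [screen_matrix()].
#' @param expr The expression matrix the screen was run on (means are
#'   taken over all its columns).
#' @param mode `"absolute"` or `"quantile"`.
#' @param threshold Mean cutoff (absolute mode, >= 0) or fraction
#'   (quantile mode, in (0,1)). Defaults 0.5 and 0.15.
#' @return Data frame: `gene_id`, `mean_expression`,
#'   `is_time_independent`, `is_noise`.
#' @export
flag_noise <- function(screen, expr, mode = c("absolute", "quantile"),
                       threshold = NULL) {
  mode <- match.arg(mode)
  validate_expression(expr)
  missing_genes <- setdiff(screen$gene_id, rownames(expr))
  if (length(missing_genes))
    stop("screen results refer to genes absent from the matrix: ",
         paste(utils::head(missing_genes, 3L), collapse = ", "), call. = FALSE)
  means <- rowMeans(expr)[screen$gene_id]
  ti <- screen$label == "time_independent"
  if (mode == "absolute") {
    if (is.null(threshold)) threshold <- 0.5
    if (threshold < 0) stop("absolute threshold must be >= 0", call. = FALSE)
    noise <- ti & means < threshold
  } else {
    if (is.null(threshold)) threshold <- 0.15
    if (threshold <= 0 || threshold >= 1)
      stop("quantile threshold must lie in (0, 1)", call. = FALSE)
    noise <- rep(FALSE, nrow(screen))
    n_ti <- sum(ti)
    n_flag <- floor(threshold * n_ti + 1e-9)
    if (n_flag >= 1L) {
      cut <- sort(means[ti])[n_flag]
      noise <- ti & means <= cut
    }
  }
  data.frame(gene_id = screen$gene_id,
             mean_expression = unname(means),
             is_time_independent = ti,
             is_noise = unname(noise),
             stringsAsFactors = FALSE)
}

#' Drop flagged noise genes from an expression matrix
#'
#' @param expr Expression matrix.
#' @param decisions Data frame from [flag_noise()]; must cover every
#'   gene of `expr`.
#' @param quiet Suppress the count message.
#' @return The matrix without noise genes, row order preserved. Warns
#'   when nothing survives.
#' @export
filter_matrix <- function(expr, decisions, quiet = FALSE) {
  validate_expression(expr)
  idx <- match(rownames(expr), decisions$gene_id)
  if (anyNA(idx))
    stop("no noise decision for gene(s): ",
         paste(utils::head(rownames(expr)[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  keep <- !decisions$is_noise[idx]
  out <- expr[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("all genes flagged as noise; returning an empty matrix",
            call. = FALSE)
  if (!quiet)
    message(sprintf("noise filter: removed %d of %d genes",
                    sum(!keep), nrow(expr)))
  out
}

#' Write a noise-decision table as TSV
#' @param decisions Data frame from [flag_noise()].
#' @param path Output path.
#' @export
write_noise <- function(decisions, path) {
  out <- decisions
  out$mean_expression <- signif(out$mean_expression, 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
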