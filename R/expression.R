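#' Read a gene-by-time expression matrix from TSV
#'
#' The expected layout is one header row, a gene identifier in the first
#' column and one column per time point, in chronological order. When the
#' experiment spans several successive cycles the cycles are concatenated
#' left to right (cycle 1 points, then cycle 2 points, ...).
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene identifiers as row names and one
#'   column per time point.
#' @seealso [write_expression()], [collapse_cycles()]
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression file needs a gene-id column plus at least one time point",
         call. = FALSE)
  ids <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(ids))
    stop("duplicated gene identifiers in expression file", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix with gene row names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr),
                   signif(expr, 6L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression data must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(expr)))
    stop("expression matrix must have gene identifiers as row names",
         call. = FALSE)
  if (any(!is.finite(expr)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  invisible(expr)
}
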