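## Autoregressive screen for time-dependent expression profiles.
##
## A profile x_1..x_M is fitted by an AR(p) model
##   x_m = b0 + b1 x_{m-1} + ... + bp x_{m-p} + e_m,  m = p+1..M
## and by the nested constant model x_m = b0 + e_m on the same response
## window m = p+1..M. Both are maximum-likelihood Gaussian fits, so the
## residual variances use divisor M - p. The likelihood ratio
##   Lambda = (s2_ar / s2_const)^((M-p)/2)
## is monotone in the variance ratio, and
##   F = ((M - 2p - 1)/p) * (s2_const/s2_ar - 1)
## follows F(p, M - 2p - 1) under the constant (time-independent) model.

#' Fit an autoregressive model of a given order to one profile
#'
#' Ordinary least squares on the lagged design matrix, solved by QR
#' factorisation. Rank of the design is checked by singular values
#' (columns are declared dependent below `1e-10` times the largest
#' singular value); a rank-deficient design (e.g. a constant series)
#' yields `rank_ok = FALSE` and no coefficients.
#'
#' @param values Numeric vector, the expression profile in time order.
#' @param order AR order `p`; must satisfy `p <= (M-1)/2` and
#'   `M - 2p - 1 >= 1` so the F-test denominator has positive degrees of
#'   freedom.
#' @return An object of class `ar_fit`: a list with `order`,
#'   `coefficients` (intercept first, then lag-1..lag-p), `residual_variance`
#'   (maximum-likelihood, divisor `M - p`), `n_obs = M - p`, `rank_ok`.
#' @examples
#' fit_ar(c(1, 2, 4, 8, 16), 1)   # exact AR(1): coefficients (0, 2)
#' @export
fit_ar <- function(values, order) {
  values <- check_series(values)
  M <- length(values)
  p <- check_order(order, M)
  E <- stats::embed(values, p + 1L)      # row m-p: (x_m, x_{m-1}, ..., x_{m-p})
  Y <- E[, 1L]
  X <- cbind(1, E[, 2L:(p + 1L), drop = FALSE])
  d <- svd(X, nu = 0L, nv = 0L)$d
  rank_ok <- d[p + 1L] > 1e-10 * d[1L]
  if (!rank_ok) {
    fit <- list(order = p, rank_ok = FALSE, n_obs = M - p)
  } else {
    beta <- qr.coef(qr(X), Y)
    rss <- sum((Y - drop(X %*% beta))^2)
    fit <- list(order = p,
                coefficients = unname(beta),
                residual_variance = rss / (M - p),
                n_obs = M - p,
                rank_ok = TRUE)
  }
  structure(fit, class = "ar_fit")
}

#' Fit the time-independent (constant) model to one profile
#'
#' Models the last `M - p` observations as a constant plus Gaussian
#' noise; the response window matches [fit_ar()] at the same order so the
#' two fits are nested.
#'
#' @inheritParams fit_ar
#' @return An object of class `constant_fit`: `beta0` (mean of the last
#'   `M - p` values), `residual_variance` (ML, divisor `M - p`),
#'   `n_obs`, `order`.
#' @export
fit_constant <- function(values, order) {
  values <- check_series(values)
  M <- length(values)
  p <- check_order(order, M)
  y <- values[(p + 1L):M]
  b0 <- mean(y)
  structure(list(order = p,
                 beta0 = b0,
                 residual_variance = mean((y - b0)^2),
                 n_obs = M - p),
            class = "constant_fit")
}

#' Likelihood-ratio F-test of time dependence at one AR order
#'
#' Compares the AR(p) fit against the nested constant fit on the same
#' response window. Under the constant model the statistic follows
#' `F(p, M - 2p - 1)`. Degenerate cases: a perfect AR fit
#' (`s2_ar = 0 < s2_const`) gives an infinite statistic and p-value 0; a
#' series whose response window is exactly constant (`s2_const = 0`)
#' gives p-value 1 with `degenerate = TRUE`.
#'
#' @param ar An `ar_fit` from [fit_ar()].
#' @param const A `constant_fit` from [fit_constant()] on the same
#'   series and order.
#' @return An object of class `order_test`: `order`, `lambda_ratio`,
#'   `f_stat`, `df` (length-2), `p_value`, `degenerate`.
#' @export
f_test <- function(ar, const) {
  stopifnot(inherits(ar, "ar_fit"), inherits(const, "constant_fit"))
  if (ar$order != const$order || ar$n_obs != const$n_obs)
    stop("AR and constant fits come from different series or orders",
         call. = FALSE)
  if (!isTRUE(ar$rank_ok))
    stop("AR fit is rank-deficient; no test at this order", call. = FALSE)
  p <- ar$order
  M <- ar$n_obs + p
  df1 <- p
  df2 <- M - 2L * p - 1L
  s2 <- ar$residual_variance
  s2c <- const$residual_variance
  if (s2c == 0) {
    # response window constant: both models fit exactly, no evidence either way
    out <- list(order = p, lambda_ratio = 1, f_stat = 0,
                df = c(df1, df2), p_value = 1, degenerate = TRUE)
  } else if (s2 == 0) {
    out <- list(order = p, lambda_ratio = 0, f_stat = Inf,
                df = c(df1, df2), p_value = 0, degenerate = FALSE)
  } else {
    f <- max(0, (df2 / df1) * (s2c / s2 - 1))
    out <- list(order = p,
                lambda_ratio = (s2 / s2c)^((M - p) / 2),
                f_stat = f,
                df = c(df1, df2),
                p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                degenerate = FALSE)
  }
  structure(out, class = "order_test")
}

#' Classify one expression profile as time-dependent or not
#'
#' Runs the F-test at every order `p = 1..p_max` (clipped so each order
#' is testable), skipping rank-deficient orders, and labels the profile
#' time-dependent when the smallest per-order p-value falls below
#' `alpha`. No multiple-testing correction is applied across orders: a
#' single sufficiently small p-value at any order triggers the label.
#'
#' @param values Numeric profile in time order.
#' @param p_max Largest AR order to try (default 6).
#' @param alpha Significance level for the per-order test (default 0.01).
#' @param gene_id Optional identifier carried into the result.
#' @return An object of class `dependence_result`: `gene_id`,
#'   `per_order` (data frame of order, lambda_ratio, f_stat, df1, df2,
#'   p_value), `min_p_value`, `best_order`, `label`
#'   (`"time_dependent"` or `"time_independent"`), `degenerate`.
#' @export
classify_profile <- function(values, p_max = 6L, alpha = 0.01,
                             gene_id = NA_character_) {
  values <- check_series(values)
  stopifnot(length(p_max) == 1L, p_max >= 1L,
            length(alpha) == 1L, alpha > 0, alpha < 1)
  M <- length(values)
  p_hi <- min(as.integer(p_max), (M - 2L) %/% 2L)  # needs M - 2p - 1 >= 1
  if (p_hi < 1L)
    stop("series too short: no testable AR order", call. = FALSE)
  rows <- vector("list", p_hi)
  degenerate <- FALSE
  for (p in seq_len(p_hi)) {
    ar <- fit_ar(values, p)
    if (!ar$rank_ok) next
    ot <- f_test(ar, fit_constant(values, p))
    degenerate <- degenerate || ot$degenerate
    rows[[p]] <- data.frame(order = p, lambda_ratio = ot$lambda_ratio,
                            f_stat = ot$f_stat, df1 = ot$df[1L],
                            df2 = ot$df[2L], p_value = ot$p_value)
  }
  per_order <- do.call(rbind, rows)
  if (is.null(per_order)) {
    # every order rank-deficient (constant series): nothing to test
    res <- list(gene_id = gene_id,
                per_order = data.frame(order = integer(), lambda_ratio = double(),
                                       f_stat = double(), df1 = integer(),
                                       df2 = integer(), p_value = double()),
                min_p_value = 1, best_order = NA_integer_,
                label = "time_independent", degenerate = TRUE)
    return(structure(res, class = "dependence_result"))
  }
  i <- which.min(per_order$p_value)
  minp <- per_order$p_value[i]
  label <- if (!degenerate && minp < alpha) "time_dependent" else "time_independent"
  structure(list(gene_id = gene_id, per_order = per_order,
                 min_p_value = minp, best_order = per_order$order[i],
                 label = label, degenerate = degenerate),
            class = "dependence_result")
}

#' Screen every gene in an expression matrix for time dependence
#'
#' @param expr Numeric gene-by-time matrix with gene row names (all
#'   genes share the same number of time points by construction).
#' @inheritParams classify_profile
#' @param quiet Suppress the summary message.
#' @return A data frame with one row per gene: `gene_id`, `min_p_value`,
#'   `best_order`, `label`, `degenerate`.
#' @export
screen_matrix <- function(expr, p_max = 6L, alpha = 0.01, quiet = FALSE) {
  validate_expression(expr)
  res <- lapply(seq_len(nrow(expr)), function(i)
    classify_profile(expr[i, ], p_max = p_max, alpha = alpha,
                     gene_id = rownames(expr)[i]))
  out <- data.frame(
    gene_id = vapply(res, `[[`, character(1L), "gene_id"),
    min_p_value = vapply(res, `[[`, double(1L), "min_p_value"),
    best_order = vapply(res, `[[`, integer(1L), "best_order"),
    label = vapply(res, `[[`, character(1L), "label"),
    degenerate = vapply(res, `[[`, logical(1L), "degenerate"),
    stringsAsFactors = FALSE)
  if (!quiet) {
    frac <- mean(out$label == "time_dependent")
    message(sprintf("screened %d genes: %.1f%% time-dependent, %.1f%% time-independent",
                    nrow(out), 100 * frac, 100 * (1 - frac)))
  }
  out
}

#' Write a screening table as TSV
#'
#' @param screen Data frame from [screen_matrix()].
#' @param path Output path.
#' @export
write_screen <- function(screen, path) {
  out <- screen
  out$min_p_value <- signif(out$min_p_value, 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_series <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("series too short: need at least 4 observations", call. = FALSE)
  if (any(!is.finite(values)))
    stop("series contains non-finite values", call. = FALSE)
  values
}

check_order <- function(order, M) {
  if (length(order) != 1L || is.na(order) || order < 1L ||
      order > (M - 1) / 2 || M - 2 * order - 1 < 1)
    stop(sprintf("invalid AR order %s for series of length %d", order, M),
         call. = FALSE)
  as.integer(order)
}
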