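## Seeded synthetic data. The generator emulates the shape of a yeast
## metabolic-cycle expression experiment (3 successive cycles x 12 time
## points, positive intensities) and a DIP-style static PIN with planted
## complexes, so every pipeline stage can be exercised without external
## downloads. Three gene classes are produced:
##   * time-dependent: stationary AR(p) fluctuations around a positive
##     mean (partial autocorrelations drawn away from zero, converted to
##     AR coefficients by the Levinson-Durbin recursion, which
##     guarantees stationarity);
##   * time-independent: constant mean (above the noise bound) plus iid
##     Gaussian noise;
##   * noise: constant mean below the noise bound plus small iid noise.
## Planted complexes are dense subgraphs whose member genes share a
## common within-cycle activation window (a spike repeated in every
## cycle), so they survive cycle averaging, activity thresholding and
## network intersection.

#' Specification for the synthetic generator
#'
#' All sizes, ranges and rates used by [gen_expression()] and
#' [gen_benchmark()]. Defaults emulate a 300-gene slice of a
#' metabolic-cycle experiment: 20% time-dependent profiles and about
#' 17% of the remaining profiles below the noise bound, with 12 points
#' per cycle and 3 cycles.
#'
#' @param n_time_dependent,n_time_independent,n_noise Gene counts per
#'   class (defaults 60 / 200 / 40).
#' @param T Time points per cycle (default 12).
#' @param n_cycles Successive cycles (default 3).
#' @param ar_orders Candidate AR orders for time-dependent genes
#'   (default `1:2`).
#' @param pacf_range Magnitude range for the partial autocorrelations of
#'   time-dependent genes (default `c(0.6, 0.9)`); signs are random.
#' @param innovation_sd Innovation standard deviation of the AR genes
#'   (default 0.4).
#' @param td_mean_range Mean level range of time-dependent genes
#'   (default `c(2, 5)`).
#' @param ti_mean_range Mean range of time-independent genes, above the
#'   noise bound (default `c(4, 7)`).
#' @param ti_sd Noise standard deviation of time-independent genes
#'   (default 2.5): large enough that flat genes rarely clear their own
#'   activity threshold.
#' @param noise_mean_bound Upper bound for noise-gene means
#'   (default 0.5, the noise-filter cutoff).
#' @param noise_sd Noise-gene standard deviation (default 0.1).
#' @param n_complexes Number of planted complexes (default 10).
#' @param complex_sizes Candidate sizes for planted complexes
#'   (default `4:8`).
#' @param within_complex_density Edge density inside a planted complex,
#'   in (0, 1] (default 0.9); a spanning ring keeps each complex
#'   connected at any density.
#' @param n_background_edges Random background edges among and towards
#'   non-complex proteins (default 60).
#' @param active_window_length Length of each complex's shared
#'   activation window, in time points per cycle (default 3).
#' @param baseline,spike_height Member expression outside / added inside
#'   the activation window (defaults 1 and 2.5; the spike clears the
#'   k-sigma threshold at `k = 2.5` with margin).
#' @param member_jitter_sd Gaussian jitter on member profiles
#'   (default 0.08).
#' @param seed Optional integer seed; when set, generation is fully
#'   reproducible.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_time_dependent = 60L, n_time_independent = 200L,
                       n_noise = 40L, T = 12L, n_cycles = 3L,
                       ar_orders = 1:2, pacf_range = c(0.6, 0.9),
                       innovation_sd = 0.4, td_mean_range = c(2, 5),
                       ti_mean_range = c(4, 7), ti_sd = 2.5,
                       noise_mean_bound = 0.5, noise_sd = 0.1,
                       n_complexes = 10L, complex_sizes = 4:8,
                       within_complex_density = 0.9,
                       n_background_edges = 60L,
                       active_window_length = 3L,
                       baseline = 1, spike_height = 2.5,
                       member_jitter_sd = 0.08, seed = NULL) {
  spec <- as.list(environment())
  stopifnot(n_time_dependent >= 0, n_time_independent >= 0, n_noise >= 0,
            T >= 2, n_cycles >= 1, all(ar_orders >= 1),
            innovation_sd >= 0, ti_sd >= 0, noise_sd >= 0,
            noise_mean_bound > 0, n_complexes >= 0,
            all(complex_sizes >= 2),
            within_complex_density > 0, within_complex_density <= 1,
            n_background_edges >= 0,
            active_window_length >= 1, active_window_length <= T)
  structure(spec, class = "synth_spec")
}

## Levinson-Durbin: partial autocorrelations -> AR coefficients.
## |pacf| < 1 guarantees the AR polynomial has all roots outside the
## unit circle, i.e. a stationary process.
pacf_to_ar <- function(pacf) {
  a <- numeric(0)
  for (k in pacf) a <- c(a - k * rev(a), k)
  a
}

## One stationary AR(p) series of length M around mean mu, with a
## burn-in so the start is (approximately) drawn from the stationary
## distribution. With zero innovation variance the recursion is run
## deterministically from random initial values (no burn-in), giving a
## decaying transient that an AR(p) fit reproduces exactly.
sim_ar_series <- function(M, mu, phi, sd, burn = 100L) {
  p <- length(phi)
  if (sd == 0) {
    x <- numeric(M)
    x[seq_len(p)] <- stats::rnorm(p, 0, 0.5)
    for (m in (p + 1):M) x[m] <- sum(phi * x[(m - 1):(m - p)])
    return(mu + x)
  }
  n <- M + burn
  x <- numeric(n)
  e <- stats::rnorm(n, 0, sd)
  for (m in seq_len(n)) {
    past <- if (m > p) x[(m - 1):(m - p)]
            else c(rev(x[seq_len(m - 1)]), numeric(p - m + 1))
    x[m] <- sum(phi * past) + e[m]
  }
  mu + x[(burn + 1):n]
}

#' Generate an expression matrix with known gene classes
#'
#' @param spec A [synth_spec()] object.
#' @return List with `expression` (gene-by-time matrix,
#'   `M = n_cycles * T` columns, positive values) and `labels` (data
#'   frame `gene_id`, `class` in time_dependent / time_independent /
#'   noise, `ar_order`).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  M <- spec$n_cycles * spec$T
  n <- spec$n_time_dependent + spec$n_time_independent + spec$n_noise
  ids <- sprintf("G%04d", seq_len(n))
  cls <- rep(c("time_dependent", "time_independent", "noise"),
             c(spec$n_time_dependent, spec$n_time_independent, spec$n_noise))
  ord <- rep(NA_integer_, n)
  expr <- matrix(0, n, M, dimnames = list(ids, paste0("m", seq_len(M))))
  for (i in seq_len(n)) {
    expr[i, ] <- switch(cls[i],
      time_dependent = {
        p <- if (length(spec$ar_orders) == 1L) spec$ar_orders
             else sample(spec$ar_orders, 1L)
        ord[i] <- p
        pacf <- stats::runif(p, spec$pacf_range[1L], spec$pacf_range[2L]) *
          sample(c(-1, 1), p, replace = TRUE)
        mu <- stats::runif(1L, spec$td_mean_range[1L], spec$td_mean_range[2L])
        sim_ar_series(M, mu, pacf_to_ar(pacf), spec$innovation_sd)
      },
      time_independent = stats::runif(1L, spec$ti_mean_range[1L],
                                      spec$ti_mean_range[2L]) +
        stats::rnorm(M, 0, spec$ti_sd),
      noise = stats::runif(1L, 0.05, spec$noise_mean_bound - 0.05) +
        stats::rnorm(M, 0, spec$noise_sd))
  }
  expr <- pmax(expr, 0.01)          # intensities are positive
  list(expression = expr,
       labels = data.frame(gene_id = ids, class = cls, ar_order = ord,
                           stringsAsFactors = FALSE))
}

#' Generate a PIN benchmark with planted complexes and coupled expression
#'
#' Plants `n_complexes` dense subgraphs whose member genes carry an
#' expression spike during a shared within-cycle window, embeds them in
#' a background of time-independent and noise genes connected by random
#' edges, and returns everything a full pipeline run needs.
#'
#' @param spec A [synth_spec()] object.
#' @return List with `pin` (igraph), `complexes` (list of member sets,
#'   the ground truth), `expression` (raw gene-by-time matrix covering
#'   every protein), `labels` (data frame `gene_id`, `role`, `complex`,
#'   `window_start`), and `activity_truth` (logical gene-by-time matrix
#'   of the planted activation windows on the collapsed time axis).
#' @export
gen_benchmark <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  T_ <- spec$T
  M <- spec$n_cycles * T_
  w <- spec$active_window_length

  sizes <- sample(rep(spec$complex_sizes, length.out = max(spec$n_complexes, 1L)))
  sizes <- sizes[seq_len(spec$n_complexes)]
  n_members <- sum(sizes)
  n_bg <- spec$n_time_independent + spec$n_noise
  n <- n_members + n_bg
  ids <- sprintf("P%04d", seq_len(n))
  member_ids <- ids[seq_len(n_members)]
  bg_ids <- ids[setdiff(seq_len(n), seq_len(n_members))]
  ti_ids <- bg_ids[seq_len(spec$n_time_independent)]
  noise_ids <- setdiff(bg_ids, ti_ids)

  complexes <- split(member_ids, rep(seq_along(sizes), sizes))
  complexes <- lapply(unname(complexes), sort)

  ## expression + truth windows
  expr <- matrix(0, n, M, dimnames = list(ids, paste0("m", seq_len(M))))
  truth <- matrix(FALSE, n, T_, dimnames = list(ids, paste0("t", seq_len(T_))))
  win_start <- rep(NA_integer_, n)
  role <- rep(NA_character_, n)
  cx_of <- rep(NA_integer_, n)
  for (cx in seq_along(complexes)) {
    start <- sample.int(T_ - w + 1L, 1L)
    window <- start:(start + w - 1L)
    in_window <- rep(seq_len(T_) %in% window, spec$n_cycles)
    for (id in complexes[[cx]]) {
      i <- match(id, ids)
      expr[i, ] <- spec$baseline + spec$spike_height * in_window +
        stats::rnorm(M, 0, spec$member_jitter_sd)
      truth[i, window] <- TRUE
      win_start[i] <- start
      role[i] <- "complex_member"
      cx_of[i] <- cx
    }
  }
  for (id in ti_ids) {
    i <- match(id, ids)
    expr[i, ] <- stats::runif(1L, spec$ti_mean_range[1L], spec$ti_mean_range[2L]) +
      stats::rnorm(M, 0, spec$ti_sd)
    role[i] <- "background_ti"
  }
  for (id in noise_ids) {
    i <- match(id, ids)
    expr[i, ] <- stats::runif(1L, 0.05, spec$noise_mean_bound - 0.05) +
      stats::rnorm(M, 0, spec$noise_sd)
    role[i] <- "background_noise"
  }
  expr <- pmax(expr, 0.01)

  ## edges: dense within complexes (spanning ring + random extras), plus
  ## random background edges that avoid intra-complex pairs
  edges <- list()
  for (cx in complexes) {
    s <- length(cx)
    ring <- cbind(cx, cx[c(2:s, 1L)])
    all_pairs <- t(utils::combn(cx, 2L))
    key <- function(m) paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
    extra <- all_pairs[!(key(all_pairs) %in% key(ring)), , drop = FALSE]
    n_target <- ceiling(spec$within_complex_density * nrow(all_pairs))
    n_extra <- max(0L, min(nrow(extra), n_target - s))
    if (n_extra > 0L)
      extra <- extra[sample.int(nrow(extra), n_extra), , drop = FALSE]
    else extra <- extra[0L, , drop = FALSE]
    edges[[length(edges) + 1L]] <- rbind(ring, extra)
  }
  intra_keys <- unlist(lapply(complexes, function(cx) {
    p <- t(utils::combn(cx, 2L))
    paste(pmin(p[, 1L], p[, 2L]), pmax(p[, 1L], p[, 2L]))
  }))
  bg_edges <- matrix(character(0), 0L, 2L)
  seen <- character(0)
  guard <- 0L
  while (nrow(bg_edges) < spec$n_background_edges && guard < 50L * spec$n_background_edges) {
    guard <- guard + 1L
    pair <- sort(sample(ids, 2L))
    k <- paste(pair[1L], pair[2L])
    if (k %in% seen || k %in% intra_keys) next
    seen <- c(seen, k)
    bg_edges <- rbind(bg_edges, pair)
  }
  if (nrow(bg_edges) < spec$n_background_edges)
    stop("infeasible background edge count for this protein pool", call. = FALSE)
  el <- do.call(rbind, c(edges, list(bg_edges)))
  pin <- igraph::simplify(igraph::graph_from_data_frame(
    data.frame(a = el[, 1L], b = el[, 2L], stringsAsFactors = FALSE),
    directed = FALSE, vertices = ids))

  list(pin = pin,
       complexes = complexes,
       expression = expr,
       labels = data.frame(gene_id = ids, role = role, complex = cx_of,
                           window_start = win_start, stringsAsFactors = FALSE),
       activity_truth = truth)
}
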