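## End-to-end orchestration: screen -> noise filter -> cycle collapse ->
## activity -> dynamic network -> MCL per time point -> cross-time merge
## -> evaluation. Deterministic for fixed inputs and config.

#' Pipeline configuration
#'
#' Inputs may be file paths (expression TSV, PIN edge list, benchmark
#' complex file) or in-memory objects (matrix, igraph, list of member
#' vectors). Defaults follow the study settings: `p_max = 6`,
#' `alpha = 0.01`, absolute noise threshold 0.5, `k = 2.5`
#' (`tau = 0.7` for the global-threshold comparison mode),
#' `OS >= 0.2` for evaluation.
#'
#' @param expression Expression matrix or TSV path (required).
#' @param pin Static PIN igraph or edge-list path (required).
#' @param benchmark Benchmark complexes (list or path), or `NULL` to
#'   skip evaluation.
#' @param outdir Directory for stage artifacts, or `NULL` to keep
#'   everything in memory.
#' @param p_max,alpha AR screen settings.
#' @param noise_mode,noise_threshold Noise-filter settings (see
#'   [flag_noise()]).
#' @param n_cycles Cycles to collapse (see [collapse_cycles()]).
#' @param activity_mode,k,tau Activity-calling settings (see
#'   [activity_matrix()]).
#' @param inflation,expansion,self_loop_weight,prune_threshold,max_iter,tol,min_cluster_size
#'   MCL settings (see [mcl_cluster()]).
#' @param merge_os Cross-time merge threshold (see
#'   [merge_time_clusters()]).
#' @param os_threshold,metric_mode Evaluation settings (see
#'   [evaluate()]).
#' @param seed Optional seed recorded in the manifest (the pipeline
#'   itself is deterministic; the seed matters when the inputs were
#'   generated).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, pin, benchmark = NULL, outdir = NULL,
                            p_max = 6L, alpha = 0.01,
                            noise_mode = "absolute", noise_threshold = 0.5,
                            n_cycles = 3L,
                            activity_mode = "ksigma", k = 2.5, tau = 0.7,
                            inflation = 2, expansion = 2L,
                            self_loop_weight = 1, prune_threshold = 1e-5,
                            max_iter = 200L, tol = 1e-6,
                            min_cluster_size = 2L,
                            merge_os = 0.8, os_threshold = 0.2,
                            metric_mode = "brohee", seed = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A list of class `nfapin_run` with every stage's output:
#'   `screen`, `noise`, `expression_filtered`, `expression_collapsed`,
#'   `activity`, `network`, `clusters` (per time point), `complexes`
#'   (merged predictions), `report` (or `NULL` when no benchmark),
#'   `n_active_pairs`, `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  expr <- if (is.character(cfg$expression)) read_expression(cfg$expression)
          else { validate_expression(cfg$expression); cfg$expression }
  pin <- if (is.character(cfg$pin)) read_pin(cfg$pin, quiet = quiet) else cfg$pin
  benchmark <- cfg$benchmark
  if (is.character(benchmark)) {
    if (file.exists(benchmark)) {
      benchmark <- read_complexes(benchmark)
    } else {
      warning("benchmark file not found: skipping evaluation", call. = FALSE)
      benchmark <- NULL
    }
  }

  screen <- screen_matrix(expr, p_max = cfg$p_max, alpha = cfg$alpha,
                          quiet = quiet)
  noise <- flag_noise(screen, expr, mode = cfg$noise_mode,
                      threshold = cfg$noise_threshold)
  kept <- filter_matrix(expr, noise, quiet = quiet)
  if (nrow(kept) == 0L)
    stop("pipeline stage 'noise_filter': no genes left after filtering",
         call. = FALSE)
  collapsed <- collapse_cycles(kept, n_cycles = cfg$n_cycles)
  act <- activity_matrix(collapsed, mode = cfg$activity_mode,
                         k = cfg$k, tau = cfg$tau)
  dyn <- build_dynamic(pin, act)
  clusters <- cluster_dynamic(dyn,
                              inflation = cfg$inflation,
                              expansion = cfg$expansion,
                              self_loop_weight = cfg$self_loop_weight,
                              prune_threshold = cfg$prune_threshold,
                              max_iter = cfg$max_iter, tol = cfg$tol,
                              min_cluster_size = cfg$min_cluster_size)
  merged <- merge_time_clusters(clusters, merge_os = cfg$merge_os)
  report <- NULL
  if (!is.null(benchmark))
    report <- evaluate(merged, benchmark, os_threshold = cfg$os_threshold,
                       metric_mode = cfg$metric_mode)

  run <- structure(list(screen = screen, noise = noise,
                        expression_filtered = kept,
                        expression_collapsed = collapsed,
                        activity = act, network = dyn,
                        clusters = clusters, complexes = merged,
                        report = report,
                        n_active_pairs = sum(act$active),
                        config = cfg),
                   class = "nfapin_run")
  if (!is.null(cfg$outdir)) write_run(run, cfg$outdir)
  if (!quiet && !is.null(report)) print(report)
  run
}

#' @exportS3Method print nfapin_run
print.nfapin_run <- function(x, ...) {
  cat("nfapin pipeline run\n")
  cat(sprintf("  genes screened: %d (%.1f%% time-dependent), kept after noise filter: %d\n",
              nrow(x$screen),
              100 * mean(x$screen$label == "time_dependent"),
              nrow(x$expression_filtered)))
  cat(sprintf("  active (gene, time) pairs: %d\n", x$n_active_pairs))
  nv <- vapply(x$network$subnetworks, function(g) as.integer(igraph::vcount(g)), integer(1L))
  ne <- vapply(x$network$subnetworks, function(g) as.integer(igraph::ecount(g)), integer(1L))
  cat(sprintf("  subnetworks: %d (mean %.1f nodes, %.1f edges)\n",
              length(nv), mean(nv), mean(ne)))
  cat(sprintf("  predicted complexes after merge: %d\n", length(x$complexes)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

## Write every stage artifact plus a manifest of the configuration.
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_screen(run$screen, file.path(outdir, "screen.tsv"))
  write_noise(run$noise, file.path(outdir, "noise.tsv"))
  write_activity(run$activity, file.path(outdir, "activity.tsv"))
  write_dynamic(run$network, file.path(outdir, "network"))
  write_clusters(run$clusters, file.path(outdir, "clusters.tsv"))
  write_complexes(run$complexes, file.path(outdir, "complexes.tsv"))
  if (!is.null(run$report))
    write_report(run$report, file.path(outdir, "report.tsv"))
  cfg <- run$config
  scalar <- vapply(cfg, function(v) is.null(v) ||
                     (is.atomic(v) && length(v) == 1L), logical(1L))
  keys <- names(cfg)[scalar & names(cfg) != "expression"]
  lines <- c(sprintf("nfapin_version=%s",
                     as.character(utils::packageVersion("nfapin"))),
             vapply(keys, function(k)
               sprintf("%s=%s", k,
                       if (is.null(cfg[[k]])) "" else format(cfg[[k]])),
               character(1L)))
  writeLines(lines, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}

#' Sweep the activity coefficient and the noise mean threshold
#'
#' Reruns noise filtering, activity calling, network construction,
#' clustering, merging and evaluation over a grid of `k` (activity
#' coefficient) and mean thresholds, reusing a single AR screen. Useful
#' for mapping how the f-measure responds to the two filtering knobs.
#'
#' @param config A [pipeline_config()] with a benchmark set.
#' @param k_grid Values of `k` (e.g. `seq(0, 3, 0.1)`).
#' @param mean_grid Values of the absolute noise mean threshold
#'   (e.g. `seq(0, 1, 0.1)`).
#' @param quiet Suppress messages.
#' @return Data frame with one row per grid cell: `k`,
#'   `mean_threshold`, `n_predicted`, `n_matched`, `f_measure`,
#'   `n_active_pairs`.
#' @export
parameter_sweep <- function(config, k_grid, mean_grid, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"),
            length(k_grid) >= 1L, length(mean_grid) >= 1L)
  cfg <- config
  expr <- if (is.character(cfg$expression)) read_expression(cfg$expression)
          else cfg$expression
  pin <- if (is.character(cfg$pin)) read_pin(cfg$pin, quiet = TRUE) else cfg$pin
  benchmark <- if (is.character(cfg$benchmark)) read_complexes(cfg$benchmark)
               else cfg$benchmark
  if (is.null(benchmark)) stop("parameter_sweep needs a benchmark", call. = FALSE)

  screen <- screen_matrix(expr, p_max = cfg$p_max, alpha = cfg$alpha,
                          quiet = TRUE)
  rows <- list()
  for (mth in mean_grid) {
    noise <- flag_noise(screen, expr, mode = "absolute", threshold = mth)
    kept <- suppressWarnings(filter_matrix(expr, noise, quiet = TRUE))
    collapsed <- if (nrow(kept)) collapse_cycles(kept, cfg$n_cycles) else NULL
    for (kk in k_grid) {
      if (is.null(collapsed)) {
        rows[[length(rows) + 1L]] <- data.frame(
          k = kk, mean_threshold = mth, n_predicted = 0L, n_matched = 0L,
          f_measure = 0, n_active_pairs = 0L)
        next
      }
      act <- activity_matrix(collapsed, mode = "ksigma", k = kk)
      dyn <- build_dynamic(pin, act)
      clusters <- cluster_dynamic(dyn,
                                  inflation = cfg$inflation,
                                  expansion = cfg$expansion,
                                  self_loop_weight = cfg$self_loop_weight,
                                  prune_threshold = cfg$prune_threshold,
                                  max_iter = cfg$max_iter, tol = cfg$tol,
                                  min_cluster_size = cfg$min_cluster_size)
      merged <- merge_time_clusters(clusters, merge_os = cfg$merge_os)
      rep_ <- evaluate(merged, benchmark, os_threshold = cfg$os_threshold,
                       metric_mode = cfg$metric_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        k = kk, mean_threshold = mth,
        n_predicted = rep_$n_predicted, n_matched = rep_$n_matched_known,
        f_measure = rep_$f_measure, n_active_pairs = sum(act$active))
      if (!quiet)
        message(sprintf("sweep k=%.2f mean=%.2f -> f=%.3f", kk, mth,
                        rep_$f_measure))
    }
  }
  do.call(rbind, rows)
}
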