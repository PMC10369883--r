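#' Run the full DTU detection pipeline
#'
#' Stages, in order: pre-filter, isoform-fraction transform, empirical null
#' from control splits, significance threshold, per-transcript case
#' partitioning and testing, confounding filter (when covariates are
#' available), binary DTU matrix, SPIT-Chart table. The run is a pure
#' function of its inputs and `params` (including `params$seed`): each
#' stochastic stage draws from a stream derived from the seed and the stage
#' name.
#'
#' @param counts A [spit_count_table()].
#' @param meta A [spit_metadata()].
#' @param params A [spit_params()].
#' @param prefilter_steps Subset of 1:6 of pre-filter steps to apply.
#' @param confound Apply the confounding filter when covariates are present.
#'   With no covariates the stage is skipped with a message and every
#'   candidate kept.
#' @return Object of class `spit_run`: `params`, `filter_report`, `if_table`,
#'   `null`, `threshold`, `partitions`, `results` (per-transcript table with
#'   `confound_flag`), `confound`, `dtu` (the `spit_dtu_matrix`),
#'   `called_genes`, `chart`.
#' @examples
#' \donttest{
#' exp <- make_experiment("splicotype", n_genes = 60, n_samples = 80,
#'                        n_dtu_genes = 10, genes_per_splicotype = 4,
#'                        seed = 1)
#' run <- run_spit(exp$counts, exp$meta,
#'                 spit_params(n_iter = 100, seed = 1))
#' run$called_genes
#' }
#' @export
run_spit <- function(counts, meta, params = spit_params(),
                     prefilter_steps = 1:6, confound = TRUE) {
  filt <- prefilter(counts, meta, params, prefilter_steps)
  if_table <- compute_if(filt$counts)
  null <- build_null(if_table, meta$control_ids, n_iter = params$n_iter,
                     seed = params$seed)
  threshold <- spit_threshold(null, params$kappa)
  partitions <- partition_transcripts(if_table, meta, params)
  results <- test_transcripts(partitions, if_table, meta, threshold)
  pre_dtu <- build_dtu_matrix(results, partitions, meta$case_ids)
  conf <- NULL
  keep <- NULL
  if (confound) {
    if (is.null(meta$covariates) || ncol(meta$covariates) == 0) {
      message("no covariates supplied; confounding stage skipped")
    } else {
      conf <- confound_filter(results, pre_dtu, if_table, meta, params,
                              seed = params$seed)
      keep <- conf$keep
    }
  }
  dtu <- build_dtu_matrix(results, partitions, meta$case_ids, keep)
  dropped <- if (is.null(keep)) character(0) else names(keep)[!keep]
  results$confound_flag <- results$transcript_id %in% dropped
  structure(list(params = params, filter_report = filt$report,
                 filtered_counts = filt$counts, if_table = if_table,
                 null = null, threshold = threshold,
                 partitions = partitions, results = results,
                 confound = conf, dtu = dtu,
                 called_genes = rownames(dtu$M),
                 chart = spit_chart(null, results)),
            class = "spit_run")
}

#' @export
print.spit_run <- function(x, ...) {
  cat("SPIT run\n")
  cat(sprintf("  transcripts tested: %d, threshold p' = %.4g (kappa = %g)\n",
              nrow(x$results), x$threshold, x$params$kappa))
  cat(sprintf("  significant transcripts: %d; DTU genes: %d\n",
              sum(x$results$significant), length(x$called_genes)))
  if (!is.null(x$confound))
    cat(sprintf("  confounding filter dropped %d candidate(s)\n",
                sum(!x$confound$keep)))
  invisible(x)
}

#' Write every result table of a run to a directory
#'
#' Writes: filtered counts, IF table, per-transcript results, DTU matrix,
#' null distribution, SPIT-Chart table, and a run log recording seed,
#' parameter values and per-stage record counts.
#'
#' @param run A `spit_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_spit_results <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_counts(run$filtered_counts, fp("filtered_counts.tsv"))
  write_if_table(run$if_table, fp("if_table.tsv"))
  res <- run$results
  res$m_case <- vapply(run$partitions[res$transcript_id], `[[`, numeric(1),
                       "m_case")
  write.table(res[, c("transcript_id", "gene_id", "m_case", "mode",
                      "p_left", "p_right", "p_min", "significant",
                      "confound_flag")],
              fp("results.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_dtu_matrix(run$dtu, fp("dtu_matrix.tsv"))
  write_null(run$null, fp("null_distribution.tsv"))
  write.table(run$chart, fp("spit_chart.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(run$confound) && nrow(run$confound$summary) > 0) {
    write.table(run$confound$summary, fp("confound_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(run$confound$scores, fp("confound_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- c(
    sprintf("seed\t%d", run$params$seed),
    sprintf("h\t%g", run$params$h),
    sprintf("kappa\t%g", run$params$kappa),
    sprintf("n_small\t%d", run$params$n_small),
    sprintf("n_iter\t%d", run$params$n_iter),
    sprintf("threshold\t%.10g", run$threshold),
    sprintf("transcripts_tested\t%d", nrow(run$results)),
    sprintf("null_entries\t%d", nrow(run$null$entries)),
    sprintf("significant_transcripts\t%d", sum(run$results$significant)),
    sprintf("dtu_genes\t%d", length(run$called_genes)))
  writeLines(log, fp("run_log.tsv"))
  invisible(dir)
}
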