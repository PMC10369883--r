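#' Build simulated experiments for parameter fitting
#'
#' Each experiment splits the control samples into two equal halves to form a
#' pseudo case/control design, applies the pre-filter with the dominance step
#' skipped, and injects splicotype-structured DTU events (with `n_g`
#' splicotypes). Control groups below 32 samples trigger a warning: the
#' fitting experiments are expected to be most informative at that size and
#' above.
#'
#' @param control_counts A [spit_count_table()] holding control samples only.
#' @param params A [spit_params()]; supplies `n_e`, `n_g`, `epsilon` and the
#'   filter settings.
#' @param n_dtu_genes,genes_per_splicotype Injection layout per experiment.
#' @param seed Optional integer; stage stream `"paramfit"`.
#' @return List of `n_e` experiments, each a list `counts`, `meta`, `truth`.
#' @export
build_fit_experiments <- function(control_counts, params = spit_params(),
                                  n_dtu_genes = 100L,
                                  genes_per_splicotype = 30L, seed = NULL) {
  seed_stage(seed, "paramfit")
  n <- length(control_counts$sample_ids)
  if (n < 32)
    warning(sprintf(
      "control group has %d samples; parameter fitting works best with >= 32",
      n))
  if (floor(n / 2) < 2 * params$n_small)
    stop("control group too small to split into halves of >= 2*n_small")
  lapply(seq_len(params$n_e), function(e) {
    perm <- sample(control_counts$sample_ids)
    n_case <- floor(n / 2)
    case_ids <- perm[seq_len(n_case)]
    group <- stats::setNames(
      ifelse(control_counts$sample_ids %in% case_ids, "case", "control"),
      control_counts$sample_ids)
    meta <- spit_metadata(group)
    filt <- prefilter(control_counts, meta, params, enabled_steps = 1:5)
    inj <- inject_dtu(filt$counts, case_ids, n_dtu_genes = n_dtu_genes,
                      n_splicotypes = params$n_g,
                      genes_per_splicotype = genes_per_splicotype,
                      epsilon = params$epsilon, pd = params$pd)
    list(counts = inj$counts, meta = meta, truth = inj$truth)
  })
}

# Gene-level F-score grid for one experiment: the null distribution does not
# depend on h or kappa, the per-transcript minimal p-values depend only on h,
# and each kappa maps to an order statistic of the same null -- so one null
# build and one partition pass per h cover the whole grid.
fit_f_grid <- function(experiment, h_grid, kappa_grid, params, n_iter) {
  if_table <- compute_if(experiment$counts)
  meta <- experiment$meta
  null <- build_null(if_table, meta$control_ids, n_iter = n_iter,
                     retain_p = FALSE)
  thresholds <- vapply(kappa_grid, function(k) spit_threshold(null, k),
                       numeric(1))
  f <- matrix(NA_real_, length(h_grid), length(kappa_grid))
  for (hi in seq_along(h_grid)) {
    p <- params
    p$h <- h_grid[hi]
    partitions <- partition_transcripts(if_table, meta, p)
    res <- test_transcripts(partitions, if_table, meta, NA_real_)
    for (ki in seq_along(kappa_grid)) {
      called <- unique(res$gene_id[res$p_min < thresholds[ki]])
      f[hi, ki] <- score_calls(experiment$truth, called)$f_score
    }
  }
  f
}

#' Fit the bandwidth and threshold hyperparameters by LOOCV
#'
#' Evaluates every `(h, kappa)` grid combination on simulated experiments by
#' leave-one-out cross-validation: for each held-out experiment, the pair
#' maximizing the mean gene-level F-score over the remaining experiments is
#' selected and its F-score on the held-out experiment recorded. The
#' consensus pair is the most frequently selected one; ties prefer the
#' smaller `kappa`, then the smaller `h` (the more conservative setting).
#' The mean held-out F-score estimates the pipeline's overall accuracy on
#' data with this dispersion profile.
#'
#' @param experiments List from [build_fit_experiments()] (>= 2).
#' @param h_grid,kappa_grid Search grids; defaults are `0.02..0.20` by 0.01
#'   and `0.1..1` by 0.1.
#' @param params A [spit_params()].
#' @param n_iter Null iterations per experiment (defaults to
#'   `params$n_iter`).
#' @param seed Optional integer; stage stream `"loocv"`.
#' @return Object of class `spit_fit_result`: `h`, `kappa` (consensus),
#'   `mean_f`, `per_iteration` (data.frame of selected pairs and held-out F),
#'   `f_array` (experiments x h x kappa F-scores).
#' @export
loocv_fit <- function(experiments, h_grid = seq(0.02, 0.20, by = 0.01),
                      kappa_grid = seq(0.1, 1, by = 0.1),
                      params = spit_params(), n_iter = params$n_iter,
                      seed = NULL) {
  if (length(experiments) < 2) stop("need at least 2 experiments for LOOCV")
  seed_stage(seed, "loocv")
  n_e <- length(experiments)
  f_arr <- array(NA_real_, c(n_e, length(h_grid), length(kappa_grid)))
  for (e in seq_len(n_e)) {
    f_arr[e, , ] <- fit_f_grid(experiments[[e]], h_grid, kappa_grid,
                               params, n_iter)
  }
  # pair order: kappa ascending, then h ascending, so that which.max ties
  # resolve to the more conservative setting
  pairs <- expand.grid(hi = seq_along(h_grid), ki = seq_along(kappa_grid))
  pairs <- pairs[order(pairs$ki, pairs$hi), ]
  sel <- data.frame(iteration = seq_len(n_e), h = NA_real_,
                    kappa = NA_real_, f_heldout = NA_real_)
  for (s in seq_len(n_e)) {
    train_mean <- vapply(seq_len(nrow(pairs)), function(r) {
      mean(f_arr[-s, pairs$hi[r], pairs$ki[r]])
    }, numeric(1))
    best <- which.max(train_mean)
    sel$h[s] <- h_grid[pairs$hi[best]]
    sel$kappa[s] <- kappa_grid[pairs$ki[best]]
    sel$f_heldout[s] <- f_arr[s, pairs$hi[best], pairs$ki[best]]
  }
  key <- paste(sel$kappa, sel$h)
  tab <- table(key)
  winners <- names(tab)[tab == max(tab)]
  parts <- do.call(rbind, strsplit(winners, " "))
  ord <- order(as.numeric(parts[, 1]), as.numeric(parts[, 2]))
  win <- parts[ord[1], ]
  structure(list(h = as.numeric(win[2]), kappa = as.numeric(win[1]),
                 mean_f = mean(sel$f_heldout), per_iteration = sel,
                 f_array = f_arr, h_grid = h_grid, kappa_grid = kappa_grid),
            class = "spit_fit_result")
}

#' @export
print.spit_fit_result <- function(x, ...) {
  cat(sprintf(
    "spit_fit_result: consensus (h, kappa) = (%g, %g), mean F = %.3f over %d folds\n",
    x$h, x$kappa, x$mean_f, nrow(x$per_iteration)))
  invisible(x)
}

#' Write a fit result to TSV
#'
#' @param fit A `spit_fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  df <- fit$per_iteration
  df$consensus_h <- fit$h
  df$consensus_kappa <- fit$kappa
  df$mean_f <- fit$mean_f
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
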