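#' Fit a depth-one random forest regressor
#'
#' An ensemble of regression stumps used to judge whether the high/low-IF
#' partition of a candidate DTU transcript is better explained by the DTU
#' indicator or by a covariate. Each tree is trained on a bootstrap of the
#' same size as the input; the split minimizing the L2 loss on the leaf-mean
#' IF is chosen over all features and all midpoint thresholds. A root with
#' fewer than `n_small` samples is not split (the stump predicts the global
#' mean). Ties in split loss are broken conservatively in favour of the
#' later column: a covariate that separates the samples exactly as well as
#' the DTU indicator (the first column) takes the split, so the indicator
#' only accumulates importance it strictly earns.
#'
#' @param X Numeric matrix or data.frame, samples x features; typically the
#'   binary DTU indicator `v` plus the covariates (categoricals already
#'   coded as integers).
#' @param y Numeric response (the transcript's IF values, same sample order).
#' @param n_small Minimum number of samples required to split the root.
#' @param n_trees Number of stumps.
#' @return Object of class `spit_stump_forest`: list of trees (each with
#'   `feature`, `threshold`, `left_mean`, `right_mean`, or an unsplit mean)
#'   plus the feature names.
#' @export
fit_stump_forest <- function(X, y, n_small = 12L, n_trees = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- fit_stump(X[idx, , drop = FALSE], y[idx], n_small)
  }
  structure(list(trees = trees, features = colnames(X)),
            class = "spit_stump_forest")
}

# Best single split on one bootstrap; returns an unsplit stump when no valid
# split exists or the root is too small.
fit_stump <- function(X, y, n_small) {
  n <- length(y)
  no_split <- list(split = FALSE, mean = mean(y))
  if (n < n_small) return(no_split)
  cand <- list()
  for (f in seq_len(ncol(X))) {
    x <- X[, f]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cut_at <- which(diff(xs) > 0)      # split between distinct sorted values
    if (length(cut_at) == 0) next
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    tot <- cs[n]; tot2 <- cs2[n]
    i <- cut_at
    sse <- (cs2[i] - cs[i]^2 / i) +
      ((tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i))
    b <- which.min(sse)
    cand[[length(cand) + 1L]] <-
      list(feature = f, threshold = (xs[i[b]] + xs[i[b] + 1]) / 2,
           loss = sse[b],
           left_mean = cs[i[b]] / i[b],
           right_mean = (tot - cs[i[b]]) / (n - i[b]))
  }
  if (length(cand) == 0) return(no_split)
  losses <- vapply(cand, `[[`, numeric(1), "loss")
  # conservative tie-break: the candidate with the highest feature index wins,
  # so a covariate that explains the partition exactly as well as the DTU
  # indicator (first column) takes the split and the indicator earns no
  # importance it does not strictly deserve
  eligible <- which(losses <= min(losses) + 1e-12)
  pick <- eligible[length(eligible)]
  c(cand[[pick]][c("feature", "threshold", "left_mean", "right_mean")],
    list(split = TRUE))
}

predict_stump <- function(tree, X) {
  if (!tree$split) return(rep(tree$mean, nrow(X)))
  ifelse(X[, tree$feature] <= tree$threshold, tree$left_mean,
         tree$right_mean)
}

#' Predict from a stump forest
#'
#' @param object A `spit_stump_forest`.
#' @param newdata Samples x features matrix (same column order as training).
#' @param ... Unused.
#' @return Numeric vector of ensemble-mean predictions.
#' @export
predict.spit_stump_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  preds <- vapply(object$trees, function(t) predict_stump(t, newdata),
                  numeric(nrow(newdata)))
  rowMeans(preds)
}

#' Coefficient of determination of a stump forest
#'
#' `R^2 = 1 - u/v` where `u` is the squared error of the ensemble predictions
#' and `v` the total squared deviation of `y` from its mean. Defined as 0 for
#' constant `y`; negative values (anti-predictive features) are reported
#' as-is.
#'
#' @param forest A `spit_stump_forest`.
#' @param X Samples x features matrix.
#' @param y Response.
#' @return Numeric scalar.
#' @export
r_squared <- function(forest, X, y) {
  v <- sum((y - mean(y))^2)
  if (v == 0) return(0)
  u <- sum((y - predict(forest, X))^2)
  1 - u / v
}

#' Permutation importance of one feature
#'
#' Permutes the feature column `n_perm` times; each score is the drop in the
#' forest's R-squared relative to the unpermuted baseline (computed once).
#'
#' @param forest A `spit_stump_forest`.
#' @param X,y Training data.
#' @param feature Column index or name.
#' @param n_perm Number of independent permutations.
#' @return Numeric vector of `n_perm` importance scores.
#' @export
permutation_importance <- function(forest, X, y, feature, n_perm = 100L) {
  X <- as.matrix(X)
  if (is.character(feature)) feature <- match(feature, colnames(X))
  n <- nrow(X)
  v <- sum((y - mean(y))^2)
  if (v == 0) return(rep(0, n_perm))
  # baseline predictions; only trees splitting on `feature` change under
  # permutation, so their contribution is swapped in and out
  tree_preds <- vapply(forest$trees, function(t) predict_stump(t, X),
                       numeric(n))
  base_pred <- rowMeans(tree_preds)
  r2_base <- 1 - sum((y - base_pred)^2) / v
  uses <- vapply(forest$trees, function(t)
    isTRUE(t$split) && t$feature == feature, logical(1))
  affected <- which(uses)
  base_contrib <- if (length(affected) > 0)
    rowSums(tree_preds[, affected, drop = FALSE]) else numeric(n)
  nt <- length(forest$trees)
  vapply(seq_len(n_perm), function(r) {
    if (length(affected) == 0) return(0)
    Xp <- X
    Xp[, feature] <- X[sample.int(n), feature]
    new_contrib <- rowSums(vapply(forest$trees[affected],
                                  function(t) predict_stump(t, Xp),
                                  numeric(n)))
    pred <- base_pred + (new_contrib - base_contrib) / nt
    r2_base - (1 - sum((y - pred)^2) / v)
  }, numeric(1))
}

#' Keep/drop decision for a candidate DTU transcript
#'
#' The transcript is kept only when the first quartile of the DTU
#' indicator's importance scores strictly exceeds the maximum over covariates
#' of their third quartiles. With no covariates the maximum over the empty
#' set is `-Inf` and the transcript is trivially kept. Quartiles use the
#' linear-interpolation convention (`quantile` type 7).
#'
#' @param gamma_v Importance scores of the DTU indicator.
#' @param gamma_cov Named list of importance-score vectors, one per
#'   covariate.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
confound_decision <- function(gamma_v, gamma_cov = list()) {
  q1_v <- unname(quantile(gamma_v, 0.25))
  if (length(gamma_cov) == 0) return(TRUE)
  q3 <- vapply(gamma_cov, function(g) unname(quantile(g, 0.75)), numeric(1))
  q1_v > max(q3)
}

#' Filter candidate DTU transcripts for confounding
#'
#' For every significant transcript, builds the binary event vector `v` over
#' all samples (0 for every control), regresses the transcript's IF values on
#' `v` plus the covariates with a depth-one stump forest, scores every
#' feature by permutation importance, and keeps the transcript only when `v`
#' outranks every covariate ([confound_decision()]). Categorical covariates
#' are coded as integers in lexicographic level order.
#'
#' @param results data.frame from [test_transcripts()].
#' @param dtu A `spit_dtu_matrix` built without confound filtering (supplies
#'   the per-transcript event vectors).
#' @param if_table A `spit_if_table`.
#' @param meta A [spit_metadata()]; its `covariates` drive the analysis. With
#'   no covariates every candidate is kept.
#' @param params A [spit_params()]; uses `n_small`, `n_trees`, `n_perm`.
#' @param seed Optional integer; stage stream `"confound"`.
#' @return Object of class `spit_confound_report`: `keep` (named logical),
#'   `summary` (per transcript x feature quartiles and decision), `scores`
#'   (long data.frame transcript_id, feature, gamma, ready for box plots).
#' @export
confound_filter <- function(results, dtu, if_table, meta,
                            params = spit_params(), seed = NULL) {
  seed_stage(seed, "confound")
  cand <- names(dtu$tx_events)
  keep <- stats::setNames(rep(TRUE, length(cand)), cand)
  covs <- meta$covariates
  if (is.null(covs) || ncol(covs) == 0 || length(cand) == 0) {
    return(structure(list(keep = keep,
                          summary = data.frame(), scores = data.frame()),
                     class = "spit_confound_report"))
  }
  Xcov <- vapply(covs, function(col) {
    if (is.numeric(col)) col else as.numeric(factor(col))
  }, numeric(nrow(covs)))
  colnames(Xcov) <- colnames(covs)
  all_ids <- names(meta$group_of)
  summary_rows <- list()
  score_rows <- list()
  for (id in cand) {
    v <- stats::setNames(rep(0, length(all_ids)), all_ids)
    ev <- dtu$tx_events[[id]]
    v[names(ev)] <- ev
    X <- cbind(v = unname(v), Xcov[match(all_ids, rownames(covs)), ,
                                   drop = FALSE])
    y <- if_table$ifs[id, all_ids]
    forest <- fit_stump_forest(X, y, n_small = params$n_small,
                               n_trees = params$n_trees)
    gam <- lapply(seq_len(ncol(X)), function(f)
      permutation_importance(forest, X, y, f, n_perm = params$n_perm))
    names(gam) <- colnames(X)
    keep[id] <- confound_decision(gam$v, gam[-1])
    for (f in names(gam)) {
      qs <- quantile(gam[[f]], c(0.25, 0.5, 0.75))
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(transcript_id = id, feature = f,
                   q1 = qs[[1]], median = qs[[2]], q3 = qs[[3]],
                   decision = ifelse(keep[id], "keep", "drop"),
                   stringsAsFactors = FALSE)
      score_rows[[length(score_rows) + 1L]] <-
        data.frame(transcript_id = id, feature = f, gamma = gam[[f]],
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(keep = keep,
                 summary = do.call(rbind, summary_rows),
                 scores = do.call(rbind, score_rows)),
            class = "spit_confound_report")
}

#' @export
print.spit_confound_report <- function(x, ...) {
  cat(sprintf("spit_confound_report: %d kept / %d candidates\n",
              sum(x$keep), length(x$keep)))
  invisible(x)
}
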