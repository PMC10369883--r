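# Fixture: IF values driven by a binary DTU indicator, optional covariate.
confound_fixture <- function(n = 60, n_event = 20, noise = 0.03,
                             covariate = c("independent", "copy"),
                             seed = 1) {
  covariate <- match.arg(covariate)
  set.seed(seed)
  v <- c(rep(1, n_event), rep(0, n - n_event))
  y <- ifelse(v == 1, 0.1, 0.9) + rnorm(n, 0, noise)
  cov <- switch(covariate,
                independent = rnorm(n),
                copy = v + rnorm(n, 0, 1e-6))
  list(X = cbind(v = v, cov = cov), y = y)
}

test_that("a perfectly separating indicator wins every split", {
  fx <- confound_fixture(seed = 2)
  set.seed(2)
  forest <- fit_stump_forest(fx$X, fx$y, n_small = 12, n_trees = 50)
  feats <- vapply(forest$trees, function(t) t$feature, numeric(1))
  expect_true(all(feats == 1))
  # exhaustive split-search oracle on one deterministic stump (no bootstrap)
  set.seed(3)
  stump <- spit:::fit_stump(fx$X, fx$y, n_small = 12)
  best_sse <- Inf
  for (f in 1:2) {
    for (thr in sort(unique(fx$X[, f]))[-1] - 1e-9) {
      left <- fx$X[, f] <= thr
      sse <- sum((fx$y[left] - mean(fx$y[left]))^2) +
        sum((fx$y[!left] - mean(fx$y[!left]))^2)
      best_sse <- min(best_sse, sse)
    }
  }
  pred <- ifelse(fx$X[, stump$feature] <= stump$threshold,
                 stump$left_mean, stump$right_mean)
  expect_equal(sum((fx$y - pred)^2), best_sse, tolerance = 1e-8)
})

test_that("degenerate targets and tiny roots yield unsplit stumps", {
  fx <- confound_fixture()
  set.seed(4)
  forest <- fit_stump_forest(fx$X, rep(0.5, nrow(fx$X)), n_small = 12,
                             n_trees = 10)
  expect_equal(r_squared(forest, fx$X, rep(0.5, nrow(fx$X))), 0)
  small <- fit_stump_forest(fx$X[1:5, ], fx$y[1:5], n_small = 12,
                            n_trees = 10)
  expect_true(all(!vapply(small$trees, `[[`, logical(1), "split")))
  pred <- predict(small, fx$X[1:5, ])
  expect_true(all(abs(pred - pred[1]) < 1e-12))  # constant prediction
})

test_that("R-squared approaches 1 for a perfect split and 0 at the mean", {
  fx <- confound_fixture(noise = 1e-4, seed = 5)
  set.seed(5)
  forest <- fit_stump_forest(fx$X, fx$y, n_small = 12, n_trees = 200)
  expect_gt(r_squared(forest, fx$X, fx$y), 0.99)
  mean_forest <- structure(
    list(trees = list(list(split = FALSE, mean = mean(fx$y))),
         features = colnames(fx$X)),
    class = "spit_stump_forest")
  expect_equal(r_squared(mean_forest, fx$X, fx$y), 0)
})

test_that("permutation importance separates used from unused features", {
  fx <- confound_fixture(seed = 6)
  set.seed(6)
  forest <- fit_stump_forest(fx$X, fx$y, n_small = 12, n_trees = 100)
  r2 <- r_squared(forest, fx$X, fx$y)
  g_v <- permutation_importance(forest, fx$X, fx$y, "v", n_perm = 50)
  g_c <- permutation_importance(forest, fx$X, fx$y, "cov", n_perm = 50)
  expect_length(g_v, 50)
  expect_true(all(abs(g_c) < 0.05))          # unused feature
  expect_gt(median(g_v), 0.5 * r2)           # permuting v destroys the fit
  expect_length(permutation_importance(forest, fx$X, fx$y, "v", n_perm = 1),
                1)
})

test_that("the keep rule compares Q1 of v against the max covariate Q3", {
  expect_true(confound_decision(c(0.3, 0.4, 0.5, 0.6),
                                list(a = rep(0.1, 4), b = rep(0.05, 4))))
  expect_false(confound_decision(rep(0.1, 4), list(a = rep(0.2, 4))))
  expect_true(confound_decision(rep(0.01, 4), list()))  # no covariates
  # decision invariant to score order
  set.seed(7)
  gv <- runif(100); gc <- list(a = runif(100, 0, 0.5))
  expect_equal(confound_decision(gv, gc),
               confound_decision(rev(gv), lapply(gc, sample)))
})

test_that("a covariate duplicating the indicator forces a drop", {
  for (seed in 1:3) {
    fx <- confound_fixture(covariate = "copy", seed = seed)
    set.seed(seed)
    forest <- fit_stump_forest(fx$X, fx$y, n_small = 12, n_trees = 100)
    g_v <- permutation_importance(forest, fx$X, fx$y, "v", n_perm = 100)
    g_c <- permutation_importance(forest, fx$X, fx$y, "cov", n_perm = 100)
    expect_false(confound_decision(g_v, list(cov = g_c)))
  }
})

test_that("an independent covariate lets the indicator through", {
  for (seed in 1:3) {
    fx <- confound_fixture(covariate = "independent", seed = seed)
    set.seed(seed)
    forest <- fit_stump_forest(fx$X, fx$y, n_small = 12, n_trees = 100)
    g_v <- permutation_importance(forest, fx$X, fx$y, "v", n_perm = 100)
    g_c <- permutation_importance(forest, fx$X, fx$y, "cov", n_perm = 100)
    expect_true(confound_decision(g_v, list(cov = g_c)))
  }
})

test_that("confound_filter wires events, covariates and decisions together", {
  n <- 40
  samples <- paste0("s", seq_len(n))
  case_ids <- samples[1:20]
  v_case <- stats::setNames(c(rep(1L, 10), rep(0L, 10)), case_ids)
  y <- ifelse(c(v_case, stats::setNames(rep(0, 20), samples[21:40])) == 1,
              0.15, 0.85)
  set.seed(8)
  ifs <- matrix(pmin(pmax(y + rnorm(n, 0, 0.02), 0), 1), nrow = 1,
                dimnames = list("tx1", samples))
  it <- if_table_from_matrix(ifs, c(tx1 = "g1"))
  covs <- data.frame(indep = rnorm(n),
                     copy = unname(c(v_case, rep(0L, 20))) +
                       rnorm(n, 0, 1e-6),
                     row.names = samples)
  meta <- spit_metadata(stats::setNames(rep(c("case", "control"), each = 20),
                                        samples), covs)
  results <- data.frame(transcript_id = "tx1", gene_id = "g1",
                        mode = "tail_wise", p_left = 1e-5, p_right = 1,
                        p_min = 1e-5, significant = TRUE,
                        left_significant = TRUE, right_significant = FALSE,
                        stringsAsFactors = FALSE)
  dtu <- structure(list(M = matrix(1L, 1, 20,
                                   dimnames = list("g1", case_ids)),
                        tx_events = list(tx1 = v_case)),
                   class = "spit_dtu_matrix")
  p <- spit_params(n_small = 10, n_perm = 50, n_trees = 50)
  rep1 <- confound_filter(results, dtu, it, meta, p, seed = 1)
  expect_false(rep1$keep[["tx1"]])     # the copy covariate explains y
  expect_true(all(c("q1", "q3", "decision") %in% names(rep1$summary)))
  # without covariates every candidate is kept
  meta0 <- spit_metadata(meta$group_of)
  rep0 <- confound_filter(results, dtu, it, meta0, p, seed = 1)
  expect_true(rep0$keep[["tx1"]])
})
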