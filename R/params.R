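#' Hyperparameters for a SPIT analysis
#'
#' Collects every tunable parameter of the pipeline into one validated list.
#' Defaults are the fitted optima for a large heterogeneous RNA-Seq cohort
#' (`h = 0.09`, `kappa = 0.6`) together with the standard pre-filter and
#' simulation settings.
#'
#' @param h Gaussian KDE bandwidth, in isoform-fraction units. Larger values
#'   oversmooth the IF distribution so that only the strongest bimodality is
#'   detected.
#' @param kappa Fraction in (0, 1] of the empirical null used for the
#'   significance threshold: the threshold is the `ceiling(kappa * N)`-th
#'   smallest minimal p-value of the null (see [spit_threshold()]).
#' @param n_small Smallest subgroup size (in samples) the analysis is allowed
#'   to detect or compare; also governs pre-filter steps and stump splits.
#' @param pr Minimum fraction of samples (in each of case and control) with a
#'   positive read count (pre-filter step 2).
#' @param gc,gn A gene must have a read count of at least `gc` in at least
#'   `gn` samples (pre-filter step 3).
#' @param f Minimum isoform fraction: each transcript must have IF > `f` in at
#'   least `n_small` samples (pre-filter step 4).
#' @param pd Dominance fraction: the same isoform must have the largest IF in
#'   at least this fraction of control samples (pre-filter step 6).
#' @param epsilon Simulation noise half-width on injected isoform fractions.
#' @param n_iter Number of SPIT-Test iterations used to build the null.
#' @param n_e Number of simulated experiments for parameter fitting.
#' @param n_g Number of splicotypes injected per fitting experiment.
#' @param n_perm Number of permutations per feature in the permutation
#'   importance test.
#' @param n_trees Number of depth-one trees in the confounding forest.
#' @param seed Integer seed; every stochastic stage derives its own stream
#'   from it (see Details).
#'
#' @details One seed governs the full pipeline: each stochastic stage
#'   (null building, confounding permutations, simulation) re-seeds from a
#'   sub-seed derived from `seed` and the stage name, so skipping one stage
#'   never shifts another stage's random stream.
#'
#' @return An object of class `spit_params` (a named list).
#' @examples
#' p <- spit_params(kappa = 0.4, seed = 7)
#' p$kappa
#' @export
spit_params <- function(h = 0.09, kappa = 0.6, n_small = 12L,
                        pr = 0.20, gc = 10, gn = 10, f = 0.1, pd = 0.75,
                        epsilon = 0.05, n_iter = 1000L, n_e = 10L, n_g = 5L,
                        n_perm = 100L, n_trees = 100L, seed = 1L) {
  p <- list(h = h, kappa = kappa, n_small = as.integer(n_small),
            pr = pr, gc = gc, gn = gn, f = f, pd = pd,
            epsilon = epsilon, n_iter = as.integer(n_iter),
            n_e = as.integer(n_e), n_g = as.integer(n_g),
            n_perm = as.integer(n_perm), n_trees = as.integer(n_trees),
            seed = as.integer(seed))
  validate_spit_params(p)
  structure(p, class = "spit_params")
}

validate_spit_params <- function(p) {
  stopifnot(is.numeric(p$h), is.numeric(p$kappa))
  if (!(p$kappa > 0 && p$kappa <= 1))
    stop("kappa must be in (0, 1], got ", p$kappa)
  if (p$h <= 0) stop("bandwidth h must be positive, got ", p$h)
  if (!(p$epsilon >= 0 && p$epsilon < 0.5))
    stop("epsilon must be in [0, 0.5), got ", p$epsilon)
  if (p$n_iter < 1) stop("n_iter must be >= 1")
  for (nm in c("n_small", "gc", "gn", "n_e", "n_g", "n_perm", "n_trees")) {
    if (p[[nm]] < 1) stop(nm, " must be >= 1")
  }
  if (!(p$pd > 0 && p$pd <= 1)) stop("pd must be in (0, 1]")
  if (!(p$pr >= 0 && p$pr <= 1)) stop("pr must be in [0, 1]")
  if (!(p$f >= 0 && p$f < 1)) stop("f must be in [0, 1)")
  invisible(p)
}

#' @export
print.spit_params <- function(x, ...) {
  cat("SPIT hyperparameters\n")
  cat(sprintf("  h = %g, kappa = %g, n_small = %d, n_iter = %d, seed = %d\n",
              x$h, x$kappa, x$n_small, x$n_iter, x$seed))
  cat(sprintf("  filters: pr = %g, gc = %g, gn = %g, f = %g, pd = %g\n",
              x$pr, x$gc, x$gn, x$f, x$pd))
  cat(sprintf("  simulation/fit: epsilon = %g, n_e = %d, n_g = %d\n",
              x$epsilon, x$n_e, x$n_g))
  cat(sprintf("  confounding: n_perm = %d, n_trees = %d\n",
              x$n_perm, x$n_trees))
  invisible(x)
}

# Derive a per-stage sub-seed (< 2^31) so stages have independent streams.
stage_seed <- function(seed, stage) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch)) %% 2011L
  (as.integer(seed) %% 1000003L) * 2011L + h
}

# Seed the RNG for a stage unless seed is NULL (use the ambient stream).
seed_stage <- function(seed, stage) {
  if (!is.null(seed)) set.seed(stage_seed(seed, stage))
  invisible(NULL)
}
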