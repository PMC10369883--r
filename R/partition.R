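#' Gaussian kernel density estimate on isoform fractions
#'
#' Evaluates `density(x) = (1/(n*h)) * sum_v phi((x - v)/h)` with `phi` the
#' standard Gaussian, at the requested grid points. No boundary correction is
#' applied; oversmoothing through a large bandwidth is the intended
#' mitigation for support artifacts.
#'
#' @param values Isoform fractions in \[0, 1\]; non-empty.
#' @param h Bandwidth (> 0), in IF units.
#' @param grid Ordered evaluation points in \[0, 1\]; defaults to the fixed
#'   512-point uniform grid used throughout the package.
#' @return Numeric vector of density values, one per grid point.
#' @export
kde_density <- function(values, h, grid = spit_kde_grid()) {
  if (length(values) == 0) stop("values must be non-empty")
  if (h <= 0) stop("bandwidth h must be positive")
  z <- outer(grid, values, "-") / h
  rowMeans(stats::dnorm(z)) / h
}

#' The fixed KDE evaluation grid
#'
#' A 512-point uniform grid over \[0, 1\]. A fixed grid makes minimum
#' locations deterministic and comparable across bandwidths.
#' @return Numeric vector of length 512.
#' @export
spit_kde_grid <- function() seq(0, 1, length.out = 512L)

# Indices of interior local minima of a density evaluated on a grid that are
# flanked by an *interior* local maximum on each side; a bump whose peak sits
# on the grid boundary (e.g. a lone outlier at IF = 1) does not count as a
# flanking mode. Plateau valleys resolve to their middle grid point.
interior_minima <- function(d) {
  s <- sign(diff(d))
  keep <- which(s != 0)
  if (length(keep) < 2) return(integer(0))
  sk <- s[keep]
  mins <- which(sk[-length(sk)] == -1 & sk[-1] == 1)
  maxs <- which(sk[-length(sk)] == 1 & sk[-1] == -1)
  mins <- mins[vapply(mins, function(j) any(maxs < j) && any(maxs > j),
                      logical(1))]
  vapply(mins, function(j) {
    lo <- keep[j] + 1L          # first point of the valley floor
    hi <- keep[j + 1L]          # last point of the valley floor
    as.integer(floor((lo + hi) / 2))
  }, integer(1))
}

#' Locate the interior global minimum of the case-IF density
#'
#' Fits the Gaussian KDE on the fixed grid and returns the location of the
#' deepest interior local minimum flanked by a rise on each side -- the point
#' that splits a bimodal IF distribution into its two modes. Returns a guard
#' instead when fewer than `2 * n_small` values are available (a split could
#' not produce two interpretable subgroups) or when the density has no
#' interior minimum (unimodal).
#'
#' @param values Isoform fractions in \[0, 1\].
#' @param h Bandwidth.
#' @param n_small Minimum subgroup size.
#' @return List with `m` (the IF value of the minimum, or `NA`) and `guard`
#'   (`"none"`, `"too_few_samples"` or `"no_minimum"`).
#' @export
find_global_minimum <- function(values, h, n_small = 12L) {
  if (length(values) < 2L * n_small)
    return(list(m = NA_real_, guard = "too_few_samples"))
  grid <- spit_kde_grid()
  d <- kde_density(values, h, grid)
  idx <- interior_minima(d)
  if (length(idx) == 0) return(list(m = NA_real_, guard = "no_minimum"))
  depth <- d[idx]
  best <- idx[depth == min(depth)]
  if (length(best) > 1) {
    # tie at grid resolution: take the minimum closest to the data median
    med <- median(values)
    best <- best[which.min(abs(grid[best] - med))]
  }
  list(m = grid[best], guard = "none")
}

#' Assign left/right tails around a density minimum
#'
#' Samples with IF at or below `m` form the left tail, samples above `m` the
#' right tail, in both groups. Control tails smaller than `n_small` are
#' expanded across `m` (the left control tail to the right, the right
#' control tail to the left, nearest samples first) until each holds
#' `n_small` samples. Case tails are meaningful stratifications and are not
#' expanded: if either holds fewer than `n_small` samples the partition is
#' rejected and the transcript falls back to a whole-group comparison.
#'
#' @param m IF value of the density minimum.
#' @param case_ifs,control_ifs Named numeric vectors (names = sample ids).
#' @param n_small Minimum subgroup size; must not exceed the number of
#'   control samples.
#' @return List of class `spit_partition` with fields `bimodal`, `m_case`,
#'   `l_case`, `r_case`, `l_control`, `r_control`, `guard`.
#' @export
assign_tails <- function(m, case_ifs, control_ifs, n_small = 12L) {
  if (n_small > length(control_ifs))
    stop("n_small exceeds the number of control samples")
  l_case <- names(case_ifs)[case_ifs <= m]
  r_case <- names(case_ifs)[case_ifs > m]
  if (length(l_case) < n_small || length(r_case) < n_small) {
    return(structure(list(bimodal = FALSE, m_case = m,
                          l_case = character(0), r_case = character(0),
                          l_control = character(0), r_control = character(0),
                          guard = "case_tail_too_small"),
                     class = "spit_partition"))
  }
  l_control <- names(control_ifs)[control_ifs <= m]
  r_control <- names(control_ifs)[control_ifs > m]
  if (length(l_control) < n_small) {
    above <- control_ifs[control_ifs > m]
    add <- names(sort(above))[seq_len(min(n_small - length(l_control),
                                          length(above)))]
    l_control <- c(l_control, add)
  }
  if (length(r_control) < n_small) {
    below <- control_ifs[control_ifs <= m]
    add <- names(sort(below, decreasing = TRUE))[
      seq_len(min(n_small - length(r_control), length(below)))]
    r_control <- c(r_control, add)
  }
  structure(list(bimodal = TRUE, m_case = m,
                 l_case = l_case, r_case = r_case,
                 l_control = l_control, r_control = r_control,
                 guard = "none"),
            class = "spit_partition")
}

#' Flag bimodality in the control-IF density
#'
#' Annotation only: a transcript whose control distribution is itself bimodal
#' is flagged (divergence in controls suggests technical or biological
#' variability unrelated to disease status), but the flag never changes the
#' test outcome.
#'
#' @inheritParams find_global_minimum
#' @return Logical flag.
#' @export
flag_control_bimodality <- function(values, h, n_small = 12L) {
  res <- find_global_minimum(values, h, n_small)
  identical(res$guard, "none")
}

#' Partition every transcript's case samples
#'
#' Runs [find_global_minimum()] and [assign_tails()] per transcript and flags
#' control bimodality.
#'
#' @param if_table A `spit_if_table`.
#' @param meta A [spit_metadata()].
#' @param params A [spit_params()]; uses `h` and `n_small`.
#' @return List of `spit_partition` objects (one per transcript, named), each
#'   augmented with `control_bimodal`.
#' @export
partition_transcripts <- function(if_table, meta, params = spit_params()) {
  case_ids <- meta$case_ids
  ctrl_ids <- meta$control_ids
  out <- vector("list", nrow(if_table$ifs))
  names(out) <- if_table$tx_ids
  for (j in seq_len(nrow(if_table$ifs))) {
    case_ifs <- if_table$ifs[j, case_ids]
    ctrl_ifs <- if_table$ifs[j, ctrl_ids]
    gm <- find_global_minimum(case_ifs, params$h, params$n_small)
    part <- if (identical(gm$guard, "none")) {
      assign_tails(gm$m, case_ifs, ctrl_ifs, params$n_small)
    } else {
      structure(list(bimodal = FALSE, m_case = NA_real_,
                     l_case = character(0), r_case = character(0),
                     l_control = character(0), r_control = character(0),
                     guard = gm$guard),
                class = "spit_partition")
    }
    part$control_bimodal <-
      flag_control_bimodality(ctrl_ifs, params$h, params$n_small)
    out[[j]] <- part
  }
  out
}

#' Summarize partitions as a data frame
#'
#' @param partitions Output of [partition_transcripts()].
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `bimodal`, `m_case`, tail sizes, `control_bimodal`, `guard`.
#' @export
partition_table <- function(partitions) {
  data.frame(
    transcript_id = names(partitions),
    bimodal = vapply(partitions, `[[`, logical(1), "bimodal"),
    m_case = vapply(partitions, `[[`, numeric(1), "m_case"),
    n_l_case = vapply(partitions, function(p) length(p$l_case), integer(1)),
    n_r_case = vapply(partitions, function(p) length(p$r_case), integer(1)),
    n_l_control = vapply(partitions, function(p) length(p$l_control),
                         integer(1)),
    n_r_control = vapply(partitions, function(p) length(p$r_control),
                         integer(1)),
    control_bimodal = vapply(partitions, `[[`, logical(1), "control_bimodal"),
    guard = vapply(partitions, `[[`, character(1), "guard"),
    row.names = NULL, stringsAsFactors = FALSE)
}
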