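#' One SPIT-Test iteration
#'
#' Splits the control samples into two random halves, draws a random split
#' point `o` uniformly on \[0, 1\], and for every transcript compares the
#' left tails of the two halves (IF <= `o`) and the right tails (IF > `o`)
#' with Mann-Whitney U tests, assigning each transcript the smaller of its
#' two p-values. A side whose tails do not both hold at least 2 samples is
#' skipped; when both sides are skipped the whole halves are compared, so
#' every transcript receives a p-value.
#'
#' Uses the ambient RNG stream; [build_null()] seeds it per stage.
#'
#' @param control_ifs Numeric matrix of isoform fractions, transcripts x
#'   control samples.
#' @return List with `o` (the split point) and `p` (named vector of minimal
#'   tail p-values, one per transcript).
#' @export
spit_test_iteration <- function(control_ifs) {
  iv <- round(round(control_ifs, 2) * 100)
  storage.mode(iv) <- "integer"
  spit_test_iteration_int(control_ifs, iv)
}

spit_test_iteration_int <- function(raw, iv) {
  n <- ncol(raw)
  if (n < 4) stop("need at least 4 control samples to split")
  perm <- sample.int(n)
  n1 <- ceiling(n / 2)                 # odd n: first (shuffled) half is larger
  h1 <- perm[seq_len(n1)]
  h2 <- perm[(n1 + 1):n]
  o <- runif(1)
  left <- raw <= o
  nt <- nrow(raw)
  p <- numeric(nt)
  for (j in seq_len(nt)) {
    l1 <- h1[left[j, h1]]; l2 <- h2[left[j, h2]]
    r1 <- h1[!left[j, h1]]; r2 <- h2[!left[j, h2]]
    pl <- if (length(l1) >= 2 && length(l2) >= 2)
      mw_p_int(iv[j, l1], iv[j, l2]) else NA_real_
    pr <- if (length(r1) >= 2 && length(r2) >= 2)
      mw_p_int(iv[j, r1], iv[j, r2]) else NA_real_
    p[j] <- if (is.na(pl) && is.na(pr)) {
      mw_p_int(iv[j, h1], iv[j, h2])
    } else {
      min(pl, pr, na.rm = TRUE)
    }
  }
  names(p) <- rownames(raw)
  list(o = o, p = p)
}

#' Build the empirical null distribution of minimal p-values
#'
#' Runs [spit_test_iteration()] `n_iter` times on the control samples. Each
#' iteration stores the minimum p-value across transcripts together with the
#' transcript it came from; to keep outlier transcripts from dominating the
#' null, a transcript contributes this minimum at most once across all
#' iterations. If every transcript has been consumed before `n_iter`
#' iterations the process stops early with a warning and the null shrinks
#' accordingly.
#'
#' @param if_table A `spit_if_table` (any sample set; only `control_ids` are
#'   used).
#' @param control_ids Character vector of control sample ids.
#' @param n_iter Number of iterations.
#' @param seed Optional integer; when given, the stage stream
#'   `"spit_test"` derived from it is used, making the null reproducible.
#' @param retain_p Keep the full transcripts x iterations matrix of
#'   per-iteration minimal tail p-values (needed for the SPIT-Chart medians).
#' @return Object of class `spit_null`: `entries` (data.frame `iteration`,
#'   `transcript_id`, `o`, `p_prime`), and `p_matrix` (or `NULL`).
#' @export
build_null <- function(if_table, control_ids, n_iter = 1000L, seed = NULL,
                       retain_p = TRUE) {
  seed_stage(seed, "spit_test")
  raw <- if_table$ifs[, control_ids, drop = FALSE]
  iv <- round(round(raw, 2) * 100)
  storage.mode(iv) <- "integer"
  nt <- nrow(raw)
  eligible <- rep(TRUE, nt)
  entries <- vector("list", n_iter)
  pmat <- if (retain_p) matrix(NA_real_, nt, n_iter,
                               dimnames = list(rownames(raw), NULL)) else NULL
  done <- 0L
  for (s in seq_len(n_iter)) {
    if (!any(eligible)) {
      warning(sprintf(
        "all %d transcripts consumed after %d iterations; null shrunk", nt, done))
      break
    }
    it <- spit_test_iteration_int(raw, iv)
    if (retain_p) pmat[, s] <- it$p
    pe <- it$p[eligible]
    w <- which(eligible)[which.min(pe)]
    entries[[s]] <- data.frame(iteration = s,
                               transcript_id = rownames(raw)[w],
                               o = it$o, p_prime = it$p[[w]],
                               stringsAsFactors = FALSE)
    eligible[w] <- FALSE
    done <- s
  }
  entries <- do.call(rbind, entries[seq_len(done)])
  if (retain_p) pmat <- pmat[, seq_len(done), drop = FALSE]
  structure(list(entries = entries, p_matrix = pmat), class = "spit_null")
}

#' @export
print.spit_null <- function(x, ...) {
  cat(sprintf("spit_null: %d iterations, p' range [%.3g, %.3g]\n",
              nrow(x$entries), min(x$entries$p_prime),
              max(x$entries$p_prime)))
  invisible(x)
}

#' Significance threshold from the empirical null
#'
#' Returns the `ceiling(kappa * N)`-th smallest minimal p-value of the null,
#' where `N` is the number of null entries. For instance with `kappa = 0.1`
#' and 1000 iterations the threshold is the 100th smallest p-value.
#'
#' @param null A `spit_null` from [build_null()], or a bare numeric vector of
#'   minimal p-values.
#' @param kappa Fraction in (0, 1\].
#' @return The threshold p-value.
#' @examples
#' spit_threshold(c(0.2, 0.4, 0.6), kappa = 0.5)  # 2nd smallest -> 0.4
#' @export
spit_threshold <- function(null, kappa) {
  p <- if (inherits(null, "spit_null")) null$entries$p_prime else null
  if (length(p) == 0) stop("empty null distribution")
  if (!(kappa > 0 && kappa <= 1)) stop("kappa must be in (0, 1]")
  k <- ceiling(kappa * length(p))
  sort(p, partial = k)[k]
}

#' Write the null distribution to TSV
#'
#' @param null A `spit_null`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null <- function(null, path) {
  write.table(null$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
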