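test_that("isoform fractions follow the within-gene proportion rule", {
  m <- matrix(c(30, 50, 0,
                70, 0, 0),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  ct <- spit_count_table(m, c(t1 = "g1", t2 = "g1"))
  ifs <- compute_if(ct)$ifs
  expect_equal(unname(ifs[, "s1"]), c(0.3, 0.7))
  expect_equal(unname(ifs[, "s2"]), c(1, 0))      # single expressed isoform
  expect_equal(unname(ifs[, "s3"]), c(0, 0))      # zero-total gene

  single <- spit_count_table(matrix(50, 1, 1, dimnames = list("t", "s")),
                             c(t = "g"))
  expect_equal(unname(compute_if(single)$ifs[1, 1]), 1)
})

test_that("per-gene fractions sum to one in every sample with expression", {
  set.seed(42)
  for (rep in 1:5) {
    ct <- generate_base_counts(n_genes = 20, n_samples = 10, dispersion = 0.4)
    ift <- compute_if(ct)
    gsum <- rowsum(ift$ifs, ift$gene_of)
    csum <- rowsum(ct$counts, ct$gene_of)
    expect_true(all(abs(gsum[csum > 0] - 1) < 1e-9))
    expect_true(all(gsum[csum == 0] == 0))
    expect_true(all(ift$ifs >= 0 & ift$ifs <= 1))
  }
})

# Toy table for filter checks: gene A fails the CPM step, gene B fails the
# dominance step (alternating dominant isoform), gene C passes everything.
prefilter_toy <- function() {
  n <- 30
  samples <- paste0("s", seq_len(n))
  cA <- matrix(1, 2, n)                              # CPM ~ 1 each
  cB <- rbind(rep(c(600, 400), n / 2), rep(c(400, 600), n / 2))
  cC <- rbind(rep(6e5, n), rep(2.5e5, n), rep(1.5e5, n))
  m <- rbind(cA, cB, cC)
  rownames(m) <- c("A.t1", "A.t2", "B.t1", "B.t2", "C.t1", "C.t2", "C.t3")
  colnames(m) <- samples
  gene_of <- stats::setNames(sub("\\..*", "", rownames(m)), rownames(m))
  list(counts = spit_count_table(m, gene_of), meta = make_meta(samples))
}

# Independent literal re-implementation of the six filter rules (fixed CPM
# denominator, IFs recomputed after each removal).
prefilter_oracle <- function(ct, meta, p) {
  lib <- colSums(ct$counts)
  keep <- rownames(ct$counts)
  cnt <- function() ct$counts[keep, , drop = FALSE]
  ifs <- function() {
    x <- cnt()
    g <- ct$gene_of[keep]
    out <- x
    for (s in colnames(x)) {
      for (gg in unique(g)) {
        rows <- which(g == gg)
        tot <- sum(x[rows, s])
        out[rows, s] <- if (tot > 0) x[rows, s] / tot else 0
      }
    }
    out
  }
  # 1
  cpm <- sweep(cnt(), 2, lib, "/") * 1e6
  keep <- keep[rowSums(cpm >= 10) >= p$n_small]
  # 2
  x <- cnt()
  keep <- keep[rowSums(x[, meta$case_ids, drop = FALSE] > 0) >=
                 p$pr * length(meta$case_ids) &
               rowSums(x[, meta$control_ids, drop = FALSE] > 0) >=
                 p$pr * length(meta$control_ids)]
  # 3
  x <- cnt(); g <- ct$gene_of[keep]
  gk <- vapply(unique(g), function(gg) {
    tot <- colSums(x[g == gg, , drop = FALSE])
    sum(tot >= p$gc) >= p$gn
  }, logical(1))
  keep <- keep[g %in% unique(g)[gk]]
  # 4
  keep <- keep[rowSums(ifs() > p$f) >= p$n_small]
  # 5
  g <- ct$gene_of[keep]
  keep <- keep[g %in% names(table(g))[table(g) >= 2]]
  # 6
  x <- ifs(); g <- ct$gene_of[keep]
  gk <- vapply(unique(g), function(gg) {
    sub <- x[g == gg, meta$control_ids, drop = FALSE]
    top <- apply(sub, 2, function(col) {
      w <- which(col == max(col))
      if (length(w) > 1) NA_integer_ else w
    })
    any(tabulate(top[!is.na(top)], nrow(sub)) >= p$pd * ncol(sub))
  }, logical(1))
  keep[g %in% unique(g)[gk]]
}

test_that("the six-step pre-filter matches a literal rule-by-rule oracle", {
  toy <- prefilter_toy()
  p <- spit_params(n_small = 5)
  res <- prefilter(toy$counts, toy$meta, p)
  expect_equal(sort(res$counts$tx_ids),
               sort(prefilter_oracle(toy$counts, toy$meta, p)))
  expect_equal(sort(res$counts$tx_ids), c("C.t1", "C.t2", "C.t3"))
  # step bookkeeping: A's transcripts at step 1, B's gene at step 6
  per <- res$report$per_step
  expect_equal(per$removed_transcripts[per$step == 1], 2L)
  expect_equal(per$removed_genes[per$step == 6], 1L)
})

test_that("pre-filter retains dominance at pd and drops single-tx genes", {
  n <- 20
  samples <- paste0("s", seq_len(n))
  # gene with dominant isoform largest in 80% of controls, pd = 0.75
  dom <- ifelse(seq_len(10) <= 8, 700, 300)
  m <- rbind(c(rep(700, 10), dom), c(rep(300, 10), 1000 - dom))
  rownames(m) <- c("g.t1", "g.t2"); colnames(m) <- samples
  ct <- spit_count_table(m, c(g.t1 = "g", g.t2 = "g"))
  meta <- make_meta(samples)   # s11..s20 controls: 8/10 dominant
  res <- prefilter(ct, meta, spit_params(n_small = 4), enabled_steps = 6)
  expect_equal(res$counts$tx_ids, c("g.t1", "g.t2"))
  # raising pd above the observed 8/10 dominance removes the only gene
  expect_error(prefilter(ct, meta, spit_params(n_small = 4, pd = 0.9),
                         enabled_steps = 6),
               "empty matrix after filtering")
})

test_that("pre-filter is idempotent and monotone in its thresholds", {
  set.seed(7)
  ct <- generate_base_counts(n_genes = 60, n_samples = 40, dispersion = 0.3)
  meta <- make_meta(ct$sample_ids)
  p <- spit_params(n_small = 8)
  once <- prefilter(ct, meta, p)
  twice <- prefilter(once$counts, meta, p)
  expect_equal(twice$counts$tx_ids, once$counts$tx_ids)

  surv <- function(p) prefilter(ct, meta, p)$counts$tx_ids
  base <- surv(p)
  for (pp in list(spit_params(n_small = 10), spit_params(n_small = 8, f = 0.2),
                  spit_params(n_small = 8, pd = 0.9),
                  spit_params(n_small = 8, gc = 40, gn = 20))) {
    expect_true(all(surv(pp) %in% base))
  }
})

test_that("filtering everything reports an empty matrix error", {
  toy <- prefilter_toy()
  expect_error(prefilter(toy$counts, toy$meta, spit_params(n_small = 31)),
               "empty matrix after filtering")
})
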