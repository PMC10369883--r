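#' Generate an overdispersed multi-isoform base count table
#'
#' Emulates a healthy bulk RNA-Seq population: per-gene totals are drawn from
#' a negative binomial (variance `mu + mu^2 * dispersion`), and isoform
#' counts are multinomial draws with per-sample isoform fractions sampled
#' from a Dirichlet centred on a gene profile with one clearly dominant
#' isoform. The Dirichlet concentration is tied to the same dispersion
#' parameter (`theta = 10 / dispersion`) so that as `dispersion -> 0` both
#' the totals and the fractions collapse to their means and transcript
#' counts approach the Poisson limit.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Integer range (length-2 vector) of isoforms per
#'   gene; each gene draws uniformly from it.
#' @param n_samples Number of samples.
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param mean_range Per-gene mean total count, drawn log-uniformly from this
#'   range.
#' @param dominant_range Mean IF of the dominant isoform, drawn uniformly
#'   from this range (centred on 0.75 by default, compatible with the
#'   dominance pre-filter).
#' @param seed Optional integer seed.
#' @return A [spit_count_table()] with samples `s1..sN`, genes `g1..gG` and
#'   transcripts `g<i>.t<j>`.
#' @export
generate_base_counts <- function(n_genes = 300L, isoforms_per_gene = c(2L, 4L),
                                 n_samples = 120L, dispersion = 0.3,
                                 mean_range = c(300, 3000),
                                 dominant_range = c(0.65, 0.85),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(dispersion > 0, n_genes >= 1, n_samples >= 1)
  theta <- 10 / dispersion
  sample_ids <- paste0("s", seq_len(n_samples))
  rows <- list()
  gene_of <- character(0)
  iso_range <- seq(isoforms_per_gene[1], isoforms_per_gene[2])
  for (g in seq_len(n_genes)) {
    k <- if (length(iso_range) == 1) iso_range else sample(iso_range, 1)
    mu <- exp(runif(1, log(mean_range[1]), log(mean_range[2])))
    dom <- runif(1, dominant_range[1], dominant_range[2])
    rest <- rgamma(k - 1, shape = 2)
    profile <- c(dom, (1 - dom) * rest / sum(rest))
    profile <- profile[sample.int(k)]   # dominant slot position is arbitrary
    totals <- rnbinom(n_samples, mu = mu, size = 1 / dispersion)
    frac <- matrix(rgamma(k * n_samples, shape = rep(profile * theta,
                                                     n_samples)),
                   nrow = k)
    frac <- sweep(frac, 2, colSums(frac), "/")
    cnt <- matrix(0, k, n_samples)
    for (i in seq_len(n_samples)) {
      if (totals[i] > 0) cnt[, i] <- rmultinom(1, totals[i], frac[, i])
    }
    rownames(cnt) <- paste0("g", g, ".t", seq_len(k))
    rows[[g]] <- cnt
    gene_of <- c(gene_of,
                 stats::setNames(rep(paste0("g", g), k), rownames(cnt)))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- sample_ids
  spit_count_table(m, gene_of)
}

#' Inject splicotype-structured DTU events
#'
#' Case samples are divided as evenly as possible into `n_splicotypes`
#' subgroups. A superset `D` of `n_dtu_genes` genes with a consistently
#' dominant isoform in controls is drawn, and each splicotype samples
#' `genes_per_splicotype` genes from `D` *with replacement*, so some events
#' are shared between splicotypes and some are exclusive. For an affected
#' gene, the dominance status of the most dominant isoform (mean control IF
#' `u`) and the least dominant isoform (mean control IF `v`) is switched in
#' the splicotype's samples: the new fractions are `v + delta` and
#' `u + delta'` with `delta, delta'` uniform on \[-epsilon, epsilon\];
#' remaining isoforms are rescaled so the gene's fractions sum to one
#' (clipped at zero and renormalized if noise pushes a fraction outside
#' \[0, 1\]). Transcript counts are rewritten as the gene total times the new
#' fraction, rounded half-to-even, and the gene total becomes the sum of the
#' rounded counts.
#'
#' @param counts A [spit_count_table()] (typically pre-filtered with the
#'   dominance step skipped).
#' @param case_ids Case sample ids.
#' @param n_dtu_genes Size of the DTU superset `D`.
#' @param n_splicotypes Number of splicotype subgroups.
#' @param genes_per_splicotype Number of with-replacement draws from `D` per
#'   splicotype.
#' @param epsilon Noise half-width on the injected fractions.
#' @param pd Dominance fraction used to determine eligibility.
#' @param seed Optional integer seed.
#' @return List with `counts` (modified [spit_count_table()]) and `truth`
#'   (class `spit_sim_truth`): superset `D`, per-splicotype gene sets,
#'   case-sample labels, the per-gene swap table, and `true_genes` (the union
#'   of injected sets).
#' @export
inject_dtu <- function(counts, case_ids, n_dtu_genes = 100L,
                       n_splicotypes = 5L, genes_per_splicotype = 30L,
                       epsilon = 0.05, pd = 0.75, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  control_ids <- setdiff(counts$sample_ids, case_ids)
  ifs <- compute_if(counts)$ifs
  ntx <- table(counts$gene_of)
  multi <- names(ntx)[ntx >= 2]
  dom <- consistent_dominance(ifs, counts$gene_of, control_ids, pd)
  eligible <- intersect(multi, names(dom)[dom])
  if (length(eligible) < n_dtu_genes)
    stop(sprintf("only %d genes eligible for DTU injection, need %d",
                 length(eligible), n_dtu_genes))
  D <- sample(eligible, n_dtu_genes)
  labels <- stats::setNames(
    sample(rep(seq_len(n_splicotypes), length.out = length(case_ids))),
    case_ids)
  D_pi <- lapply(seq_len(n_splicotypes), function(s)
    unique(sample(D, genes_per_splicotype, replace = TRUE)))
  used <- sort(unique(unlist(D_pi)))

  # per-gene swap bookkeeping from control means
  swaps <- do.call(rbind, lapply(used, function(g) {
    rows <- which(counts$gene_of == g)
    mu <- rowMeans(ifs[rows, control_ids, drop = FALSE])
    data.frame(gene_id = g,
               alpha = names(mu)[which.max(mu)],
               beta = names(mu)[which.min(mu)],
               u = max(mu), v = min(mu), stringsAsFactors = FALSE)
  }))
  rownames(swaps) <- swaps$gene_id

  m <- counts$counts
  for (s in seq_len(n_splicotypes)) {
    members <- names(labels)[labels == s]
    for (g in D_pi[[s]]) {
      rows <- which(counts$gene_of == g)
      tx <- counts$tx_ids[rows]
      a <- swaps[g, "alpha"]; b <- swaps[g, "beta"]
      u <- swaps[g, "u"]; v <- swaps[g, "v"]
      others <- setdiff(tx, c(a, b))
      for (i in members) {
        total <- sum(m[tx, i])
        old <- m[tx, i] / max(total, 1)
        new <- old
        new[a] <- v + runif(1, -epsilon, epsilon)
        new[b] <- u + runif(1, -epsilon, epsilon)
        if (length(others) > 0) {
          old_rest <- 1 - old[a] - old[b]
          new_rest <- 1 - new[a] - new[b]
          new[others] <- if (old_rest > 1e-12) {
            old[others] * max(new_rest, 0) / old_rest
          } else {
            max(new_rest, 0) / length(others)
          }
        }
        new <- pmax(new, 0)
        new <- new / sum(new)
        m[tx, i] <- round(total * new)
      }
    }
  }
  truth <- structure(list(D = D, splicotype_genes = D_pi, labels = labels,
                          swaps = swaps, true_genes = used),
                     class = "spit_sim_truth")
  list(counts = spit_count_table(m, counts$gene_of), truth = truth)
}

#' @export
print.spit_sim_truth <- function(x, ...) {
  cat(sprintf(
    "spit_sim_truth: |D| = %d, %d splicotypes, %d genes injected\n",
    length(x$D), length(x$splicotype_genes), length(x$true_genes)))
  invisible(x)
}

#' Simulate a complete case/control experiment
#'
#' Generates a base population, splits it at random into pseudo case and
#' control groups, applies the pre-filter with the dominance step skipped
#' (keeping it would bias the filtered set toward the genes about to receive
#' DTU), and -- for `kind = "splicotype"` -- injects splicotype-structured
#' DTU events into the case half. `kind = "null"` returns the unmodified
#' split with no truth, for false-discovery experiments.
#'
#' @param kind `"splicotype"` or `"null"`.
#' @param params A [spit_params()]; supplies `epsilon` and the filter
#'   settings.
#' @param n_genes,n_samples,dispersion,isoforms_per_gene Base population
#'   size, dispersion and isoform-count range.
#' @param n_dtu_genes,n_splicotypes,genes_per_splicotype Injection layout.
#' @param seed Optional integer; stage stream `"simulate"`.
#' @return List with `counts`, `meta`, `truth` (`NULL` for null experiments).
#' @export
make_experiment <- function(kind = c("splicotype", "null"),
                            params = spit_params(),
                            n_genes = 300L, n_samples = 120L,
                            dispersion = 0.3, isoforms_per_gene = c(2L, 4L),
                            n_dtu_genes = 100L,
                            n_splicotypes = 5L, genes_per_splicotype = 30L,
                            seed = NULL) {
  kind <- match.arg(kind)
  seed_stage(seed, "simulate")
  base <- generate_base_counts(n_genes = n_genes,
                               isoforms_per_gene = isoforms_per_gene,
                               n_samples = n_samples,
                               dispersion = dispersion)
  perm <- sample(base$sample_ids)
  n_case <- floor(n_samples / 2)
  case_ids <- perm[seq_len(n_case)]
  control_ids <- perm[(n_case + 1):n_samples]
  group <- stats::setNames(
    ifelse(base$sample_ids %in% case_ids, "case", "control"),
    base$sample_ids)
  meta <- spit_metadata(group)
  filt <- prefilter(base, meta, params, enabled_steps = 1:5)
  if (kind == "null")
    return(list(counts = filt$counts, meta = meta, truth = NULL))
  inj <- inject_dtu(filt$counts, case_ids, n_dtu_genes = n_dtu_genes,
                    n_splicotypes = n_splicotypes,
                    genes_per_splicotype = genes_per_splicotype,
                    epsilon = params$epsilon, pd = params$pd)
  list(counts = inj$counts, meta = meta, truth = inj$truth)
}

#' Score DTU calls against simulation truth
#'
#' Gene-level scores: `TPR = |called & true| / |true|`,
#' `FDR = |called \ true| / |called|` (0 when nothing is called),
#' `F = 2PR / (P + R)` with precision `P = 1 - FDR` and recall `R = TPR`.
#' When a DTU matrix is given, the adjusted Rand index between the true
#' splicotype labels and the flat clustering of the matrix at
#' `k = ` number of splicotypes is added.
#'
#' @param truth A `spit_sim_truth`.
#' @param called_genes Character vector of genes called DTU.
#' @param M Optional `spit_dtu_matrix` for cluster-recovery scoring.
#' @return List with `tpr`, `fdr`, `f_score`, `ari` (`NA` without `M` or
#'   with an empty matrix).
#' @export
score_calls <- function(truth, called_genes, M = NULL) {
  true_genes <- truth$true_genes
  tp <- length(intersect(called_genes, true_genes))
  tpr <- if (length(true_genes) > 0) tp / length(true_genes) else 0
  fdr <- if (length(called_genes) > 0)
    (length(called_genes) - tp) / length(called_genes) else 0
  p <- 1 - fdr
  r <- tpr
  f <- if (p + r > 0 && length(called_genes) > 0) 2 * p * r / (p + r) else 0
  ari <- NA_real_
  if (!is.null(M) && inherits(M, "spit_dtu_matrix") && nrow(M$M) > 0) {
    k <- length(truth$splicotype_genes)
    cl <- hierarchical_cluster(M, k = k)
    ari <- mclust::adjustedRandIndex(
      truth$labels[names(cl$assignment)], cl$assignment)
  }
  list(tpr = tpr, fdr = fdr, f_score = f, ari = ari)
}

#' Write simulation truth to TSV
#'
#' @param truth A `spit_sim_truth`.
#' @param path Output path (gene, splicotypes carrying it, alpha, beta, u, v).
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  spl <- vapply(truth$swaps$gene_id, function(g) {
    paste(which(vapply(truth$splicotype_genes, function(s) g %in% s,
                       logical(1))), collapse = ",")
  }, character(1))
  df <- cbind(truth$swaps, splicotypes = unname(spl))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
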