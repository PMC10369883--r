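test_that("base count generation is reproducible and well-formed", {
  a <- generate_base_counts(n_genes = 15, n_samples = 10, seed = 5)
  b <- generate_base_counts(n_genes = 15, n_samples = 10, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_s3_class(a, "spit_count_table")
  ntx <- table(a$gene_of)
  expect_true(all(ntx >= 2 & ntx <= 4))
})

test_that("the dispersion parameter controls the Poisson limit", {
  set.seed(20)
  # near-zero dispersion: transcript SD approaches sqrt(mean)
  ct <- generate_base_counts(n_genes = 40, n_samples = 1000,
                             dispersion = 1e-6)
  mu <- rowMeans(ct$counts)
  s <- apply(ct$counts, 1, sd)
  hi <- mu >= 100
  expect_true(any(hi))
  expect_true(all(abs(s[hi] / sqrt(mu[hi]) - 1) < 0.10))
})

test_that("substantial dispersion puts transcripts above the Poisson line", {
  set.seed(21)
  ct <- generate_base_counts(n_genes = 500, n_samples = 120,
                             dispersion = 0.5)
  mu <- rowMeans(ct$counts)
  s <- apply(ct$counts, 1, sd)
  hi <- mu > 50
  expect_gt(mean(s[hi] > sqrt(mu[hi])), 0.90)
})

test_that("noise-free injection swaps the dominant and minor fractions", {
  # deterministic 2-isoform gene: u = 0.8, v = 0.2 in every sample
  n <- 24
  samples <- paste0("s", 1:n)
  m <- rbind(rep(800, n), rep(200, n))
  dimnames(m) <- list(c("g1.t1", "g1.t2"), samples)
  ct <- spit_count_table(m, c(g1.t1 = "g1", g1.t2 = "g1"))
  case_ids <- samples[1:12]
  inj <- inject_dtu(ct, case_ids, n_dtu_genes = 1, n_splicotypes = 1,
                    genes_per_splicotype = 1, epsilon = 0, seed = 3)
  ifs <- compute_if(inj$counts)$ifs
  expect_equal(unname(ifs["g1.t1", case_ids]), rep(0.2, 12))
  expect_equal(unname(ifs["g1.t2", case_ids]), rep(0.8, 12))
  # controls untouched
  expect_equal(inj$counts$counts[, samples[13:24]], ct$counts[, samples[13:24]])
  expect_identical(inj$truth$swaps$alpha, "g1.t1")
  expect_equal(inj$truth$swaps$u, 0.8)
  # counts are gene total times the new fraction
  expect_equal(unname(inj$counts$counts[, "s1"]), c(200, 800))
})

test_that("fractions stay conserved after injection", {
  set.seed(30)
  ct <- generate_base_counts(n_genes = 60, n_samples = 40, dispersion = 0.3)
  meta <- make_meta(ct$sample_ids)
  filt <- prefilter(ct, meta, spit_params(n_small = 8), 1:5)
  iso_count <- table(filt$counts$gene_of)
  inj <- inject_dtu(filt$counts, meta$case_ids, n_dtu_genes = 10,
                    n_splicotypes = 2, genes_per_splicotype = 5,
                    epsilon = 0.05, seed = 4)
  ifs <- compute_if(inj$counts)$ifs
  gsum <- rowsum(ifs, inj$counts$gene_of)
  csum <- rowsum(inj$counts$counts, inj$counts$gene_of)
  expect_true(all(abs(gsum[csum > 0] - 1) < 1e-9))
  # rounding moved each gene total by at most half a count per isoform
  before <- rowsum(filt$counts$counts, filt$counts$gene_of)
  after <- csum[rownames(before), ]
  lim <- as.numeric(iso_count[rownames(before)]) / 2
  expect_true(all(abs(after - before) <= lim + 1e-9))
})

test_that("with-replacement splicotype draws share and split events", {
  set.seed(40)
  ct <- generate_base_counts(n_genes = 150, n_samples = 60, dispersion = 0.3)
  meta <- make_meta(ct$sample_ids)
  filt <- prefilter(ct, meta, spit_params(n_small = 8), 1:5)
  inj <- inject_dtu(filt$counts, meta$case_ids, n_dtu_genes = 50,
                    n_splicotypes = 5, genes_per_splicotype = 15,
                    epsilon = 0.05, seed = 6)
  sets <- inj$truth$splicotype_genes
  shared <- any(vapply(1:4, function(i)
    length(intersect(sets[[i]], sets[[i + 1]])) > 0, logical(1)))
  exclusive <- any(vapply(seq_along(sets), function(i)
    length(setdiff(sets[[i]], unlist(sets[-i]))) > 0, logical(1)))
  expect_true(shared)
  expect_true(exclusive)
  expect_setequal(inj$truth$true_genes, unique(unlist(sets)))
  expect_true(all(inj$truth$true_genes %in% inj$truth$D))
  # labels partition the case group near-evenly
  expect_setequal(names(inj$truth$labels), meta$case_ids)
  expect_true(max(table(inj$truth$labels)) -
                min(table(inj$truth$labels)) <= 1)
})

test_that("injection refuses when too few genes are eligible", {
  n <- 24
  m <- rbind(rep(500, n), rep(500, n))  # permanent dominance tie
  dimnames(m) <- list(c("g1.t1", "g1.t2"), paste0("s", 1:n))
  ct <- spit_count_table(m, c(g1.t1 = "g1", g1.t2 = "g1"))
  expect_error(inject_dtu(ct, paste0("s", 1:12), n_dtu_genes = 1,
                          n_splicotypes = 1, genes_per_splicotype = 1),
               "eligible")
})

test_that("experiments are reproducible and null runs carry no truth", {
  e1 <- make_experiment("null", n_genes = 40, n_samples = 40,
                        params = spit_params(n_small = 8), seed = 9)
  e2 <- make_experiment("null", n_genes = 40, n_samples = 40,
                        params = spit_params(n_small = 8), seed = 9)
  expect_null(e1$truth)
  expect_identical(e1$counts$counts, e2$counts$counts)
  expect_identical(e1$meta$group_of, e2$meta$group_of)
  e3 <- make_experiment("splicotype", n_genes = 100, n_samples = 40,
                        params = spit_params(n_small = 8),
                        n_dtu_genes = 20, n_splicotypes = 2,
                        genes_per_splicotype = 8, seed = 9)
  expect_s3_class(e3$truth, "spit_sim_truth")
  expect_length(e3$truth$D, 20)
})

test_that("call scoring implements TPR, FDR, F and the empty convention", {
  truth <- structure(list(true_genes = paste0("g", 1:10),
                          splicotype_genes = list(paste0("g", 1:10)),
                          labels = c(a = 1)),
                     class = "spit_sim_truth")
  s <- score_calls(truth, paste0("g", 1:10))
  expect_equal(c(s$tpr, s$fdr, s$f_score), c(1, 0, 1))
  s0 <- score_calls(truth, character(0))
  expect_equal(c(s0$tpr, s0$fdr, s0$f_score), c(0, 0, 0))
  # P = 0.9, R = 0.8 -> F = 2*0.72/1.7
  called <- c(paste0("g", 1:8), "x1")  # 8 of 10 true, 1 of 9 false
  truth2 <- truth
  s2 <- score_calls(truth2, called)
  expect_equal(s2$tpr, 0.8)
  expect_equal(s2$fdr, 1 / 9)
  p <- 1 - 1 / 9; r <- 0.8
  expect_equal(s2$f_score, 2 * p * r / (p + r))
  expect_equal(2 * 0.9 * 0.8 / 1.7, 0.8471, tolerance = 1e-4)
})

test_that("truth tables serialize with swap bookkeeping", {
  set.seed(50)
  ct <- generate_base_counts(n_genes = 50, n_samples = 30, dispersion = 0.3)
  inj <- inject_dtu(ct, ct$sample_ids[1:15], n_dtu_genes = 8,
                    n_splicotypes = 2, genes_per_splicotype = 4, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sim_truth(inj$truth, path)
  df <- read.delim(path)
  expect_setequal(df$gene_id, inj$truth$true_genes)
  expect_true(all(c("alpha", "beta", "u", "v", "splicotypes") %in% names(df)))
})
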