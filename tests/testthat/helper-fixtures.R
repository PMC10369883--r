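# Shared fixtures and independent oracles for the test suite.

# --- exact Mann-Whitney oracle (independent of the package implementation) --
# Number of arrangements of m x-ranks among m+n with Mann-Whitney statistic
# W = u, by the standard recurrence N(m,n,u) = N(m-1,n,u-n) + N(m,n-1,u).
mw_count_table <- function(m, n) {
  # f[[i]][j+1, u+1] built iteratively: counts for i x's and j y's
  maxu <- m * n
  f <- array(0, dim = c(m + 1, n + 1, maxu + 1))
  f[1, , 1] <- 1  # zero x's: only W = 0
  for (i in seq_len(m)) {
    f[i + 1, 1, 1] <- 1  # zero y's: only W = 0
    for (j in seq_len(n)) {
      for (u in 0:maxu) {
        a <- if (u - j >= 0) f[i, j + 1, u - j + 1] else 0
        b <- f[i + 1, j, u + 1]
        f[i + 1, j + 1, u + 1] <- a + b
      }
    }
  }
  f[m + 1, n + 1, ]
}

# Exact two-sided p-value by enumeration of the U distribution (no ties).
mw_exact_p_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  u <- sum(outer(x, y, ">"))
  pmf <- mw_count_table(m, n) / choose(m + n, m)
  pl <- sum(pmf[seq_len(u + 1)])
  pr <- sum(pmf[(u + 1):(m * n + 1)])
  min(1, 2 * min(pl, pr))
}

# --- small deterministic count tables ---------------------------------------
toy_counts <- function() {
  m <- matrix(c(10, 20, 30,
                5, 0, 15), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  spit_count_table(m, c(t1 = "g1", t2 = "g1"))
}

# A 2-gene/2-isoform table with clean fractions for IF checks.
two_gene_counts <- function() {
  m <- matrix(c(30, 60, 10,
                70, 40, 90,
                50,  0, 25,
                50,  0, 75),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("a1", "a2", "b1", "b2"),
                              c("s1", "s2", "s3")))
  spit_count_table(m, c(a1 = "gA", a2 = "gA", b1 = "gB", b2 = "gB"))
}

# Balanced metadata over given sample ids (first half case).
make_meta <- function(sample_ids, covariates = NULL) {
  n <- length(sample_ids)
  g <- stats::setNames(rep(c("case", "control"),
                           c(floor(n / 2), ceiling(n / 2))), sample_ids)
  spit_metadata(g, covariates)
}

# IF table straight from a matrix of fractions (bypassing counts).
if_table_from_matrix <- function(ifs, gene_of = NULL) {
  if (is.null(gene_of))
    gene_of <- stats::setNames(rownames(ifs), rownames(ifs))
  structure(list(ifs = ifs, tx_ids = rownames(ifs),
                 gene_of = gene_of, sample_ids = colnames(ifs)),
            class = "spit_if_table")
}
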