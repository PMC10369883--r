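#' Splicotype distance between two binary event vectors
#'
#' The proportion of events unique to either sample (the symmetric
#' difference of their event sets) relative to the total number of DTU
#' events detected.
#'
#' @param a,b Binary (0/1) vectors over the same genes.
#' @param total_events Total number of DTU genes (> 0); defaults to the
#'   vector length.
#' @return Distance in \[0, 1\].
#' @examples
#' splicotype_distance(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0))  # 2/5
#' @export
splicotype_distance <- function(a, b, total_events = length(a)) {
  if (length(a) != length(b)) stop("vectors must cover the same gene set")
  if (total_events <= 0) stop("total_events must be positive")
  sum(a != b) / total_events
}

#' Hierarchically cluster case samples on the DTU matrix
#'
#' Agglomerative clustering of the case samples under the splicotype
#' distance. The dendrogram is always computed; a flat assignment is added
#' when a cluster count `k` is requested. Average linkage is the default: on
#' a bounded set-difference metric it avoids the chaining behavior of single
#' linkage.
#'
#' @param dtu A `spit_dtu_matrix` (or a bare binary gene x sample matrix).
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param k Optional number of flat clusters.
#' @return Object of class `spit_clustering`: `dist` (the `dist` object),
#'   `hclust`, and `assignment` (named integer vector, or `NULL`).
#' @export
hierarchical_cluster <- function(dtu, linkage = "average", k = NULL) {
  M <- if (inherits(dtu, "spit_dtu_matrix")) dtu$M else as.matrix(dtu)
  if (nrow(M) == 0) stop("empty DTU matrix: nothing to cluster")
  if (ncol(M) < 2) stop("need at least 2 case samples to cluster")
  d <- stats::dist(t(M), method = "manhattan") / nrow(M)
  hc <- hclust(d, method = linkage)
  assignment <- if (!is.null(k)) cutree(hc, k = k) else NULL
  structure(list(dist = d, hclust = hc, assignment = assignment),
            class = "spit_clustering")
}

#' @export
print.spit_clustering <- function(x, ...) {
  cat(sprintf("spit_clustering: %d samples", attr(x$dist, "Size")))
  if (!is.null(x$assignment))
    cat(sprintf(", %d flat clusters", length(unique(x$assignment))))
  cat("\n")
  invisible(x)
}

#' Write a clustering dendrogram in Newick format
#'
#' @param clustering A `spit_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write flat cluster assignments to TSV
#'
#' @param clustering A `spit_clustering` with a flat assignment.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(clustering, path) {
  if (is.null(clustering$assignment))
    stop("clustering has no flat assignment; pass k to hierarchical_cluster")
  write.table(data.frame(sample_id = names(clustering$assignment),
                         cluster = unname(clustering$assignment)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
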