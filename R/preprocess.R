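#' Transform transcript counts to isoform fractions
#'
#' Each transcript's count is divided by the summed counts of all transcripts
#' of its gene in the same sample, so within a gene the fractions of a sample
#' sum to one. Genes with zero total count in a sample get IF = 0 for all of
#' their isoforms in that sample (such genes never survive the gene-count
#' pre-filter, so the convention is inert downstream).
#'
#' @param counts A [spit_count_table()].
#' @return An object of class `spit_if_table`: list with `ifs` (matrix of
#'   fractions in \[0, 1\]), `tx_ids`, `gene_of`, `sample_ids`.
#' @examples
#' m <- matrix(c(30, 70), nrow = 2, dimnames = list(c("t1", "t2"), "s1"))
#' ct <- spit_count_table(m, c(t1 = "g1", t2 = "g1"))
#' compute_if(ct)$ifs
#' @export
compute_if <- function(counts) {
  gsum <- rowsum(counts$counts, group = counts$gene_of, reorder = FALSE)
  denom <- gsum[match(counts$gene_of, rownames(gsum)), , drop = FALSE]
  ifs <- counts$counts / denom
  ifs[denom == 0] <- 0
  dimnames(ifs) <- dimnames(counts$counts)
  structure(list(ifs = ifs, tx_ids = counts$tx_ids,
                 gene_of = counts$gene_of, sample_ids = counts$sample_ids),
            class = "spit_if_table")
}

#' @export
print.spit_if_table <- function(x, ...) {
  cat(sprintf("spit_if_table: %d transcripts x %d samples\n",
              nrow(x$ifs), ncol(x$ifs)))
  invisible(x)
}

# Dominance indicator used by pre-filter step 6 and the simulator:
# for each gene, TRUE iff one isoform has the (untied) largest IF in at
# least fraction pd of the given samples. Ties count toward neither isoform.
consistent_dominance <- function(ifs, gene_of, samples, pd) {
  genes <- unique(gene_of)
  ok <- logical(length(genes))
  names(ok) <- genes
  sub <- ifs[, samples, drop = FALSE]
  for (g in genes) {
    rows <- which(gene_of == g)
    m <- sub[rows, , drop = FALSE]
    if (length(rows) == 1) { ok[g] <- TRUE; next }
    top <- apply(m, 2, function(col) {
      mx <- max(col)
      w <- which(col == mx)
      if (length(w) > 1) NA_integer_ else w
    })
    tab <- tabulate(top[!is.na(top)], nbins = length(rows))
    ok[g] <- any(tab >= pd * ncol(m))
  }
  ok
}

#' Pre-filter a count table
#'
#' Applies up to six stringent filtering steps, in order:
#' 1. each transcript must have CPM >= 10 in at least `n_small` samples
#'    (CPM computed against the per-sample total over the full input
#'    transcript set, fixed before filtering);
#' 2. each transcript must have a positive count in at least a fraction `pr`
#'    of the samples in both the case and the control group;
#' 3. each gene must have a read count of at least `gc` in at least `gn`
#'    samples;
#' 4. each transcript must have an IF value larger than `f` in at least
#'    `n_small` samples;
#' 5. at least 2 transcripts must remain for each gene;
#' 6. the control group must have a consistently dominant isoform for each
#'    gene: the same isoform has the largest IF in at least a fraction `pd`
#'    of control samples (ties count toward neither isoform).
#'
#' Isoform fractions are recomputed over the remaining transcripts after each
#' removal, so steps 4-6 see fractions that sum to one within each surviving
#' gene.
#'
#' @param counts A [spit_count_table()].
#' @param meta A [spit_metadata()].
#' @param params A [spit_params()].
#' @param enabled_steps Integer subset of 1:6; steps not listed are skipped
#'   (the simulator skips step 6 when constructing experiments).
#' @return List with `counts` (the filtered [spit_count_table()]) and
#'   `report` (class `spit_filter_report`): per-step transcript/gene removal
#'   counts and the surviving id sets.
#' @export
prefilter <- function(counts, meta, params = spit_params(),
                      enabled_steps = 1:6) {
  stopifnot(inherits(counts, "spit_count_table"),
            inherits(meta, "spit_metadata"))
  lib_size <- colSums(counts$counts)  # fixed denominator for CPM
  keep <- counts$tx_ids
  steps <- sort(intersect(enabled_steps, 1:6))
  report <- data.frame(step = steps, removed_transcripts = 0L,
                       removed_genes = 0L)
  cur <- counts

  drop_tx <- function(cur, keep_tx) {
    if (length(keep_tx) == 0) stop("empty matrix after filtering")
    subset_count_table(cur, tx = keep_tx)
  }

  for (k in seq_along(steps)) {
    s <- steps[k]
    before_tx <- cur$tx_ids
    before_genes <- unique(cur$gene_of)
    if (s == 1) {
      cpm <- sweep(cur$counts, 2, pmax(lib_size, 1), "/") * 1e6
      pass <- rowSums(cpm >= 10) >= params$n_small
      cur <- drop_tx(cur, cur$tx_ids[pass])
    } else if (s == 2) {
      pos_case <- rowSums(cur$counts[, meta$case_ids, drop = FALSE] > 0)
      pos_ctrl <- rowSums(cur$counts[, meta$control_ids, drop = FALSE] > 0)
      pass <- pos_case >= params$pr * length(meta$case_ids) &
        pos_ctrl >= params$pr * length(meta$control_ids)
      cur <- drop_tx(cur, cur$tx_ids[pass])
    } else if (s == 3) {
      gsum <- rowsum(cur$counts, cur$gene_of, reorder = FALSE)
      gpass <- rownames(gsum)[rowSums(gsum >= params$gc) >= params$gn]
      cur <- drop_tx(cur, cur$tx_ids[cur$gene_of %in% gpass])
    } else if (s == 4) {
      ifs <- compute_if(cur)$ifs
      pass <- rowSums(ifs > params$f) >= params$n_small
      cur <- drop_tx(cur, cur$tx_ids[pass])
    } else if (s == 5) {
      ntx <- table(cur$gene_of)
      gpass <- names(ntx)[ntx >= 2]
      cur <- drop_tx(cur, cur$tx_ids[cur$gene_of %in% gpass])
    } else if (s == 6) {
      ifs <- compute_if(cur)$ifs
      dom <- consistent_dominance(ifs, cur$gene_of, meta$control_ids,
                                  params$pd)
      gpass <- names(dom)[dom]
      cur <- drop_tx(cur, cur$tx_ids[cur$gene_of %in% gpass])
    }
    report$removed_transcripts[k] <- length(before_tx) - length(cur$tx_ids)
    report$removed_genes[k] <-
      length(before_genes) - length(unique(cur$gene_of))
  }

  rep_obj <- structure(list(per_step = report,
                            surviving_tx = cur$tx_ids,
                            surviving_genes = unique(cur$gene_of)),
                       class = "spit_filter_report")
  list(counts = cur, report = rep_obj)
}

#' @export
print.spit_filter_report <- function(x, ...) {
  cat("Pre-filter report:\n")
  print(x$per_step, row.names = FALSE)
  cat(sprintf("surviving: %d transcripts in %d genes\n",
              length(x$surviving_tx), length(x$surviving_genes)))
  invisible(x)
}

#' Write an isoform-fraction table to TSV
#'
#' @param if_table A `spit_if_table` from [compute_if()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_if_table <- function(if_table, path) {
  df <- data.frame(transcript_id = if_table$tx_ids,
                   gene_id = unname(if_table$gene_of), if_table$ifs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
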