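#' Test one transcript for differential transcript usage
#'
#' With a bimodal case partition, the left tails of case and control are
#' compared with a Mann-Whitney U test, as are the right tails; otherwise a
#' single whole-group test between all case and all control samples is used.
#' The transcript's minimal p-value is compared with the empirical-null
#' threshold; significance is strict (`p_min < threshold`).
#'
#' @param partition A `spit_partition` for the transcript.
#' @param case_ifs,control_ifs Named IF vectors for the transcript.
#' @param threshold Numeric threshold from [spit_threshold()] (may be `NA` to
#'   defer the significance call).
#' @return List of class `spit_test_result`: `p_left`, `p_right`, `p_min`,
#'   `mode` (`"tail_wise"` or `"whole_group"`), `significant`,
#'   `left_significant`, `right_significant`.
#' @export
test_transcript <- function(partition, case_ifs, control_ifs, threshold) {
  if (isTRUE(partition$bimodal) &&
      length(partition$l_case) >= 2 && length(partition$l_control) >= 2 &&
      length(partition$r_case) >= 2 && length(partition$r_control) >= 2) {
    p_left <- mann_whitney_p(case_ifs[partition$l_case],
                             control_ifs[partition$l_control])
    p_right <- mann_whitney_p(case_ifs[partition$r_case],
                              control_ifs[partition$r_control])
    p_min <- min(p_left, p_right)
    mode <- "tail_wise"
  } else {
    p_left <- NA_real_
    p_right <- NA_real_
    p_min <- mann_whitney_p(case_ifs, control_ifs)
    mode <- "whole_group"
  }
  structure(list(p_left = p_left, p_right = p_right, p_min = p_min,
                 mode = mode,
                 significant = isTRUE(p_min < threshold),
                 left_significant = isTRUE(p_left < threshold),
                 right_significant = isTRUE(p_right < threshold)),
            class = "spit_test_result")
}

#' Test every transcript against the threshold
#'
#' @param partitions Output of [partition_transcripts()].
#' @param if_table A `spit_if_table`.
#' @param meta A [spit_metadata()].
#' @param threshold Threshold from [spit_threshold()].
#' @return data.frame with one row per transcript (`transcript_id`,
#'   `gene_id`, `mode`, `p_left`, `p_right`, `p_min`, `significant`,
#'   `left_significant`, `right_significant`).
#' @export
test_transcripts <- function(partitions, if_table, meta, threshold) {
  tx <- names(partitions)
  res <- lapply(tx, function(id) {
    test_transcript(partitions[[id]],
                    if_table$ifs[id, meta$case_ids],
                    if_table$ifs[id, meta$control_ids],
                    threshold)
  })
  data.frame(
    transcript_id = tx,
    gene_id = unname(if_table$gene_of[tx]),
    mode = vapply(res, `[[`, character(1), "mode"),
    p_left = vapply(res, `[[`, numeric(1), "p_left"),
    p_right = vapply(res, `[[`, numeric(1), "p_right"),
    p_min = vapply(res, `[[`, numeric(1), "p_min"),
    significant = vapply(res, `[[`, logical(1), "significant"),
    left_significant = vapply(res, `[[`, logical(1), "left_significant"),
    right_significant = vapply(res, `[[`, logical(1), "right_significant"),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Per-transcript binary event vector over the case samples: which case
# samples carry the transcript's DTU event. Tail-wise transcripts mark the
# members of each individually significant tail; whole-group transcripts
# mark every case sample.
transcript_event_vector <- function(result_row, partition, case_ids) {
  v <- stats::setNames(rep(0L, length(case_ids)), case_ids)
  if (result_row$mode == "whole_group") {
    if (result_row$significant) v[] <- 1L
  } else {
    if (result_row$left_significant) v[partition$l_case] <- 1L
    if (result_row$right_significant) v[partition$r_case] <- 1L
  }
  v
}

#' Build the binary DTU event matrix M
#'
#' One row per gene with at least one significant, non-confounded transcript;
#' one column per case sample. An entry is 1 when the sample carries a DTU
#' event of the gene: for tail-wise transcripts the members of each
#' significant tail, for whole-group transcripts every case sample. A gene
#' row is the element-wise OR over its transcripts.
#'
#' @param results data.frame from [test_transcripts()].
#' @param partitions Output of [partition_transcripts()].
#' @param case_ids Case sample ids (matrix columns).
#' @param keep Optional named logical vector (transcript id -> keep) from the
#'   confounding filter; transcripts absent from it are kept.
#' @return Object of class `spit_dtu_matrix`: `M` (binary gene x case-sample
#'   matrix), `provenance` (data.frame transcript_id, gene_id), `tx_events`
#'   (list of per-transcript event vectors).
#' @export
build_dtu_matrix <- function(results, partitions, case_ids, keep = NULL) {
  sig <- results[results$significant, , drop = FALSE]
  if (!is.null(keep)) {
    drop <- names(keep)[!keep]
    sig <- sig[!(sig$transcript_id %in% drop), , drop = FALSE]
  }
  tx_events <- list()
  genes <- unique(sig$gene_id)
  M <- matrix(0L, length(genes), length(case_ids),
              dimnames = list(genes, case_ids))
  for (i in seq_len(nrow(sig))) {
    id <- sig$transcript_id[i]
    v <- transcript_event_vector(sig[i, ], partitions[[id]], case_ids)
    tx_events[[id]] <- v
    g <- sig$gene_id[i]
    M[g, ] <- pmax(M[g, ], v)
  }
  structure(list(M = M,
                 provenance = sig[, c("transcript_id", "gene_id")],
                 tx_events = tx_events),
            class = "spit_dtu_matrix")
}

#' @export
print.spit_dtu_matrix <- function(x, ...) {
  cat(sprintf("spit_dtu_matrix: %d gene(s) x %d case sample(s), %d events\n",
              nrow(x$M), ncol(x$M), sum(x$M)))
  invisible(x)
}

#' SPIT-Chart table
#'
#' For every transcript, pairs the median of its per-iteration minimal tail
#' p-values across the null-building iterations with the p-value observed in
#' the actual case-control comparison, both also on the -log10 scale.
#' Transcripts far above the diagonal are the strongest DTU candidates.
#'
#' @param null A `spit_null` built with `retain_p = TRUE`.
#' @param results data.frame from [test_transcripts()].
#' @return data.frame `transcript_id`, `median_null_p`, `observed_p`,
#'   `neg_log10_median_null_p`, `neg_log10_observed_p`.
#' @export
spit_chart <- function(null, results) {
  if (is.null(null$p_matrix))
    stop("null was built with retain_p = FALSE; medians unavailable")
  med <- apply(null$p_matrix, 1, median)
  med <- med[results$transcript_id]
  data.frame(transcript_id = results$transcript_id,
             median_null_p = unname(med),
             observed_p = results$p_min,
             neg_log10_median_null_p = -log10(unname(med)),
             neg_log10_observed_p = -log10(results$p_min),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write the DTU matrix to TSV
#'
#' @param dtu A `spit_dtu_matrix`.
#' @param path Output path (genes x case samples, 0/1; header always
#'   written, even when no gene is significant).
#' @return `path`, invisibly.
#' @export
write_dtu_matrix <- function(dtu, path) {
  df <- data.frame(gene_id = rownames(dtu$M), dtu$M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    df <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = ncol(dtu$M) + 1)),
      c("gene_id", colnames(dtu$M)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DTU matrix written by [write_dtu_matrix()]
#'
#' @param path Path to the TSV.
#' @return A `spit_dtu_matrix` (with empty provenance).
#' @export
read_dtu_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "integer"
  structure(list(M = M,
                 provenance = data.frame(transcript_id = character(0),
                                         gene_id = character(0)),
                 tx_events = list()),
            class = "spit_dtu_matrix")
}
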