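#' Construct a transcript-level count table
#'
#' The central data container of the pipeline: a transcripts x samples matrix
#' of non-negative integer counts plus a transcript-to-gene map.
#'
#' @param counts Numeric matrix, transcripts in rows, samples in columns.
#'   Row names are transcript ids and column names sample ids (or supply
#'   `tx_ids` / `sample_ids`). Values must be finite, non-negative and
#'   integer-valued (fractional quantifier estimates are rounded
#'   half-to-even by [read_counts()], not here).
#' @param gene_of Named character vector mapping transcript id -> gene id;
#'   must cover every transcript.
#' @param tx_ids,sample_ids Optional ids overriding the dimnames.
#' @return An object of class `spit_count_table` with elements `counts`,
#'   `tx_ids`, `gene_of`, `sample_ids`.
#' @examples
#' m <- matrix(c(10, 20, 30, 5, 0, 15), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
#' ct <- spit_count_table(m, c(t1 = "g1", t2 = "g1"))
#' @export
spit_count_table <- function(counts, gene_of, tx_ids = rownames(counts),
                             sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(tx_ids)) stop("transcript ids are required (row names)")
  if (is.null(sample_ids) || length(sample_ids) == 0)
    stop("no samples: the count table has no sample columns")
  if (anyDuplicated(tx_ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(tx_ids[duplicated(tx_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integer-valued")
  counts <- round(counts)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(tx_ids, sample_ids)
  missing_tx <- setdiff(tx_ids, names(gene_of))
  if (length(missing_tx) > 0) {
    stop("transcripts missing from the transcript-to-gene map: ",
         paste(missing_tx, collapse = ", "))
  }
  gene_of <- gene_of[tx_ids]
  structure(list(counts = counts, tx_ids = tx_ids,
                 gene_of = gene_of, sample_ids = sample_ids),
            class = "spit_count_table")
}

#' @export
print.spit_count_table <- function(x, ...) {
  cat(sprintf("spit_count_table: %d transcripts, %d genes, %d samples\n",
              length(x$tx_ids), length(unique(x$gene_of)),
              length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.spit_count_table <- function(x) dim(x$counts)

# Restrict a count table to a subset of transcripts and/or samples.
subset_count_table <- function(ct, tx = NULL, samples = NULL) {
  tx <- if (is.null(tx)) ct$tx_ids else tx
  samples <- if (is.null(samples)) ct$sample_ids else samples
  spit_count_table(ct$counts[tx, samples, drop = FALSE],
                   ct$gene_of[tx], tx_ids = tx, sample_ids = samples)
}

#' Read a transcript count matrix and transcript-to-gene map
#'
#' Reads a tab-delimited count file (first column transcript ids, remaining
#' columns one per sample, header row of sample ids) and a two-column
#' tab-delimited transcript-to-gene map. Fractional estimated counts (as
#' produced by quantifiers such as Salmon) are rounded half-to-even.
#'
#' @param path Path to the counts TSV.
#' @param tx2gene_path Path to the transcript-to-gene TSV (two columns:
#'   transcript id, gene id; a header is detected and skipped).
#' @return A [spit_count_table()].
#' @export
read_counts <- function(path, tx2gene_path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("no samples: counts file needs >= 1 sample column")
  tx_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed counts TSV: non-numeric count values")
  if (any(!is.finite(m))) stop("malformed counts TSV: missing/non-finite values")
  if (any(m < 0)) stop("counts must be non-negative")
  m <- round(m)  # half-to-even
  rownames(m) <- tx_ids

  t2g <- read.delim(tx2gene_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(t2g) < 2) stop("malformed tx2gene TSV: need two columns")
  # tolerate a header line
  if (nrow(t2g) > 0 && t2g[1, 1] %in% c("transcript_id", "tx", "TXNAME"))
    t2g <- t2g[-1, , drop = FALSE]
  gene_of <- stats::setNames(as.character(t2g[[2]]), as.character(t2g[[1]]))
  spit_count_table(m, gene_of)
}

#' Construct sample metadata
#'
#' @param group_of Named character vector sample id -> `"case"`/`"control"`.
#' @param covariates Optional data.frame of covariates, one row per sample
#'   (rownames = sample ids). Columns are used as numeric when numeric,
#'   otherwise as categorical (factor).
#' @return An object of class `spit_metadata` with elements `group_of`,
#'   `covariates`, `case_ids`, `control_ids`.
#' @export
spit_metadata <- function(group_of, covariates = NULL) {
  bad <- setdiff(unique(group_of), c("case", "control"))
  if (length(bad) > 0)
    stop("group values must be 'case' or 'control', found: ",
         paste(bad, collapse = ", "))
  if (is.null(names(group_of))) stop("group_of must be named by sample id")
  case_ids <- names(group_of)[group_of == "case"]
  control_ids <- names(group_of)[group_of == "control"]
  if (length(case_ids) == 0 || length(control_ids) == 0)
    stop("single-group design: both case and control groups must be non-empty")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    miss <- setdiff(names(group_of), rownames(covariates))
    if (length(miss) > 0)
      stop("covariate rows missing for samples: ", paste(miss, collapse = ", "))
    covariates <- covariates[names(group_of), , drop = FALSE]
    for (j in seq_along(covariates)) {
      if (!is.numeric(covariates[[j]]))
        covariates[[j]] <- factor(covariates[[j]])
    }
  }
  structure(list(group_of = group_of, covariates = covariates,
                 case_ids = case_ids, control_ids = control_ids),
            class = "spit_metadata")
}

#' @export
print.spit_metadata <- function(x, ...) {
  cat(sprintf("spit_metadata: %d case, %d control, %d covariate(s)\n",
              length(x$case_ids), length(x$control_ids),
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' Read sample metadata
#'
#' Reads a tab-delimited metadata file with columns `sample_id`, `group`
#' (values `case`/`control`) and zero or more covariate columns. Covariate
#' columns in which every value parses as a number become numeric covariates;
#' the rest become categorical.
#'
#' @param path Path to the metadata TSV.
#' @param samples Character vector of sample ids expected (normally
#'   `ct$sample_ids`); presence is validated in both directions.
#' @return A [spit_metadata()].
#' @export
read_metadata <- function(path, samples) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("metadata TSV must have columns sample_id and group")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  missing_meta <- setdiff(samples, df$sample_id)
  if (length(missing_meta) > 0)
    stop("samples present in counts but absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  extra <- setdiff(df$sample_id, samples)
  if (length(extra) > 0)
    stop("samples present in metadata but absent from counts: ",
         paste(extra, collapse = ", "))
  df <- df[match(samples, df$sample_id), , drop = FALSE]
  group_of <- stats::setNames(df$group, df$sample_id)
  cov_cols <- setdiff(names(df), need)
  covariates <- NULL
  if (length(cov_cols) > 0) {
    covariates <- df[, cov_cols, drop = FALSE]
    rownames(covariates) <- df$sample_id
    for (j in seq_along(covariates)) {
      v <- covariates[[j]]
      num <- suppressWarnings(as.numeric(v))
      covariates[[j]] <- if (!any(is.na(num))) num else factor(v)
    }
  }
  spit_metadata(group_of, covariates)
}

#' Write a count table to TSV
#'
#' @param ct A [spit_count_table()].
#' @param path Output path; a `transcript_id` first column is written.
#' @param tx2gene_path Optional path for the matching transcript-to-gene TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(ct, path, tx2gene_path = NULL) {
  df <- data.frame(transcript_id = ct$tx_ids, ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tx2gene_path)) {
    write.table(data.frame(ct$tx_ids, unname(ct$gene_of[ct$tx_ids])),
                tx2gene_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write sample metadata to TSV
#'
#' @param meta A [spit_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  df <- data.frame(sample_id = names(meta$group_of),
                   group = unname(meta$group_of),
                   stringsAsFactors = FALSE)
  if (!is.null(meta$covariates)) {
    cv <- meta$covariates
    for (j in seq_along(cv)) cv[[j]] <- as.character(cv[[j]])
    df <- cbind(df, cv)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
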