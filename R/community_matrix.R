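#' Read an OTU read-count table from delimited text
#'
#' Reads a samples-by-OTUs (or OTUs-by-samples) table of non-negative
#' integer read counts with a header row and row identifiers in the first
#' column. The result is always oriented samples x OTUs.
#'
#' @param path Path to a CSV/TSV file.
#' @param orientation Either `"samples_by_otus"` (rows are samples) or
#'   `"otus_by_samples"` (rows are OTUs; the table is transposed on read).
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return An integer matrix of class `read_count_table` with sample ids as
#'   row names and OTU ids as column names.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_by_otus",
                                             "otus_by_samples"),
                             sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  m <- as.matrix(body)
  if (!is.numeric(m))
    storage.mode(m) <- "double"
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at row '%s', column '%s'",
      ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  if (orientation == "otus_by_samples") m <- t(m)
  as_read_count_table(m)
}

#' Construct a read-count table from a matrix
#'
#' @param m Non-negative integer matrix, samples in rows, OTUs in columns,
#'   with row and column names.
#' @return An object of class `read_count_table`.
#' @export
as_read_count_table <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("sample and OTU identifiers (dimnames) are required")
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicate sample identifier '%s'",
                 rownames(m)[duplicated(rownames(m))][1]))
  if (anyDuplicated(colnames(m)))
    stop(sprintf("duplicate OTU identifier '%s'",
                 colnames(m)[duplicated(colnames(m))][1]))
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be finite non-negative integers")
  storage.mode(m) <- "integer"
  class(m) <- c("read_count_table", class(matrix()))
  m
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(sprintf("Read-count table: %d samples x %d OTUs, %s reads total\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

rct_subset <- function(m, rows = NULL, cols = NULL) {
  cl <- class(m)
  out <- unclass(m)
  if (!is.null(rows)) out <- out[rows, , drop = FALSE]
  if (!is.null(cols)) out <- out[, cols, drop = FALSE]
  class(out) <- cl
  out
}

#' Remove samples with low sequencing depth
#'
#' Samples whose total read count is strictly less than `min_reads` are
#' removed; a sample with exactly `min_reads` reads is retained.
#'
#' @param table A `read_count_table`.
#' @param min_reads Minimum total reads per sample (default 20).
#' @return Filtered `read_count_table`.
#' @export
filter_low_read_samples <- function(table, min_reads = 20) {
  stopifnot(min_reads >= 0)
  keep <- rowSums(table) >= min_reads
  if (!any(keep))
    warning("all samples fall below the read threshold; empty table returned")
  rct_subset(table, rows = keep)
}

#' Zero out within-sample minor OTUs
#'
#' Within each sample independently, counts that make up strictly less than
#' `threshold` of that sample's total reads are set to zero (a count equal
#' to exactly `threshold` x total is kept). OTU columns left with no reads
#' anywhere are dropped when `drop_empty = TRUE`.
#'
#' @param table A `read_count_table`.
#' @param threshold Within-sample relative-abundance cutoff in \[0, 1\]
#'   (default 0.05).
#' @param drop_empty Drop all-zero OTU columns afterwards (default `TRUE`).
#' @return Filtered `read_count_table`.
#' @export
filter_minor_otus <- function(table, threshold = 0.05, drop_empty = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1)
  tot <- rowSums(table)
  m <- unclass(table)
  pos <- tot > 0
  if (any(pos)) {
    frac <- m[pos, , drop = FALSE] / tot[pos]
    sub <- m[pos, , drop = FALSE]
    sub[frac < threshold] <- 0L
    m[pos, ] <- sub
  }
  class(m) <- class(table)
  if (drop_empty) m <- rct_subset(m, cols = colSums(m) > 0)
  m
}

#' Remove samples flagged for contamination
#'
#' Drops samples whose metadata record has `exclude_flag = TRUE` (e.g.
#' samples containing non-host plant DNA).
#'
#' @param table A `read_count_table`.
#' @param metadata Data frame with columns `sample_id` and `exclude_flag`
#'   (plus optional `host`, `x`, `y`).
#' @return Filtered `read_count_table`.
#' @export
drop_flagged_samples <- function(table, metadata) {
  metadata <- validate_metadata(metadata)
  missing <- setdiff(rownames(table), metadata$sample_id)
  if (length(missing) > 0)
    stop(sprintf("no metadata record for sample '%s'", missing[1]))
  flagged <- metadata$sample_id[isTRUE_vec(metadata$exclude_flag)]
  keep <- !(rownames(table) %in% flagged)
  if (!any(keep))
    warning("all samples flagged; empty table returned")
  rct_subset(table, rows = keep)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

validate_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% names(metadata))
    stop("metadata must have a 'sample_id' column")
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  if (!"exclude_flag" %in% names(metadata)) metadata$exclude_flag <- FALSE
  if (all(c("x", "y") %in% names(metadata))) {
    if (any(!is.finite(metadata$x) | !is.finite(metadata$y)))
      stop("coordinates must be finite")
  }
  metadata
}

#' Convert a read-count table to a binary community matrix
#'
#' @param table A `read_count_table` (or 0/1 matrix).
#' @return A `bincom` presence/absence matrix (1 where count > 0).
#' @export
binarize <- function(table) {
  if (nrow(table) == 0 || ncol(table) == 0)
    stop("cannot binarize an empty table")
  as_bincom((unclass(table) > 0) * 1L, dimnames = dimnames(table))
}

#' Binary community matrix
#'
#' Constructs a samples-by-OTUs presence/absence matrix. Per-OTU occurrence
#' totals and per-sample richness are exposed through [occurrence()] and
#' [richness()].
#'
#' @param x Matrix of 0/1 values (samples in rows).
#' @param dimnames Optional dimnames to attach.
#' @return An integer matrix of class `bincom`.
#' @export
as_bincom <- function(x, dimnames = NULL) {
  x <- as.matrix(x)
  if (!is.null(dimnames)) dimnames(x) <- dimnames
  if (any(!(x %in% c(0, 1))))
    stop("presence matrix must contain only 0 and 1")
  storage.mode(x) <- "integer"
  if (is.null(rownames(x)))
    rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("otu_", seq_len(ncol(x)))
  class(x) <- c("bincom", class(matrix()))
  x
}

#' @rdname as_bincom
#' @export
occurrence <- function(x) colSums(unclass(x))

#' @rdname as_bincom
#' @export
richness <- function(x) rowSums(unclass(x))

#' @export
print.bincom <- function(x, ...) {
  cat(sprintf(
    "Binary community matrix: %d samples x %d OTUs, fill %.3f, mean richness %.2f\n",
    nrow(x), ncol(x), mean(unclass(x)), mean(richness(x))))
  invisible(x)
}

#' Apply the full filtering pipeline and binarize
#'
#' Convenience wrapper applying, in order: the low-read sample filter, the
#' within-sample minor-OTU filter, removal of flagged (contaminated)
#' samples, and binarization. Empty OTU columns are dropped so matrix
#' dimensions reflect the retained community.
#'
#' @param table A `read_count_table`.
#' @param metadata Optional sample metadata (for the contamination filter).
#' @param min_reads Per-sample read threshold (default 20).
#' @param threshold Within-sample minor-OTU proportion (default 0.05).
#' @return A `bincom` matrix.
#' @export
prepare_matrix <- function(table, metadata = NULL, min_reads = 20,
                           threshold = 0.05) {
  table <- filter_low_read_samples(table, min_reads)
  table <- filter_minor_otus(table, threshold)
  if (!is.null(metadata)) table <- drop_flagged_samples(table, metadata)
  table <- rct_subset(table, cols = colSums(table) > 0)
  binarize(table)
}

#' Screen OTU pairs eligible for randomization testing
#'
#' Returns all unordered OTU pairs (i, j) such that each member occurs in at
#' least `min_occurrence` samples and the two occurrence totals sum to at
#' least `min_pair_sum`. These are the eligibility rules applied before the
#' pairwise randomization tests (5/25 per host dataset, 10/50 pooled).
#'
#' @param matrix A `bincom` matrix.
#' @param min_occurrence Minimum per-OTU occurrence (default 5).
#' @param min_pair_sum Minimum summed occurrence of the pair (default 25).
#' @return A data frame of class `pair_set` with columns `i`, `j` (column
#'   indices, i < j), `otu_i`, `otu_j`, `R_i`, `R_j`.
#' @export
screen_pairs <- function(matrix, min_occurrence = 5, min_pair_sum = 25) {
  stopifnot(min_occurrence >= 0, min_pair_sum >= 0)
  R <- occurrence(matrix)
  eligible <- which(R >= min_occurrence)
  if (length(eligible) < 2) {
    warning("fewer than 2 OTUs pass the occurrence threshold; no pairs")
    out <- data.frame(i = integer(), j = integer(),
                      otu_i = character(), otu_j = character(),
                      R_i = integer(), R_j = integer())
  } else {
    cmb <- t(combn(eligible, 2L))
    keep <- R[cmb[, 1]] + R[cmb[, 2]] >= min_pair_sum
    cmb <- cmb[keep, , drop = FALSE]
    out <- data.frame(
      i = cmb[, 1], j = cmb[, 2],
      otu_i = colnames(matrix)[cmb[, 1]],
      otu_j = colnames(matrix)[cmb[, 2]],
      R_i = R[cmb[, 1]], R_j = R[cmb[, 2]],
      row.names = NULL)
  }
  attr(out, "min_occurrence") <- min_occurrence
  attr(out, "min_pair_sum") <- min_pair_sum
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Write / read a binary community matrix as CSV
#'
#' The on-disk layout is samples x OTUs with sample identifiers in the
#' first column, so a pre-filtered deposited matrix in the same layout can
#' be loaded directly. On read, orientation is detected from the axis
#' sizes when ambiguous cues are absent, and a non-numeric `host` column,
#' if present, is split off into an attribute.
#'
#' @param matrix A `bincom` matrix.
#' @param path Output / input CSV path.
#' @return `read_binary_matrix` returns a `bincom` matrix (with attribute
#'   `host` when a host-label column was present in the file).
#' @export
write_binary_matrix <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix),
                   unclass(matrix), check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binary_matrix
#' @export
read_binary_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  host <- NULL
  nonnum <- !vapply(body, is.numeric, logical(1))
  if (any(nonnum)) {
    hc <- which(nonnum)[1]
    host <- as.character(body[[hc]])
    body <- body[, vapply(body, is.numeric, logical(1)), drop = FALSE]
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  out <- as_bincom(m)
  if (!is.null(host)) attr(out, "host") <- setNames(host, ids)
  out
}
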