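#' OTU count tables
#'
#' An OTU table is represented as a tibble whose first column, `sample_id`,
#' holds unique sample labels and whose remaining columns hold non-negative
#' integer read counts, one column per OTU. This is the canonical
#' samples-by-OTUs orientation used throughout the package; on disk the
#' classic tab-separated dialect (OTUs as rows, optional `#OTU ID` header)
#' is supported as well.
#'
#' @param path Path to a tab-separated count table.
#' @param orientation Orientation of the file: `"otus_as_rows"` (classic
#'   dialect, the default) or `"samples_as_rows"`.
#' @return A validated tibble (`sample_id` plus one numeric column per OTU).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("#OTU ID\tS1\tS2", "OTU_1\t5\t0", "OTU_2\t0\t5"), tf)
#' read_otu_table(tf)
#' @export
read_otu_table <- function(path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    abort(paste0("OTU table file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  # Leading comment lines without tabs (e.g. "# Constructed from biom file")
  # are skipped; the header itself may start with "#OTU ID".
  while (length(lines) > 0 && startsWith(lines[[1]], "#") && !grepl("\t", lines[[1]], fixed = TRUE)) {
    lines <- lines[-1]
  }
  if (length(lines) < 2) {
    abort("OTU table must contain a header row and at least one data row")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  n_col <- length(header)
  bad_len <- which(lengths(body) != n_col)
  if (length(bad_len) > 0) {
    abort(paste0("row ", bad_len[[1]] + 1L, " has ", lengths(body)[bad_len[[1]]],
                 " fields, expected ", n_col))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  col_ids <- header[-1]
  cells <- do.call(rbind, lapply(body, function(x) x[-1]))
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | !is_wholenumber(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(paste0("count cell at row '", row_ids[i], "', column '", col_ids[j],
                 "' is not a non-negative integer: '", cells[i, j], "'"))
  }
  mat <- matrix(num, nrow = nrow(cells), dimnames = list(row_ids, col_ids))
  if (orientation == "otus_as_rows") mat <- t(mat)
  as_otu_tbl(mat)
}

#' Write an OTU table in the classic tab-separated dialect
#'
#' @param table An OTU table tibble (see [read_otu_table()]).
#' @param path Output path.
#' @param orientation Orientation to write; the default `"otus_as_rows"`
#'   produces the classic `#OTU ID` layout.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  mat <- otu_matrix(table)
  if (orientation == "otus_as_rows") {
    mat <- t(mat)
    header <- paste(c("#OTU ID", colnames(mat)), collapse = "\t")
  } else {
    header <- paste(c("sample_id", colnames(mat)), collapse = "\t")
  }
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format(mat[i, ], scientific = FALSE, trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# Construct the canonical tibble from a samples-by-OTUs matrix.
as_otu_tbl <- function(mat) {
  if (anyDuplicated(rownames(mat))) {
    abort(paste0("duplicated sample id: ",
                 rownames(mat)[duplicated(rownames(mat))][[1]]))
  }
  if (anyDuplicated(colnames(mat))) {
    abort(paste0("duplicated OTU id: ",
                 colnames(mat)[duplicated(colnames(mat))][[1]]))
  }
  out <- as_tibble(mat, .name_repair = "minimal")
  out <- bind_cols(tibble(sample_id = rownames(mat)), out)
  validate_otu_table(out)
}

#' Validate an OTU table tibble
#'
#' Checks the structural invariants: a `sample_id` first column with unique
#' labels, unique OTU column names, and non-negative integral counts.
#'
#' @param table A candidate OTU table tibble.
#' @return The table, invisibly usable in a pipe (returned unchanged).
#' @export
validate_otu_table <- function(table) {
  if (!is.data.frame(table) || ncol(table) < 2 || names(table)[[1]] != "sample_id") {
    abort("an OTU table must be a data frame with 'sample_id' as its first column")
  }
  if (anyDuplicated(table$sample_id)) {
    abort(paste0("duplicated sample id: ", table$sample_id[duplicated(table$sample_id)][[1]]))
  }
  if (anyDuplicated(names(table))) {
    abort(paste0("duplicated OTU id: ", names(table)[duplicated(names(table))][[1]]))
  }
  counts <- as.matrix(table[, -1, drop = FALSE])
  if (!is.numeric(counts)) {
    abort("OTU counts must be numeric")
  }
  if (any(!is_wholenumber(counts)) || any(counts < 0)) {
    abort("OTU counts must be non-negative integers")
  }
  as_tibble(table)
}

# Samples-by-OTUs numeric matrix with sample ids as rownames. Counts must
# be integral; proportion tables use numeric_matrix() below.
otu_matrix <- function(table) {
  validate_otu_table(table)
  mat <- as.matrix(table[, -1, drop = FALSE])
  rownames(mat) <- table$sample_id
  storage.mode(mat) <- "double"
  mat
}

# Same shape checks as otu_matrix() but admits real-valued entries
# (relative abundances).
numeric_matrix <- function(table) {
  if (!is.data.frame(table) || ncol(table) < 2 || names(table)[[1]] != "sample_id") {
    abort("expected a data frame with 'sample_id' as its first column")
  }
  if (anyDuplicated(table$sample_id)) {
    abort(paste0("duplicated sample id: ", table$sample_id[duplicated(table$sample_id)][[1]]))
  }
  mat <- as.matrix(table[, -1, drop = FALSE])
  if (!is.numeric(mat) || any(mat < 0) || any(!is.finite(mat))) {
    abort("entries must be finite non-negative numbers")
  }
  rownames(mat) <- table$sample_id
  mat
}

otu_ids <- function(table) setdiff(names(table), "sample_id")

#' Convert counts to within-sample relative abundances
#'
#' Each count is divided by its sample's total, so every row of the result
#' sums to one.
#'
#' @param table An OTU table tibble.
#' @return A tibble of the same shape with proportions in place of counts.
#' @examples
#' tbl <- tibble::tibble(sample_id = "a", OTU_1 = 2, OTU_2 = 2, OTU_3 = 0)
#' relative_abundance(tbl)
#' @export
relative_abundance <- function(table) {
  mat <- otu_matrix(table)
  totals <- rowSums(mat)
  if (any(totals <= 0)) {
    abort(paste0("sample '", rownames(mat)[totals <= 0][[1]],
                 "' has zero total reads; cannot compute relative abundance"))
  }
  prop <- sweep(mat, 1, totals, "/")
  bind_cols(tibble(sample_id = rownames(prop)), as_tibble(prop, .name_repair = "minimal"))
}

#' Filter OTUs by prevalence and pooled read share
#'
#' Retains OTUs detected (count > 0) in at least `min_individuals` samples
#' AND holding at least `min_total_proportion` of the pooled read total
#' across all samples. Both thresholds are inclusive. The sample set is
#' never changed. The fraction of reads retained is attached as the
#' `retained_read_fraction` attribute.
#'
#' @param table An OTU table tibble.
#' @param min_individuals Minimum number of samples an OTU must occur in.
#' @param min_total_proportion Minimum share of the pooled grand total
#'   (e.g. `0.001` for 0.1%).
#' @return The filtered OTU table (possibly with zero OTU columns).
#' @export
filter_otus <- function(table, min_individuals = 0, min_total_proportion = 0) {
  stopifnot(min_individuals >= 0, min_total_proportion >= 0, min_total_proportion <= 1)
  mat <- otu_matrix(table)
  prevalence <- colSums(mat > 0)
  grand_total <- sum(mat)
  share <- if (grand_total > 0) colSums(mat) / grand_total else rep(0, ncol(mat))
  keep <- prevalence >= min_individuals & share >= min_total_proportion
  out <- table[, c("sample_id", colnames(mat)[keep]), drop = FALSE]
  attr(out, "retained_read_fraction") <-
    if (grand_total > 0) sum(mat[, keep, drop = FALSE]) / grand_total else NA_real_
  out
}
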