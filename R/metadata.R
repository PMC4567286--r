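#' Read per-sample metadata
#'
#' Metadata files are tab-separated with columns `sample_id`, `sex`,
#' `pair_id` and `colony_id`. Sex tokens `M`, `F`, `male`, `female` are
#' accepted case-insensitively and normalised to `"M"`/`"F"`.
#'
#' @param path Path to the metadata TSV.
#' @return A validated tibble with columns `sample_id`, `sex`, `pair_id`,
#'   `colony_id`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("metadata file not found: ", path))
  }
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  validate_sample_metadata(meta)
}

#' Write per-sample metadata as TSV
#'
#' @param metadata A metadata tibble (see [read_sample_metadata()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(validate_sample_metadata(metadata), path)
  invisible(path)
}

#' Validate a sample-metadata table
#'
#' Normalises sex tokens and checks the pairing invariants: unique sample
#' ids and no breeding pair with two members of the same sex. Pairs with a
#' single recorded member are tolerated here; the pair-similarity tests
#' reject them.
#'
#' @param metadata A data frame with columns `sample_id`, `sex`, `pair_id`,
#'   `colony_id`.
#' @return The normalised metadata tibble.
#' @export
validate_sample_metadata <- function(metadata) {
  required <- c("sample_id", "sex", "pair_id", "colony_id")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(metadata) == 0) {
    abort("no samples in metadata")
  }
  meta <- as_tibble(metadata)[required]
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicated sample id in metadata: ",
                 meta$sample_id[duplicated(meta$sample_id)][[1]]))
  }
  tok <- tolower(trimws(meta$sex))
  sex <- dplyr::case_when(
    tok %in% c("m", "male") ~ "M",
    tok %in% c("f", "female") ~ "F",
    TRUE ~ NA_character_
  )
  if (anyNA(sex)) {
    abort(paste0("unknown sex token: '", meta$sex[is.na(sex)][[1]],
                 "' (expected M/F/male/female)"))
  }
  meta$sex <- sex
  dup_sex <- meta |>
    count(.data$pair_id, .data$sex) |>
    filter(.data$n > 1)
  if (nrow(dup_sex) > 0) {
    abort(paste0("pair '", dup_sex$pair_id[[1]], "' has ", dup_sex$n[[1]],
                 " samples of sex ", dup_sex$sex[[1]]))
  }
  meta
}

# One row per complete male-female pair, ordered by pair id so results do
# not depend on metadata row order; errors (naming the pairs) when a pair
# is missing a member, since the pair tests are undefined for it.
pair_members <- function(metadata) {
  meta <- arrange(validate_sample_metadata(metadata), .data$pair_id)
  pairs <- meta |>
    select("pair_id", "sex", "sample_id") |>
    pivot_wider(names_from = "sex", values_from = "sample_id")
  for (col in c("M", "F")) {
    if (!col %in% names(pairs)) pairs[[col]] <- NA_character_
  }
  incomplete <- pairs$pair_id[is.na(pairs$M) | is.na(pairs$F)]
  if (length(incomplete) > 0) {
    abort(paste0("incomplete breeding pair(s): ", paste(incomplete, collapse = ", ")))
  }
  tibble(pair_id = pairs$pair_id, male = pairs$M, female = pairs$F)
}
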