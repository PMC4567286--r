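#' Pairwise community distance matrices
#'
#' Distance results are stored as a `comm_dist` object: a symmetric matrix
#' of pairwise sample distances plus the metric name and, when the input
#' was rarefied, the rarefaction depth and seed. `as.matrix()`,
#' `as.dist()` and `tidy()` convert to the usual forms.
#'
#' @name comm_dist
NULL

new_comm_dist <- function(d, metric, rarefaction_depth = NULL, seed = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  structure(
    list(d = d, metric = metric,
         rarefaction_depth = rarefaction_depth %||% NA_integer_,
         seed = seed %||% NA_integer_,
         sample_ids = rownames(d)),
    class = "comm_dist"
  )
}

#' @export
as.matrix.comm_dist <- function(x, ...) x$d

#' @export
print.comm_dist <- function(x, ...) {
  cat("<comm_dist> ", x$metric, ": ", nrow(x$d), " samples", sep = "")
  if (!is.na(x$rarefaction_depth)) cat(", rarefied to ", x$rarefaction_depth, sep = "")
  cat("\n")
  print(round(x$d, 4))
  invisible(x)
}

#' @rdname comm_dist
#' @param x A `comm_dist` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per unordered sample pair with columns
#'   `sample_a`, `sample_b`, `distance`, `metric`.
#' @export
tidy.comm_dist <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    sample_a = rownames(x$d)[idx[, 1]],
    sample_b = colnames(x$d)[idx[, 2]],
    distance = x$d[idx],
    metric = x$metric
  )
}

#' Write a distance matrix as square TSV
#'
#' @param d A `comm_dist` object (or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- bind_cols(tibble(sample_id = rownames(m)),
                  as_tibble(m, .name_repair = "minimal"))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Hellinger distance between samples
#'
#' Euclidean distance between square-rooted relative-abundance vectors;
#' bounded above by `sqrt(2)` (attained by samples with no shared OTU).
#'
#' @param table An OTU table tibble (counts; converted to proportions
#'   internally). Row totals must be positive.
#' @return A [comm_dist] object.
#' @export
hellinger_dist <- function(table) {
  mat <- otu_matrix(table)
  if (any(rowSums(mat) <= 0)) {
    abort(paste0("sample '", rownames(mat)[rowSums(mat) <= 0][[1]],
                 "' has zero total reads"))
  }
  h <- vegan::decostand(mat, method = "hellinger")
  d <- as.matrix(stats::dist(h))
  new_comm_dist(d, "hellinger",
                rarefaction_depth = attr(table, "rarefaction_depth"),
                seed = attr(table, "seed"))
}

#' UniFrac distances between samples
#'
#' Phylogeny-aware beta diversity. Unweighted UniFrac is the fraction of
#' branch length unique to one of the two samples among branch length
#' leading to taxa present in either; weighted UniFrac sums branch lengths
#' weighted by the difference in the fraction of each sample's reads
#' descending from the branch, optionally normalised to `[0, 1]` by the
#' abundance-weighted root-to-leaf distances.
#'
#' @param table An OTU table tibble; every OTU with a nonzero count must be
#'   a leaf of `tree`.
#' @param tree A rooted `phylo` with branch lengths.
#' @param weighted Use abundance weighting (default `FALSE`).
#' @param normalized For the weighted variant, divide by the maximal
#'   attainable value (default `FALSE`, the raw sum as in QIIME 1.x).
#' @return A [comm_dist] object with metric `"unweighted_unifrac"`,
#'   `"weighted_unifrac_raw"` or `"weighted_unifrac_normalized"`.
#' @export
unifrac_dist <- function(table, tree, weighted = FALSE, normalized = FALSE) {
  validate_phylo_tree(tree)
  mat <- otu_matrix(table)
  if (any(rowSums(mat) <= 0)) {
    abort(paste0("sample '", rownames(mat)[rowSums(mat) <= 0][[1]],
                 "' has zero total reads"))
  }
  check_leaves(colnames(mat)[colSums(mat) > 0], tree)
  keep <- intersect(colnames(mat), tree$tip.label)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(mat[, keep, drop = FALSE], taxa_are_rows = FALSE),
    phyloseq::phy_tree(tree)
  )
  d <- as.matrix(phyloseq::UniFrac(ps, weighted = weighted,
                                   normalized = normalized, parallel = FALSE))
  d <- d[rownames(mat), rownames(mat)]
  metric <- if (!weighted) {
    "unweighted_unifrac"
  } else if (normalized) {
    "weighted_unifrac_normalized"
  } else {
    "weighted_unifrac_raw"
  }
  new_comm_dist(d, metric,
                rarefaction_depth = attr(table, "rarefaction_depth"),
                seed = attr(table, "seed"))
}

#' Rarefied beta-diversity matrices
#'
#' Convenience wrapper: rarefies the table once to `depth` and computes the
#' requested distance matrices on the same subsample, mirroring the usual
#' practice of computing all metrics at a common depth.
#'
#' @param table An OTU table tibble.
#' @param tree Rooted phylogeny (required for UniFrac metrics).
#' @param metrics Subset of `c("hellinger", "unweighted_unifrac",
#'   "weighted_unifrac")`.
#' @param depth Rarefaction depth; `NULL` skips rarefaction.
#' @param seed Optional integer seed for the rarefaction draw.
#' @param weighted_normalized Use the normalised weighted variant.
#' @return A named list of [comm_dist] objects.
#' @export
beta_diversity <- function(table, tree = NULL,
                           metrics = c("hellinger", "unweighted_unifrac", "weighted_unifrac"),
                           depth = 1600, seed = NULL, weighted_normalized = FALSE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (any(metrics != "hellinger") && is.null(tree)) {
    abort("a phylogeny is required for UniFrac metrics")
  }
  tbl <- if (is.null(depth)) table else rarefy(table, depth, seed = seed)
  out <- list()
  for (m in metrics) {
    out[[m]] <- switch(m,
      hellinger = hellinger_dist(tbl),
      unweighted_unifrac = unifrac_dist(tbl, tree, weighted = FALSE),
      weighted_unifrac = unifrac_dist(tbl, tree, weighted = TRUE,
                                      normalized = weighted_normalized)
    )
  }
  out
}
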