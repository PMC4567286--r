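#' Chao1 richness estimate for one sample
#'
#' The classic estimator \eqn{S_{obs} + F_1^2 / (2 F_2)} from singleton
#' (\eqn{F_1}) and doubleton (\eqn{F_2}) counts; when no doubletons are
#' present the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} is used so the estimate is
#' defined for every sample.
#'
#' @param counts Non-negative integer count vector for a single sample.
#' @return The estimated richness (always `>=` observed richness).
#' @examples
#' chao1(c(1, 1, 2, 3)) # 6
#' @export
chao1 <- function(counts) {
  counts <- check_sample_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' Good's coverage for one sample
#'
#' `1 - F1/N`: the estimated fraction of the community captured by the
#' reads, where `F1` is the number of singleton OTUs and `N` the read total.
#'
#' @inheritParams chao1
#' @return Coverage in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  counts <- check_sample_counts(counts)
  1 - sum(counts == 1) / sum(counts)
}

check_sample_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || any(!is_wholenumber(counts)) || any(counts < 0)) {
    abort("counts must be a non-empty vector of non-negative integers")
  }
  if (sum(counts) == 0) {
    abort("all counts are zero; diversity is undefined for an empty sample")
  }
  counts
}

#' Faith's phylogenetic diversity for one sample
#'
#' Total branch length of the minimal subtree connecting the root and all
#' OTUs observed in the sample (the path to the root is included).
#'
#' @param counts Named non-negative count vector (names are OTU ids), or a
#'   character vector of observed OTU ids.
#' @param tree A rooted `phylo` whose leaves include every observed OTU.
#' @return Total branch length; `0` for an empty sample.
#' @export
faith_pd <- function(counts, tree) {
  validate_phylo_tree(tree)
  if (is.character(counts)) {
    present <- unique(counts)
  } else {
    if (is.null(names(counts))) {
      abort("counts must be named by OTU id (or be a character vector of ids)")
    }
    present <- names(counts)[counts > 0]
  }
  if (length(present) == 0) {
    return(0)
  }
  check_leaves(present, tree)
  comm <- matrix(as.integer(tree$tip.label %in% present), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  picante::pd(comm, tree, include.root = TRUE)$PD[[1]]
}

#' Per-sample alpha diversity summary
#'
#' Observed richness, singleton/doubleton counts, Chao1, Good's coverage
#' and (when a tree is supplied) Faith's PD for every sample of an OTU
#' table.
#'
#' @param table An OTU table tibble.
#' @param tree Optional rooted phylogeny for Faith's PD.
#' @return A tibble with one row per sample: `sample_id`, `n_reads`,
#'   `s_obs`, `f1`, `f2`, `chao1`, `goods_coverage`, and `faith_pd` if a
#'   tree was given.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  mat <- otu_matrix(table)
  if (any(rowSums(mat) == 0)) {
    abort(paste0("sample '", rownames(mat)[rowSums(mat) == 0][[1]],
                 "' has zero total reads"))
  }
  out <- tibble(
    sample_id = rownames(mat),
    n_reads = rowSums(mat),
    s_obs = rowSums(mat > 0),
    f1 = rowSums(mat == 1),
    f2 = rowSums(mat == 2),
    chao1 = unname(apply(mat, 1, chao1)),
    goods_coverage = unname(apply(mat, 1, goods_coverage))
  )
  if (!is.null(tree)) {
    validate_phylo_tree(tree)
    check_leaves(colnames(mat)[colSums(mat) > 0], tree)
    comm <- (mat > 0) * 1
    keep <- intersect(tree$tip.label, colnames(comm))
    pd <- picante::pd(comm[, keep, drop = FALSE], tree, include.root = TRUE)
    out$faith_pd <- pd$PD[match(out$sample_id, rownames(pd))]
  }
  out
}

#' Rarefy an OTU table to a fixed read depth
#'
#' Draws, for every sample, a random subsample of exactly `depth` reads
#' without replacement. Samples whose total is below `depth` are dropped
#' with a warning. The draw is reproducible for a fixed `seed`.
#'
#' @param table An OTU table tibble.
#' @param depth Target depth (reads per sample), a positive integer.
#' @param seed Optional integer seed.
#' @return The rarefied OTU table; every row sums to exactly `depth`.
#'   Attributes `rarefaction_depth` and `seed` record the draw.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  if (length(depth) != 1 || !is_wholenumber(depth) || depth <= 0) {
    abort("depth must be a single positive integer")
  }
  mat <- otu_matrix(table)
  totals <- rowSums(mat)
  drop <- totals < depth
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
                paste(rownames(mat)[drop], collapse = ", ")))
    mat <- mat[!drop, , drop = FALSE]
  }
  if (nrow(mat) == 0) {
    abort("no samples at or above the rarefaction depth")
  }
  sub <- with_seed_if(seed, rrarefy_quiet(mat, depth))
  out <- bind_cols(tibble(sample_id = rownames(mat)),
                   as_tibble(sub, .name_repair = "minimal"))
  attr(out, "rarefaction_depth") <- as.integer(depth)
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out
}

#' Rarefaction curves of observed richness
#'
#' Mean observed OTU count per sample over replicate random subsamples at a
#' grid of depths. Depths exceeding a sample's read total are skipped for
#' that sample; depth 0 contributes 0 observed OTUs.
#'
#' @param table An OTU table tibble.
#' @param depths Integer vector of subsampling depths.
#' @param replicates Number of random subsamples per depth.
#' @param seed Optional integer seed.
#' @return A tibble of class `rarefaction_curves` with columns `sample_id`,
#'   `depth`, `mean_otus`, `n_replicates`.
#' @export
rarefaction_curves <- function(table, depths = seq(0, 3000, by = 250),
                               replicates = 10, seed = NULL) {
  stopifnot(replicates >= 1)
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 0)) abort("depths must be non-negative")
  mat <- otu_matrix(table)
  totals <- rowSums(mat)
  rows <- with_seed_if(seed, {
    purrr::map(depths, function(d) {
      keep <- totals >= d
      if (!any(keep)) return(NULL)
      if (d == 0) {
        return(tibble(sample_id = rownames(mat)[keep], depth = d,
                      mean_otus = 0, n_replicates = as.integer(replicates)))
      }
      sub <- mat[keep, , drop = FALSE]
      rich <- replicate(replicates, rowSums(rrarefy_quiet(sub, d) > 0))
      rich <- matrix(rich, nrow = sum(keep))
      tibble(sample_id = rownames(sub), depth = d,
             mean_otus = rowMeans(rich), n_replicates = as.integer(replicates))
    })
  })
  out <- list_rbind(rows)
  class(out) <- c("rarefaction_curves", class(out))
  out
}
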