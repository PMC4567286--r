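#' Permutation tests of within-pair community similarity
#'
#' Two complementary permutation frameworks ask whether the two members of
#' a breeding pair carry more similar microbial communities than random
#' male-female pairings would produce.
#'
#' The *sample-centred* test ([sample_centred_test()]) compares the observed
#' mean of within-pair distances (Hellinger or UniFrac) with the null
#' distribution of that mean over random male-female bijections.
#'
#' The *OTU-centred* test ([otu_centred_test()]) computes, for each OTU,
#' the Spearman correlation between its male and female relative abundances
#' across pairs; the mean of the Fisher-z-transformed correlations is the
#' observed similarity index, and the null reshuffles which male is paired
#' with which female. Results are summarised as a standardised effect size
#' SES = (observed - null mean) / null sd.
#'
#' Both tests use the add-one permutation p-value
#' `p = (1 + #extreme) / (B + 1)`; the smallest attainable one-tailed p with
#' B permutations is `1 / (B + 1)`. Two-tailed p is
#' `min(1, 2 * min(p_lower, p_upper))`.
#'
#' @name pair_perm_test
NULL

new_pair_perm_test <- function(statistic_name, observed, null, B, seed,
                               n_units, extra = list()) {
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  ses <- if (isTRUE(null_sd > 0)) (observed - null_mean) / null_sd else NA_real_
  p_lower <- (1 + sum(null <= observed)) / (B + 1)
  p_upper <- (1 + sum(null >= observed)) / (B + 1)
  structure(
    c(list(
      statistic_name = statistic_name,
      observed = observed,
      null = null,
      null_mean = null_mean,
      null_sd = null_sd,
      ses = ses,
      p_lower = p_lower,
      p_upper = p_upper,
      p_two_tailed = min(1, 2 * min(p_lower, p_upper)),
      n_permutations = as.integer(B),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      n_units = as.integer(n_units)
    ), extra),
    class = "pair_perm_test"
  )
}

#' @export
print.pair_perm_test <- function(x, ...) {
  cat("<pair_perm_test> ", x$statistic_name, "\n", sep = "")
  cat(sprintf("  observed = %.6g  (null mean %.6g, sd %.6g over %d permutations)\n",
              x$observed, x$null_mean, x$null_sd, x$n_permutations))
  cat(sprintf("  SES = %.4g\n", x$ses))
  cat(sprintf("  p (lower / upper / two-tailed) = %.4g / %.4g / %.4g\n",
              x$p_lower, x$p_upper, x$p_two_tailed))
  cat(sprintf("  units contributing: %d;  seed: %s\n", x$n_units,
              ifelse(is.na(x$seed), "<none>", x$seed)))
  invisible(x)
}

#' @rdname pair_perm_test
#' @param x A `pair_perm_test` object.
#' @param ... Unused.
#' @return `tidy()` gives the one-row statistical summary; `glance()` the
#'   one-row run metadata (permutations, seed, contributing units).
#' @export
tidy.pair_perm_test <- function(x, ...) {
  tibble(
    statistic = x$statistic_name,
    estimate = x$observed,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    ses = x$ses,
    p_lower = x$p_lower,
    p_upper = x$p_upper,
    p.value = x$p_two_tailed
  )
}

#' @rdname pair_perm_test
#' @export
glance.pair_perm_test <- function(x, ...) {
  tibble(
    statistic = x$statistic_name,
    n_permutations = x$n_permutations,
    n_units = x$n_units,
    n_undefined = x$n_undefined %||% NA_integer_,
    seed = x$seed
  )
}

#' Mean within-pair distance
#'
#' Arithmetic mean of the male-female distance over complete breeding
#' pairs.
#'
#' @param d A [comm_dist] object (or symmetric distance matrix with sample
#'   ids as dimnames).
#' @param metadata A sample-metadata tibble; every pair must be complete
#'   and both members present in `d`.
#' @return The mean distance (a single number).
#' @export
mean_within_pair_distance <- function(d, metadata) {
  m <- as.matrix(d)
  pairs <- pair_members(metadata)
  missing <- pairs$pair_id[!(pairs$male %in% rownames(m)) | !(pairs$female %in% rownames(m))]
  if (length(missing) > 0) {
    abort(paste0("pair(s) with member(s) absent from the distance matrix: ",
                 paste(missing, collapse = ", ")))
  }
  mean(m[cbind(pairs$male, pairs$female)])
}

#' Sample-centred permutation test of within-pair similarity
#'
#' Compares the observed mean within-pair distance with its null
#' distribution over uniformly random male-female bijections (the true
#' pairing is a permissible draw). Small distances mean similar
#' communities, so `p_lower` is the similarity-direction p-value.
#'
#' @inheritParams mean_within_pair_distance
#' @param B Number of random bijections (default 1000).
#' @param seed Optional integer seed.
#' @return A [pair_perm_test] object.
#' @export
sample_centred_test <- function(d, metadata, B = 1000, seed = NULL) {
  if (B < 1) abort("B must be at least 1")
  m <- as.matrix(d)
  pairs <- pair_members(metadata)
  if (nrow(pairs) < 2) {
    abort("at least two complete pairs are required for re-pairing")
  }
  observed <- mean_within_pair_distance(d, metadata)
  n <- nrow(pairs)
  sub <- m[pairs$male, pairs$female, drop = FALSE] # rows: males, cols: females
  null <- with_seed_if(seed, vapply(seq_len(B), function(b) {
    perm <- sample.int(n)
    mean(sub[cbind(seq_len(n), perm)])
  }, numeric(1)))
  metric <- if (inherits(d, "comm_dist")) d$metric else "distance"
  new_pair_perm_test(
    statistic_name = paste0("mean_within_pair_", metric),
    observed = observed, null = null, B = B, seed = seed, n_units = n,
    extra = list(n_pairs = n, metric = metric)
  )
}

# Per-pair male/female profile matrices (pairs x OTUs), column-standardised
# for fast correlation under row permutations of the female block. When
# `rank_transform` the Spearman path ranks each column first (average
# ranks for ties); otherwise the Pearson path uses the raw proportions.
pair_profile_matrices <- function(prop, metadata, otu_subset = NULL,
                                  rank_transform = TRUE) {
  pairs <- pair_members(metadata)
  mat <- numeric_matrix(prop)
  absent <- setdiff(c(pairs$male, pairs$female), rownames(mat))
  if (length(absent) > 0) {
    abort(paste0("sample(s) in metadata absent from the table: ",
                 paste(absent, collapse = ", ")))
  }
  ids <- otu_subset %||% colnames(mat)
  unknown <- setdiff(ids, colnames(mat))
  if (length(unknown) > 0) {
    abort(paste0("OTU id(s) not in the table: ", paste(head(unknown, 10), collapse = ", ")))
  }
  if (length(ids) == 0) abort("empty OTU subset")
  M <- mat[pairs$male, ids, drop = FALSE]
  F_ <- mat[pairs$female, ids, drop = FALSE]
  if (rank_transform) {
    M <- apply(M, 2, rank)
    F_ <- apply(F_, 2, rank)
    if (nrow(pairs) == 1) { # apply() drops to a vector for one pair
      M <- matrix(M, nrow = 1, dimnames = list(pairs$male, ids))
      F_ <- matrix(F_, nrow = 1, dimnames = list(pairs$female, ids))
    }
  }
  center_scale <- function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    ss <- sqrt(colSums(Xc^2))
    list(scaled = sweep(Xc, 2, pmax(ss, 1e-300), "/"), ss = ss)
  }
  csM <- center_scale(M)
  csF <- center_scale(F_)
  defined <- csM$ss > 1e-10 & csF$ss > 1e-10
  list(pairs = pairs, otu_ids = ids,
       Ms = csM$scaled, Fs = csF$scaled, defined = defined)
}

#' Per-OTU within-pair correlation profile
#'
#' For each OTU, the correlation between its male relative abundances and
#' its female relative abundances, ordered by breeding pair. Ties receive
#' average ranks (Spearman); correlations are clamped to
#' `±(1 - 1e-12)` before the Fisher z transform. OTUs whose male or female
#' vector is constant across pairs have no defined correlation and are
#' reported as `NA`.
#'
#' @param prop A proportion table from [relative_abundance()] (counts work
#'   too; only ranks are used for Spearman).
#' @param metadata Sample metadata with complete pairs.
#' @param otu_subset Optional character vector restricting the OTUs
#'   profiled (e.g. from [filter_otus()]).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A tibble: `otu_id`, `r`, `fisher_z`, `n_pairs_used`.
#' @export
pair_correlation_profile <- function(prop, metadata, otu_subset = NULL,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  pm <- pair_profile_matrices(prop, metadata, otu_subset,
                              rank_transform = method == "spearman")
  r <- colSums(pm$Ms * pm$Fs)
  r[!pm$defined] <- NA_real_
  tibble(
    otu_id = pm$otu_ids,
    r = unname(r),
    fisher_z = ifelse(is.na(r), NA_real_, fisher_z(r)),
    n_pairs_used = nrow(pm$pairs)
  )
}

#' OTU-centred permutation test of within-pair similarity
#'
#' The observed statistic is the mean (over OTUs with a defined
#' correlation) of the Fisher-z-transformed within-pair correlations. Null
#' realisations reshuffle individual identity under the sex constraint —
#' each random matrix pairs a random male with a random female — and
#' recompute the same mean. OTUs with a constant male or female vector are
#' dropped from the mean in the observed and every null realisation (the
#' defined set is permutation-invariant, since reshuffling only reorders a
#' sex's values).
#'
#' @inheritParams pair_correlation_profile
#' @param B Number of randomised matrices (default 1000).
#' @param seed Optional integer seed.
#' @param transform `"fisher_z"` (default) averages `atanh(r)`; `"raw"`
#'   averages the correlations themselves (robustness variant).
#' @return A [pair_perm_test] object; `$mean_r` holds the untransformed
#'   mean correlation and `$n_undefined` the number of dropped OTUs.
#' @export
otu_centred_test <- function(prop, metadata, otu_subset = NULL, B = 1000,
                             seed = NULL, method = c("spearman", "pearson"),
                             transform = c("fisher_z", "raw")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (B < 1) abort("B must be at least 1")
  pm <- pair_profile_matrices(prop, metadata, otu_subset,
                              rank_transform = method == "spearman")
  n <- nrow(pm$pairs)
  if (n < 3) abort("at least three complete pairs are required for a rank correlation")
  if (!any(pm$defined)) abort("no OTU has a defined within-pair correlation")
  Ms <- pm$Ms[, pm$defined, drop = FALSE]
  Fs <- pm$Fs[, pm$defined, drop = FALSE]
  stat <- if (transform == "fisher_z") {
    function(r) mean(fisher_z(r))
  } else {
    function(r) mean(r)
  }
  r_obs <- colSums(Ms * Fs)
  observed <- stat(r_obs)
  null <- with_seed_if(seed, vapply(seq_len(B), function(b) {
    perm <- sample.int(n)
    stat(colSums(Ms * Fs[perm, , drop = FALSE]))
  }, numeric(1)))
  new_pair_perm_test(
    statistic_name = paste0("mean_", transform, "_", method, "_within_pair"),
    observed = observed, null = null, B = B, seed = seed,
    n_units = sum(pm$defined),
    extra = list(
      mean_r = mean(r_obs),
      n_undefined = sum(!pm$defined),
      n_pairs = n,
      method = method,
      transform = transform
    )
  )
}

#' Drop OTUs from a subset by label
#'
#' Set difference preserving the original order; used for sensitivity
#' analyses that exclude named taxa (e.g. putative non-resident bacteria).
#'
#' @param otu_subset Character vector of OTU ids.
#' @param exclusion_list Character vector of ids to remove.
#' @return `otu_subset` without the excluded ids, order preserved.
#' @export
exclude_otus_by_label <- function(otu_subset, exclusion_list) {
  stray <- setdiff(exclusion_list, otu_subset)
  if (length(stray) > 0) {
    warn(paste0(length(stray), " exclusion id(s) not present in the subset: ",
                paste(head(stray, 10), collapse = ", ")))
  }
  otu_subset[!otu_subset %in% exclusion_list]
}

#' Serialise a permutation-test result
#'
#' @param x A [pair_perm_test] object.
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_pair_test <- function(x, path) {
  row <- bind_cols(tidy(x), glance(x)[-1])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(row), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    readr::write_tsv(row, path)
  }
  invisible(path)
}
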