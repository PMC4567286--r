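#' Simulate a random rooted OTU phylogeny
#'
#' Coalescent-style topology (uniformly random successive joins of
#' lineages) with branch lengths redrawn independently from an exponential
#' distribution with mean 0.1. Leaves are labelled `OTU_1 ... OTU_n`.
#'
#' @param n_otus Number of leaves (`>= 2`).
#' @param seed Optional integer seed.
#' @return A rooted, bifurcating `phylo` object.
#' @export
simulate_tree <- function(n_otus, seed = NULL) {
  if (n_otus < 2) abort("n_otus must be at least 2")
  with_seed_if(seed, {
    tree <- ape::rcoal(n_otus, tip.label = paste0("OTU_", seq_len(n_otus)))
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 10)
    tree
  })
}

#' Simulate a paired-community dataset
#'
#' Generates an OTU table, metadata and phylogeny with the structure of a
#' two-colony, male-female breeding-pair amplicon survey. Per-OTU
#' log-abundance is a sum of a base effect, a pair-shared effect and an
#' individual effect:
#' \deqn{w_{jki} = \exp(\mu_j + u_{jk} + e_{jki})}
#' with \eqn{\mu_j \sim N(0, 2)}, \eqn{u_{jk} \sim N(0, \rho\sigma^2)}
#' shared by both members of pair k, and
#' \eqn{e_{jki} \sim N(0, (1-\rho)\sigma^2)} idiosyncratic, so `rho` is the
#' share of the tunable log-abundance variance that is common within a
#' pair. Weights are zeroed independently with probability
#' `zero_inflation` (re-drawn, boundedly, if a sample loses every OTU),
#' renormalised, and counts are drawn multinomially at a per-sample depth
#' uniform on `depth_range`. A colony shift of `colony_effect` is added to
#' \eqn{\mu} for a disjoint random 10% of OTUs per colony, for samples of
#' that colony; pairs are split between colonies.
#'
#' @param n_pairs Number of breeding pairs (default 7).
#' @param n_otus Number of OTUs (default 300).
#' @param depth_range Inclusive integer range of per-sample read depths
#'   (default `c(1656, 8110)`).
#' @param rho Within-pair share of log-abundance variance, in `[0, 1]`
#'   (default 0: no planted pair similarity).
#' @param sigma_total Standard deviation of the pair + individual
#'   log-abundance effects (default 2).
#' @param zero_inflation Probability an OTU is absent from an individual,
#'   independently (default 0.4, which together with the log-normal
#'   abundance spread reproduces the sparse, aggregated prevalence
#'   structure typical of cloacal/gut amplicon surveys).
#' @param n_colonies Number of breeding colonies (default 2).
#' @param colony_effect Log-scale abundance shift of colony-marker OTUs
#'   (default 0, i.e. no colony structure).
#' @param seed Optional integer seed.
#' @return A list of class `paired_community`: `table` (OTU tibble,
#'   samples `P<k>M`/`P<k>F`), `metadata`, `tree`, and `truth` (per-OTU
#'   base log-means, planted `rho`, per-sample depths, colony marker OTUs).
#' @export
simulate_paired_community <- function(n_pairs = 7, n_otus = 300,
                                      depth_range = c(1656, 8110),
                                      rho = 0, sigma_total = 2,
                                      zero_inflation = 0.4,
                                      n_colonies = 2, colony_effect = 0,
                                      seed = NULL) {
  stopifnot(n_pairs >= 1, n_otus >= 2, length(depth_range) == 2,
            all(depth_range > 0), depth_range[1] <= depth_range[2],
            rho >= 0, rho <= 1, sigma_total > 0,
            zero_inflation >= 0, zero_inflation < 1,
            n_colonies >= 1, colony_effect >= 0)
  with_seed_if(seed, {
    tree <- simulate_tree(n_otus)
    otus <- tree$tip.label
    pair_ids <- paste0("P", seq_len(n_pairs))
    colony <- paste0("C", rep_len(seq_len(n_colonies), n_pairs))
    samples <- tibble(
      sample_id = c(rbind(paste0(pair_ids, "M"), paste0(pair_ids, "F"))),
      sex = rep(c("M", "F"), n_pairs),
      pair_id = rep(pair_ids, each = 2),
      colony_id = rep(colony, each = 2)
    )
    n_samples <- nrow(samples)

    mu <- stats::rnorm(n_otus, 0, sqrt(2))
    # disjoint colony-marker subsets, 10% of OTUs each
    n_mark <- floor(0.1 * n_otus)
    marker_pool <- sample.int(n_otus, min(n_otus, n_mark * n_colonies))
    colony_otus <- if (n_mark > 0) {
      split(marker_pool[seq_len(n_mark * n_colonies)],
            rep(seq_len(n_colonies), each = n_mark))
    } else {
      stats::setNames(vector("list", n_colonies), seq_len(n_colonies))
    }

    u <- matrix(stats::rnorm(n_otus * n_pairs, 0, sqrt(rho) * sigma_total),
                nrow = n_pairs)
    counts <- matrix(0L, nrow = n_samples, ncol = n_otus,
                     dimnames = list(samples$sample_id, otus))
    depth_vals <- seq(depth_range[1], depth_range[2])
    depths <- depth_vals[sample.int(length(depth_vals), n_samples, replace = TRUE)]
    for (i in seq_len(n_samples)) {
      k <- match(samples$pair_id[i], pair_ids)
      ci <- match(samples$colony_id[i], paste0("C", seq_len(n_colonies)))
      mu_i <- mu
      if (colony_effect > 0 && length(colony_otus[[ci]]) > 0) {
        mu_i[colony_otus[[ci]]] <- mu_i[colony_otus[[ci]]] + colony_effect
      }
      e <- stats::rnorm(n_otus, 0, sqrt(1 - rho) * sigma_total)
      w <- exp(mu_i + u[k, ] + e)
      for (try in seq_len(100)) {
        mask <- stats::runif(n_otus) >= zero_inflation
        if (any(w * mask > 0)) break
        if (try == 100) abort("could not draw a nonzero community after 100 attempts")
      }
      wz <- w * mask
      counts[i, ] <- stats::rmultinom(1, depths[i], wz / sum(wz))
    }
    table <- bind_cols(tibble(sample_id = samples$sample_id),
                       as_tibble(counts, .name_repair = "minimal"))
    structure(
      list(
        table = validate_otu_table(table),
        metadata = validate_sample_metadata(samples),
        tree = tree,
        truth = list(mu = stats::setNames(mu, otus), rho = rho,
                     sigma_total = sigma_total, zero_inflation = zero_inflation,
                     depths = stats::setNames(depths, samples$sample_id),
                     colony_otus = lapply(colony_otus, function(i) otus[i]),
                     colony_effect = colony_effect)
      ),
      class = "paired_community"
    )
  })
}

#' @export
print.paired_community <- function(x, ...) {
  cat("<paired_community> ", nrow(x$table), " samples (",
      nrow(x$metadata) / 2, " pairs), ", length(otu_ids(x$table)), " OTUs\n",
      sep = "")
  cat("  planted rho = ", x$truth$rho,
      ", zero inflation = ", x$truth$zero_inflation,
      ", depths ", min(x$truth$depths), "-", max(x$truth$depths), "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to standard files
#'
#' Emits the classic OTU TSV, the metadata TSV, the newick tree and a JSON
#' truth record into a directory.
#'
#' @param x A `paired_community` from [simulate_paired_community()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_paired_community <- function(x, dir) {
  stopifnot(inherits(x, "paired_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    otu_table = file.path(dir, "otu_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  write_otu_table(x$table, paths[["otu_table"]])
  write_sample_metadata(x$metadata, paths[["metadata"]])
  ape::write.tree(x$tree, paths[["tree"]])
  jsonlite::write_json(x$truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
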