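#' Run the full paired-community analysis pipeline
#'
#' Orchestrates the standard analysis: load (or simulate) the OTU table,
#' metadata and phylogeny; per-sample alpha diversity; rarefied distance
#' matrices; per-OTU aggregation (corrected negative-binomial k); the
#' sample-centred permutation test for every requested distance metric;
#' and the OTU-centred permutation test on the filtered OTU subset. All
#' results are written to `output_dir` together with a JSON run manifest
#' recording the resolved configuration, seeds and every warning raised
#' (dropped samples, undefined correlations, undefined k estimates), so
#' silent exclusions are visible.
#'
#' @param config A named list, or a path to a YAML file, with any of:
#'   `input` (`otu_table`, `metadata`, `tree`, `orientation` paths) or
#'   `simulate` (arguments of [simulate_paired_community()]);
#'   `rarefaction_depth` (default 1600); `metrics` (default all of
#'   `hellinger`, `unweighted_unifrac`, `weighted_unifrac`); `B` (default
#'   1000); `otu_filter` with `min_individuals` (default 4) and
#'   `min_total_proportion` (default 0.001); `correlation`
#'   (`spearman`/`pearson`); `transform` (`fisher_z`/`raw`);
#'   `weighted_normalized` (default `FALSE`); `seed` (default 1);
#'   `output_dir`.
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return Invisibly, a list with the in-memory results (`alpha`,
#'   `distances`, `k_table`, `k_summary`, `sample_centred`, `otu_centred`,
#'   `correlation_profile`, `manifest`).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  cfg <- resolve_pipeline_config(config)
  output_dir <- output_dir %||% cfg$output_dir
  if (is.null(output_dir)) abort("an output directory is required")

  # validation before any computation
  if (any(cfg$metrics %in% c("unweighted_unifrac", "weighted_unifrac")) &&
      is.null(cfg$simulate) && is.null(cfg$input$tree)) {
    abort("UniFrac metrics requested but no tree supplied")
  }
  if (is.null(cfg$simulate) && is.null(cfg$input$otu_table)) {
    abort("either an input block or a simulate block is required")
  }

  warnings_log <- character()
  res <- withCallingHandlers(
    run_pipeline_impl(cfg, output_dir),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  res$manifest$warnings <- warnings_log
  jsonlite::write_json(res$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(res)
}

resolve_pipeline_config <- function(config) {
  defaults <- list(
    input = NULL,
    simulate = NULL,
    rarefaction_depth = 1600,
    metrics = c("hellinger", "unweighted_unifrac", "weighted_unifrac"),
    B = 1000,
    otu_filter = list(min_individuals = 4, min_total_proportion = 0.001),
    correlation = "spearman",
    transform = "fisher_z",
    weighted_normalized = FALSE,
    seed = 1,
    output_dir = NULL
  )
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  cfg$otu_filter <- utils::modifyList(defaults$otu_filter, config$otu_filter %||% list())
  bad <- setdiff(cfg$metrics, c("hellinger", "unweighted_unifrac", "weighted_unifrac"))
  if (length(bad) > 0) abort(paste0("unknown metric(s): ", paste(bad, collapse = ", ")))
  cfg$correlation <- match.arg(cfg$correlation, c("spearman", "pearson"))
  cfg$transform <- match.arg(cfg$transform, c("fisher_z", "raw"))
  cfg
}

run_pipeline_impl <- function(cfg, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  if (!is.null(cfg$simulate)) {
    sim <- do.call(simulate_paired_community,
                   c(cfg$simulate, list(seed = seed)))
    table <- sim$table
    metadata <- sim$metadata
    tree <- sim$tree
    write_paired_community(sim, file.path(output_dir, "simulated_input"))
  } else {
    table <- read_otu_table(cfg$input$otu_table,
                            orientation = cfg$input$orientation %||% "otus_as_rows")
    metadata <- read_sample_metadata(cfg$input$metadata)
    tree <- if (!is.null(cfg$input$tree)) read_phylo_tree(cfg$input$tree) else NULL
  }

  alpha <- alpha_diversity(table, tree)
  alpha_long <- pivot_longer(alpha, -"sample_id",
                             names_to = "metric", values_to = "value")
  readr::write_tsv(alpha_long, file.path(output_dir, "alpha_diversity.tsv"))

  distances <- beta_diversity(table, tree, metrics = cfg$metrics,
                              depth = cfg$rarefaction_depth, seed = seed + 1L,
                              weighted_normalized = cfg$weighted_normalized)
  for (m in names(distances)) {
    write_distance_matrix(distances[[m]], file.path(output_dir, paste0("distance_", m, ".tsv")))
  }

  filtered <- filter_otus(table,
                          min_individuals = cfg$otu_filter$min_individuals,
                          min_total_proportion = cfg$otu_filter$min_total_proportion)
  ktab <- k_table(filtered)
  ksum <- k_summary(ktab)
  readr::write_tsv(ktab, file.path(output_dir, "k_table.tsv"))
  readr::write_tsv(ksum, file.path(output_dir, "k_summary.tsv"))

  sample_centred <- list()
  for (i in seq_along(distances)) {
    m <- names(distances)[[i]]
    sample_centred[[m]] <- sample_centred_test(distances[[m]], metadata,
                                               B = cfg$B, seed = seed + 1L + i)
    write_pair_test(sample_centred[[m]],
                    file.path(output_dir, paste0("sample_centred_", m, ".json")))
  }

  prop <- relative_abundance(table)
  subset_ids <- otu_ids(filtered)
  profile <- pair_correlation_profile(prop, metadata, otu_subset = subset_ids,
                                      method = cfg$correlation)
  readr::write_tsv(profile, file.path(output_dir, "otu_correlations.tsv"))
  otu_centred <- otu_centred_test(prop, metadata, otu_subset = subset_ids,
                                  B = cfg$B, seed = seed + 100L,
                                  method = cfg$correlation,
                                  transform = cfg$transform)
  write_pair_test(otu_centred, file.path(output_dir, "otu_centred.json"))

  all_tests <- c(sample_centred, list(otu_centred = otu_centred))
  tests_tbl <- list_rbind(purrr::map(all_tests, function(x) bind_cols(tidy(x), glance(x)[-1])))
  readr::write_tsv(tests_tbl, file.path(output_dir, "pair_tests.tsv"))

  cfg_for_hash <- cfg[order(names(cfg))]
  manifest <- list(
    package = "micropair",
    package_version = as.character(utils::packageVersion("micropair")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg,
    config_hash = rlang::hash(cfg_for_hash),
    seed = seed,
    n_samples = nrow(table),
    n_otus = length(otu_ids(table)),
    n_otus_filtered = length(subset_ids),
    retained_read_fraction = attr(filtered, "retained_read_fraction"),
    n_undefined_correlations = otu_centred$n_undefined,
    n_undefined_k = ksum$n_undefined,
    outputs = list.files(output_dir, recursive = TRUE)
  )
  list(alpha = alpha, distances = distances, k_table = ktab, k_summary = ksum,
       sample_centred = sample_centred, otu_centred = otu_centred,
       correlation_profile = profile, manifest = manifest)
}
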