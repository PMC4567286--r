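#' Plot a permutation null distribution with the observed statistic
#'
#' @param object A [pair_perm_test] object.
#' @param ... Unused.
#' @return A ggplot: histogram of the null realisations with the observed
#'   statistic as a vertical line.
#' @export
autoplot.pair_perm_test <- function(object, ...) {
  df <- tibble(null = object$null)
  ggplot(df, aes(x = .data$null)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed, colour = "firebrick", linewidth = 1) +
    labs(
      x = object$statistic_name,
      y = "null realisations",
      title = sprintf("observed = %.4g, SES = %.3g, two-tailed p = %.3g",
                      object$observed, object$ses, object$p_two_tailed)
    ) +
    theme_minimal()
}

#' Plot rarefaction curves
#'
#' @param object A `rarefaction_curves` tibble from [rarefaction_curves()].
#' @param ... Unused.
#' @return A ggplot of mean observed OTUs against depth, one line per
#'   sample.
#' @export
autoplot.rarefaction_curves <- function(object, ...) {
  ggplot(object, aes(x = .data$depth, y = .data$mean_otus,
                     colour = .data$sample_id)) +
    geom_line() +
    labs(x = "reads subsampled", y = "mean observed OTUs", colour = "sample") +
    theme_minimal()
}

#' Heatmap of a pairwise distance matrix
#'
#' @param object A [comm_dist] object.
#' @param ... Unused.
#' @return A ggplot tile heatmap of the pairwise distances.
#' @export
autoplot.comm_dist <- function(object, ...) {
  m <- as.matrix(object)
  df <- as_tibble(m, .name_repair = "minimal") |>
    mutate(sample_a = rownames(m)) |>
    pivot_longer(-"sample_a", names_to = "sample_b", values_to = "distance")
  ggplot(df, aes(x = .data$sample_a, y = .data$sample_b, fill = .data$distance)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = object$metric) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}
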