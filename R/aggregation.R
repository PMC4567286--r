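#' Corrected moment estimate of the negative-binomial k for one OTU
#'
#' The aggregation parameter k of the negative binomial, estimated by the
#' corrected moment formula used in the macroparasite literature:
#' \deqn{k = (m^2 - s^2/n) / (s^2 - m)}
#' with `m` the mean count per host, `s^2` the sample variance (n - 1
#' denominator) and `n` the number of hosts. Small k indicates a highly
#' aggregated distribution across hosts; k > 20 is near-Poisson. The
#' estimate is undefined for under- or equi-dispersed counts (`s^2 <= m`).
#'
#' @param counts Per-host count vector for a single OTU (length `>= 2`).
#' @return One-row tibble: `n`, `mean`, `variance`, `k` (`NA` when
#'   undefined), `defined`.
#' @examples
#' nb_k(c(0, 0, 1, 3)) # k = 0.5
#' @export
nb_k <- function(counts) {
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n < 2) {
    abort("at least two host samples are required to estimate k")
  }
  m <- mean(counts)
  s2 <- stats::var(counts)
  defined <- s2 > m
  k <- if (defined) (m^2 - s2 / n) / (s2 - m) else NA_real_
  if (defined && k <= 0) {
    warn("corrected moment estimate of k is non-positive (m^2 <= s^2/n)")
  }
  tibble(n = n, mean = m, variance = s2, k = k, defined = defined)
}

#' Per-OTU aggregation table
#'
#' Applies [nb_k()] to every OTU of a table, across host samples.
#'
#' @param table An OTU table tibble (typically pre-filtered with
#'   [filter_otus()]).
#' @return A tibble with one row per OTU: `otu_id`, `n`, `mean`,
#'   `variance`, `k`, `defined`.
#' @export
k_table <- function(table) {
  mat <- otu_matrix(table)
  if (ncol(mat) == 0) {
    abort("no OTUs in table (did the filter remove everything?)")
  }
  if (nrow(mat) < 2) {
    abort("at least two host samples are required to estimate k")
  }
  n <- nrow(mat)
  m <- colMeans(mat)
  s2 <- apply(mat, 2, stats::var)
  defined <- s2 > m
  k <- ifelse(defined, (m^2 - s2 / n) / (s2 - m), NA_real_)
  n_nonpos <- sum(defined & k <= 0)
  if (n_nonpos > 0) {
    warn(paste0(n_nonpos, " OTU(s) have a non-positive corrected k estimate"))
  }
  tibble(otu_id = colnames(mat), n = n, mean = m, variance = s2,
         k = unname(k), defined = unname(defined))
}

#' Summary of per-OTU aggregation
#'
#' Median and quartiles (linear interpolation between order statistics) of
#' the defined k estimates; undefined (near-Poisson, `s^2 <= m`) estimates
#' are excluded and counted separately.
#'
#' @param ktab A per-OTU table from [k_table()] (or an OTU table tibble,
#'   which is passed through [k_table()] first).
#' @return One-row tibble: `n_otus`, `n_defined`, `n_undefined`,
#'   `median_k`, `q1_k`, `q3_k`.
#' @export
k_summary <- function(ktab) {
  if (!all(c("k", "defined") %in% names(ktab))) {
    ktab <- k_table(ktab)
  }
  if (nrow(ktab) == 0) {
    abort("empty aggregation table")
  }
  kd <- ktab$k[ktab$defined]
  if (length(kd) == 0) {
    warn("no defined k estimates (all OTUs under- or equi-dispersed)")
    return(tibble(n_otus = nrow(ktab), n_defined = 0L,
                  n_undefined = nrow(ktab),
                  median_k = NA_real_, q1_k = NA_real_, q3_k = NA_real_))
  }
  q <- stats::quantile(kd, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(n_otus = nrow(ktab), n_defined = length(kd),
         n_undefined = nrow(ktab) - length(kd),
         median_k = q[[2]], q1_k = q[[1]], q3_k = q[[3]])
}
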