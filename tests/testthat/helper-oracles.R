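# Brute-force UniFrac oracle: enumerates every branch and its descendant
# leaf set directly from the edge table. Deliberately naive and independent
# of the implementation path used by the package.

oracle_descendant_leaves <- function(tree, node) {
  n_tips <- length(tree$tip.label)
  if (node <= n_tips) {
    return(tree$tip.label[node])
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_descendant_leaves, tree = tree))
}

# x, y: named count vectors over the tree's leaves
oracle_unifrac <- function(tree, x, y, weighted = FALSE, normalized = FALSE) {
  leaves <- tree$tip.label
  px <- x[leaves] / sum(x)
  py <- y[leaves] / sum(y)
  present_x <- leaves[px > 0]
  present_y <- leaves[py > 0]
  unique_len <- 0
  union_len <- 0
  wsum <- 0
  for (e in seq_len(nrow(tree$edge))) {
    desc <- oracle_descendant_leaves(tree, tree$edge[e, 2])
    len <- tree$edge.length[e]
    in_x <- any(desc %in% present_x)
    in_y <- any(desc %in% present_y)
    if (in_x || in_y) union_len <- union_len + len
    if (xor(in_x, in_y)) unique_len <- unique_len + len
    wsum <- wsum + len * abs(sum(px[desc]) - sum(py[desc]))
  }
  if (!weighted) {
    return(unique_len / union_len)
  }
  if (!normalized) {
    return(wsum)
  }
  # root-to-leaf distances
  depth <- numeric(max(tree$edge))
  # fixed-point walk so parents are settled before children
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      d <- depth[p] + tree$edge.length[e]
      if (depth[ch] != d) { depth[ch] <- d; done <- FALSE }
    }
    if (done) break
  }
  dj <- depth[seq_along(leaves)]
  names(dj) <- leaves
  wsum / sum(dj * (px + py))
}

# Random instance: rooted bifurcating tree with <= max_leaves leaves and two
# random count vectors, each guaranteed non-empty.
random_unifrac_instance <- function(max_leaves = 12) {
  n <- sample(3:max_leaves, 1)
  tree <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 5)
  draw <- function() {
    repeat {
      v <- stats::rpois(n, lambda = 2) * stats::rbinom(n, 1, 0.7)
      if (sum(v) > 0) return(stats::setNames(v, tree$tip.label))
    }
  }
  list(tree = tree, x = draw(), y = draw())
}

# Package-side UniFrac of a two-sample instance, as a single number.
package_unifrac <- function(inst, weighted, normalized = FALSE) {
  tbl <- tibble::tibble(sample_id = c("a", "b"))
  m <- rbind(inst$x, inst$y)
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(m, .name_repair = "minimal"))
  as.matrix(unifrac_dist(tbl, inst$tree, weighted = weighted,
                         normalized = normalized))["a", "b"]
}
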