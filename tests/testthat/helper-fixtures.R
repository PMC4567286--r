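# Small in-code fixtures used across test files.

toy_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- sample_ids %||% paste0("S", seq_len(nrow(counts)))
  colnames(counts) <- otu_ids %||% paste0("OTU_", seq_len(ncol(counts)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(counts)),
                   tibble::as_tibble(counts, .name_repair = "minimal"))
}

# n complete male-female pairs; sample ids P<k>M / P<k>F.
toy_metadata <- function(n_pairs = 7, n_colonies = 2) {
  pair_ids <- paste0("P", seq_len(n_pairs))
  tibble::tibble(
    sample_id = c(rbind(paste0(pair_ids, "M"), paste0(pair_ids, "F"))),
    sex = rep(c("M", "F"), n_pairs),
    pair_id = rep(pair_ids, each = 2),
    colony_id = rep(paste0("C", rep_len(seq_len(n_colonies), n_pairs)), each = 2)
  )
}

four_leaf_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

`%||%` <- rlang::`%||%`
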