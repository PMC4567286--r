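# Internal helpers shared across modules.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG;
# a NULL seed uses (and advances) the current RNG state.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}

# TRUE where x is a whole number within floating-point tolerance.
is_wholenumber <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}

# vegan::rrarefy, muffling only its usage note about tables whose smallest
# positive count exceeds 1 (common in simulated fixtures, harmless here).
rrarefy_quiet <- function(mat, depth) {
  withCallingHandlers(
    vegan::rrarefy(mat, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

clamp_correlation <- function(r, eps = 1e-12) {
  pmin(pmax(r, -(1 - eps)), 1 - eps)
}

fisher_z <- function(r) {
  atanh(clamp_correlation(r))
}
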