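# Alignment-free pairwise model similarity (Q-score).
#
# The Q-score compares the internal CA-CA distance matrices of two models
# over their common residues, so it needs no superposition and is
# invariant under any rigid motion (and under reflection: it cannot detect
# chirality, a known trade-off of alignment-free scores).

#' Alignment-free Q-score between two models
#'
#' Over the `Nc` target positions common to both models (indexed
#' `j = 1..Nc` in order), compares the intramolecular CA-CA distance
#' matrices `dA`, `dB`:
#'
#' `Q = 2 / ((Nc-1)(Nc-2)) * sum_{k >= j+2} exp(-(dA[j,k] - dB[j,k])^2 /
#' (2 sigma_jk^2))`, with `sigma_jk = |j-k|^sigmaExponent`.
#'
#' Pairs of sequence separation < 2 are excluded (trivially constrained by
#' the chain), so the normalizer counts exactly the included pairs and
#' identical internal geometry gives `Q = 1`.
#'
#' @param modelA,modelB [ModelStructure-class] objects of the same target,
#'   sharing at least 4 target positions.
#' @param sigmaExponent exponent of the sequence-separation-dependent
#'   width `sigma_jk` (default 0.15).
#' @return the Q-score, a number in `[0, 1]`.
#' @export
qCompare <- function(modelA, modelB, sigmaExponent = 0.15) {
  common <- intersect(modelA@positions, modelB@positions)
  n <- length(common)
  if (n < 4L)
    stop("models share fewer than 4 target positions; cannot compute Q")
  xa <- modelA@coords[match(common, modelA@positions), , drop = FALSE]
  xb <- modelB@coords[match(common, modelB@positions), , drop = FALSE]
  da <- as.matrix(stats::dist(xa))
  db <- as.matrix(stats::dist(xb))
  idx <- seq_len(n)
  sep <- abs(outer(idx, idx, `-`))
  mask <- upper.tri(sep) & sep >= 2L
  sigma <- sep[mask]^sigmaExponent
  terms <- exp(-(da[mask] - db[mask])^2 / (2 * sigma^2))
  2 * sum(terms) / ((n - 1) * (n - 2))
}
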