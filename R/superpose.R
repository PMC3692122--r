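# Rigid-body superposition and TM-score.
#
# The TM-score between two models of one target, normalized by the target
# length L, is
#
#   TM = max over rigid motions of (1/L) * sum_i 1 / (1 + (d_i/d0)^2),
#   d0(L) = 1.24 * (L - 15)^(1/3) - 1.8   (floored at 0.5),
#
# where d_i are CA-CA distances between residues aligned by target
# position. The maximum is searched with the standard fragment-seeding
# heuristic: least-squares superpositions seeded from contiguous fragments
# of several lengths are refined by iteratively re-superposing on the
# residue subset within a distance cutoff, for a descending schedule of
# cutoffs, and the best transform found is kept.

#' Length-dependent TM-score distance scale
#'
#' @param L normalization length (number of target residues).
#' @return `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstroms.
#' @export
tmD0 <- function(L) {
  d0 <- if (L > 15) 1.24 * (L - 15)^(1 / 3) - 1.8 else 0.5
  max(d0, 0.5)
}

#' Optimal least-squares superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `coordsA` and the transformed `coordsB` (`x -> R x + t`, rows
#' as points), via singular value decomposition of the covariance matrix
#' with the usual determinant correction so that no reflection occurs.
#'
#' @param coordsA,coordsB numeric n x 3 matrices, n >= 3, of matched points.
#' @return a list with elements `rotation` (3 x 3, det = +1),
#'   `translation` (length 3) and `rmsd` (the minimized value, Angstroms).
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' kabsch(a, a)$rmsd  # 0
#' @export
kabsch <- function(coordsA, coordsB) {
  if (!is.matrix(coordsA) || !is.matrix(coordsB) ||
      ncol(coordsA) != 3L || ncol(coordsB) != 3L)
    stop("'coordsA' and 'coordsB' must be n x 3 matrices")
  n <- nrow(coordsA)
  if (nrow(coordsB) != n) stop("coordinate sets differ in length")
  if (n < 3L) stop("at least 3 points are required")
  cA <- colMeans(coordsA); cB <- colMeans(coordsB)
  Ac <- sweep(coordsA, 2, cA); Bc <- sweep(coordsB, 2, cB)
  H <- crossprod(Bc, Ac)                    # 3 x 3 covariance
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  tr <- as.numeric(cA - R %*% cB)
  fitted <- Bc %*% t(R)                      # centered B rotated
  rmsd <- sqrt(mean(rowSums((Ac - fitted)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a superposition's rigid transform to coordinates
#'
#' @param superposition a [Superposition-class].
#' @param xyz numeric n x 3 matrix of coordinates (in the second model's
#'   frame).
#' @return the transformed n x 3 matrix (`x -> R x + t` per row).
#' @export
transformCoords <- function(superposition, xyz) {
  sweep(xyz %*% t(superposition@rotation), 2,
        superposition@translation, `+`)
}

#' TM-score superposition of two models
#'
#' Superposes `modelB` onto `modelA` over their common target positions so
#' as to maximize the TM-score normalized by `normLength` (conventionally
#' the target length `L`), using fragment seeding and iterative
#' cutoff-restricted re-superposition. Distances `d_i` under the best
#' transform are reported for every common position, not only those inside
#' the final cutoff, because the per-residue S-score needs each residue's
#' distance.
#'
#' @param modelA,modelB [ModelStructure-class] objects of the same target,
#'   sharing at least 3 target positions.
#' @param normLength normalization length `L` (default: the largest target
#'   position seen; in pipeline use, always the target length).
#' @return a [Superposition-class].
#' @export
tmSuperpose <- function(modelA, modelB,
                        normLength = max(modelA@positions, modelB@positions)) {
  common <- intersect(modelA@positions, modelB@positions)
  n <- length(common)
  if (n < 3L)
    stop("models share fewer than 3 target positions; cannot superpose")
  L <- as.integer(normLength)
  xa <- modelA@coords[match(common, modelA@positions), , drop = FALSE]
  xb <- modelB@coords[match(common, modelB@positions), , drop = FALSE]
  d0 <- tmD0(L)

  lens <- unique(pmax(4L, c(n, n %/% 2L, n %/% 4L, 4L)))
  lens <- lens[lens <= n]
  # cutoff schedule descends from 8 A to d0 so that tight local
  # superpositions are found even between globally dissimilar models
  dcuts <- c(8, 6, 4.5, 3.5, 2.5, 1.75, 1.25, 0.9, d0)
  dcuts <- sort(unique(pmax(dcuts, d0)), decreasing = TRUE)

  best <- .tmSearchCpp(xa, xb, d0, L, as.integer(lens), as.numeric(dcuts))
  new("Superposition", rotation = best$rotation,
      translation = as.numeric(best$translation),
      positions = as.integer(common), distances = as.numeric(best$distances),
      tmScore = min(best$tm, 1), normLength = L)
}
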