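# Clustering QA engine: pool construction, global score combination,
# per-residue mean S-score and predicted distance.
#
# Each model is scored by consensus: its global score is the blend of its
# mean TM-score and mean Q-score against the other N-1 pool members, and
# its per-residue accuracy is the mean S-score of each residue over the
# N-1 pairwise superpositions, converted to a predicted distance from the
# native structure.

S_D0 <- 3.9  # S-score distance threshold (Angstroms); S(d0) = 1/2
DR_CAP <- 15 # upper limit (Angstroms) for the predicted distance d_r

#' Per-residue S-score of a superposition distance
#'
#' `S_i = 1 / (1 + (d_i/d_0)^2)` with distance threshold `d_0 = 3.9`
#' Angstroms, and `S_i = 0` whenever `d_i > 3.9` (hard cutoff). At the
#' threshold itself `S = 1/2`.
#'
#' @param d distance(s) `d_i` in Angstroms between aligned residues under
#'   a TM-score superposition; non-negative.
#' @param d0 distance threshold (default 3.9 Angstroms).
#' @return S-score(s) in `[0, 1]`, vectorized over `d`.
#' @examples
#' residueSScore(c(0, 3.9, 5))  # 1, 0.5, 0
#' @export
residueSScore <- function(d, d0 = S_D0) {
  if (any(is.na(d)) || any(d < 0)) stop("distances must be non-negative")
  s <- 1 / (1 + (d / d0)^2)
  s[d > d0] <- 0
  s
}

#' Predicted distance from the native structure
#'
#' Inverts the S-score: `d_r = d_0 * sqrt(1/S_r - 1)`, capped at 15
#' Angstroms (`S_r = 0` maps to 15, `S_r = 1` to 0). For
#' `d in [0, 3.9]`, `predictedDistance(residueSScore(d)) == d`.
#'
#' @param sr mean per-residue S-score(s) in `[0, 1]`.
#' @param d0 distance threshold (default 3.9 Angstroms).
#' @param cap upper limit for the predicted distance (default 15 Angstroms).
#' @return predicted distance(s) in `[0, 15]`, vectorized over `sr`.
#' @examples
#' predictedDistance(c(1, 0.5, 0))  # 0, 3.9, 15
#' @export
predictedDistance <- function(sr, d0 = S_D0, cap = DR_CAP) {
  if (any(is.na(sr)) || any(sr < 0) || any(sr > 1))
    stop("S-scores must lie in [0, 1]")
  d <- ifelse(sr > 0, d0 * sqrt(1 / sr - 1), cap)
  pmin(d, cap)
}

#' Build the comparison pool
#'
#' Pools the user-submitted models with the reference models. All user
#' models are kept (duplicate submissions are each scored and reported);
#' reference models that duplicate a user model or an earlier reference
#' (identical positions and coordinates) are dropped. With a single user
#' model a non-empty reference pool is mandatory: that is quasi-single-model
#' mode, in which the reference models gauge the submitted model's quality.
#'
#' @param userModels list of [ModelStructure-class] objects (>= 1).
#' @param referenceModels list of [ModelStructure-class] objects (may be
#'   empty when >= 2 user models are supplied).
#' @param target the [TargetSequence-class].
#' @return a [ModelPool-class]; `poolSize()` gives `N`.
#' @export
buildPool <- function(userModels, referenceModels = list(), target) {
  if (is(userModels, "ModelStructure")) userModels <- list(userModels)
  if (is(referenceModels, "ModelStructure"))
    referenceModels <- list(referenceModels)
  if (length(userModels) < 1L) stop("at least one user model is required")
  if (length(userModels) == 1L && length(referenceModels) == 0L)
    stop("a single submitted model cannot be scored by consensus alone: ",
         "quasi-single-model mode requires a non-empty reference pool ",
         "(supply reference models or submit multiple models)")
  seen <- vapply(userModels, modelSignature, character(1))
  keepRef <- list()
  for (m in referenceModels) {
    sig <- modelSignature(m)
    if (sig %in% seen) next
    seen <- c(seen, sig)
    keepRef <- c(keepRef, m)
  }
  ids <- make.unique(vapply(c(userModels, keepRef), modelId, character(1)))
  all <- c(userModels, keepRef)
  for (i in seq_along(all)) all[[i]]@modelId <- ids[i]
  new("ModelPool", target = target,
      userModels = all[seq_along(userModels)],
      referenceModels = if (length(keepRef))
        all[(length(userModels) + 1):length(all)] else list())
}

# All models of a pool in fixed order (user first, then reference).
poolModels <- function(pool) c(pool@userModels, pool@referenceModels)

#' All-against-all pairwise comparisons of a pool
#'
#' Computes each of the `N(N-1)/2` unordered pairwise comparisons once:
#' the TM-score superposition (normalized by the target length) and the
#' alignment-free Q-score. A pair sharing too few residues to compare
#' contributes TM = 0, Q = 0 (and S-scores of 0), a conservative penalty,
#' with a warning.
#'
#' @param pool a [ModelPool-class].
#' @param sigmaExponent passed to [qCompare()].
#' @return a list with `tm` and `q` (N x N symmetric score matrices, unit
#'   diagonal) and `pairs`, a list of per-pair records holding the aligned
#'   positions and superposition distances `d_i` (indexed `"i:j"`, i < j).
#' @export
poolComparisons <- function(pool, sigmaExponent = 0.15) {
  mods <- poolModels(pool)
  N <- length(mods)
  L <- targetLength(pool@target)
  tm <- diag(N); q <- diag(N)
  pairs <- list()
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      rec <- tryCatch({
        sup <- tmSuperpose(mods[[i]], mods[[j]], normLength = L)
        qs <- tryCatch(qCompare(mods[[i]], mods[[j]],
                                sigmaExponent = sigmaExponent),
                       error = function(e) 0)
        list(tm = sup@tmScore, q = qs, positions = sup@positions,
             distances = sup@distances)
      }, error = function(e) {
        warning("comparison of '", modelId(mods[[i]]), "' and '",
                modelId(mods[[j]]), "' failed (", conditionMessage(e),
                "); scored as 0", call. = FALSE)
        list(tm = 0, q = 0, positions = integer(0), distances = numeric(0))
      })
      tm[i, j] <- tm[j, i] <- rec$tm
      q[i, j] <- q[j, i] <- rec$q
      pairs[[paste(i, j, sep = ":")]] <- rec
    }
  }
  list(tm = tm, q = q, pairs = pairs)
}

#' Mean per-residue S-score of one pool member
#'
#' For each target position present in the scored model, averages the
#' per-residue S-scores over the model's `N-1` pairwise superpositions:
#' `S_r = (1/(N-1)) * sum_a S_ia`. A pairwise alignment that lacks the
#' position contributes `S_ia = 0` (the divisor stays fixed at `N-1`).
#' Positions absent from the scored model itself are `NA` (reported as
#' `"X"`).
#'
#' @param modelIndex index of the scored model in the pool (user models
#'   first, then reference models).
#' @param pool a [ModelPool-class] with at least 2 members.
#' @param comparisons the result of [poolComparisons()] on `pool`.
#' @return numeric vector of length `L`: `S_r` per target position.
#' @export
meanResidueScore <- function(modelIndex, pool, comparisons) {
  mods <- poolModels(pool)
  N <- length(mods)
  if (N < 2L) stop("pool must contain at least 2 models")
  L <- targetLength(pool@target)
  own <- mods[[modelIndex]]@positions
  ssum <- numeric(L)
  for (a in setdiff(seq_len(N), modelIndex)) {
    key <- paste(min(modelIndex, a), max(modelIndex, a), sep = ":")
    rec <- comparisons$pairs[[key]]
    if (length(rec$positions))
      ssum[rec$positions] <- ssum[rec$positions] +
        residueSScore(rec$distances)
  }
  sr <- ssum / (N - 1)
  sr[setdiff(seq_len(L), own)] <- NA_real_
  sr
}

#' Global consensus score of one pool member
#'
#' Blend of the model's mean TM-score and mean Q-score against the other
#' `N-1` pool members: `G = w * meanTM + (1-w) * meanQ`, default
#' `w = 0.5`.
#'
#' @inheritParams meanResidueScore
#' @param weight blend weight `w` in `[0, 1]` given to the TM-based mean.
#' @return the global score, a number in `[0, 1]`.
#' @export
globalScore <- function(modelIndex, pool, comparisons, weight = 0.5) {
  stopifnot(weight >= 0, weight <= 1)
  N <- length(poolModels(pool))
  if (N < 2L) stop("pool must contain at least 2 models")
  others <- setdiff(seq_len(N), modelIndex)
  meanTM <- mean(comparisons$tm[modelIndex, others])
  meanQ <- mean(comparisons$q[modelIndex, others])
  weight * meanTM + (1 - weight) * meanQ
}

#' Score a model pool
#'
#' Runs the full consensus engine: all `N(N-1)/2` pairwise comparisons are
#' computed once, then every model's global score and every user model's
#' per-residue `S_r` and predicted distance `d_r` are derived. User models
#' are ranked by global score (descending, ties broken by model name);
#' reference models are scored internally but reported separately. When a
#' [CalibrationCurve-class] is supplied, each global score also receives a
#' P-value that the model is incorrect.
#'
#' @param pool a [ModelPool-class].
#' @param weight blend weight between TM-based and Q-based means
#'   (default 0.5).
#' @param calibration optional [CalibrationCurve-class] for P-values.
#' @param sigmaExponent passed to [qCompare()].
#' @param comparisons optional precomputed [poolComparisons()] result.
#' @return a [PoolQAResult-class].
#' @export
scorePool <- function(pool, weight = 0.5, calibration = NULL,
                      sigmaExponent = 0.15, comparisons = NULL) {
  mods <- poolModels(pool)
  N <- length(mods)
  L <- targetLength(pool@target)
  nUser <- length(pool@userModels)
  if (is.null(comparisons))
    comparisons <- poolComparisons(pool, sigmaExponent = sigmaExponent)

  ids <- vapply(mods, modelId, character(1))
  g <- vapply(seq_len(N), globalScore, numeric(1),
              pool = pool, comparisons = comparisons, weight = weight)
  meanTM <- vapply(seq_len(N), function(i)
    mean(comparisons$tm[i, -i]), numeric(1))
  meanQ <- vapply(seq_len(N), function(i)
    mean(comparisons$q[i, -i]), numeric(1))
  pv <- if (is.null(calibration)) rep(NA_real_, N)
        else vapply(g, function(s) pValue(calibration, s), numeric(1))

  sr <- matrix(NA_real_, L, nUser, dimnames = list(NULL, ids[seq_len(nUser)]))
  for (i in seq_len(nUser)) sr[, i] <- meanResidueScore(i, pool, comparisons)
  dr <- sr
  present <- !is.na(sr)
  dr[present] <- predictedDistance(sr[present])

  gs <- data.frame(model = ids, globalScore = g, meanTM = meanTM,
                   meanQ = meanQ, pValue = pv,
                   isReference = rep(c(FALSE, TRUE), c(nUser, N - nUser)),
                   stringsAsFactors = FALSE)
  ord <- order(gs$isReference, -gs$globalScore, gs$model)
  gs <- gs[ord, , drop = FALSE]
  rownames(gs) <- NULL
  new("PoolQAResult", target = pool@target, globalScores = gs,
      sr = sr, dr = dr, weight = weight)
}
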