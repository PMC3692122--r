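# Synthetic fixture generation: toy natives, decoy pools with controlled
# global/local deviations, and calibration sets of known-incorrect models.
#
# Natives are idealised CA-only folds -- ideal alpha-helical segments
# joined at randomised turn directions, self-avoiding, with consecutive
# CA-CA distances inside 3.8 +/- 0.05 Angstroms. They are not physically
# realistic proteins; they do not need to be, because every score in the
# package consumes CA geometry only.

# Ideal alpha-helix CA trace in a canonical frame: radius 2.3 A, rise
# 1.5 A, 100 degrees per residue => consecutive CA-CA distance ~3.83 A.
.helixTemplate <- function(n) {
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
}

# Minimum distance between residues >= 3 apart in sequence.
.minNonlocal <- function(xyz) {
  n <- nrow(xyz)
  if (n < 5L) return(Inf)
  D <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  min(D[sep >= 3L])
}

#' Generate a synthetic native CA trace
#'
#' Builds a self-avoiding CA-only fold of length `L`: ideal alpha-helical
#' segments (6-12 residues) joined at randomised directions, rejected and
#' redrawn until no two residues more than 2 apart in sequence come closer
#' than 3.5 Angstroms. Deterministic under `seed`.
#'
#' @param L number of residues (>= 10).
#' @param seed integer seed.
#' @return a [ModelStructure-class] covering positions `1..L`.
#' @export
makeNative <- function(L, seed = 1) {
  if (L < 10L) stop("'L' must be at least 10")
  withSeed(seed, {
    for (attempt in 1:500) {
      xyz <- .helixTemplate(min(L, sample(6:12, 1)))
      while (nrow(xyz) < L) {
        len <- min(L - nrow(xyz), sample(6:12, 1))
        seg <- .helixTemplate(len) %*% t(randomRotation())
        p <- nrow(xyz)
        u <- xyz[p, ] - xyz[p - 1, ]
        dir <- u / sqrt(sum(u^2)) + 0.9 * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        # joint bond: first residue of the new segment sits exactly
        # 3.8 A from the current chain end, along a turn direction
        anchor <- xyz[p, ] + 3.8 * dir
        seg <- sweep(seg, 2, seg[1, ] - anchor, `-`)
        xyz <- rbind(xyz, seg)
      }
      xyz <- xyz[seq_len(L), , drop = FALSE]
      if (.minNonlocal(xyz) >= 3.5) break
      xyz <- NULL
    }
    if (is.null(xyz))
      stop("failed to build a self-avoiding trace of length ", L)
    newModel(sprintf("native_L%d_s%d", L, as.integer(seed)),
             seq_len(L), xyz)
  })
}

#' Decoy specification constructor
#'
#' @param globalNoise standard deviation (Angstroms) of isotropic
#'   per-coordinate Gaussian noise applied to every residue.
#' @param perturbations list of `c(start, end, displacement)` windows:
#'   residues `start..end` are additionally displaced coherently by
#'   `displacement` Angstroms in a random direction.
#' @param seed integer seed for this decoy.
#' @return a [DecoySpec-class].
#' @export
decoySpec <- function(globalNoise = 0, perturbations = list(), seed = 1) {
  new("DecoySpec", globalNoise = as.numeric(globalNoise),
      perturbations = perturbations, seed = as.integer(seed))
}

#' Generate decoys from a native structure
#'
#' Each decoy is the native trace plus isotropic Gaussian coordinate noise
#' and optional coherent window displacements per its [DecoySpec-class],
#' finally placed in a random rigid-body orientation. The ground-truth
#' per-residue deviation from the native (before the rigid motion, which
#' does not change true deviations) is attached as attribute
#' `"trueDeviation"`, and the true (pre-noise) per-residue displacement
#' structure is what [scorePool()] is expected to recover.
#'
#' @param native a [ModelStructure-class] (e.g. from [makeNative()]).
#' @param specs list of [DecoySpec-class] objects (or a single one).
#' @return list of [ModelStructure-class] decoys, each carrying a
#'   `trueDeviation` attribute (numeric, per residue).
#' @export
makeDecoys <- function(native, specs) {
  if (is(specs, "DecoySpec")) specs <- list(specs)
  stopifnot(all(vapply(specs, is, logical(1), "DecoySpec")))
  L <- length(native@positions)
  lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    bad <- vapply(sp@perturbations, function(p) p[2] > L, logical(1))
    if (any(bad)) stop("perturbation window outside 1..", L)
    withSeed(sp@seed, {
      xyz <- native@coords +
        matrix(stats::rnorm(3 * L, sd = sp@globalNoise), L, 3)
      for (p in sp@perturbations) {
        v <- stats::rnorm(3); v <- v / sqrt(sum(v^2)) * p[3]
        idx <- p[1]:p[2]
        xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, v, `+`)
      }
      dev <- sqrt(rowSums((xyz - native@coords)^2))
      R <- randomRotation()
      xyz <- sweep(xyz %*% t(R), 2, stats::rnorm(3, sd = 20), `+`)
      m <- newModel(sprintf("decoy%03d_s%d", k, sp@seed),
                    native@positions, xyz)
      attr(m, "trueDeviation") <- dev
      m
    })
  })
}

# One random-walk CA trace (uncorrelated step directions, 3.8 A bonds):
# globally dissimilar to any compact fold, used as an "incorrect" model.
.randomWalkModel <- function(L, id) {
  steps <- matrix(stats::rnorm(3 * (L - 1)), L - 1, 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  xyz <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  newModel(id, seq_len(L), xyz)
}

#' Generate a calibration set of known-incorrect models
#'
#' Emulates the P-value calibration procedure at desk scale: random-walk
#' decoys with TM-score against the native below `threshold` are drawn by
#' rejection sampling, scored by the consensus engine inside mixed pools
#' (each batch of incorrect models is pooled with a few near-native
#' models, so scoring reflects realistic pool composition), and the
#' resulting `(global_score, native_tm)` rows are written to a two-column
#' calibration file.
#'
#' @param native a [ModelStructure-class].
#' @param nIncorrect number of incorrect models to generate (>= 50 for a
#'   fit with default settings).
#' @param seed integer seed.
#' @param path optional output path for the calibration file.
#' @param threshold native-TM threshold defining "incorrect" (default 0.2).
#' @param batchSize number of incorrect models scored per mixed pool.
#' @param nGood near-native companions added to each scoring pool.
#' @param weight global-score blend weight (default 0.5).
#' @return data.frame with columns `score` and `nativeTM` (one row per
#'   incorrect model, all `nativeTM < threshold`), invisibly written to
#'   `path` when given.
#' @export
makeCalibrationSet <- function(native, nIncorrect = 100, seed = 1,
                               path = NULL, threshold = 0.2,
                               batchSize = 9, nGood = 3, weight = 0.5) {
  L <- length(native@positions)
  target <- new("TargetSequence",
                id = sprintf("synthetic_L%d", L),
                residues = rep("A", L))
  withSeed(seed, {
    walks <- list(); tms <- numeric(0)
    attempts <- 0L
    while (length(walks) < nIncorrect) {
      attempts <- attempts + 1L
      if (attempts > 30L * nIncorrect)
        stop("rejection sampling failed to produce ", nIncorrect,
             " incorrect models (target length too small?)")
      cand <- .randomWalkModel(L, sprintf("incorrect%04d", attempts))
      tm <- tmScore(tmSuperpose(cand, native, normLength = L))
      if (tm < threshold) {
        walks[[length(walks) + 1L]] <- cand
        tms <- c(tms, tm)
      }
    }
    good <- makeDecoys(native, lapply(seq_len(nGood), function(i)
      decoySpec(globalNoise = 1.0, seed = 10000L + i)))
    scores <- numeric(nIncorrect)
    batches <- split(seq_len(nIncorrect),
                     (seq_len(nIncorrect) - 1L) %/% batchSize)
    for (b in batches) {
      pool <- buildPool(userModels = walks[b], referenceModels = good,
                        target = target)
      res <- scorePool(pool, weight = weight)
      gs <- globalScores(res)
      ids <- vapply(walks[b], modelId, character(1))
      scores[b] <- gs$globalScore[match(ids, gs$model)]
    }
    dat <- data.frame(score = scores, nativeTM = tms)
    if (!is.null(path)) writeCalibrationFile(dat, path)
    dat
  })
}
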