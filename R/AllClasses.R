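#' @import methods
NULL

AA_ALPHABET1 <- c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V","X")

#' Target protein sequence
#'
#' Holds the amino-acid sequence of the prediction target. All candidate
#' models of one target are numbered against positions `1..L` of this
#' sequence, and `L` is the normalization length for the TM-score.
#'
#' @slot id short text label for the target.
#' @slot residues character vector of one-letter amino-acid codes
#'   (20-letter alphabet plus `"X"`), positions `1..L`.
#'
#' @seealso [readTarget()], [targetLength()]
#' @exportClass TargetSequence
setClass("TargetSequence",
         representation(id = "character", residues = "character"))

setValidity("TargetSequence", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  if (length(object@residues) < 1L)
    return("sequence must contain at least one residue")
  bad <- setdiff(unique(object@residues), AA_ALPHABET1)
  if (length(bad))
    return(paste0("invalid residue code(s): ", paste(bad, collapse = ", ")))
  TRUE
})

#' One candidate 3D model of a target
#'
#' A candidate model reduced to its C-alpha trace: an ordered set of
#' residues, each mapped to a target-sequence position and carrying a
#' 3D coordinate in Angstroms. All scoring in the package operates on
#' these CA coordinates; residue correspondence between models of one
#' target is by target position (residue sequence number), never by
#' structural re-alignment.
#'
#' @slot modelId text identifier (usually the file name).
#' @slot positions integer vector of target positions, strictly increasing,
#'   each in `1..L` of the target.
#' @slot coords numeric matrix (n x 3) of CA coordinates in Angstroms,
#'   one row per entry of `positions`.
#' @slot sourcePath path of the PDB file the model was read from
#'   (`NA` for models built in memory).
#'
#' @seealso [readModel()], [writeModelPdb()]
#' @exportClass ModelStructure
setClass("ModelStructure",
         representation(modelId = "character", positions = "integer",
                        coords = "matrix", sourcePath = "character"))

setValidity("ModelStructure", function(object) {
  n <- length(object@positions)
  if (n < 3L) return("a model needs at least 3 residues with coordinates")
  if (any(diff(object@positions) <= 0L))
    return("target positions must be strictly increasing")
  if (any(object@positions < 1L))
    return("target positions must be >= 1")
  if (!is.numeric(object@coords) || !identical(dim(object@coords), c(n, 3L)))
    return("'coords' must be an n x 3 numeric matrix matching 'positions'")
  if (any(!is.finite(object@coords)))
    return("coordinates must be finite")
  TRUE
})

#' Model with per-residue predicted distances for B-factor annotation
#'
#' Couples a [ModelStructure-class] with the predicted distance (in
#' Angstroms, capped at 15) of each of its residues from the native
#' structure, ready to be written into the B-factor column of the
#' model's PDB file.
#'
#' @slot base the underlying [ModelStructure-class].
#' @slot bfactor numeric vector of predicted distances, one per model
#'   residue (same order as `positions(base)`), each in `[0, 15]`.
#'
#' @seealso [annotateModel()], [writeAnnotatedPdb()]
#' @exportClass AnnotatedModel
setClass("AnnotatedModel",
         representation(base = "ModelStructure", bfactor = "numeric"))

setValidity("AnnotatedModel", function(object) {
  if (length(object@bfactor) != length(object@base@positions))
    return("one B-factor value per model residue is required")
  if (any(!is.finite(object@bfactor)))
    return("B-factor values must be finite")
  if (any(object@bfactor < 0 | object@bfactor > 15))
    return("B-factor (predicted distance) values must lie in [0, 15]")
  TRUE
})

#' Rigid-body superposition of two models
#'
#' The result of optimally superposing two models of one target under the
#' TM-score: the proper rotation and translation applied to the second
#' model, the per-residue distances `d_i` between aligned residues under
#' that transform (for every common target position), and the TM-score.
#'
#' @slot rotation 3 x 3 proper rotation matrix (det = +1) applied to the
#'   second model's coordinates (as column vectors).
#' @slot translation length-3 numeric translation (Angstroms).
#' @slot positions integer vector of target positions common to both models.
#' @slot distances numeric vector of distances `d_i` (Angstroms) between
#'   aligned residues under the superposition, one per common position.
#' @slot tmScore the TM-score in `(0, 1]`.
#' @slot normLength integer normalization length (the target length `L`).
#'
#' @seealso [tmSuperpose()], [transformCoords()]
#' @exportClass Superposition
setClass("Superposition",
         representation(rotation = "matrix", translation = "numeric",
                        positions = "integer", distances = "numeric",
                        tmScore = "numeric", normLength = "integer"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  if (!identical(dim(R), c(3L, 3L))) return("'rotation' must be 3 x 3")
  if (abs(det(R) - 1) > 1e-6) return("'rotation' must be proper (det = +1)")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("'rotation' must be orthonormal")
  if (length(object@translation) != 3L) return("'translation' must be length 3")
  if (length(object@distances) != length(object@positions))
    return("one distance per common position is required")
  if (any(object@distances < 0)) return("distances must be non-negative")
  if (object@tmScore > 1 + 1e-9) return("tmScore must be <= 1")
  TRUE
})

#' Pool of models of one target
#'
#' The model pool over which all-against-all comparisons are computed.
#' With two or more user models the pool operates in full-clustering mode;
#' with exactly one user model a non-empty reference pool is required and
#' the engine runs in quasi-single-model mode, gauging the submitted model
#' against the reference models.
#'
#' @slot target the [TargetSequence-class].
#' @slot userModels list of user-submitted [ModelStructure-class] objects.
#' @slot referenceModels list of reference [ModelStructure-class] objects
#'   (may be empty in full-clustering mode).
#'
#' @seealso [buildPool()], [scorePool()]
#' @exportClass ModelPool
setClass("ModelPool",
         representation(target = "TargetSequence", userModels = "list",
                        referenceModels = "list"))

setValidity("ModelPool", function(object) {
  mods <- c(object@userModels, object@referenceModels)
  if (length(object@userModels) < 1L)
    return("at least one user model is required")
  if (length(mods) < 2L)
    return("a pool needs at least 2 models for any scoring to proceed")
  if (!all(vapply(mods, is, logical(1), "ModelStructure")))
    return("all pool members must be ModelStructure objects")
  L <- length(object@target@residues)
  ok <- vapply(mods, function(m) all(m@positions <= L), logical(1))
  if (!all(ok))
    return("all models must be indexed against the same target (positions <= L)")
  TRUE
})

#' Quality-assessment result for a model pool
#'
#' Per-model global quality scores (with P-values when a calibration curve
#' was supplied) and per-residue predicted accuracies: the mean S-score
#' `S_r` and the predicted distance `d_r` from the native structure, with
#' `NA` (reported as `"X"`) at target positions absent from a model.
#' User models are ranked by global score; reference models are scored
#' internally but reported separately.
#'
#' @slot target the [TargetSequence-class].
#' @slot globalScores data.frame with columns `model`, `globalScore`,
#'   `meanTM`, `meanQ`, `pValue`, `isReference`, ranked by `globalScore`
#'   (descending; ties broken by model name) within user models.
#' @slot sr numeric matrix (L x n_user) of mean per-residue S-scores,
#'   `NA` where the model lacks the residue.
#' @slot dr numeric matrix (L x n_user) of predicted distances (Angstroms,
#'   capped at 15), `NA` where the model lacks the residue.
#' @slot weight blend weight between the TM-based and Q-based global means.
#'
#' @seealso [scorePool()], [writeQAFile()]
#' @exportClass PoolQAResult
setClass("PoolQAResult",
         representation(target = "TargetSequence", globalScores = "data.frame",
                        sr = "matrix", dr = "matrix", weight = "numeric"))

setValidity("PoolQAResult", function(object) {
  gs <- object@globalScores
  need <- c("model", "globalScore", "meanTM", "meanQ", "pValue", "isReference")
  if (!all(need %in% names(gs)))
    return(paste("globalScores must have columns:", paste(need, collapse = ", ")))
  L <- length(object@target@residues)
  if (nrow(object@dr) != L || nrow(object@sr) != L)
    return("per-residue matrices must have L rows")
  dr <- object@dr[!is.na(object@dr)]
  if (length(dr) && (any(dr < 0) || any(dr > 15)))
    return("predicted distances must lie in [0, 15]")
  TRUE
})

#' P-value calibration curve
#'
#' The null distribution of global quality scores of known-incorrect models
#' (models whose TM-score against the native structure is below a
#' threshold, by default 0.2). A boundary-reflected Gaussian kernel density
#' is fitted over `[0, 1]`, and its upper-tail mass at a score is the
#' P-value that a model achieving that score is incorrect.
#'
#' @slot scores global scores of the retained incorrect models.
#' @slot threshold native-TM threshold below which a model counts as
#'   incorrect (default 0.2, strict inequality).
#' @slot bandwidth kernel bandwidth used for the density fit.
#' @slot grid score grid on `[0, 1]` at which the density was evaluated.
#' @slot density fitted density values over `grid` (integrates to 1).
#' @slot tail upper-tail mass at each grid point; `tail[1] = 1`,
#'   monotonically non-increasing.
#'
#' @seealso [fitCalibration()], [pValue()]
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
         representation(scores = "numeric", threshold = "numeric",
                        bandwidth = "numeric", grid = "numeric",
                        density = "numeric", tail = "numeric"))

setValidity("CalibrationCurve", function(object) {
  if (length(object@grid) != length(object@density) ||
      length(object@grid) != length(object@tail))
    return("'grid', 'density' and 'tail' must have equal length")
  if (abs(object@tail[1] - 1) > 1e-6) return("tail(0) must be 1")
  if (any(diff(object@tail) > 1e-9))
    return("tail must be monotonically non-increasing")
  if (any(object@tail <= 0) || any(object@tail > 1 + 1e-9))
    return("tail values must lie in (0, 1]")
  TRUE
})

#' Specification of one synthetic decoy
#'
#' Controls how a decoy is derived from a reference (native) structure:
#' isotropic Gaussian coordinate noise applied to every residue, plus
#' optional coherent local displacements of residue windows. The decoy is
#' finally placed in a random rigid-body orientation so superposition is
#' non-trivial.
#'
#' @slot globalNoise standard deviation (Angstroms) of isotropic
#'   per-coordinate Gaussian noise.
#' @slot perturbations list of length-3 numeric vectors
#'   `c(start, end, displacement)`: residues `start..end` are displaced
#'   coherently by `displacement` Angstroms in a random direction.
#' @slot seed integer seed making the decoy deterministic.
#'
#' @seealso [decoySpec()], [makeDecoys()]
#' @exportClass DecoySpec
setClass("DecoySpec",
         representation(globalNoise = "numeric", perturbations = "list",
                        seed = "integer"))

setValidity("DecoySpec", function(object) {
  if (length(object@globalNoise) != 1L || object@globalNoise < 0)
    return("'globalNoise' must be a single non-negative number")
  ok <- vapply(object@perturbations, function(p)
    is.numeric(p) && length(p) == 3L && p[1] >= 1 && p[2] >= p[1] && p[3] >= 0,
    logical(1))
  if (!all(ok))
    return("each perturbation must be c(start, end, displacement) with start <= end")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("'seed' must be a single integer")
  TRUE
})
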