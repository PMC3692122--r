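#' Accessors for ConsensusQA classes
#'
#' Small accessor generics: `targetLength()` returns the number of target
#' residues `L`; `modelId()` a model's identifier; `positions()` the target
#' positions covered by a model; `coords()` its CA coordinate matrix;
#' `tmScore()` the TM-score of a superposition; `poolSize()` the total
#' number of models `N` in a pool; `globalScores()` the ranked global-score
#' table of a result; `localScores()` the per-residue table for one model;
#' `calibrationScores()` the retained incorrect-model scores of a
#' calibration curve.
#'
#' @param x the object.
#' @param ... further arguments for methods.
#' @return see the individual method descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("targetLength", function(x) standardGeneric("targetLength"))

#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("tmScore", function(x) standardGeneric("tmScore"))

#' @rdname accessors
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))

#' @rdname accessors
#' @export
setGeneric("globalScores", function(x, ...) standardGeneric("globalScores"))

#' @rdname accessors
#' @export
setGeneric("localScores", function(x, ...) standardGeneric("localScores"))

#' @rdname accessors
#' @export
setGeneric("calibrationScores",
           function(x) standardGeneric("calibrationScores"))

#' @rdname accessors
setMethod("targetLength", "TargetSequence",
          function(x) length(x@residues))

#' @rdname accessors
setMethod("modelId", "ModelStructure", function(x) x@modelId)

#' @rdname accessors
setMethod("positions", "ModelStructure", function(x) x@positions)

#' @rdname accessors
setMethod("coords", "ModelStructure", function(x) x@coords)

#' @rdname accessors
setMethod("positions", "Superposition", function(x) x@positions)

#' @rdname accessors
setMethod("tmScore", "Superposition", function(x) x@tmScore)

#' @rdname accessors
setMethod("poolSize", "ModelPool",
          function(x) length(x@userModels) + length(x@referenceModels))

#' @rdname accessors
#' @param referenceModels for `globalScores()` on a [PoolQAResult-class]:
#'   include the (separately reported) reference models?
setMethod("globalScores", "PoolQAResult",
          function(x, referenceModels = FALSE) {
  gs <- x@globalScores
  if (!referenceModels) gs <- gs[!gs$isReference, , drop = FALSE]
  rownames(gs) <- NULL
  gs
})

#' @rdname accessors
#' @param model for `localScores()`: a user model name (or index into the
#'   ranked user table).
setMethod("localScores", "PoolQAResult", function(x, model) {
  if (is.numeric(model)) model <- globalScores(x)$model[model]
  if (!model %in% colnames(x@dr))
    stop("no per-residue scores for model '", model, "'")
  data.frame(position = seq_len(nrow(x@dr)),
             residue = x@target@residues,
             sr = x@sr[, model],
             dr = x@dr[, model])
})

#' @rdname accessors
setMethod("calibrationScores", "CalibrationCurve", function(x) x@scores)

setMethod("show", "TargetSequence", function(object) {
  L <- length(object@residues)
  s <- paste(object@residues, collapse = "")
  if (L > 40) s <- paste0(substr(s, 1, 37), "...")
  cat("TargetSequence '", object@id, "': ", L, " residues\n  ", s, "\n",
      sep = "")
})

setMethod("show", "ModelStructure", function(object) {
  cat("ModelStructure '", object@modelId, "': ", length(object@positions),
      " CA residues, target positions ", min(object@positions), "..",
      max(object@positions), "\n", sep = "")
})

setMethod("show", "Superposition", function(object) {
  cat("Superposition over ", length(object@positions),
      " common residues (L = ", object@normLength, ")\n",
      "  TM-score: ", sprintf("%.4f", object@tmScore),
      ", mean d_i: ", sprintf("%.2f", mean(object@distances)), " A\n",
      sep = "")
})

setMethod("show", "ModelPool", function(object) {
  nu <- length(object@userModels); nr <- length(object@referenceModels)
  mode <- if (nu >= 2) "full-clustering" else "quasi-single-model"
  cat("ModelPool for target '", object@target@id, "' (L = ",
      length(object@target@residues), ")\n  ", nu, " user model(s) + ",
      nr, " reference model(s); N = ", nu + nr, " [", mode, " mode]\n",
      sep = "")
})

setMethod("show", "PoolQAResult", function(object) {
  gs <- globalScores(object)
  cat("PoolQAResult for target '", object@target@id, "': ",
      nrow(gs), " user model(s) ranked by global score\n", sep = "")
  print(utils::head(gs[, c("model", "globalScore", "pValue")], 5))
  if (nrow(gs) > 5) cat("  ...\n")
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve: ", length(object@scores),
      " incorrect-model scores (native TM < ", object@threshold, ")\n",
      "  score range ", sprintf("%.3f..%.3f", min(object@scores),
                                max(object@scores)),
      ", bandwidth ", sprintf("%.4f", object@bandwidth), "\n", sep = "")
})
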