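# End-to-end pipeline: score a set of submitted models against an
# optional reference pool, attach P-values, and write every output a user
# of the tool expects (ranked table, CASP QMODE2 file, annotated PDBs,
# per-residue error plots, log). A thin command-line wrapper over these
# functions ships in inst/scripts/qa.R.

#' Plot the per-residue predicted error of one model
#'
#' Residue index against predicted distance from the native structure
#' (Angstroms, capped at 15); gaps where the model lacks the residue.
#'
#' @param result a [PoolQAResult-class].
#' @param model user model name or rank index.
#' @param path optional PNG output path; when `NULL`, plots to the active
#'   device.
#' @return the path (or `NULL`), invisibly.
#' @export
plotResidueError <- function(result, model, path = NULL) {
  ls <- localScores(result, model)
  if (is.numeric(model)) model <- globalScores(result)$model[model]
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 420)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(ls$position, ls$dr, type = "h", lwd = 2,
                 col = "steelblue4", ylim = c(0, 15),
                 xlab = "Residue position", ylab = "Predicted distance (Å)",
                 main = paste("Per-residue predicted error:", model))
  graphics::abline(h = S_D0, lty = 2, col = "grey50")
  if (any(is.na(ls$dr)))
    graphics::rug(ls$position[is.na(ls$dr)], col = "red3")
  invisible(path)
}

#' Diagnostic plot of a calibration fit
#'
#' Histogram of the retained incorrect-model scores with the fitted
#' density overlaid.
#'
#' @param curve a [CalibrationCurve-class].
#' @param path optional PNG output path.
#' @return the path (or `NULL`), invisibly.
#' @export
plotCalibration <- function(curve, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::hist(curve@scores, breaks = 30, freq = FALSE,
                 xlim = c(0, 1), col = "grey85", border = "grey60",
                 xlab = "Global score of incorrect models",
                 main = sprintf("Null score distribution (n = %d)",
                                length(curve@scores)))
  graphics::lines(curve@grid, curve@density, col = "red3", lwd = 2)
  invisible(path)
}

#' Run the full quality-assessment pipeline
#'
#' Reads the target and models, builds the pool (full-clustering with
#' several user models; quasi-single-model when one model is submitted
#' with a reference pool), scores it, fits or loads the P-value
#' calibration, and writes to `outDir`:
#' `ranking.tsv` (model, global score, P-value), `qa_qmode2.txt` (CASP
#' QMODE2), one B-factor-annotated PDB and one per-residue error PNG per
#' user model, and `run.log`. File writes are atomic (write-then-rename),
#' so a failed run leaves no half-written output.
#'
#' @param targetPath FASTA file of the target sequence.
#' @param modelPaths character vector of model PDB paths, or a directory.
#' @param refPoolDir optional directory of reference-pool PDB models.
#' @param calibrationPath optional calibration file
#'   (see [readCalibrationFile()]); when absent, a synthetic default
#'   calibration is built from random-walk decoys of a synthetic native of
#'   the target's length.
#' @param weight blend weight between TM-based and Q-based global means.
#' @param outDir output directory (created if needed).
#' @param seed integer seed for every source of randomness in the run.
#' @param calibrationSize incorrect models in the synthetic default
#'   calibration (ignored when `calibrationPath` is given).
#' @param verbose print progress messages?
#' @return the [PoolQAResult-class], invisibly; outputs in `outDir`.
#' @export
runQA <- function(targetPath, modelPaths, refPoolDir = NULL,
                  calibrationPath = NULL, weight = 0.5, outDir,
                  seed = 1, calibrationSize = 60, verbose = TRUE) {
  stopifnot(weight >= 0, weight <= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    if (verbose) message(msg)
  }
  say("run seed: ", seed, "; weight: ", weight)
  target <- readTarget(targetPath)
  say("target '", target@id, "', L = ", targetLength(target))

  if (length(modelPaths) == 1L && dir.exists(modelPaths)) {
    userModels <- readModelsDir(modelPaths, target)
  } else {
    bad <- modelPaths[!file.exists(modelPaths)]
    if (length(bad))
      stop("unreadable model file(s): ", paste(bad, collapse = ", "))
    userModels <- lapply(modelPaths, readModel, target = target)
  }
  refModels <- if (!is.null(refPoolDir)) readModelsDir(refPoolDir, target)
               else list()
  pool <- buildPool(userModels, refModels, target)
  say(length(userModels), " user model(s) + ",
      length(pool@referenceModels), " reference model(s); N = ",
      poolSize(pool), " (",
      if (length(userModels) >= 2) "full-clustering" else "quasi-single-model",
      " mode)")

  if (!is.null(calibrationPath)) {
    cal <- readCalibrationFile(calibrationPath)
    curve <- fitCalibration(cal$score, cal$nativeTM)
    say("calibration: ", length(calibrationScores(curve)),
        " incorrect models from ", calibrationPath)
  } else {
    say("no calibration file supplied; building a synthetic default (",
        calibrationSize, " random-walk decoys)")
    synthNative <- makeNative(targetLength(target), seed = seed)
    cal <- makeCalibrationSet(synthNative, nIncorrect = calibrationSize,
                              seed = seed, weight = weight)
    curve <- fitCalibration(cal$score, cal$nativeTM,
                            minIncorrect = min(50, calibrationSize))
  }

  result <- scorePool(pool, weight = weight, calibration = curve)
  gs <- globalScores(result)
  say("scored ", poolSize(pool), " models (",
      poolSize(pool) * (poolSize(pool) - 1) / 2, " pairwise comparisons)")

  tsv <- c("model\tglobal_score\tp_value",
           sprintf("%s\t%.5f\t%.3g", gs$model, gs$globalScore, gs$pValue))
  writeLinesAtomic(tsv, file.path(outDir, "ranking.tsv"))
  writeQAFile(result, mode = 2, path = file.path(outDir, "qa_qmode2.txt"))
  for (i in seq_len(nrow(gs))) {
    name <- gs$model[i]
    m <- pool@userModels[[match(name, vapply(pool@userModels, modelId,
                                             character(1)))]]
    ann <- annotateModel(m, result@dr[, name])
    writeAnnotatedPdb(ann, file.path(outDir, paste0(name, "_annotated.pdb")))
    plotResidueError(result, name,
                     file.path(outDir, paste0(name, "_error.png")))
  }
  say("outputs written to ", outDir)
  writeLinesAtomic(log, file.path(outDir, "run.log"))
  invisible(result)
}

#' Build a calibration file from synthetic decoys
#'
#' Generates a synthetic native of length `L`, draws `nIncorrect`
#' known-incorrect random-walk decoys, scores them in mixed pools, writes
#' the two-column calibration file and a diagnostic plot of the fitted
#' density over the score histogram.
#'
#' @param outFile output calibration file path.
#' @param L synthetic native length.
#' @param nIncorrect number of incorrect models (>= 50).
#' @param seed integer seed.
#' @param weight global-score blend weight.
#' @param verbose print a fit summary?
#' @return the fitted [CalibrationCurve-class], invisibly.
#' @export
runCalibrate <- function(outFile, L = 40, nIncorrect = 60, seed = 1,
                         weight = 0.5, verbose = TRUE) {
  native <- makeNative(L, seed = seed)
  dat <- makeCalibrationSet(native, nIncorrect = nIncorrect, seed = seed,
                            path = outFile, weight = weight)
  curve <- fitCalibration(dat$score, dat$nativeTM,
                          minIncorrect = min(50, nIncorrect))
  if (verbose)
    message("calibration fit: retained ", length(calibrationScores(curve)),
            " incorrect models (native TM < ", curve@threshold, "), ",
            "scores ", sprintf("%.3f..%.3f", min(curve@scores),
                               max(curve@scores)))
  plotCalibration(curve, paste0(sub("\\.[^./]*$", "", outFile),
                                "_density.png"))
  invisible(curve)
}
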