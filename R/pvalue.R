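# P-value calibration: the null distribution of global scores of
# known-incorrect models.
#
# A model is taken to be incorrect when its TM-score against the native
# structure is below 0.2 (strict inequality) -- at that level the model
# shares no significant similarity with the native fold. The global scores
# of incorrect models form a null distribution; the upper-tail mass of a
# density fitted to it at a given score is the P-value that a model
# achieving that score is incorrect, i.e. the proportion of
# no-native-similarity models scoring at least as high.

PVALUE_FLOOR <- 1e-6

#' Fit a P-value calibration curve
#'
#' Retains the global scores of models whose native TM-score is below
#' `threshold` (strictly), fits a Gaussian kernel density (Silverman
#' bandwidth) boundary-reflected on `[0, 1]`, and stores its upper-tail
#' mass function.
#'
#' @param scores numeric vector of global quality scores in `[0, 1]`.
#' @param nativeTM numeric vector, same length: TM-score of each model
#'   against the native structure.
#' @param threshold native-TM threshold below which a model counts as
#'   incorrect (default 0.2).
#' @param minIncorrect minimum number of retained incorrect models
#'   (default 50).
#' @param bandwidth optional kernel bandwidth override.
#' @param gridSize number of grid points over `[0, 1]` (default 2001).
#' @return a [CalibrationCurve-class].
#' @seealso [pValue()], [readCalibrationFile()], [makeCalibrationSet()]
#' @export
fitCalibration <- function(scores, nativeTM, threshold = 0.2,
                           minIncorrect = 50, bandwidth = NULL,
                           gridSize = 2001) {
  stopifnot(length(scores) == length(nativeTM))
  keep <- !is.na(nativeTM) & nativeTM < threshold
  s <- scores[keep]
  if (any(s < 0 | s > 1)) stop("global scores must lie in [0, 1]")
  if (length(s) < minIncorrect)
    stop("only ", length(s), " incorrect models (native TM < ", threshold,
         ") in the calibration set; at least ", minIncorrect,
         " are required -- supply a larger calibration set")
  bw <- if (!is.null(bandwidth)) bandwidth
        else if (length(s) >= 2) stats::bw.nrd0(s)
        else 0.05
  if (!is.finite(bw) || bw <= 0) bw <- 0.01
  grid <- seq(0, 1, length.out = gridSize)
  # Boundary reflection: the KDE of the augmented sample {-s, s, 2-s},
  # restricted to [0, 1] and rescaled, leaks no mass outside the support.
  dens <- stats::density(c(-s, s, 2 - s), bw = bw, from = 0, to = 1,
                         n = gridSize)$y * 3
  h <- grid[2] - grid[1]
  cdf <- c(0, cumsum((dens[-1] + dens[-gridSize]) / 2) * h)  # trapezoid
  total <- max(cdf[gridSize], .Machine$double.eps)
  cdf <- cdf / total
  dens <- dens / total
  tail <- pmax(1 - cdf, 1e-12)
  tail <- rev(cummax(rev(tail)))                        # enforce monotone
  tail[1] <- 1
  new("CalibrationCurve", scores = s, threshold = threshold,
      bandwidth = bw, grid = grid, density = dens, tail = tail)
}

#' P-value that a model is incorrect
#'
#' The upper-tail mass of the calibration density at `score`: the
#' estimated proportion of models sharing no similarity with the native
#' structure that reach a global score at least this high. Floored at
#' `1e-6` so a P-value is always reportable and positive.
#'
#' @param curve a [CalibrationCurve-class].
#' @param score global quality score(s) in `[0, 1]`.
#' @return P-value(s) in `(0, 1]`, vectorized over `score`.
#' @export
pValue <- function(curve, score) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("scores must lie in [0, 1]")
  p <- stats::approx(curve@grid, curve@tail, xout = score, rule = 2)$y
  pmin(pmax(p, PVALUE_FLOOR), 1)
}

#' Read a calibration score file
#'
#' Parses the two-column whitespace-separated calibration format:
#' `global_score native_tm` per line, `#` comments and blank lines
#' ignored.
#'
#' @param path path to the calibration file.
#' @return a data.frame with columns `score` and `nativeTM`.
#' @seealso [fitCalibration()], [makeCalibrationSet()]
#' @export
readCalibrationFile <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  dat <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("score", "nativeTM"))
  if (!nrow(dat)) stop("calibration file '", path, "' is empty")
  dat
}

#' Write a calibration score file
#'
#' @param dat data.frame with columns `score` and `nativeTM`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCalibrationFile <- function(dat, path) {
  lines <- c("# global_score native_tm",
             sprintf("%.6f %.6f", dat$score, dat$nativeTM))
  writeLinesAtomic(lines, path)
}
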