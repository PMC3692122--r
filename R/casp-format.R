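# CASP QA data-standard records.
#
# Emitted dialect (documented here because the standard only lives at a
# URL): header lines PFRMAT QA / TARGET <id> / AUTHOR ... / METHOD ... /
# QMODE <1|2>, then one record per model and a final END line. A QMODE 1
# record is "name global"; a QMODE 2 record is "name global e1 e2 ... eL"
# with per-residue predicted errors in Angstroms, "X" for residues missing
# from the model, wrapped at 20 values per line (continuation lines hold
# values only). Global scores are printed to 3 decimals, per-residue
# errors to 1 decimal; errors never exceed 15.0 (the d_r cap).

QA_WRAP <- 20L

#' Write a CASP QA results file
#'
#' Emits the scored user models of a [PoolQAResult-class] in the CASP QA
#' format: QMODE 1 (global scores only) or QMODE 2 (global scores plus the
#' `L` per-residue predicted distances, `"X"` marking target positions
#' missing from a model).
#'
#' @param result a [PoolQAResult-class].
#' @param mode 1 or 2.
#' @param path output path.
#' @param author,method optional AUTHOR / METHOD header text.
#' @return the path, invisibly.
#' @export
writeQAFile <- function(result, mode = 2, path, author = NULL,
                        method = "Consensus (clustering) model quality assessment") {
  stopifnot(mode %in% c(1, 2))
  gs <- globalScores(result)
  L <- targetLength(result@target)
  header <- c("PFRMAT QA",
              paste("TARGET", result@target@id),
              if (!is.null(author)) paste("AUTHOR", author),
              if (!is.null(method)) paste("METHOD", method),
              paste("QMODE", mode))
  recs <- character(0)
  for (i in seq_len(nrow(gs))) {
    name <- gs$model[i]
    head <- sprintf("%s %.3f", name, gs$globalScore[i])
    if (mode == 1) {
      recs <- c(recs, head)
      next
    }
    dr <- result@dr[, name]
    if (length(dr) != L)
      stop("per-residue data missing for model '", name, "'")
    vals <- ifelse(is.na(dr), "X", sprintf("%.1f", dr))
    chunks <- split(vals, (seq_len(L) - 1L) %/% QA_WRAP)
    lines <- vapply(chunks, paste, character(1), collapse = " ")
    lines[1] <- paste(head, lines[1])
    recs <- c(recs, lines)
  }
  writeLinesAtomic(c(header, recs, "END"), path)
}

#' Parse a CASP QA results file
#'
#' Reads a file in the dialect emitted by [writeQAFile()] (QMODE 1 or 2;
#' Windows line endings tolerated). A model record starts with a model
#' name token; continuation lines carry per-residue values only. Unknown
#' header keys are preserved as metadata.
#'
#' @param path path to the QA file.
#' @param L expected number of per-residue values per QMODE 2 record
#'   (optional; when given, a record with a different count is an error).
#' @return a list with `target`, `mode`, `metadata` (named character
#'   vector of remaining header fields) and `records`, a data.frame with
#'   columns `model` and `globalScore` plus, for QMODE 2, a list-column
#'   `residueErrors` of numeric vectors (`NA` where the file had `"X"`).
#' @export
parseQAFile <- function(path, L = NULL) {
  if (!file.exists(path)) stop("QA file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || lines[1] != "PFRMAT QA")
    stop("'", path, "' is not a CASP QA file (missing PFRMAT QA header)")
  headKeys <- c("PFRMAT", "TARGET", "AUTHOR", "METHOD", "QMODE", "REMARK")
  i <- 1L
  meta <- character(0)
  target <- NA_character_; mode <- NA_integer_
  while (i <= length(lines)) {
    key <- sub("\\s.*$", "", lines[i])
    if (!key %in% headKeys) break
    val <- trimws(sub("^\\S+\\s*", "", lines[i]))
    if (key == "TARGET") target <- val
    else if (key == "QMODE") mode <- as.integer(val)
    else if (key != "PFRMAT") meta[key] <- val
    i <- i + 1L
  }
  if (is.na(mode)) stop("'", path, "' has no QMODE header")
  body <- lines[seq(i, length(lines))]
  body <- body[body != "END"]
  isValue <- function(tok) grepl("^([0-9.+-]+|X)$", tok)
  models <- character(0); globals <- numeric(0); errs <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    models <<- c(models, cur$name)
    globals <<- c(globals, cur$global)
    errs[[length(errs) + 1L]] <<- cur$vals
  }
  for (ln in body) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(toks)) next
    if (!isValue(toks[1])) {            # new model record
      flush()
      if (length(toks) < 2L)
        stop("malformed record for model '", toks[1], "' in ", path)
      cur <- list(name = toks[1], global = as.numeric(toks[2]),
                  vals = toks[-(1:2)])
    } else {
      if (is.null(cur)) stop("orphan value line in ", path)
      cur$vals <- c(cur$vals, toks)
    }
  }
  flush()
  parseVals <- function(v, name) {
    bad <- v[!isValue(v)]
    if (length(bad))
      stop("non-numeric per-residue field '", bad[1], "' for model '",
           name, "'")
    out <- suppressWarnings(as.numeric(v))
    out[v == "X"] <- NA_real_
    if (any(is.na(out) & v != "X"))
      stop("unparseable per-residue field for model '", name, "'")
    out
  }
  if (mode == 2) {
    errs <- Map(parseVals, errs, models)
    if (!is.null(L)) {
      n <- vapply(errs, length, integer(1))
      if (any(n != L))
        stop("model '", models[which(n != L)[1]], "' has ",
             n[which(n != L)[1]], " per-residue values; expected ", L)
    }
  }
  records <- data.frame(model = models, globalScore = globals,
                        stringsAsFactors = FALSE)
  if (mode == 2) records$residueErrors <- I(errs)
  list(target = target, mode = mode, metadata = meta, records = records)
}
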