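# Reading targets and PDB models; writing (annotated) PDB.
#
# Only CA atoms enter the internal representation: every score in the
# package is a function of CA geometry. Full-atom records of the source
# file are preserved untouched for B-factor annotation output.

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA_1TO3 <- stats::setNames(names(AA_3TO1), AA_3TO1)

#' Read a target sequence from a FASTA file
#'
#' Reads the first record of a FASTA file as the prediction target. The
#' sequence is upper-cased and must use the 20-letter amino-acid alphabet
#' plus `"X"` for unknown residues.
#'
#' @param path path to a FASTA file with at least one record.
#' @return a [TargetSequence-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1", "MKVLAT"), fa)
#' targetLength(readTarget(fa))  # 6
#' @export
readTarget <- function(path) {
  if (!file.exists(path)) stop("target file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e)
                     stop("could not parse FASTA file '", path, "': ",
                          conditionMessage(e)))
  if (length(seqs) < 1L)
    stop("FASTA file '", path, "' contains no records")
  if (length(seqs) > 1L)
    warning("FASTA file '", path, "' has ", length(seqs),
            " records; using the first")
  s <- toupper(as.character(seqs[[1]]))
  res <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(res), AA_ALPHABET1)
  if (length(bad))
    stop("target sequence contains non-amino-acid character(s): ",
         paste(bad, collapse = ", "))
  id <- names(seqs)[1]
  id <- sub("\\s.*$", "", id)
  if (!nzchar(id)) id <- "target"
  new("TargetSequence", id = id, residues = res)
}

#' Read a PDB-format model and map it onto the target
#'
#' Reads the ATOM records of a PDB file through [bio3d::read.pdb()] and
#' extracts one CA coordinate per residue. Residue sequence numbers are
#' taken as target positions (`1..L`): models are numbered against the
#' target, never re-aligned. When a file holds several MODEL blocks or
#' chains, the first MODEL and first chain are used with a warning.
#' Alternate-location duplicates of a CA keep the first altLoc; files with
#' insertion codes, fewer than 3 CA atoms, positions outside `1..L`, or a
#' residue-number collision are rejected.
#'
#' @param path path to a PDB file.
#' @param target the [TargetSequence-class] the model belongs to.
#' @return a [ModelStructure-class].
#' @export
readModel <- function(path, target) {
  stopifnot(is(target, "TargetSequence"))
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^MODEL ", lines)) && sum(grepl("^ENDMDL", lines)) > 0) {
    end <- which(grepl("^ENDMDL", lines))[1]
    if (end < length(lines) &&
        any(grepl("^ATOM", lines[(end + 1):length(lines)]))) {
      warning("'", basename(path), "' has multiple MODEL blocks; using the first")
      lines <- lines[seq_len(end)]
    }
  }
  if (!any(grepl("^ATOM", lines)))
    stop("'", path, "' contains no ATOM records")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e)))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("'", path, "' contains no ATOM records")
  chains <- unique(atoms$chain)
  if (length(chains) > 1L) {
    warning("'", basename(path), "' has ", length(chains),
            " chains; using the first ('", chains[1], "')")
    keep <- if (is.na(chains[1])) is.na(atoms$chain)
            else !is.na(atoms$chain) & atoms$chain == chains[1]
    atoms <- atoms[keep, , drop = FALSE]
  }
  if (any(!is.na(atoms$insert)))
    stop("'", path, "' uses insertion codes; models must be numbered ",
         "against the target sequence without insertions")
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) < 3L)
    stop("'", path, "' has fewer than 3 CA atoms")
  # altLoc duplicates keep the first; identical residue numbers without
  # altLoc codes are a numbering collision.
  dup <- duplicated(ca$resno)
  if (any(dup)) {
    for (rn in unique(ca$resno[dup])) {
      grp <- ca[ca$resno == rn, , drop = FALSE]
      if (all(is.na(grp$alt)))
        stop("'", path, "' has a residue number collision at ", rn)
    }
    ca <- ca[!dup, , drop = FALSE]
  }
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]
  L <- targetLength(target)
  if (any(ca$resno < 1L | ca$resno > L))
    stop("'", path, "' has residue number(s) outside the target range 1..",
         L, ": ", paste(utils::head(ca$resno[ca$resno < 1 | ca$resno > L], 5),
                        collapse = ", "))
  newModel(id = sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
           positions = ca$resno,
           coords = cbind(ca$x, ca$y, ca$z),
           sourcePath = normalizePath(path))
}

#' Read all PDB models from a directory
#'
#' @param dir directory containing `*.pdb` files.
#' @param target the [TargetSequence-class].
#' @return a named list of [ModelStructure-class] objects.
#' @export
readModelsDir <- function(dir, target) {
  files <- list.files(dir, pattern = "\\.(pdb|ent)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files)) stop("no PDB files found in ", dir)
  mods <- lapply(files, readModel, target = target)
  names(mods) <- vapply(mods, modelId, character(1))
  mods
}

#' Write a CA-trace model as a PDB file
#'
#' Writes minimal PDB v3.3 ATOM records (one CA per residue, chain A) for
#' a model held in memory, optionally with B-factor values. Residue names
#' are taken from the target sequence when supplied, else `GLY`.
#'
#' @param model a [ModelStructure-class].
#' @param path output path.
#' @param target optional [TargetSequence-class] supplying residue names.
#' @param bfactor numeric vector of B-factor values, one per model residue
#'   (default 0).
#' @return the path, invisibly.
#' @export
writeModelPdb <- function(model, path, target = NULL, bfactor = NULL) {
  n <- length(model@positions)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  stopifnot(length(bfactor) == n)
  resn <- rep("GLY", n)
  if (!is.null(target)) {
    aa <- target@residues[model@positions]
    known <- aa %in% names(AA_1TO3)
    resn[known] <- AA_1TO3[aa[known]]
    resn[!known] <- "UNK"
  }
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), resn, model@positions,
    model@coords[, 1], model@coords[, 2], model@coords[, 3],
    1.00, bfactor)
  writeLinesAtomic(c(lines, "TER", "END"), path)
}

#' Attach per-residue predicted distances to a model
#'
#' Builds an [AnnotatedModel-class] from a model and its predicted
#' per-residue distances from the native structure, as produced by
#' [scorePool()].
#'
#' @param model a [ModelStructure-class].
#' @param distances predicted distances in Angstroms: either one value per
#'   model residue (in `positions(model)` order), or a full target-length
#'   vector indexed by position (e.g. a column of the `dr` matrix of a
#'   [PoolQAResult-class]), from which the model's positions are taken.
#' @return an [AnnotatedModel-class].
#' @export
annotateModel <- function(model, distances) {
  n <- length(model@positions)
  d <- if (length(distances) == n) distances
       else if (length(distances) >= max(model@positions))
         distances[model@positions]
       else stop("'distances' must cover every model residue")
  if (any(is.na(d)))
    stop("missing predicted distance for residue(s) present in the model")
  new("AnnotatedModel", base = model, bfactor = as.numeric(d))
}

#' Write a B-factor-annotated copy of a model's PDB file
#'
#' Copies the model's source PDB file byte-for-byte, except that columns
#' 61-66 (the B-factor field) of each ATOM record carry the residue's
#' predicted distance from the native structure, formatted `%6.2f`. All
#' atoms of a residue receive the residue's value. Models without a source
#' file (built in memory) are written as CA-only records via
#' [writeModelPdb()].
#'
#' @param annotated an [AnnotatedModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnnotatedPdb <- function(annotated, path) {
  model <- annotated@base
  bmap <- stats::setNames(annotated@bfactor, model@positions)
  if (is.na(model@sourcePath) || !file.exists(model@sourcePath))
    return(writeModelPdb(model, path, bfactor = annotated@bfactor))
  lines <- readLines(model@sourcePath, warn = FALSE)
  isAtom <- grepl("^ATOM", lines)
  for (i in which(isAtom)) {
    ln <- lines[i]
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (is.na(resno) || !as.character(resno) %in% names(bmap)) next
    if (nchar(ln) < 66) ln <- formatC(ln, width = -66)
    substr(ln, 61, 66) <- sprintf("%6.2f", bmap[[as.character(resno)]])
    lines[i] <- ln
  }
  writeLinesAtomic(lines, path)
}
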