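# Fixtures are generated in code: toy targets, PDB snippets, natives and
# decoy pools. Everything is deterministic under explicit seeds.

polyTarget <- function(L, id = "t1") {
  new("TargetSequence", id = id, residues = rep("A", L))
}

writeFasta <- function(seq, id = "t1", path = tempfile(fileext = ".fasta")) {
  writeLines(c(paste0(">", id), seq), path)
  path
}

# Minimal hand-built PDB text for a CA-only model.
caPdbLines <- function(positions, coords, resn = "GLY", chain = "A",
                       alt = " ", icode = " ", bfac = 0) {
  resn <- rep_len(resn, length(positions))
  alt <- rep_len(alt, length(positions))
  icode <- rep_len(icode, length(positions))
  bfac <- rep_len(bfac, length(positions))
  sprintf("ATOM  %5d  CA %s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          seq_along(positions), alt, resn, chain, positions, icode,
          coords[, 1], coords[, 2], coords[, 3], 1.00, bfac)
}

writeCaPdb <- function(positions, coords, path = tempfile(fileext = ".pdb"),
                       ...) {
  writeLines(c(caPdbLines(positions, coords, ...), "TER", "END"), path)
  path
}

# Straight-line CA trace (exactly 3.8 A apart along x).
lineCoords <- function(n) cbind(3.8 * (seq_len(n) - 1), 0, 0)

# Apply a rigid motion (rotation about z by `deg`, then translation).
rigidMove <- function(xyz, deg = 0, shift = c(0, 0, 0), axis = "z") {
  th <- deg * pi / 180
  R <- switch(axis,
    z = matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3),
    x = matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3))
  sweep(xyz %*% t(R), 2, shift, `+`)
}

memModel <- function(positions, coords, id = "m") {
  new("ModelStructure", modelId = id, positions = as.integer(positions),
      coords = coords, sourcePath = NA_character_)
}

# A noise-ladder decoy pool around a native, with known true TM to native.
noiseLadderPool <- function(L = 30, nDecoys = 20, seedBase = 1,
                            maxNoise = 5) {
  native <- makeNative(L, seed = seedBase)
  specs <- lapply(seq_len(nDecoys), function(k)
    decoySpec(globalNoise = maxNoise * k / nDecoys,
              seed = seedBase * 1000L + k))
  decoys <- makeDecoys(native, specs)
  list(native = native, decoys = decoys, target = polyTarget(L))
}
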