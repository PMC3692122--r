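# Internal helpers shared across modules.

# Run `expr` under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Random proper rotation matrix (uniform over SO(3), via QR of a Gaussian).
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Content signature of a model, used for de-duplication of pool members.
modelSignature <- function(model) {
  paste(c(model@positions, sprintf("%.3f", model@coords)), collapse = ",")
}

# Construct a ModelStructure from positions + coordinate matrix.
newModel <- function(id, positions, coords, sourcePath = NA_character_) {
  new("ModelStructure", modelId = id, positions = as.integer(positions),
      coords = coords, sourcePath = sourcePath)
}

# Atomic write: emit lines to a temp file in the destination directory,
# then rename, so readers never see a half-written file.
writeLinesAtomic <- function(lines, path, sep = "\n") {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".part")
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeLines(lines, con, sep = sep)
    close(con); con <- NULL
    ok <- file.rename(tmp, path)
  }, finally = {
    if (!is.null(con)) try(close(con), silent = TRUE)
    if (!ok && file.exists(tmp)) unlink(tmp)
  })
  if (!ok) stop("failed to write ", path)
  invisible(path)
}
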