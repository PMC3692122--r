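# A scored result with controllable per-residue values, built directly.
fakeResult <- function(L, models, drList, scores = NULL) {
  tgt <- polyTarget(L, id = "T0001")
  if (is.null(scores)) scores <- seq(0.9, by = -0.1,
                                     length.out = length(models))
  dr <- do.call(cbind, drList)
  colnames(dr) <- models
  sr <- dr
  present <- !is.na(dr)
  sr[present] <- residueSScore(pmin(dr[present], 3.9))
  gs <- data.frame(model = models, globalScore = scores,
                   meanTM = scores, meanQ = scores,
                   pValue = NA_real_, isReference = FALSE,
                   stringsAsFactors = FALSE)
  new("PoolQAResult", target = tgt, globalScores = gs, sr = sr, dr = dr,
      weight = 0.5)
}

test_that("QMODE2 records carry L per-residue errors with X gap markers", {
  res <- fakeResult(7, c("m1", "m2"),
                    list(rep(0, 7), c(1.2, 3.9, 15, 0.05, NA, 2.25, 0)))
  p <- tempfile(fileext = ".txt")
  writeQAFile(res, mode = 2, path = p)
  lines <- readLines(p)
  expect_equal(lines[1], "PFRMAT QA")
  expect_true("QMODE 2" %in% lines)
  expect_equal(lines[length(lines)], "END")
  m1 <- grep("^m1 ", lines, value = TRUE)
  expect_equal(m1, paste("m1 0.900", paste(rep("0.0", 7), collapse = " ")))
  m2 <- grep("^m2 ", lines, value = TRUE)
  fields <- strsplit(m2, " ")[[1]]
  expect_equal(fields[7], "X")          # missing residue 5 -> 5th error field
  expect_equal(fields[3:9], c("1.2", "3.9", "15.0", "0.1", "X", "2.2", "0.0"))
})

test_that("QMODE2 write-parse round trip is exact at printed precision", {
  set.seed(51)
  L <- 45   # exercises wrapping at 20 values per line
  drs <- lapply(1:3, function(i) {
    d <- round(runif(L, 0, 15), 1)
    if (i == 2) d[c(3, 44)] <- NA
    d
  })
  res <- fakeResult(L, paste0("mod", 1:3), drs,
                    scores = c(0.812, 0.5, 0.123))
  p <- tempfile(fileext = ".txt")
  writeQAFile(res, mode = 2, path = p)
  parsed <- parseQAFile(p, L = L)
  expect_equal(parsed$mode, 2)
  expect_equal(parsed$target, "T0001")
  expect_equal(parsed$records$model, paste0("mod", 1:3))
  expect_equal(parsed$records$globalScore, c(0.812, 0.5, 0.123))
  for (i in 1:3)
    expect_equal(parsed$records$residueErrors[[i]], drs[[i]])

  # wrapped: each record line holds at most 20 values
  body <- readLines(p)
  expect_true(any(grepl("^[0-9]", body)))   # continuation lines exist
})

test_that("QMODE1 emits global scores only and parses back", {
  res <- fakeResult(5, c("a", "b"), list(rep(1, 5), rep(2, 5)),
                    scores = c(0.777, 0.334))
  p <- tempfile(fileext = ".txt")
  writeQAFile(res, mode = 1, path = p)
  parsed <- parseQAFile(p)
  expect_equal(parsed$mode, 1)
  expect_equal(parsed$records$globalScore, c(0.777, 0.334))
  expect_null(parsed$records$residueErrors)
})

test_that("parser tolerates CRLF and preserves unknown headers", {
  res <- fakeResult(6, "m1", list(rep(1.5, 6)), scores = 0.5)
  p <- tempfile(fileext = ".txt")
  writeQAFile(res, mode = 2, path = p, author = "1234-5678-9000")
  crlf <- tempfile(fileext = ".txt")
  writeLines(paste0(readLines(p), "\r"), crlf, sep = "\n")
  a <- parseQAFile(p, L = 6)
  b <- parseQAFile(crlf, L = 6)
  expect_equal(a$records, b$records)
  expect_equal(a$metadata[["AUTHOR"]], "1234-5678-9000")
})

test_that("malformed files are rejected with the offending model named", {
  res <- fakeResult(30, c("good", "bad"),
                    list(rep(1, 30), rep(2, 30)))
  p <- tempfile(fileext = ".txt")
  writeQAFile(res, mode = 2, path = p)
  lines <- readLines(p)
  # truncate the residue list of model 'bad' (its last line of values)
  lastBad <- max(grep("^(bad |2\\.0)", lines))
  lines[lastBad] <- sub(" 2\\.0$", "", lines[lastBad])
  trunc <- tempfile(fileext = ".txt")
  writeLines(lines, trunc)
  expect_error(parseQAFile(trunc, L = 30), "bad")

  lines2 <- readLines(p)
  lines2[grep("^good", lines2)[1]] <-
    sub("1\\.0", "oops", lines2[grep("^good", lines2)[1]])
  bad2 <- tempfile(fileext = ".txt")
  writeLines(lines2, bad2)
  expect_error(parseQAFile(bad2, L = 30), "good")

  notqa <- tempfile(fileext = ".txt")
  writeLines("hello", notqa)
  expect_error(parseQAFile(notqa), "PFRMAT")
})

test_that("round-trip identity holds for random scored pools", {
  set.seed(52)
  for (rep in 1:5) {
    L <- sample(10:60, 1)
    k <- sample(1:4, 1)
    drs <- lapply(seq_len(k), function(i) {
      d <- round(runif(L, 0, 15), 1)
      miss <- sample(L, sample(0:3, 1))
      d[miss] <- NA
      d
    })
    res <- fakeResult(L, sprintf("r%02d", seq_len(k)), drs,
                      scores = round(runif(k), 3))
    p <- tempfile(fileext = ".txt")
    writeQAFile(res, mode = 2, path = p)
    parsed <- parseQAFile(p, L = L)
    expect_equal(parsed$records$globalScore,
                 globalScores(res)$globalScore)
    ord <- match(parsed$records$model, colnames(res@dr))
    for (i in seq_len(k))
      expect_equal(parsed$records$residueErrors[[i]],
                   round(unname(res@dr[, ord[i]]), 1))
  }
})
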