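test_that("FASTA targets parse, case-fold, and reject bad alphabets", {
  tgt <- readTarget(writeFasta("MKV"))
  expect_equal(targetLength(tgt), 3)
  expect_equal(tgt@residues, c("M", "K", "V"))

  low <- readTarget(writeFasta("mkv"))
  expect_equal(low@residues, c("M", "K", "V"))

  expect_error(readTarget(writeFasta("MK9V")), "non-amino-acid")
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readTarget(empty))
})

test_that("PDB models parse with residue numbers as target positions", {
  tgt <- polyTarget(10)
  xyz <- lineCoords(3)
  p <- writeCaPdb(1:3, xyz)
  m <- readModel(p, tgt)
  expect_equal(length(positions(m)), 3)
  expect_equal(positions(m), 1:3)
  expect_equal(coords(m), xyz, ignore_attr = TRUE, tolerance = 1e-9)

  # residue numbered beyond the target length is a range violation
  p2 <- writeCaPdb(c(1, 2, 99), lineCoords(3))
  expect_error(readModel(p2, tgt), "outside the target range")

  # fewer than 3 CA atoms
  p3 <- tempfile(fileext = ".pdb")
  writeLines(c(caPdbLines(1:2, lineCoords(2)), "END"), p3)
  expect_error(readModel(p3, tgt), "fewer than 3 CA")

  # no ATOM records at all
  p4 <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), p4)
  expect_error(readModel(p4, tgt), "no ATOM records")
})

test_that("altLoc duplicates keep the first; bare collisions are rejected", {
  tgt <- polyTarget(10)
  xyz <- lineCoords(4)
  lines <- caPdbLines(c(1, 2, 2, 3), xyz, alt = c(" ", "A", "B", " "))
  p <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), p)
  m <- readModel(p, tgt)
  expect_equal(positions(m), 1:3)
  # first altLoc ("A", the second file row) retained for residue 2;
  # cross-checked against bio3d's parse of the same file
  expect_equal(coords(m)[2, ], xyz[2, ], ignore_attr = TRUE)
  ref <- bio3d::read.pdb(p, verbose = FALSE)$atom
  refCa <- ref[ref$elety == "CA" & !duplicated(ref$resno), ]
  expect_equal(coords(m), cbind(refCa$x, refCa$y, refCa$z),
               ignore_attr = TRUE)

  bad <- tempfile(fileext = ".pdb")
  writeLines(c(caPdbLines(c(1, 2, 2, 3), xyz), "END"), bad)
  expect_error(readModel(bad, tgt), "collision")
})

test_that("multi-MODEL and multi-chain files use the first, with warning", {
  tgt <- polyTarget(10)
  a <- caPdbLines(1:3, lineCoords(3))
  b <- caPdbLines(1:3, lineCoords(3) + 50)
  p <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", a, "ENDMDL", "MODEL     2", b, "ENDMDL",
               "END"), p)
  expect_warning(m <- readModel(p, tgt), "MODEL")
  expect_equal(coords(m)[1, ], c(0, 0, 0), ignore_attr = TRUE)

  p2 <- tempfile(fileext = ".pdb")
  writeLines(c(caPdbLines(1:3, lineCoords(3), chain = "A"),
               caPdbLines(4:6, lineCoords(3) + 50, chain = "B"), "END"), p2)
  expect_warning(m2 <- readModel(p2, tgt), "chains")
  expect_equal(positions(m2), 1:3)

  ins <- tempfile(fileext = ".pdb")
  writeLines(c(caPdbLines(1:3, lineCoords(3), icode = c(" ", "A", " ")),
               "END"), ins)
  expect_error(readModel(ins, tgt), "insertion")
})

test_that("read-write-read round trip preserves geometry to PDB precision", {
  tgt <- polyTarget(20)
  set.seed(42)
  m <- memModel(sort(sample(1:20, 8)), matrix(rnorm(24, sd = 8), 8, 3),
                id = "rt")
  p <- tempfile(fileext = ".pdb")
  writeModelPdb(m, p, target = tgt)
  back <- readModel(p, tgt)
  expect_equal(positions(back), positions(m))
  expect_equal(coords(back), coords(m), tolerance = 1e-3,
               ignore_attr = TRUE)
  # parsing ignores non-ATOM records and trailing whitespace
  lines <- readLines(p)
  p2 <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", paste0(lines, "   "), "REMARK x"), p2)
  back2 <- readModel(p2, tgt)
  expect_equal(coords(back2), coords(back), ignore_attr = TRUE)
})

test_that("B-factor annotation rewrites only columns 61-66 of ATOM records", {
  tgt <- polyTarget(5)
  xyz <- lineCoords(4)
  p <- writeCaPdb(1:4, xyz)
  m <- readModel(p, tgt)
  ann <- annotateModel(m, c(0, 3.9, 15, 1.25))
  out <- tempfile(fileext = ".pdb")
  writeAnnotatedPdb(ann, out)
  orig <- readLines(p)
  new <- readLines(out)
  expect_equal(length(orig), length(new))
  atom <- grepl("^ATOM", new)
  expect_equal(substr(new[atom], 61, 66),
               c("  0.00", "  3.90", " 15.00", "  1.25"))
  # byte-identical outside the B-factor field
  strip <- function(x) paste0(substr(x, 1, 60), substr(x, 67, nchar(x)))
  expect_identical(strip(new), strip(orig))
  expect_identical(new[!atom], orig[!atom])
  # round trip of the annotated file returns identical coordinates
  back <- readModel(out, tgt)
  expect_equal(coords(back), coords(m), ignore_attr = TRUE)
})

test_that("annotation rejects distances outside [0, 15]", {
  m <- memModel(1:3, lineCoords(3))
  expect_error(annotateModel(m, c(0, 1, 16)), "\\[0, 15\\]")
  expect_error(annotateModel(m, c(0, 1, -0.1)), "\\[0, 15\\]")
  expect_error(annotateModel(m, c(0, NA, 1)), "missing")
})
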