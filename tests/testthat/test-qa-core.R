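test_that("S-score follows the thresholded Levitt-Gerstein form", {
  expect_equal(residueSScore(0), 1.0)
  expect_equal(residueSScore(3.9), 0.5)   # S(d0) = 1/2; cutoff is strict
  expect_equal(residueSScore(5.0), 0.0)   # hard zero beyond 3.9 A
  expect_equal(residueSScore(2), 1 / (1 + (2 / 3.9)^2))
  expect_error(residueSScore(-1), "non-negative")

  d <- seq(0, 3.9, length.out = 50)
  expect_true(all(diff(residueSScore(seq(0, 10, by = 0.1))) <= 0))
  expect_true(all(residueSScore(seq(0, 20, by = 0.25)) >= 0))
})

test_that("predicted distance inverts the S-score and caps at 15 A", {
  expect_equal(predictedDistance(1), 0)
  expect_equal(predictedDistance(0.5), 3.9)
  expect_equal(predictedDistance(0), 15)
  d <- seq(0, 3.9, by = 0.05)
  expect_equal(predictedDistance(residueSScore(d)), d, tolerance = 1e-12)
  # very low mean S-scores saturate at the cap
  expect_equal(predictedDistance(0.001), 15)
  expect_true(all(diff(predictedDistance(seq(0, 1, by = 0.01))) <= 0))
  expect_error(predictedDistance(1.2), "\\[0, 1\\]")
})

test_that("pool construction enforces quasi-single-model preconditions", {
  tgt <- polyTarget(30)
  native <- makeNative(30, seed = 31)
  decoys <- makeDecoys(native, lapply(1:5, function(k)
    decoySpec(0.5 * k, seed = 700 + k)))

  full <- buildPool(decoys, list(), tgt)
  expect_equal(poolSize(full), 5)

  expect_error(buildPool(decoys[1], list(), tgt), "quasi-single")

  quasi <- buildPool(decoys[1], decoys[2:5], tgt)
  expect_equal(poolSize(quasi), 5)
  expect_length(quasi@userModels, 1)

  # reference models duplicating a user model are dropped; user duplicates
  # are kept and each gets scored
  dupRef <- buildPool(decoys[1:2], decoys[c(2, 3)], tgt)
  expect_equal(poolSize(dupRef), 3)
  dupUser <- buildPool(decoys[c(1, 1, 2)], list(), tgt)
  expect_equal(poolSize(dupUser), 3)
  expect_equal(anyDuplicated(vapply(c(dupUser@userModels),
                                    modelId, character(1))), 0)
})

test_that("mean residue score averages over N-1 with zero for absent partners", {
  tgt <- polyTarget(6)
  base <- lineCoords(6)
  a <- memModel(1:6, base, id = "a")
  b <- memModel(1:6, base, id = "b")             # identical to a
  cc <- memModel(c(1, 2, 3, 5, 6), base[-4, ] + 100, id = "c")  # unrelated, lacks pos 4
  pool <- buildPool(list(a, b, cc), list(), tgt)
  comp <- poolComparisons(pool)
  sr <- meanResidueScore(1, pool, comp)
  # against b every residue matches exactly (S=1); against c nothing is
  # close (straight line displaced 100 A superposes at best partially)
  expect_equal(length(sr), 6)
  expect_true(all(sr[!is.na(sr)] <= 1))
  # position 4: partner c lacks it entirely, so only b contributes
  expect_lte(sr[4], 1)

  # arithmetic: N=3, one partner S=1, other S=0 at a position -> 0.5
  # (identical line pair superposes c exactly onto a subset: force the
  # simple case with a far-apart partner whose superposition cannot bring
  # any residue within 3.9 A of matching both)
  scrambled <- memModel(1:6, matrix(c(0,0,0, 10,0,0, 0,10,0, 10,10,0,
                                      5,5,8, -5,4,2), 6, 3, byrow = TRUE),
                        id = "s")
  pool2 <- buildPool(list(a, b, scrambled), list(), tgt)
  comp2 <- poolComparisons(pool2)
  sr2 <- meanResidueScore(1, pool2, comp2)
  d_vs_s <- comp2$pairs[["1:3"]]$distances
  manual <- (1 + residueSScore(d_vs_s)) / 2
  expect_equal(sr2, manual, tolerance = 1e-12)
})

test_that("identical pools score 1.0 and outliers rank last", {
  tgt <- polyTarget(30)
  native <- makeNative(30, seed = 33)
  same <- lapply(1:3, function(k) {
    m <- native; m@modelId <- paste0("copy", k); m
  })
  res <- scorePool(buildPool(same, list(), tgt))
  expect_equal(globalScores(res)$globalScore, rep(1, 3), tolerance = 1e-9)
  expect_true(all(res@dr == 0, na.rm = TRUE))

  cluster <- makeDecoys(native, lapply(1:9, function(k)
    decoySpec(0.6, seed = 800 + k)))
  outlier <- makeDecoys(makeNative(30, seed = 99),
                        decoySpec(0.5, seed = 900))[[1]]
  outlier@modelId <- "outlier"
  res2 <- scorePool(buildPool(c(cluster, outlier), list(), tgt))
  gs <- globalScores(res2)
  expect_equal(gs$model[nrow(gs)], "outlier")
  expect_lt(gs$globalScore[nrow(gs)], min(gs$globalScore[-nrow(gs)]))
})

test_that("pool scoring matches the naive loop reimplementation to 1e-9", {
  tgt <- polyTarget(30)
  native <- makeNative(30, seed = 35)
  for (rep in 1:3) {
    nMod <- sample(4:6, 1)
    specs <- lapply(seq_len(nMod), function(k)
      decoySpec(runif(1, 0.3, 3), seed = 35000 + 100 * rep + k))
    models <- makeDecoys(native, specs)
    # drop a few residues from one model to exercise the 'X' path
    drop <- sample(5:25, 3)
    keep <- setdiff(seq_len(30), drop)
    models[[2]] <- memModel(keep, coords(models[[2]])[keep, ],
                            id = modelId(models[[2]]))
    pool <- buildPool(models, list(), tgt)
    res <- scorePool(pool)
    oracle <- naivePoolScores(models, tgt)
    ids <- vapply(models, modelId, character(1))
    gs <- globalScores(res)
    expect_equal(gs$globalScore[match(ids, gs$model)], oracle$global,
                 tolerance = 1e-9)
    expect_equal(unname(res@sr[, ids]), oracle$sr, tolerance = 1e-9)
    expect_equal(unname(res@dr[, ids]), oracle$dr, tolerance = 1e-9)
  }
})

test_that("every user model is reported once and dr covers the target", {
  tgt <- polyTarget(25)
  native <- makeNative(25, seed = 36)
  models <- makeDecoys(native, lapply(1:4, function(k)
    decoySpec(1, seed = 360 + k)))
  keep <- setdiff(1:25, c(3, 17))
  models[[1]] <- memModel(keep, coords(models[[1]])[keep, ], id = "gappy")
  res <- scorePool(buildPool(models, list(), tgt))
  gs <- globalScores(res)
  expect_setequal(gs$model, vapply(models, modelId, character(1)))
  expect_equal(nrow(gs), 4)
  # NA markers exactly at the missing positions; coverage = L
  expect_equal(which(is.na(res@dr[, "gappy"])), c(3, 17))
  expect_equal(sum(!is.na(res@dr[, "gappy"])) + 2, 25)
  expect_true(all(res@dr[!is.na(res@dr)] <= 15))
})

test_that("adding an exact duplicate does not decrease a model's score", {
  tgt <- polyTarget(30)
  native <- makeNative(30, seed = 37)
  models <- makeDecoys(native, lapply(1:5, function(k)
    decoySpec(0.8 * k, seed = 370 + k)))
  base <- scorePool(buildPool(models, list(), tgt))
  g0 <- globalScores(base)
  dup <- models[[3]]
  dup@modelId <- "dup"
  withDup <- scorePool(buildPool(c(models, dup), list(), tgt))
  g1 <- globalScores(withDup)
  expect_gte(g1$globalScore[g1$model == modelId(models[[3]])],
             g0$globalScore[g0$model == modelId(models[[3]])])
  expect_equal(g1$globalScore[g1$model == "dup"],
               g1$globalScore[g1$model == modelId(models[[3]])],
               tolerance = 1e-9)
})

test_that("reference models are scored but reported separately", {
  tgt <- polyTarget(30)
  native <- makeNative(30, seed = 38)
  mods <- makeDecoys(native, lapply(1:6, function(k)
    decoySpec(1, seed = 380 + k)))
  res <- scorePool(buildPool(mods[1], mods[2:6], tgt))
  expect_equal(nrow(globalScores(res)), 1)
  both <- globalScores(res, referenceModels = TRUE)
  expect_equal(nrow(both), 6)
  expect_equal(sum(both$isReference), 5)
  expect_equal(ncol(res@dr), 1)   # per-residue output for user models only
})
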