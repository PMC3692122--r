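# Independent oracles, deliberately naive: straight loops and generic
# numerical optimization, sharing no code path with the implementation.

# Q-score by an explicit double loop over residue pairs.
naiveQ <- function(modelA, modelB, sigmaExponent = 0.15) {
  common <- intersect(positions(modelA), positions(modelB))
  n <- length(common)
  xa <- coords(modelA)[match(common, positions(modelA)), , drop = FALSE]
  xb <- coords(modelB)[match(common, positions(modelB)), , drop = FALSE]
  total <- 0
  count <- 0
  for (j in 1:(n - 1)) {
    for (k in 1:n) {
      if (k < j + 2) next
      da <- sqrt(sum((xa[j, ] - xa[k, ])^2))
      db <- sqrt(sum((xb[j, ] - xb[k, ])^2))
      sigma <- abs(j - k)^sigmaExponent
      total <- total + exp(-(da - db)^2 / (2 * sigma^2))
      count <- count + 1
    }
  }
  stopifnot(count == (n - 1) * (n - 2) / 2)
  total / count
}

# Rotation from a unit quaternion.
quatToRot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Minimum RMSD by quaternion-grid search plus Nelder-Mead polish; the
# optimal translation for any rotation matches the centroids, so only the
# rotation is searched.
bruteForceRmsd <- function(A, B, nGrid = 20000, seed = 99) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rmsdOf <- function(q) {
    R <- quatToRot(q)
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  set.seed(seed)
  qs <- matrix(rnorm(4 * nGrid), ncol = 4)
  vals <- apply(qs, 1, rmsdOf)
  best <- qs[order(vals)[1:5], , drop = FALSE]
  opt <- min(apply(best, 1, function(q)
    stats::optim(q, rmsdOf, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))$value))
  opt
}

# TM-score by direct numerical maximization over rigid motions
# (quaternion + translation), multi-started from least-squares fits of
# sliding windows and from random orientations.
oracleTM <- function(modelA, modelB, L, seed = 7) {
  common <- intersect(positions(modelA), positions(modelB))
  xa <- coords(modelA)[match(common, positions(modelA)), , drop = FALSE]
  xb <- coords(modelB)[match(common, positions(modelB)), , drop = FALSE]
  n <- nrow(xa)
  d0 <- tmD0(L)
  negTM <- function(par) {
    R <- quatToRot(par[1:4])
    fitted <- sweep(xb %*% t(R), 2, par[5:7], `+`)
    d2 <- rowSums((xa - fitted)^2)
    -sum(1 / (1 + d2 / d0^2)) / L
  }
  rotToQuat <- function(R) {
    w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
    if (w > 1e-6) {
      c(w, (R[3, 2] - R[2, 3]) / (4 * w),
        (R[1, 3] - R[3, 1]) / (4 * w),
        (R[2, 1] - R[1, 2]) / (4 * w))
    } else c(1, 0, 0, 0)
  }
  starts <- list()
  for (len in unique(pmin(n, c(5, 8, 12, n)))) {
    for (s0 in seq(1, n - len + 1, by = max(1, len %/% 2))) {
      idx <- s0:(s0 + len - 1)
      fit <- kabsch(xa[idx, , drop = FALSE], xb[idx, , drop = FALSE])
      starts[[length(starts) + 1]] <-
        c(rotToQuat(fit$rotation), fit$translation)
    }
  }
  set.seed(seed)
  for (i in 1:10) {
    q <- rnorm(4)
    starts[[length(starts) + 1]] <-
      c(q / sqrt(sum(q^2)), colMeans(xa) - colMeans(xb))
  }
  vals <- vapply(starts, function(p)
    stats::optim(p, negTM, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-10))$value,
    numeric(1))
  -min(vals)
}

# Naive straight-line pool scoring: explicit loops, no caching beyond
# computing each unordered pair once (as the engine's contract requires),
# calling the pairwise operations directly.
naivePoolScores <- function(models, target, weight = 0.5) {
  N <- length(models)
  L <- targetLength(target)
  tm <- matrix(1, N, N)
  q <- matrix(1, N, N)
  dists <- vector("list", N)
  for (i in 1:N) dists[[i]] <- vector("list", N)
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      sup <- tmSuperpose(models[[i]], models[[j]], normLength = L)
      tm[i, j] <- tm[j, i] <- tmScore(sup)
      q[i, j] <- q[j, i] <- qCompare(models[[i]], models[[j]])
      rec <- list(pos = positions(sup), d = sup@distances)
      dists[[i]][[j]] <- rec
      dists[[j]][[i]] <- rec
    }
  }
  global <- numeric(N)
  sr <- matrix(NA_real_, L, N)
  for (i in 1:N) {
    sumTM <- 0; sumQ <- 0
    ssum <- numeric(L)
    for (j in 1:N) {
      if (j == i) next
      sumTM <- sumTM + tm[i, j]
      sumQ <- sumQ + q[i, j]
      rec <- dists[[i]][[j]]
      for (k in seq_along(rec$pos)) {
        d <- rec$d[k]
        s <- if (d > 3.9) 0 else 1 / (1 + (d / 3.9)^2)
        ssum[rec$pos[k]] <- ssum[rec$pos[k]] + s
      }
    }
    global[i] <- weight * sumTM / (N - 1) + (1 - weight) * sumQ / (N - 1)
    for (p in 1:L) {
      if (p %in% positions(models[[i]])) sr[p, i] <- ssum[p] / (N - 1)
    }
  }
  dr <- matrix(NA_real_, L, N)
  for (i in 1:N) for (p in 1:L) {
    s <- sr[p, i]
    if (!is.na(s))
      dr[p, i] <- if (s > 0) min(3.9 * sqrt(1 / s - 1), 15) else 15
  }
  list(global = global, sr = sr, dr = dr)
}

# Empirical upper-tail proportion of a score sample.
empiricalTail <- function(sample, s) mean(sample >= s)
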