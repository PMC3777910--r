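test_that("pairwise dissimilarity matches its definition on hand cases", {
  # identical profiles -> 0; perfectly anticorrelated -> 2
  X <- cbind(R1 = c(1, 2, 3), R2 = c(1, 2, 3), R3 = c(3, 2, 1))
  rownames(X) <- paste0("g", 1:3)
  ds <- datasetFromSlices(list(t1 = X, t2 = X))
  D <- pairwiseDissimilarity(ds, "t1")
  expect_equal(D["R1", "R2"], 0)
  expect_equal(D["R1", "R3"], 2)
  expect_equal(diag(D), setNames(rep(0, 3), colnames(X)))

  # zero-variance region is missing; the defined pair matches the formula
  Y <- cbind(R1 = c(1, 2, 4), R2 = c(1, 3, 5), R3 = c(2, 2, 2))
  rownames(Y) <- paste0("g", 1:3)
  ds2 <- datasetFromSlices(list(t1 = Y, t2 = Y))
  D2 <- pairwiseDissimilarity(ds2, "t1")
  x <- Y[, 1]; y <- Y[, 2]
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(D2["R1", "R2"], 1 - rHand, tolerance = 1e-12)
  expect_true(is.na(D2["R1", "R3"]))
  expect_true(is.na(D2["R2", "R3"]))
})

test_that("pairwise values equal the independent covariance-formula oracle", {
  for (seed in 1:3) {
    ds <- randomDataset(25, 7, 4, seed = seed, missFrac = 0.15)
    for (tp in timeLabels(ds)) {
      D <- pairwiseDissimilarity(ds, tp)
      O <- oracleDissimMatrix(exprValues(ds)[, , tp])
      expect_equal(D, O, tolerance = 1e-12)
    }
  }
})

test_that("dissimilarity is invariant to common affine rescaling and labels", {
  ds <- randomDataset(20, 6, 2, seed = 9)
  D <- pairwiseDissimilarity(ds, "t1")
  v <- exprValues(ds)
  v[, , 1] <- 3.7 * v[, , 1] + 1.2          # positive-slope affine map
  expect_equal(pairwiseDissimilarity(ExpressionDataset(v), "t1"), D,
               tolerance = 1e-12)
  # permuting region labels permutes, and leaves the curve unchanged
  perm <- rev(regionIds(ds))
  vp <- exprValues(ds)[, perm, , drop = FALSE]
  cu <- hourglassCurve(ds)
  cup <- hourglassCurve(ExpressionDataset(vp))
  expect_equal(cup$mean, cu$mean, tolerance = 1e-12)
  expect_equal(cup$q1, cu$q1, tolerance = 1e-12)
})

test_that("hourglass curve summarizes pair values correctly", {
  # all regions identical -> all-zero curve
  X <- matrix(rep(runif(5), 3), 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("R", 1:3)))
  ds0 <- datasetFromSlices(list(t1 = X, t2 = X))
  cu0 <- hourglassCurve(ds0)
  expect_equal(cu0$mean, c(0, 0))
  expect_equal(cu0$q3 - cu0$q1, c(0, 0))

  # 3-region toy: mean equals the average of the three pair values
  ds <- randomDataset(10, 3, 2, seed = 4)
  cu <- hourglassCurve(ds)
  for (k in 1:2) {
    D <- pairwiseDissimilarity(ds, timeLabels(ds)[k])
    pv <- D[upper.tri(D)]
    expect_equal(cu$mean[k], mean(pv), tolerance = 1e-12)
    expect_identical(cu$nPairs[k], 3L)
    expect_true(cu$mean[k] >= min(pv) && cu$mean[k] <= max(pv))
  }
})

test_that("quadratic fit reproduces exact and least-squares solutions", {
  mkCurve <- function(y) data.frame(timepoint = paste0("t", seq_along(y)),
                                    mean = y)
  co <- fitQuadratic(mkCurve((0:4)^2))
  expect_equal(unname(co), c(1, 0, 0), tolerance = 1e-10)
  co2 <- fitQuadratic(mkCurve(rep(0.7, 5)))
  expect_equal(unname(co2), c(0, 0, 0.7), tolerance = 1e-10)
  # arbitrary points against the explicit normal equations
  set.seed(11)
  y <- runif(5)
  r <- 0:4
  A <- cbind(r^2, r, 1)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(unname(fitQuadratic(mkCurve(y))), as.numeric(beta),
               tolerance = 1e-8)
  expect_error(fitQuadratic(mkCurve(c(1, 2))), "3")
})

test_that("age ANOVA matches the textbook decomposition", {
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(21)
  g1 <- runif(8); g2 <- runif(9) + 0.3
  mkSet <- function(groups) {
    mats <- lapply(groups, function(v) {
      n <- (1 + sqrt(1 + 8 * length(v))) / 2
      D <- matrix(0, n, n, dimnames = list(paste0("R", 1:n), paste0("R", 1:n)))
      D[upper.tri(D)] <- v
      D[lower.tri(D)] <- t(D)[lower.tri(D)]
      D
    })
    names(mats) <- paste0("t", seq_along(mats))
    new("DissimilaritySet", matrices = mats)
  }
  p <- ageAnova(mkSet(list(g1[1:6], g2[1:6])))
  tt <- t.test(g1[1:6], g2[1:6], var.equal = TRUE)
  expect_equal(p, tt$p.value, tolerance = 1e-10)

  # three groups against hand-computed sums of squares
  groups <- list(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6), c(0.2, 0.25, 0.45))
  allv <- unlist(groups)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - mean(allv))^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  Fh <- (ssb / 2) / (ssw / (length(allv) - 3))
  ph <- pf(Fh, 2, length(allv) - 3, lower.tail = FALSE)
  expect_equal(ageAnova(mkSet(groups)), ph, tolerance = 1e-10)
})

test_that("gene-subset robustness is seeded and degenerates correctly", {
  ds <- randomDataset(12, 5, 3, seed = 2)
  full <- hourglassCurve(ds)
  r1 <- subsetRobustness(ds, sizes = 12L, nSubsets = 3L, seed = 7)
  for (cu in r1[["12"]]) expect_equal(cu$mean, full$mean, tolerance = 1e-12)
  a <- subsetRobustness(ds, sizes = 6L, nSubsets = 4L, seed = 5)
  b <- subsetRobustness(ds, sizes = 6L, nSubsets = 4L, seed = 5)
  expect_identical(a, b)
  expect_error(subsetRobustness(ds, sizes = 13L, nSubsets = 2L), "size")
})

test_that("dropping the most variable genes removes the planted driver", {
  # one gene carries all inter-region variance; removing top-1 collapses
  # the curve to the noise floor
  set.seed(3)
  base <- matrix(rep(runif(30, 1, 2), 4), 30, 4)
  noise <- matrix(rnorm(120, sd = 0.01), 30, 4)
  X <- base + noise
  X[1, ] <- c(0, 2, 5, 9)
  dimnames(X) <- list(sprintf("g%02d", 1:30), paste0("R", 1:4))
  ds <- datasetFromSlices(list(t1 = X, t2 = X))
  cuFull <- hourglassCurve(ds)
  cuDrop <- dropTopVariable(ds, kList = 1L)[["1"]]
  expect_gt(cuFull$mean[1], 10 * cuDrop$mean[1])
  # k = 0 keeps the full curve
  expect_equal(dropTopVariable(ds, kList = 0L)[["0"]]$mean, cuFull$mean,
               tolerance = 1e-12)
  expect_error(dropTopVariable(ds, kList = 30L), "smaller")
})

test_that("leave-one-region-out equals recomputation on the reduced set", {
  ds <- randomDataset(15, 5, 3, seed = 13)
  loro <- leaveOneRegionOut(ds)
  for (r in regionIds(ds)) {
    reduced <- subsetDataset(ds, regions = setdiff(regionIds(ds), r))
    expect_equal(loro$curves[[r]]$mean, hourglassCurve(reduced)$mean,
                 tolerance = 1e-12)
  }
  # full-curve mean lies within the exclusion envelope (N = 5 regions)
  full <- hourglassCurve(ds)$mean
  mm <- vapply(loro$curves, function(cu) cu$mean, numeric(3))
  inEnv <- full >= apply(mm, 1, min) & full <= apply(mm, 1, max)
  if (!all(inEnv))
    message("exclusion envelope violated at ", sum(!inEnv), " timepoint(s)")
  # identical regions -> all exclusion curves are zero
  X <- matrix(rep(runif(8), 3), 8, 3,
              dimnames = list(paste0("g", 1:8), paste0("R", 1:3)))
  z <- leaveOneRegionOut(datasetFromSlices(list(t1 = X, t2 = X)))
  for (cu in z$curves) expect_equal(cu$mean, c(0, 0))
})

test_that("ontology-level curves aggregate leaves by unweighted means", {
  ont <- readOntology(writeTempTsv(c("child\tparent\torigin",
                                     "p1\troot\tmidbrain", "p2\troot\thindbrain",
                                     "A\tp1\t", "B\tp1\t", "C\tp2\t", "D\tp2\t")))
  set.seed(8)
  X <- matrix(runif(40, 0, 2), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), c("A", "B", "C", "D")))
  ds <- datasetFromSlices(list(t1 = X, t2 = 2 * X))
  lvl <- ontologyLevelCurves(ds, ont, nLevels = 2)
  # level 1 equals the plain curve on the leaves
  expect_equal(lvl[["1"]]$mean, hourglassCurve(ds)$mean, tolerance = 1e-12)
  # level 2: parents are hand-averaged leaves
  agg <- cbind(p1 = rowMeans(X[, c("A", "B")]), p2 = rowMeans(X[, c("C", "D")]))
  expect_equal(lvl[["2"]]$mean[1], oracleCurveMean(agg), tolerance = 1e-12)
  # two identical leaves merge into a parent equal to either leaf
  X2 <- X; X2[, "B"] <- X2[, "A"]
  ds2 <- datasetFromSlices(list(t1 = X2, t2 = X2))
  lvl2 <- ontologyLevelCurves(ds2, ont, nLevels = 2)
  expect_equal(lvl2[["2"]]$mean[1],
               oracleCurveMean(cbind(p1 = X2[, "A"],
                                     p2 = rowMeans(X2[, c("C", "D")]))),
               tolerance = 1e-12)
})
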