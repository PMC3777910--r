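test_that("region-specific index normalizes against the brain-wide mean", {
  # R3 far from two mutually identical regions: index above 1
  X <- cbind(R1 = c(1, 2, 3, 4), R2 = c(1, 2, 3, 4), R3 = c(4, 3, 2, 1))
  rownames(X) <- paste0("g", 1:4)
  ds <- datasetFromSlices(list(t1 = X, t2 = X))
  idx <- regionSpecificIndex(ds, "R3")
  expect_true(all(idx$index > 1))
  # permutation of the other regions' labels leaves the index unchanged
  Xp <- X[, c("R2", "R1", "R3")]
  expect_equal(regionSpecificIndex(datasetFromSlices(list(t1 = Xp, t2 = Xp)),
                                   "R3")$index,
               idx$index, tolerance = 1e-12)
  # averaged over all regions the index is 1 by construction
  ds2 <- randomDataset(20, 6, 2, seed = 3)
  idxAll <- vapply(regionIds(ds2), function(r)
    regionSpecificIndex(ds2, r)$index[1], numeric(1))
  expect_equal(mean(idxAll), 1, tolerance = 0.05)
})

test_that("NMDS attains near-zero stress on 2D-realizable distances", {
  # equilateral triangle
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(paste0("R", 1:3), paste0("R", 1:3))
  emb <- nmdsEmbed(D3, seed = 1)
  expect_lt(emb$stress, 1e-6)
  # random planar configuration, 8 points
  set.seed(12)
  P <- matrix(rnorm(16), 8, 2)
  D8 <- as.matrix(dist(P))
  dimnames(D8) <- list(paste0("R", 1:8), paste0("R", 1:8))
  emb8 <- nmdsEmbed(D8, seed = 4, nStarts = 10)
  expect_lt(emb8$stress, 1e-6)
  # duplicated region embeds at ~zero distance from its twin
  X <- cbind(R1 = c(1, 5, 2, 7), R2 = c(1, 5, 2, 7), R3 = c(9, 1, 4, 2),
             R4 = c(3, 3, 8, 1))
  rownames(X) <- paste0("g", 1:4)
  D <- oracleDissimMatrix(X)
  embT <- nmdsEmbed(D, seed = 2)
  dTwin <- sqrt(sum((embT$coords["R1", ] - embT$coords["R2", ])^2))
  span <- max(dist(embT$coords))
  expect_lt(dTwin, 0.01 * span)
  # seeded determinism and symmetry guard
  expect_identical(nmdsEmbed(D8, seed = 7), nmdsEmbed(D8, seed = 7))
  Dbad <- D8; Dbad[1, 2] <- Dbad[1, 2] + 1
  expect_error(nmdsEmbed(Dbad), "symmetric")
})

test_that("Procrustes alignment matches the closed-form optimum", {
  set.seed(2)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
  # rotated + scaled + shifted copy aligns with ~zero disparity
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 0.6 * X %*% R + matrix(c(2, -1), 6, 2, byrow = TRUE)
  rownames(Y) <- rownames(X)
  al <- procrustesAlign(X, Y)
  expect_lt(al$disparity, 1e-10)
  expect_equal(al$aligned, X, tolerance = 1e-8)
  # self-alignment is the identity
  al2 <- procrustesAlign(X, X)
  expect_lt(al2$disparity, 1e-12)
  expect_equal(al2$aligned, X, tolerance = 1e-10)
  # random configurations: disparity equals vegan's symmetric-free solution
  Z <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
  al3 <- procrustesAlign(X, Z)
  vp <- vegan::procrustes(X, Z, scale = TRUE, symmetric = FALSE)
  expect_equal(sweep(al3$aligned, 2, colMeans(al3$aligned)),
               sweep(vp$Yrot, 2, colMeans(vp$Yrot)),
               tolerance = 1e-8, ignore_attr = TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(al3$disparity, vp$ss / sum(Xc^2), tolerance = 1e-10)
  # disparity invariant to rigid motion + scaling of the input
  W <- 3 * Z %*% R + 5
  rownames(W) <- rownames(Z)
  expect_equal(procrustesAlign(X, W)$disparity, al3$disparity,
               tolerance = 1e-10)
})

test_that("within-region SD follows the sample definition", {
  X <- cbind(R1 = c(0, 2), R2 = c(1, 1))
  rownames(X) <- c("g1", "g2")
  ds <- datasetFromSlices(list(t1 = X))
  expect_equal(withinRegionSd(ds, "R1", "t1"), sqrt(2))
  expect_equal(withinRegionSd(ds, "R2", "t1"), 0)
  set.seed(6)
  Y <- matrix(runif(40), 20, 2, dimnames = list(sprintf("g%02d", 1:20),
                                                c("R1", "R2")))
  dsy <- datasetFromSlices(list(t1 = Y))
  x <- Y[, 1]
  expect_equal(withinRegionSd(dsy, "R1", "t1"),
               sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-12)
})

test_that("lineage correlation responds to planted block structure", {
  regs <- paste0("R", 1:8)
  origin <- rep(c("forebrain-telencephalon", "forebrain-diencephalon",
                  "midbrain", "hindbrain"), each = 2)
  ont <- readOntology(writeTempTsv(c("child\tparent\torigin",
                                     sprintf("%s\tbrain\t%s", regs, origin))))
  # dissimilarity exactly proportional to tree distance -> r = 1
  Dt <- outer(seq_along(regs), seq_along(regs), Vectorize(function(i, j)
    originTreeDistance(origin[i], origin[j])))
  dimnames(Dt) <- list(regs, regs)
  dset <- new("DissimilaritySet", matrices = list(t1 = Dt / 2))
  lc <- lineageDistanceCorrelation(dset, ont)
  expect_equal(lc$meanR, 1, tolerance = 1e-12)
  # label permutation kills the association on average
  set.seed(10)
  rs <- replicate(50, {
    perm <- sample(regs)
    Dp <- Dt / 2
    dimnames(Dp) <- list(perm, perm)
    lineageDistanceCorrelation(new("DissimilaritySet",
                                   matrices = list(t1 = Dp)), ont)$meanR
  })
  expect_lt(abs(mean(rs)), 0.1)
  # generator lineage blocks produce positive mean correlation
  pos <- vapply(1:5, function(s) {
    res <- generateDataset(syntheticConfig(nGenes = 100, nRegions = 8,
                                           seed = s))
    ot <- writeTempTsv(c("child\tparent\torigin",
                         sprintf("%s\tbrain\t%s", names(res$truth$originBlock),
                                 res$truth$originBlock)))
    lineageDistanceCorrelation(dissimilaritySet(res$dataset),
                               readOntology(ot))$meanR
  }, numeric(1))
  expect_true(all(pos > 0))
})

test_that("per-region gene contributions match brute-force recomputation", {
  ds <- randomDataset(8, 5, 2, seed = 19)
  rc <- regionGeneContributions(ds, "r02", "t1", topN = 8)
  meanToOracle <- function(X) {
    D <- oracleDissimMatrix(X)
    mean(D["r02", setdiff(colnames(D), "r02")], na.rm = TRUE)
  }
  X <- exprValues(ds)[, , "t1"]
  ref <- meanToOracle(X)
  for (i in seq_len(nrow(rc))) {
    g <- rc$gene[i]
    expect_equal(rc$contribution[i],
                 ref - meanToOracle(X[setdiff(rownames(X), g), ]),
                 tolerance = 1e-12)
  }
  # descending order, topN respected
  expect_true(all(diff(rc$contribution) <= 0))
  expect_identical(nrow(regionGeneContributions(ds, "r02", "t1", topN = 3)), 3L)
  # identical genes across regions: all contributions are zero
  X0 <- matrix(rep(runif(6, 1, 2), 4), 6, 4,
               dimnames = list(paste0("g", 1:6), paste0("R", 1:4)))
  ds0 <- datasetFromSlices(list(t1 = X0))
  expect_equal(regionGeneContributions(ds0, "R1", "t1")$contribution,
               rep(0, 6))
})

test_that("chained embeddings align each timepoint to its predecessor", {
  res <- generateDataset(syntheticConfig(nGenes = 60, nRegions = 6, seed = 4))
  emb <- embedTimepoints(res$dataset, seed = 2, nStarts = 4)
  expect_identical(names(emb), timeLabels(res$dataset))
  expect_true(is.na(emb[[1]]$disparity))
  for (tp in names(emb)[-1]) expect_false(is.na(emb[[tp]]$disparity))
  for (tp in names(emb)) {
    expect_true(all(is.finite(emb[[tp]]$coords$x)))
    expect_gte(emb[[tp]]$stress, 0)
    expect_false(anyNA(emb[[tp]]$coords$sd))
  }
})
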