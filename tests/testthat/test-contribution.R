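test_that("contribution profiles match the brute-force leave-one-out oracle", {
  ds <- randomDataset(10, 5, 3, seed = 17)
  prof <- contributionProfiles(ds)
  for (g in geneIds(ds)) {
    for (k in seq_along(timeLabels(ds))) {
      tp <- timeLabels(ds)[k]
      ref <- oracleCurveMean(exprValues(ds)[, , tp])
      loo <- oracleCurveMean(exprValues(ds)[setdiff(geneIds(ds), g), , tp])
      expect_equal(prof[g, tp], ref - loo, tolerance = 1e-12)
    }
  }
})

test_that("contribution profiles are zero without regional structure and track a planted driver", {
  # genes identical across regions: Dbar = 0 and every contribution = 0
  X <- matrix(rep(runif(8, 1, 2), 4), 8, 4,
              dimnames = list(paste0("g", 1:8), paste0("R", 1:4)))
  ds0 <- datasetFromSlices(list(t1 = X, t2 = X))
  expect_equal(unname(contributionProfiles(ds0)), matrix(0, 8, 2))

  # a single planted driver has the maximal contribution at every timepoint
  set.seed(31)
  base <- matrix(rep(runif(20, 1, 2), 5), 20, 5) +
    matrix(rnorm(100, sd = 0.02), 20, 5)
  slices <- list()
  for (tp in c("t1", "t2", "t3")) {
    Y <- base
    Y[1, ] <- c(0, 1, 3, 6, 10)
    dimnames(Y) <- list(sprintf("g%02d", 1:20), paste0("R", 1:5))
    slices[[tp]] <- Y
  }
  prof <- contributionProfiles(datasetFromSlices(slices))
  for (tp in colnames(prof))
    expect_identical(rownames(prof)[which.max(prof[, tp])], "g01")
})

test_that("k-means clustering over the grid is seeded and recovers planted groups", {
  set.seed(5)
  # two well-separated profile groups
  prof <- rbind(matrix(rnorm(150, mean = 0, sd = 0.05), 30, 5),
                matrix(rnorm(150, mean = 1, sd = 0.05), 30, 5))
  rownames(prof) <- sprintf("g%02d", 1:60)
  truth <- rep(1:2, each = 30)
  okAri <- 0
  for (s in 1:10) {
    asg <- clusterProfiles(prof, kGrid = 2L, restarts = 10L, seed = s)[["2"]]
    if (ariScore(asg, truth) == 1) okAri <- okAri + 1
  }
  expect_gte(okAri, 9)
  # k = 1 puts everything in one cluster
  expect_identical(unname(unique(clusterProfiles(prof, kGrid = 1L,
                                                 seed = 1)[["1"]])), 1L)
  # identical seeds give identical assignments; empty grid errors
  a <- clusterProfiles(prof, kGrid = c(2L, 4L), seed = 3)
  b <- clusterProfiles(prof, kGrid = c(2L, 4L), seed = 3)
  expect_identical(a, b)
  expect_error(clusterProfiles(prof, kGrid = integer(0)), "empty")
})

test_that("hypergeometric enrichment is exact and honors the size filter", {
  genes <- sprintf("g%03d", 1:100)
  asg <- setNames(rep(2L, 100), genes)
  asg[1:10] <- 1L
  parents <- list("C:big" = character(0), "C:small" = character(0))
  g2c <- c(lapply(genes[1:10], function(g) "C:big"),
           lapply(genes[11:100], function(g) character(0)))
  names(g2c) <- genes
  for (g in genes[1:9]) g2c[[g]] <- c(g2c[[g]], "C:small")
  ann <- new("GeneAnnotation", gene2cat = g2c, parents = parents,
             catNames = c("C:big" = "big", "C:small" = "small"))
  tab <- hypergeometricEnrichment(asg, ann, minGenes = 10L)
  # full overlap of a size-10 category with a size-10 cluster
  row <- tab[tab$cluster == 1 & tab$category == "C:big", ]
  expect_equal(row$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(row$p, oracleHyperTail(100, 10, 10, 10), tolerance = 1e-12)
  # category below the size threshold is excluded
  expect_false("C:small" %in% tab$category)
  # zero overlap has p = 1
  row2 <- tab[tab$cluster == 2 & tab$category == "C:big", ]
  expect_equal(row2$p, 1)
})

test_that("double FDR matches hand-computed BH at both stages", {
  mkTab <- function(p, cats, cl = 1L)
    data.frame(cluster = cl, category = cats, nCategory = 10L,
               nCluster = 10L, nOverlap = 3L, p = p)
  # constant p vector: BH leaves it unchanged at both stages
  raw <- list("10" = mkTab(rep(0.02, 4), paste0("C", 1:4)))
  dd <- doubleFdr(raw, threshold = 0.01)
  expect_equal(dd$table$q1, rep(0.02, 4))
  expect_equal(dd$table$q2, rep(0.02, 4))
  # single k, single category: stage 2 equals stage 1
  raw1 <- list("10" = mkTab(0.003, "Cx"))
  dd1 <- doubleFdr(raw1)
  expect_equal(dd1$table$q2, dd1$table$q1)
  # five arbitrary p-values against the hand BH oracle
  p5 <- c(0.011, 0.3, 0.002, 0.04, 0.9)
  dd5 <- doubleFdr(list("10" = mkTab(p5, paste0("C", 1:5))))
  expect_equal(dd5$table$q1, oracleBH(p5), tolerance = 1e-12)
  expect_equal(p.adjust(p5, "BH"), oracleBH(p5), tolerance = 1e-12)
  # q never smaller than raw p within a family
  expect_true(all(dd5$table$q1 >= dd5$table$p - 1e-15))
  # stage 2 pools the per-k minimum stage-1 q across the grid
  rawK <- list("10" = mkTab(c(0.001, 0.5), c("CA", "CB")),
               "15" = mkTab(c(0.04, 0.02), c("CA", "CB")))
  ddK <- doubleFdr(rawK)
  q1k10 <- oracleBH(c(0.001, 0.5)); q1k15 <- oracleBH(c(0.04, 0.02))
  expect_equal(sort(unique(ddK$table$q2[ddK$table$category == "CA"])),
               sort(oracleBH(c(q1k10[1], q1k15[1]))), tolerance = 1e-12)
})

test_that("hierarchy screening keeps the most refined categories", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GP", "name: grandparent", "",
               "[Term]", "id: PA", "name: parent", "is_a: GP", "",
               "[Term]", "id: CH", "name: child", "is_a: PA", "",
               "[Term]", "id: ZZ", "name: unrelated"), obo)
  ann <- readAnnotations(writeTempTsv(c("gene\tterm", "gA\tCH", "gB\tZZ")), obo)
  # unrelated categories all kept
  e0 <- data.frame(category = c("CH", "ZZ"), q2 = c(0.004, 0.002))
  expect_identical(screenHierarchy(e0, ann)$category, c("CH", "ZZ"))
  # parent dropped when the child is lower
  e1 <- data.frame(category = c("PA", "CH"), q2 = c(0.005, 0.001))
  expect_identical(screenHierarchy(e1, ann)$category, "CH")
  # chain: grandparent dropped (parent lower), parent and child kept
  e2 <- data.frame(category = c("GP", "PA", "CH"), q2 = c(0.004, 0.002, 0.003))
  expect_setequal(screenHierarchy(e2, ann)$category, c("PA", "CH"))
})

test_that("phase assignment separates embryonic from postnatal clusters", {
  tps <- c("E11.5", "E13.5", "E15.5", "E18.5", "P4", "P14", "P28")
  genes <- sprintf("g%02d", 1:10)
  # all contribution mass embryonic
  prof <- matrix(0, 10, 7, dimnames = list(genes, tps))
  prof[, 1:4] <- 1
  expect_identical(phaseAssignment(prof, genes), "embryonic")
  # mirrored mass is postnatal
  prof2 <- matrix(0, 10, 7, dimnames = list(genes, tps))
  prof2[, 5:7] <- 1
  expect_identical(phaseAssignment(prof2, genes), "postnatal")
  # identical pooled distributions: neither
  prof3 <- matrix(0.5, 10, 7, dimnames = list(genes, tps))
  expect_identical(phaseAssignment(prof3, genes), "neither")
})

test_that("category contribution index is the mean over annotated genes", {
  tps <- c("E11.5", "P28")
  prof <- matrix(c(0.001, 0.002, 0.003, 0.01, 0.02, 0.03), 3, 2,
                 dimnames = list(c("gA", "gB", "gC"), tps))
  parents <- list("C1" = character(0))
  ann <- new("GeneAnnotation",
             gene2cat = list(gA = "C1", gB = "C1", gC = "C1"),
             parents = parents, catNames = c("C1" = "one"))
  expect_equal(categoryContributionIndex(prof, ann, "C1", "E11.5"), 0.002)
  expect_equal(categoryContributionIndex(prof, ann, "C1", "P28"), 0.02)
  expect_error(categoryContributionIndex(prof, ann, "C1", "nope"), "timepoint")
})

test_that("planted construction and plasticity categories swap contribution ranks", {
  res <- generateDataset(syntheticConfig(nGenes = 150, nRegions = 10, seed = 23))
  prof <- contributionProfiles(res$dataset)
  ann <- annotationFromTable(res$annotationTable)
  first <- timeLabels(res$dataset)[1]
  last <- timeLabels(res$dataset)[7]
  conF <- categoryContributionIndex(prof, ann, "CAT:construction", first)
  plaF <- categoryContributionIndex(prof, ann, "CAT:plasticity", first)
  conL <- categoryContributionIndex(prof, ann, "CAT:construction", last)
  plaL <- categoryContributionIndex(prof, ann, "CAT:plasticity", last)
  expect_gt(conF, plaF)
  expect_gt(plaL, conL)
})
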