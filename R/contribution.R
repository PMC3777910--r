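# Leave-one-gene-out contribution profiles and their functional analysis:
# k-means clustering over a grid of k, hypergeometric GO enrichment with a
# two-stage (double) FDR correction, GO-hierarchy screening, a
# developmental-phase call per cluster, and the category contribution
# index.

#' Leave-one-gene-out contribution profiles
#'
#' For every gene g and timepoint t computes
#' `deltaD_g(t) = Dbar(t) - Dbar_without_g(t)`, where `Dbar(t)` is the mean
#' inter-region dissimilarity over all region pairs and `Dbar_without_g`
#' the same after deleting gene g from the dataset. A positive value means
#' the gene increases inter-region dissimilarity at that age. The
#' leave-one-out curve is recomputed from scratch per gene (no incremental
#' shortcuts), on the identical region masks as the reference.
#'
#' Contribution profiling is restricted to developmental timepoints by
#' passing `timepoints` (e.g. excluding an adult endpoint).
#'
#' @param dataset an [ExpressionDataset-class] with >= 3 genes.
#' @param timepoints timepoints to profile (default: all).
#' @param minCommon passed to the dissimilarity kernel.
#' @return numeric matrix `gene x timepoint` of contribution values.
#' @export
contributionProfiles <- function(dataset, timepoints = NULL, minCommon = 3L) {
  if (!is.null(timepoints))
    dataset <- subsetDataset(dataset, timepoints = timepoints)
  genes <- geneIds(dataset)
  if (length(genes) < 3L) stop("need at least 3 genes")
  tps <- timeLabels(dataset)
  ref <- hourglassCurve(dataset, minCommon = minCommon)$mean
  prof <- matrix(NA_real_, length(genes), length(tps),
                 dimnames = list(genes, tps))
  for (g in genes) {
    cu <- hourglassCurve(subsetDataset(dataset, genes = setdiff(genes, g)),
                         minCommon = minCommon)$mean
    prof[g, ] <- ref - cu
  }
  if (any(!is.finite(prof)))
    stop("contribution profile not finite; too few genes after exclusion?")
  prof
}

# k-means++-style seeding: first centre uniform, then proportional to
# squared distance from the nearest chosen centre.
.kmeansPPCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k == 1L) return(centers)
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = probs)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Cluster contribution profiles over a grid of k
#'
#' k-means on the raw (unstandardized) contribution profiles, Euclidean
#' metric, for every k in the grid. Each k is run `restarts` times with
#' k-means++-style seeded initializations (Lloyd iterations) and the
#' restart with the lowest total within-cluster sum of squares is kept.
#'
#' @param profiles matrix `gene x timepoint` from [contributionProfiles()].
#' @param kGrid integer vector of cluster counts (default the 10..50
#'   step-5 grid).
#' @param restarts seeded initializations per k.
#' @param seed integer seed.
#' @return named list, one element per k (named by k), each an integer
#'   vector of cluster labels named by gene.
#' @export
clusterProfiles <- function(profiles, kGrid = seq(10L, 50L, by = 5L),
                            restarts = 10L, seed = 1L) {
  if (length(kGrid) == 0L) stop("empty k grid")
  if (any(kGrid > nrow(profiles)))
    stop("k exceeds the number of genes")
  set.seed(seed)
  out <- lapply(kGrid, function(k) {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- .kmeansPPCenters(profiles, k)
      fit <- suppressWarnings(
        kmeans(profiles, centers = centers, iter.max = 100L,
               algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    setNames(best$cluster, rownames(profiles))
  })
  names(out) <- as.character(kGrid)
  out
}

#' Hypergeometric GO enrichment of gene clusters
#'
#' Upper-tail hypergeometric test of category over-representation in each
#' cluster. The universe is the set of clustered genes; categories are
#' restricted to `categoryWhitelist` (when given) and to categories with at
#' least `minGenes` annotated genes in the universe.
#'
#' @param assignment named integer vector of cluster labels (one entry per
#'   gene), as one element of [clusterProfiles()]'s result.
#' @param annotation a [GeneAnnotation-class].
#' @param minGenes minimum annotated genes in the universe per category.
#' @param categoryWhitelist category ids to test (default: all in the
#'   annotation's DAG).
#' @return data.frame with columns `cluster`, `category`, `nCategory`,
#'   `nCluster`, `nOverlap`, `p`.
#' @export
hypergeometricEnrichment <- function(assignment, annotation, minGenes = 10L,
                                     categoryWhitelist = NULL) {
  universe <- names(assignment)
  g2c <- geneCategories(annotation)
  cats <- if (is.null(categoryWhitelist)) names(annotation@parents) else
    categoryWhitelist
  catGenes <- lapply(cats, function(cid)
    intersect(universe, names(g2c)[vapply(g2c, function(cc) cid %in% cc,
                                          logical(1))]))
  names(catGenes) <- cats
  catGenes <- catGenes[lengths(catGenes) >= minGenes]
  if (length(catGenes) == 0L)
    stop("no category passes the minGenes filter on this universe")
  N <- length(universe)
  rows <- list()
  for (cl in sort(unique(assignment))) {
    clGenes <- universe[assignment == cl]
    n <- length(clGenes)
    for (cid in names(catGenes)) {
      K <- length(catGenes[[cid]])
      ov <- length(intersect(clGenes, catGenes[[cid]]))
      p <- phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, category = cid, nCategory = K,
                   nCluster = n, nOverlap = ov, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Two-stage (double) FDR correction across the k grid
#'
#' Stage 1: within each clustering (each k), Benjamini-Hochberg across all
#' (cluster, category) tests. Stage 2: each category receives one value per
#' k — the minimum stage-1 q over that k's clusters (its best cluster) —
#' and these per-k values are BH-corrected within the category. A category
#' is reported enriched iff its smallest stage-2 q falls below `threshold`.
#'
#' @param rawTables named list over k of enrichment data.frames from
#'   [hypergeometricEnrichment()].
#' @param threshold stage-2 q-value cutoff for the enrichment call.
#' @param stage2Input `"q"` (default; per-k minimum stage-1 q) or `"p"`
#'   (per-k minimum raw p) as the stage-2 family input.
#' @return list with `table` (data.frame `k`, `cluster`, `category`,
#'   `nCategory`, `nCluster`, `nOverlap`, `p`, `q1`, `q2`) and `enriched`
#'   (data.frame `category`, `q2` of the per-category minimum stage-2 q,
#'   restricted to calls below `threshold`).
#' @export
doubleFdr <- function(rawTables, threshold = 0.01,
                      stage2Input = c("q", "p")) {
  stage2Input <- match.arg(stage2Input)
  if (length(rawTables) == 0L) stop("empty enrichment input")
  tab <- do.call(rbind, c(Map(function(k, df) cbind(k = as.integer(k), df),
                              names(rawTables), rawTables),
                          list(make.row.names = FALSE)))
  tab$q1 <- NA_real_
  for (k in unique(tab$k)) {
    sel <- tab$k == k
    tab$q1[sel] <- p.adjust(tab$p[sel], method = "BH")
  }
  # per (k, category): the category's best value within that clustering
  statCol <- if (stage2Input == "q") "q1" else "p"
  key <- paste(tab$k, tab$category, sep = "\r")
  perK <- tapply(tab[[statCol]], key, min)
  kOf <- as.integer(sub("\r.*$", "", names(perK)))
  catOf <- sub("^[^\r]*\r", "", names(perK))
  q2ByKey <- setNames(rep(NA_real_, length(perK)), names(perK))
  for (cid in unique(catOf)) {
    sel <- catOf == cid
    q2ByKey[sel] <- p.adjust(perK[sel], method = "BH")
  }
  tab$q2 <- q2ByKey[paste(tab$k, tab$category, sep = "\r")]
  best <- tapply(tab$q2, tab$category, min)
  enriched <- data.frame(category = names(best), q2 = as.numeric(best),
                         stringsAsFactors = FALSE)
  enriched <- enriched[enriched$q2 < threshold, , drop = FALSE]
  enriched <- enriched[order(enriched$q2), , drop = FALSE]
  rownames(enriched) <- NULL
  list(table = tab, enriched = enriched)
}

#' Screen enriched categories against the GO hierarchy
#'
#' Keeps the most refined calls: a category is dropped iff some enriched
#' strict descendant has a strictly lower stage-2 q.
#'
#' @param enriched data.frame `category`, `q2` (as from [doubleFdr()]).
#' @param annotation a [GeneAnnotation-class] providing the DAG.
#' @return the kept subset of `enriched`, same columns.
#' @export
screenHierarchy <- function(enriched, annotation) {
  if (nrow(enriched) == 0L) return(enriched)
  qOf <- setNames(enriched$q2, enriched$category)
  keep <- vapply(enriched$category, function(cid) {
    desc <- intersect(termDescendants(annotation, cid), enriched$category)
    !any(qOf[desc] < qOf[cid])
  }, logical(1))
  out <- enriched[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Developmental-phase call for a gene cluster
#'
#' Pools the cluster genes' contribution values over embryonic timepoints
#' and, separately, over postnatal developmental timepoints, and compares
#' the two pools with a two-sample rank test (`wilcox.test`). If the
#' difference is significant at `alpha`, the phase is the side with the
#' larger median; otherwise `"neither"`.
#'
#' @param profiles matrix `gene x timepoint` from [contributionProfiles()].
#' @param clusterGenes gene ids of the cluster.
#' @param embryonicTps,postnatalTps timepoint labels of the two pools
#'   (defaults: E11.5-E18.5 vs P4-P28).
#' @param alpha significance level of the rank test.
#' @return one of `"embryonic"`, `"postnatal"`, `"neither"`.
#' @export
phaseAssignment <- function(profiles, clusterGenes,
                            embryonicTps = c("E11.5", "E13.5", "E15.5", "E18.5"),
                            postnatalTps = c("P4", "P14", "P28"),
                            alpha = 0.05) {
  embryonicTps <- intersect(embryonicTps, colnames(profiles))
  postnatalTps <- intersect(postnatalTps, colnames(profiles))
  if (length(embryonicTps) == 0L || length(postnatalTps) == 0L)
    stop("both timepoint pools must be non-empty")
  emb <- as.numeric(profiles[clusterGenes, embryonicTps])
  post <- as.numeric(profiles[clusterGenes, postnatalTps])
  if (length(unique(c(emb, post))) == 1L) return("neither")
  p <- suppressWarnings(wilcox.test(emb, post, exact = FALSE)$p.value)
  if (is.na(p) || p >= alpha) return("neither")
  if (median(emb) > median(post)) "embryonic" else "postnatal"
}

#' Full enrichment table over the k grid, with phase per cluster
#'
#' Convenience wrapper running [hypergeometricEnrichment()] per clustering,
#' [doubleFdr()], [screenHierarchy()] and [phaseAssignment()].
#'
#' @param profiles contribution matrix (`gene x timepoint`).
#' @param assignments result of [clusterProfiles()].
#' @param annotation a [GeneAnnotation-class].
#' @param minGenes,categoryWhitelist,threshold,stage2Input passed through.
#' @param embryonicTps,postnatalTps pools for [phaseAssignment()].
#' @return list with `table` (per-row phase added), `enriched` (screened
#'   enriched categories).
#' @export
enrichmentAnalysis <- function(profiles, assignments, annotation,
                               minGenes = 10L, categoryWhitelist = NULL,
                               threshold = 0.01, stage2Input = "q",
                               embryonicTps = c("E11.5", "E13.5", "E15.5", "E18.5"),
                               postnatalTps = c("P4", "P14", "P28")) {
  raw <- lapply(assignments, hypergeometricEnrichment, annotation = annotation,
                minGenes = minGenes, categoryWhitelist = categoryWhitelist)
  dd <- doubleFdr(raw, threshold = threshold, stage2Input = stage2Input)
  screened <- screenHierarchy(dd$enriched, annotation)
  # phase per (k, cluster) row
  phase <- character(nrow(dd$table))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dd$table))) {
    k <- dd$table$k[i]; cl <- dd$table$cluster[i]
    keyi <- paste(k, cl)
    if (is.null(cache[[keyi]])) {
      gg <- names(assignments[[as.character(k)]])[
        assignments[[as.character(k)]] == cl]
      cache[[keyi]] <- phaseAssignment(profiles, gg,
                                       embryonicTps = embryonicTps,
                                       postnatalTps = postnatalTps)
    }
    phase[i] <- cache[[keyi]]
  }
  dd$table$phase <- phase
  list(table = dd$table, enriched = screened)
}

#' Category contribution index
#'
#' Mean contribution value at one timepoint over all genes assigned to a
#' category — high for large contributing categories and for small
#' categories of strongly contributing genes.
#'
#' @param profiles contribution matrix from [contributionProfiles()].
#' @param annotation a [GeneAnnotation-class].
#' @param category category id.
#' @param timepoint column of `profiles`.
#' @return the index (numeric scalar).
#' @export
categoryContributionIndex <- function(profiles, annotation, category,
                                      timepoint) {
  genes <- intersect(categoryGenes(annotation, category), rownames(profiles))
  if (length(genes) == 0L)
    stop("no profiled genes annotated to ", category)
  if (!timepoint %in% colnames(profiles))
    stop("unknown timepoint: ", timepoint)
  mean(profiles[genes, timepoint])
}
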