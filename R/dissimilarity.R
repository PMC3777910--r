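# Inter-region dissimilarity: 1 - Pearson correlation between the
# gene-expression vectors of two regions, computed per timepoint over the
# genes observed in both (pairwise-complete). The mean over all region
# pairs per timepoint traces the developmental "hourglass" curve.

# gene x region matrix slice at one timepoint, robust to length-1 axes
.sliceAt <- function(dataset, timepoint) {
  v <- exprValues(dataset)[, , timepoint, drop = FALSE]
  matrix(v, nrow = dim(v)[1], ncol = dim(v)[2],
         dimnames = dimnames(v)[1:2])
}

# Core kernel: X is the gene x region slice at one timepoint (NA = missing).
# Pairs with < minCommon commonly observed genes, or where either vector has
# zero variance on the common genes, get NA.
.dissimFromSlice <- function(X, minCommon = 3L) {
  nr <- ncol(X)
  D <- matrix(NA_real_, nr, nr, dimnames = list(colnames(X), colnames(X)))
  diag(D) <- 0
  if (nr < 2L) return(D)
  if (!anyNA(X)) {
    # complete slice: one BLAS-level correlation for all pairs
    if (nrow(X) >= minCommon) {
      sds <- apply(X, 2L, sd)
      ok <- sds > 0
      if (sum(ok) >= 2L) {
        C <- cor(X[, ok, drop = FALSE])
        D[ok, ok] <- 1 - C
      }
      D[!ok, ] <- NA_real_
      D[, !ok] <- NA_real_
      diag(D) <- 0
    }
    return(D)
  }
  obs <- !is.na(X)
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      common <- obs[, i] & obs[, j]
      if (sum(common) < minCommon) next
      x <- X[common, i]; y <- X[common, j]
      if (sd(x) == 0 || sd(y) == 0) next
      d <- 1 - cor(x, y)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Pairwise inter-region dissimilarity at one timepoint
#'
#' For every pair of regions present at `timepoint`, represents each region
#' as its vector of gene expression densities and returns
#' `1 - PCC` (Pearson correlation), a dissimilarity in `[0, 2]`. Gene sets
#' are pairwise-complete: only genes observed in both regions enter a
#' pair's correlation. Pairs with fewer than `minCommon` common genes or a
#' zero-variance vector are `NA`.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param timepoint one of `timeLabels(dataset)`.
#' @param minCommon minimum number of commonly observed genes per pair.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwiseDissimilarity <- function(dataset, timepoint, minCommon = 3L) {
  if (!timepoint %in% timeLabels(dataset))
    stop("unknown timepoint: ", timepoint)
  X <- .sliceAt(dataset, timepoint)
  # drop regions entirely unobserved at this timepoint
  present <- colSums(!is.na(X)) > 0L
  if (sum(present) < 2L)
    stop("fewer than 2 regions with data at timepoint ", timepoint)
  .dissimFromSlice(X[, present, drop = FALSE], minCommon = minCommon)
}

#' Dissimilarity matrices for all timepoints
#'
#' @param dataset an [ExpressionDataset-class].
#' @param minCommon minimum commonly observed genes per region pair.
#' @return A [DissimilaritySet-class].
#' @export
dissimilaritySet <- function(dataset, minCommon = 3L) {
  mats <- lapply(timeLabels(dataset), function(tp)
    tryCatch(pairwiseDissimilarity(dataset, tp, minCommon = minCommon),
             error = function(e) matrix(numeric(0), 0, 0)))
  names(mats) <- timeLabels(dataset)
  new("DissimilaritySet", matrices = mats)
}

.pairValues <- function(D) {
  if (nrow(D) < 2L) return(numeric(0))
  D[upper.tri(D)]
}

.summarizePairs <- function(vals) {
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    return(data.frame(mean = NA_real_, median = NA_real_, q1 = NA_real_,
                      q3 = NA_real_, whiskerLo = NA_real_, whiskerHi = NA_real_,
                      nPairs = 0L))
  qs <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lo <- qs[1] - 1.5 * iqr
  hi <- qs[3] + 1.5 * iqr
  inl <- vals[vals >= lo & vals <= hi]
  data.frame(mean = mean(vals), median = qs[2], q1 = qs[1], q3 = qs[3],
             whiskerLo = min(inl), whiskerHi = max(inl),
             nPairs = length(vals))
}

#' Hourglass curve: mean inter-region dissimilarity per timepoint
#'
#' Summarizes each timepoint's pair dissimilarities by their mean (the
#' curve), median, quartiles, 1.5 x IQR whiskers and pair count. Timepoints
#' with no valid pair are kept as `NA` rows (flagged missing).
#'
#' @param x an [ExpressionDataset-class] or a [DissimilaritySet-class].
#' @param minCommon passed to [pairwiseDissimilarity()] when `x` is a
#'   dataset.
#' @return data.frame with columns `timepoint`, `mean`, `median`, `q1`,
#'   `q3`, `whiskerLo`, `whiskerHi`, `nPairs`; one row per timepoint in
#'   developmental order.
#' @export
hourglassCurve <- function(x, minCommon = 3L) {
  dset <- if (is(x, "ExpressionDataset")) dissimilaritySet(x, minCommon) else x
  if (!is(dset, "DissimilaritySet"))
    stop("'x' must be an ExpressionDataset or DissimilaritySet")
  tps <- timeLabels(dset)
  if (length(tps) < 2L) stop("need at least 2 timepoints")
  rows <- do.call(rbind, lapply(dissimMatrices(dset), function(D)
    .summarizePairs(.pairValues(D))))
  cbind(data.frame(timepoint = tps, stringsAsFactors = FALSE), rows,
        row.names = NULL)
}

#' Quadratic least-squares fit to the hourglass curve
#'
#' Fits `mean ~ a2 * r^2 + a1 * r + a0` by ordinary least squares, where
#' `r` is the 0-based rank of the timepoint (the curve's age axis is
#' categorical, so spacing is ordinal).
#'
#' @param curve a curve data.frame from [hourglassCurve()].
#' @return named numeric `c(a2, a1, a0)`.
#' @export
fitQuadratic <- function(curve) {
  ok <- !is.na(curve$mean)
  if (sum(ok) < 3L) stop("need at least 3 non-missing curve points")
  r <- (seq_len(nrow(curve)) - 1L)[ok]
  y <- curve$mean[ok]
  fit <- lm(y ~ I(r^2) + r)
  co <- coef(fit)
  c(a2 = unname(co["I(r^2)"]), a1 = unname(co["r"]), a0 = unname(co["(Intercept)"]))
}

#' One-way ANOVA of pair dissimilarities across ages
#'
#' Tests whether mean inter-region dissimilarity differs between
#' timepoints: groups are timepoints, observations are the region-pair
#' dissimilarities at that timepoint.
#'
#' @param dissim a [DissimilaritySet-class].
#' @return the F-test p-value.
#' @export
ageAnova <- function(dissim) {
  vals <- lapply(dissimMatrices(dissim), .pairValues)
  vals <- lapply(vals, function(v) v[!is.na(v)])
  vals <- vals[lengths(vals) >= 2L]
  if (length(vals) < 2L)
    stop("need >= 2 timepoints with >= 2 pair dissimilarities each")
  df <- data.frame(value = unlist(vals, use.names = FALSE),
                   age = factor(rep(names(vals), lengths(vals))))
  summary(aov(value ~ age, data = df))[[1]][["Pr(>F)"]][1]
}

#' Hourglass curves on random gene subsets
#'
#' Recomputes the curve on `nSubsets` uniform gene subsets (sampled without
#' replacement) for each size, to test whether the curve's shape depends on
#' the particular genes analyzed.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param sizes integer vector of subset sizes (each <= number of genes).
#' @param nSubsets subsets per size.
#' @param seed integer seed; the run is fully reproducible.
#' @return named list (one element per size, named by the size) of lists of
#'   curve data.frames.
#' @export
subsetRobustness <- function(dataset, sizes, nSubsets = 100L, seed = 1L) {
  ng <- length(geneIds(dataset))
  if (any(sizes > ng))
    stop("subset size exceeds number of genes (", ng, ")")
  set.seed(seed)
  out <- lapply(sizes, function(K) {
    lapply(seq_len(nSubsets), function(i) {
      gs <- sample(geneIds(dataset), K, replace = FALSE)
      hourglassCurve(subsetDataset(dataset, genes = gs))
    })
  })
  names(out) <- as.character(sizes)
  out
}

#' Hourglass curves after removing the most variable genes
#'
#' At each timepoint, each gene's standard deviation across regions (raw
#' densities) is computed and the top `k` genes are removed *at that
#' timepoint* before the dissimilarity matrix is formed; the removal set
#' may differ between timepoints.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param kList integer vector of removal counts (each < number of genes).
#' @return named list of curve data.frames, one per `k` (named by `k`).
#' @export
dropTopVariable <- function(dataset, kList = c(50L, 100L, 200L, 500L)) {
  ng <- length(geneIds(dataset))
  if (any(kList >= ng)) stop("k must be smaller than the number of genes")
  tps <- timeLabels(dataset)
  out <- lapply(kList, function(k) {
    mats <- lapply(tps, function(tp) {
      X <- .sliceAt(dataset, tp)
      sds <- apply(X, 1L, sd, na.rm = TRUE)
      sds[is.na(sds)] <- -Inf
      drop <- if (k > 0L) order(sds, decreasing = TRUE)[seq_len(k)] else integer(0)
      keep <- setdiff(seq_len(nrow(X)), drop)
      .dissimFromSlice(X[keep, , drop = FALSE])
    })
    names(mats) <- tps
    hourglassCurve(new("DissimilaritySet", matrices = mats))
  })
  names(out) <- as.character(kList)
  out
}

#' Leave-one-region-out hourglass curves
#'
#' Recomputes the curve once per excluded region and summarizes the family
#' by its per-timepoint mean and standard deviation envelope.
#'
#' @param dataset an [ExpressionDataset-class] with >= 3 regions.
#' @return list with `curves` (named list of curve data.frames, one per
#'   excluded region) and `envelope` (data.frame `timepoint`, `mean`, `sd`
#'   across exclusions).
#' @export
leaveOneRegionOut <- function(dataset) {
  regs <- regionIds(dataset)
  if (length(regs) < 3L) stop("need at least 3 regions")
  curves <- lapply(regs, function(r)
    hourglassCurve(subsetDataset(dataset, regions = setdiff(regs, r))))
  names(curves) <- regs
  mm <- vapply(curves, function(cu) cu$mean, numeric(length(timeLabels(dataset))))
  envelope <- data.frame(timepoint = timeLabels(dataset),
                         mean = rowMeans(mm, na.rm = TRUE),
                         sd = apply(mm, 1L, sd, na.rm = TRUE))
  list(curves = curves, envelope = envelope)
}

#' Hourglass curves across ontology levels
#'
#' Aggregates leaf regions upwards through the region ontology: the
#' level-l expression of a cut node is the unweighted mean of its
#' constituent leaves' densities per gene and timepoint; the curve is then
#' computed on the aggregated regions, per level.
#'
#' @param dataset an [ExpressionDataset-class] whose regions include the
#'   ontology leaves.
#' @param ontology a [RegionOntology-class].
#' @param nLevels number of levels, starting at the leaves (level 1).
#' @return named list of curve data.frames, one per level (`"1"`,
#'   `"2"`, ...).
#' @export
ontologyLevelCurves <- function(dataset, ontology, nLevels = 3L) {
  leaves <- leafNodes(ontology)
  missing <- setdiff(leaves, regionIds(dataset))
  if (length(missing)) {
    warning("ontology leaves without expression data excluded: ",
            paste(missing, collapse = ", "))
    leaves <- setdiff(leaves, missing)
  }
  if (length(leaves) < 2L) stop("fewer than 2 ontology leaves with data")
  v <- exprValues(dataset)
  out <- lapply(seq_len(nLevels), function(lv) {
    cut <- levelCut(ontology, lv)
    cut <- lapply(cut, intersect, leaves)
    cut <- cut[lengths(cut) > 0L]
    agg <- array(NA_real_,
                 dim = c(dim(v)[1], length(cut), dim(v)[3]),
                 dimnames = list(dimnames(v)[[1]], names(cut), dimnames(v)[[3]]))
    for (i in seq_along(cut)) {
      sub <- v[, cut[[i]], , drop = FALSE]
      agg[, i, ] <- apply(sub, c(1, 3), function(z)
        if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
    }
    hourglassCurve(ExpressionDataset(agg, species = speciesLabel(dataset)))
  })
  names(out) <- as.character(seq_len(nLevels))
  out
}
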