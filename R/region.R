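# Region-level specialization: the region-specific index (a region's mean
# dissimilarity to all other regions, normalized by the overall mean
# inter-region dissimilarity), NMDS embeddings with chained Procrustes
# alignment across timepoints, within-region SD marker sizes, correlation
# of dissimilarity with embryonic lineage distance, and per-region
# leave-one-gene-out contribution rankings.

#' Region-specific specialization index over time
#'
#' For region R at each timepoint, the mean dissimilarity between R and
#' every other region, divided by the mean dissimilarity over all region
#' pairs. Values above 1 mark a region more distinct than the brain-wide
#' average. Timepoints where the region is absent are `NA`; a timepoint
#' with zero overall mean dissimilarity is an error.
#'
#' @param dataset an [ExpressionDataset-class] (or a
#'   [DissimilaritySet-class]).
#' @param region region id.
#' @return data.frame `timepoint`, `meanToOthers`, `overallMean`, `index`.
#' @export
regionSpecificIndex <- function(dataset, region) {
  dset <- if (is(dataset, "DissimilaritySet")) dataset else
    dissimilaritySet(dataset)
  tps <- timeLabels(dset)
  rows <- lapply(tps, function(tp) {
    D <- dissimMatrices(dset)[[tp]]
    if (!region %in% rownames(D))
      return(data.frame(timepoint = tp, meanToOthers = NA_real_,
                        overallMean = NA_real_, index = NA_real_))
    others <- setdiff(rownames(D), region)
    if (length(others) < 2L)
      stop("need at least 2 other regions at ", tp)
    mto <- mean(D[region, others], na.rm = TRUE)
    ov <- mean(.pairValues(D), na.rm = TRUE)
    if (!is.na(ov) && ov == 0)
      stop("overall mean dissimilarity is 0 at ", tp,
           "; region index undefined")
    data.frame(timepoint = tp, meanToOthers = mto, overallMean = ov,
               index = mto / ov)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Non-metric MDS embedding of one dissimilarity matrix
#'
#' Kruskal stress-1 non-metric MDS (vegan's global model). The classical
#' (metric) MDS configuration is always tried as one start, plus
#' `nStarts - 1` seeded random starts; the configuration with the lowest
#' final stress is returned. Missing entries are imputed by the matrix's
#' maximum observed value before embedding (conservative separation).
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param dims embedding dimension.
#' @param seed integer seed.
#' @param nStarts number of starts (including the metric start).
#' @return list with `coords` (region x dims matrix) and `stress`
#'   (Kruskal stress-1).
#' @export
nmdsEmbed <- function(D, dims = 2L, seed = 1L, nStarts = 10L) {
  if (!isTRUE(all.equal(D, t(D))))
    stop("dissimilarity matrix must be symmetric")
  if (any(is.na(D))) {
    mx <- max(D, na.rm = TRUE)
    D[is.na(D)] <- mx
    diag(D) <- 0
  }
  set.seed(seed)
  n <- nrow(D)
  dd <- as.dist(D)
  runOne <- function(y) {
    fit <- vegan::monoMDS(dd, y = y, k = dims, model = "global",
                          maxit = 500L, smin = 1e-10, sfgrmin = 1e-12,
                          sratmax = 1 - 1e-9)
    list(coords = fit$points, stress = fit$stress)
  }
  y0 <- tryCatch(cmdscale(dd, k = dims), error = function(e) NULL)
  best <- NULL
  if (!is.null(y0) && ncol(y0) == dims) best <- runOne(y0)
  for (s in seq_len(max(0L, nStarts - 1L))) {
    y <- matrix(rnorm(n * dims), n, dims)
    cand <- runOne(y)
    if (is.null(best) || cand$stress < best$stress) best <- cand
  }
  rownames(best$coords) <- rownames(D)
  colnames(best$coords) <- paste0("dim", seq_len(dims))
  best
}

#' Procrustes alignment of a configuration to a reference
#'
#' Finds the translation, orthogonal transform (rotation, reflection
#' allowed) and isotropic scaling of `coords` minimizing the sum of squared
#' differences to `reference` (the classical closed-form SVD solution).
#' Disparity is the minimized residual sum of squares divided by the
#' centred reference's total sum of squares.
#'
#' @param reference,coords numeric matrices with matching rownames (the
#'   row intersection is used when they differ) and equal column count.
#' @return list with `aligned` (transformed `coords`, all rows), and
#'   `disparity`.
#' @export
procrustesAlign <- function(reference, coords) {
  common <- intersect(rownames(reference), rownames(coords))
  if (length(common) < 2L) stop("need at least 2 common regions to align")
  X <- reference[common, , drop = FALSE]
  Y <- coords[common, , drop = FALSE]
  muX <- colMeans(X); muY <- colMeans(Y)
  X0 <- sweep(X, 2L, muX); Y0 <- sweep(Y, 2L, muY)
  normX <- sqrt(sum(X0^2)); normY <- sqrt(sum(Y0^2))
  if (normX == 0 || normY == 0) stop("degenerate configuration (zero spread)")
  sv <- svd(crossprod(X0, Y0))
  R <- sv$v %*% t(sv$u)                     # maps Y0 onto X0
  s <- sum(sv$d) / normY^2                  # isotropic scale
  resid <- X0 - s * Y0 %*% R
  disparity <- sum(resid^2) / normX^2
  allY0 <- sweep(coords, 2L, muY)
  aligned <- sweep(s * allY0 %*% R, 2L, muX, `+`)
  dimnames(aligned) <- dimnames(coords)
  list(aligned = aligned, disparity = disparity)
}

#' Embeddings for all timepoints, Procrustes-chained
#'
#' Embeds each timepoint's dissimilarity matrix with [nmdsEmbed()] and
#' aligns configurations chronologically: the first timepoint is the
#' reference and each subsequent configuration is aligned to the previous
#' aligned one, so trajectories are visually continuous. Marker sizes are
#' the within-region expression SDs.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param dims,seed,nStarts passed to [nmdsEmbed()].
#' @return named list per timepoint: `coords` (region, x, y, sd
#'   data.frame), `stress`, `disparity` (`NA` for the reference).
#' @export
embedTimepoints <- function(dataset, dims = 2L, seed = 1L, nStarts = 10L) {
  dset <- dissimilaritySet(dataset)
  tps <- timeLabels(dset)
  out <- list()
  prev <- NULL
  for (tp in tps) {
    D <- dissimMatrices(dset)[[tp]]
    if (nrow(D) < 3L) next
    emb <- nmdsEmbed(D, dims = dims, seed = seed, nStarts = nStarts)
    disparity <- NA_real_
    coords <- emb$coords
    if (!is.null(prev)) {
      al <- procrustesAlign(prev, coords)
      coords <- al$aligned
      disparity <- al$disparity
    }
    sds <- vapply(rownames(coords), function(r)
      tryCatch(withinRegionSd(dataset, r, tp), error = function(e) NA_real_),
      numeric(1))
    out[[tp]] <- list(coords = data.frame(region = rownames(coords),
                                          x = coords[, 1], y = coords[, 2],
                                          sd = sds, row.names = NULL),
                      stress = emb$stress, disparity = disparity)
    prev <- coords
  }
  out
}

#' Within-region expression standard deviation
#'
#' Sample SD (n - 1 denominator) of a region's observed expression values
#' across genes at one timepoint; used as the marker size of embeddings.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param region region id.
#' @param timepoint timepoint label.
#' @return numeric scalar.
#' @export
withinRegionSd <- function(dataset, region, timepoint) {
  if (!region %in% regionIds(dataset)) stop("unknown region: ", region)
  if (!timepoint %in% timeLabels(dataset)) stop("unknown timepoint: ", timepoint)
  x <- exprValues(dataset)[, region, timepoint]
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need >= 2 observed genes in ", region, " at ", timepoint)
  sd(x)
}

#' Correlation between dissimilarity and embryonic lineage distance
#'
#' Per timepoint, the Pearson correlation between the vectorized
#' upper-triangle region-pair dissimilarities and the path distance between
#' the regions' embryonic origins on the fixed four-leaf lineage tree
#' (telencephalon/diencephalon under forebrain; midbrain and hindbrain at
#' the root; unit branches; same origin = 0). Timepoints with a constant
#' distance vector are excluded with a warning.
#'
#' @param dissim a [DissimilaritySet-class].
#' @param ontology a [RegionOntology-class] tagging every region.
#' @return list with `perTimepoint` (data.frame `timepoint`, `r`, `nPairs`)
#'   and `meanR` (mean over usable timepoints).
#' @export
lineageDistanceCorrelation <- function(dissim, ontology) {
  tps <- timeLabels(dissim)
  rows <- lapply(tps, function(tp) {
    D <- dissimMatrices(dissim)[[tp]]
    if (nrow(D) < 3L)
      return(data.frame(timepoint = tp, r = NA_real_, nPairs = 0L))
    regs <- rownames(D)
    orig <- originOf(ontology, regs)
    idx <- which(upper.tri(D), arr.ind = TRUE)
    dval <- D[idx]
    tval <- mapply(function(i, j) originTreeDistance(orig[i], orig[j]),
                   idx[, 1], idx[, 2])
    ok <- !is.na(dval)
    dval <- dval[ok]; tval <- tval[ok]
    if (length(dval) < 3L || sd(tval) == 0 || sd(dval) == 0) {
      warning("lineage correlation undefined at ", tp, "; excluded")
      return(data.frame(timepoint = tp, r = NA_real_, nPairs = length(dval)))
    }
    data.frame(timepoint = tp, r = cor(dval, tval), nPairs = length(dval))
  })
  perTp <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(perTimepoint = perTp, meanR = mean(perTp$r, na.rm = TRUE))
}

#' Gene contributions to one region's dissimilarity
#'
#' For a focus region R and timepoint, each gene's contribution is the mean
#' dissimilarity between R and all other regions minus the same quantity
#' after deleting the gene (leave-one-gene-out, recomputed from scratch).
#' Genes are ranked by descending contribution.
#'
#' @param dataset an [ExpressionDataset-class] with >= 3 genes.
#' @param region focus region id.
#' @param timepoint timepoint label.
#' @param topN number of top-ranked genes to return.
#' @return data.frame `gene`, `contribution`, sorted descending, `topN`
#'   rows (fewer when the dataset has fewer genes).
#' @export
regionGeneContributions <- function(dataset, region, timepoint, topN = 20L) {
  if (!region %in% regionIds(dataset)) stop("unknown region: ", region)
  if (!timepoint %in% timeLabels(dataset))
    stop("region ", region, " absent: unknown timepoint ", timepoint)
  genes <- geneIds(dataset)
  if (length(genes) < 3L) stop("need at least 3 genes")
  meanTo <- function(ds) {
    D <- pairwiseDissimilarity(ds, timepoint)
    if (!region %in% rownames(D))
      stop("region ", region, " absent at ", timepoint)
    mean(D[region, setdiff(rownames(D), region)], na.rm = TRUE)
  }
  ref <- meanTo(dataset)
  contrib <- vapply(genes, function(g)
    ref - meanTo(subsetDataset(dataset, genes = setdiff(genes, g))),
    numeric(1))
  ord <- order(contrib, decreasing = TRUE)
  out <- data.frame(gene = genes[ord], contribution = contrib[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  head(out, topN)
}
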