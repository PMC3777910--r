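# Cross-species comparison over ortholog pairs: Spearman correlation of
# expression profiles for every (source timepoint, target timepoint) pair,
# averaged over mapped region pairs, plus side-by-side region-specific
# dissimilarity curves for mapped regions.

#' Region pair mapping between two datasets
#'
#' Each element pairs a set of source regions with a set of target regions;
#' a set's members are averaged into one profile before comparison (e.g.
#' two hindbrain subregions against one cerebellar cortex).
#'
#' @param sourceSets,targetSets lists of character vectors of equal length.
#' @return list of `list(source = ..., target = ...)` pairs, classed
#'   `"RegionPairMap"`.
#' @export
regionPairMap <- function(sourceSets, targetSets) {
  if (length(sourceSets) != length(targetSets))
    stop("sourceSets and targetSets must have equal length")
  out <- Map(function(s, t) list(source = as.character(s),
                                 target = as.character(t)),
             sourceSets, targetSets)
  class(out) <- "RegionPairMap"
  out
}

# averaged profile of a region set: gene x timepoint matrix
.setProfile <- function(dataset, regionSet) {
  bad <- setdiff(regionSet, regionIds(dataset))
  if (length(bad))
    stop("mapped region absent from dataset: ", paste(bad, collapse = ", "))
  v <- exprValues(dataset)[, regionSet, , drop = FALSE]
  apply(v, c(1, 3), function(z)
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
}

#' Cross-species Spearman correlation over all timepoint pairs
#'
#' For every (source timepoint, target timepoint) pair: each mapped region
#' set is averaged into one profile, the Spearman correlation across
#' ortholog genes is computed per region pair (pairwise-complete; average
#' ranks on ties), and the correlations are averaged over region pairs.
#' Setting `average = "profiles"` instead averages all mapped profiles
#' into one per species before the single correlation.
#'
#' @param sourceDS,targetDS [ExpressionDataset-class] objects.
#' @param orthologs an [OrthologMap-class] (source ids -> target ids).
#' @param mapping a [regionPairMap()]; default maps the shared region ids
#'   one-to-one.
#' @param average `"pairs"` (default) or `"profiles"`.
#' @param minOrthologs minimum usable ortholog pairs.
#' @return list with `matrix` (source x target timepoints of mean Spearman
#'   rho), `nOrthologs`, `mapping`.
#' @export
crossCorrelation <- function(sourceDS, targetDS, orthologs, mapping = NULL,
                             average = c("pairs", "profiles"),
                             minOrthologs = 10L) {
  average <- match.arg(average)
  if (is.null(mapping)) {
    shared <- intersect(regionIds(sourceDS), regionIds(targetDS))
    if (length(shared) == 0L) stop("no shared regions; supply a mapping")
    mapping <- regionPairMap(as.list(shared), as.list(shared))
  }
  op <- orthologPairs(orthologs)
  op <- op[op$source %in% geneIds(sourceDS) & op$target %in% geneIds(targetDS), ,
           drop = FALSE]
  if (nrow(op) < minOrthologs)
    stop("fewer than ", minOrthologs, " usable ortholog pairs")
  srcProf <- lapply(mapping, function(m) .setProfile(sourceDS, m$source))
  tgtProf <- lapply(mapping, function(m) .setProfile(targetDS, m$target))
  sTps <- timeLabels(sourceDS); tTps <- timeLabels(targetDS)
  M <- matrix(NA_real_, length(sTps), length(tTps),
              dimnames = list(sTps, tTps))
  spearman <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(NA_real_)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(rank(x[ok]), rank(y[ok]))
  }
  for (i in seq_along(sTps)) {
    for (j in seq_along(tTps)) {
      if (average == "pairs") {
        rhos <- vapply(seq_along(mapping), function(m)
          spearman(srcProf[[m]][op$source, i], tgtProf[[m]][op$target, j]),
          numeric(1))
        M[i, j] <- mean(rhos, na.rm = TRUE)
      } else {
        sAvg <- rowMeans(vapply(srcProf, function(P) P[op$source, i],
                                numeric(nrow(op))), na.rm = TRUE)
        tAvg <- rowMeans(vapply(tgtProf, function(P) P[op$target, j],
                                numeric(nrow(op))), na.rm = TRUE)
        M[i, j] <- spearman(sAvg, tAvg)
      }
    }
  }
  list(matrix = M, nOrthologs = nrow(op), mapping = mapping)
}

# collapse each mapped set into a single averaged pseudo-region inside its
# own dataset, leaving unmapped regions untouched
.collapseMapped <- function(dataset, sets, labels) {
  v <- exprValues(dataset)
  keep <- setdiff(regionIds(dataset), unlist(sets))
  profs <- lapply(sets, function(s) .setProfile(dataset, s))
  arr <- array(NA_real_,
               dim = c(dim(v)[1], length(keep) + length(sets), dim(v)[3]),
               dimnames = list(dimnames(v)[[1]], c(keep, labels),
                               dimnames(v)[[3]]))
  if (length(keep)) arr[, keep, ] <- v[, keep, ]
  for (i in seq_along(sets)) arr[, labels[i], ] <- profs[[i]]
  ExpressionDataset(arr, species = speciesLabel(dataset))
}

#' Side-by-side region-specific curves for mapped region pairs
#'
#' For each mapped pair, the source set and the target set are each
#' averaged into one pseudo-region inside their own dataset (other regions
#' unchanged) and the region-specific specialization index is computed
#' within each species. Orthologs are not needed for the indices (each
#' species is compared against itself); the argument is accepted for
#' interface symmetry and validated.
#'
#' @param sourceDS,targetDS [ExpressionDataset-class] objects.
#' @param mapping a [regionPairMap()].
#' @param orthologs optional [OrthologMap-class]; validated if supplied.
#' @return list per mapped pair: `source` and `target`, each the
#'   data.frame of [regionSpecificIndex()].
#' @export
parallelRegionCurves <- function(sourceDS, targetDS, mapping,
                                 orthologs = NULL) {
  if (length(regionIds(sourceDS)) < 3L || length(regionIds(targetDS)) < 3L)
    stop("need at least 3 regions in both datasets")
  if (!is.null(orthologs)) validObject(orthologs)
  out <- list()
  for (i in seq_along(mapping)) {
    m <- mapping[[i]]
    sLab <- paste(m$source, collapse = "+")
    tLab <- paste(m$target, collapse = "+")
    sDS <- .collapseMapped(sourceDS, list(m$source), sLab)
    tDS <- .collapseMapped(targetDS, list(m$target), tLab)
    out[[paste(sLab, tLab, sep = " vs ")]] <-
      list(source = regionSpecificIndex(sDS, sLab),
           target = regionSpecificIndex(tDS, tLab))
  }
  out
}
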