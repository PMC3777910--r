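# Gene-family analysis: global protein alignment score (Needleman-Wunsch,
# BLOSUM50, linear gap penalty 8 per gap symbol; score >= 0 is a family
# match) against spatial expression correlation at the two peak-
# dissimilarity ages.

.aaAlphabet <- function() {
  m <- .blosum50()
  rownames(m)
}

.blosum50 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM50", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM50
    }
    cache
  }
})

#' Global Needleman-Wunsch alignment score of two proteins
#'
#' Optimal global alignment under BLOSUM50 with a linear gap penalty of 8
#' per gap symbol. Pairs scoring >= 0 are considered members of the same
#' gene family ("matched").
#'
#' @param seqA,seqB non-empty amino-acid strings (standard alphabet; `X`
#'   scored by its BLOSUM50 row).
#' @param gap linear gap penalty per gap position (positive number).
#' @return list with `score` (numeric), `alignedA`, `alignedB` (one
#'   optimal alignment) and `matched` (`score >= 0`).
#' @examples
#' needlemanWunsch("AAA", "AAA")$score  # 15 = 3 x BLOSUM50[A, A]
#' @export
needlemanWunsch <- function(seqA, seqB, gap = 8) {
  for (s in list(A = seqA, B = seqB)) {
    if (!nzchar(s)) stop("sequences must be non-empty")
    chars <- strsplit(s, "")[[1]]
    bad <- which(!chars %in% .aaAlphabet())
    if (length(bad))
      stop(sprintf("illegal amino-acid character '%s' at position %d",
                   chars[bad[1]], bad[1]))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = .blosum50(),
    gapOpening = 0, gapExtension = gap)
  score <- Biostrings::score(al)
  list(score = score,
       alignedA = as.character(Biostrings::alignedPattern(al)),
       alignedB = as.character(Biostrings::alignedSubject(al)),
       matched = score >= 0)
}

#' Within-category gene pairs
#'
#' All unordered pairs of genes inside each listed category that have a
#' sequence available. A pair occurring in several categories is listed
#' once per category (and scored once downstream).
#'
#' @param annotation a [GeneAnnotation-class].
#' @param categories category ids to enumerate.
#' @param sequences named character vector of protein sequences (one per
#'   gene id).
#' @return data.frame `geneA`, `geneB`, `category` (geneA < geneB
#'   lexicographically).
#' @export
familyPairs <- function(annotation, categories, sequences) {
  rows <- list()
  for (cid in categories) {
    genes <- intersect(categoryGenes(annotation, cid), names(sequences))
    if (length(genes) < 2L) {
      message("category ", cid, " has fewer than 2 sequenced genes; skipped")
      next
    }
    genes <- sort(genes)
    cmb <- utils::combn(genes, 2L)
    rows[[cid]] <- data.frame(geneA = cmb[1, ], geneB = cmb[2, ],
                              category = cid, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(geneA = character(0), geneB = character(0),
                      category = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Spatial correlation of two genes' regional patterns
#'
#' Pearson correlation across regions of the two genes' expression at one
#' timepoint, over regions where both are observed. Returns `NA` when
#' fewer than 3 common regions exist or either vector has zero variance.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param geneA,geneB gene ids.
#' @param timepoint timepoint label.
#' @return Pearson r, or `NA`.
#' @export
spatialCorrelation <- function(dataset, geneA, geneB, timepoint) {
  for (g in c(geneA, geneB))
    if (!g %in% geneIds(dataset)) stop("unknown gene: ", g)
  if (!timepoint %in% timeLabels(dataset))
    stop("unknown timepoint: ", timepoint)
  a <- exprValues(dataset)[geneA, , timepoint]
  b <- exprValues(dataset)[geneB, , timepoint]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])
}

#' Family-pair table: sequence similarity vs spatial correlation
#'
#' For every within-category gene pair, the global alignment score, the
#' family-match flag, and the spatial correlation at the two peak-
#' dissimilarity timepoints (by default the first and last developmental
#' ages). Pairs are additionally stratified: `"similar-anticorrelated"`
#' (match and r < -0.2 at the first timepoint), `"similar-correlated"`
#' (match and r > 0.2), otherwise `"other"`.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param annotation a [GeneAnnotation-class].
#' @param sequences named character vector of protein sequences.
#' @param categories category ids whose gene pairs are tabulated.
#' @param timepoints two timepoint labels (default: first and last of the
#'   dataset).
#' @param gap linear gap penalty for the alignment.
#' @param corThreshold stratum cutoff on the first-timepoint correlation.
#' @return data.frame `geneA`, `geneB`, `category`, `score`, `matched`,
#'   `rT1`, `rT2`, `stratum`.
#' @export
buildFamilyTable <- function(dataset, annotation, sequences, categories,
                             timepoints = NULL, gap = 8, corThreshold = 0.2) {
  if (is.null(timepoints)) {
    tl <- timeLabels(dataset)
    timepoints <- c(tl[1], tl[length(tl)])
  }
  stopifnot(length(timepoints) == 2L)
  pairs <- familyPairs(annotation, categories, sequences)
  if (nrow(pairs) == 0L)
    return(data.frame(geneA = character(0), geneB = character(0),
                      category = character(0), score = numeric(0),
                      matched = logical(0), rT1 = numeric(0),
                      rT2 = numeric(0), stratum = character(0)))
  # each distinct pair scored once, listed per category
  key <- paste(pairs$geneA, pairs$geneB, sep = "\r")
  uniq <- !duplicated(key)
  scoreOf <- setNames(vapply(which(uniq), function(i)
    needlemanWunsch(sequences[[pairs$geneA[i]]],
                    sequences[[pairs$geneB[i]]], gap = gap)$score,
    numeric(1)), key[uniq])
  inDs <- pairs$geneA %in% geneIds(dataset) & pairs$geneB %in% geneIds(dataset)
  r1 <- rep(NA_real_, nrow(pairs)); r2 <- r1
  r1[inDs] <- mapply(function(a, b)
    spatialCorrelation(dataset, a, b, timepoints[1]),
    pairs$geneA[inDs], pairs$geneB[inDs])
  r2[inDs] <- mapply(function(a, b)
    spatialCorrelation(dataset, a, b, timepoints[2]),
    pairs$geneA[inDs], pairs$geneB[inDs])
  score <- unname(scoreOf[key])
  matched <- score >= 0
  stratum <- ifelse(matched & !is.na(r1) & r1 < -corThreshold,
                    "similar-anticorrelated",
                    ifelse(matched & !is.na(r1) & r1 > corThreshold,
                           "similar-correlated", "other"))
  data.frame(geneA = pairs$geneA, geneB = pairs$geneB,
             category = pairs$category, score = score, matched = matched,
             rT1 = r1, rT2 = r2, stratum = stratum,
             stringsAsFactors = FALSE)
}
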