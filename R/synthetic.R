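# Seeded synthetic expression generator with planted structure: a U-shaped
# temporal envelope of region-specific signal split between an embryonic
# "construction" program and a postnatal "plasticity" program, lineage
# blocks of regions sharing a gene-loading signature, planted GO-enriched
# categories with matched distractors, anti-correlated paralog pairs, and
# an optional postnatally diverging ("breakaway") region.

.defaultTimepoints <- c("E11.5", "E13.5", "E15.5", "E18.5", "P4", "P14", "P28")

# symmetric U over nT points: 1 at the ends, ~0 at the middle
.defaultEnvelope <- function(nT) {
  r <- seq(0, 1, length.out = nT)
  (2 * abs(r - 0.5))^1.5
}

#' Build and validate a synthetic-data configuration
#'
#' The defaults define the study conditions every downstream module is
#' exercised under: 200 genes x 12 regions x 7 developmental timepoints, a
#' U-shaped envelope of region-specific signal (high embryonically, near
#' zero mid-series, rising postnatally), 30% construction genes (signal
#' follows the declining limb), 30% plasticity genes (rising limb), the
#' rest null, four lineage blocks, one planted GO category per program
#' (size 20) plus matched random distractors, four paralog pairs at target
#' spatial correlation -0.6, and additive Gaussian noise (sd 0.1 on the
#' density scale, clipped at 0).
#'
#' @param nGenes,nRegions dimensions of the tensor.
#' @param timepoints ordered character labels of the developmental axis.
#' @param envelope non-negative numeric, one value per timepoint: the
#'   region-specific signal magnitude over time (default U-shaped).
#' @param fracConstruction,fracPlasticity fractions of genes in the
#'   embryonic / postnatal program (sum <= 1; the rest are null genes).
#' @param nLineageBlocks number of region blocks sharing an origin tag and
#'   a block gene-loading signature.
#' @param lineageSd magnitude of the shared block loading (0 disables).
#' @param plantedCategorySize genes per planted GO category (one category
#'   per program); 0 disables planted categories.
#' @param plantedPatternScale multiplier on the region-loading magnitude of
#'   planted-category genes; > 1 makes each planted category a coherent
#'   contribution-profile cluster of its own.
#' @param nDistractorCategories random same-size categories emitted as a
#'   calibrated enrichment null.
#' @param nParalogPairs number of planted paralog pairs.
#' @param paralogCor target spatial correlation of paralog region loadings.
#' @param breakawayRegion index (1-based) of a region whose region-specific
#'   loading is amplified postnatally, or `NA` to disable.
#' @param breakawayFactor per-timepoint multiplier of the breakaway driver
#'   amplitude: the loading magnitude is multiplied by this factor at each
#'   successive postnatal timepoint. The default (3.6) makes the planted
#'   divergence outpace the brain-wide postnatal rise in dissimilarity, so
#'   the region's *normalized* specialization index keeps increasing.
#' @param breakawayBase driver loading amplitude (density units) at the
#'   first postnatal timepoint.
#' @param nBreakawayGenes number of driver genes carrying the breakaway
#'   amplification.
#' @param postnatalFrom index of the first postnatal timepoint.
#' @param noiseSd standard deviation of additive Gaussian noise on the
#'   density scale.
#' @param baselineRange range of the gene-specific constant baseline
#'   (uniform draw), shared across regions.
#' @param seed integer seed; fully determines the output.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nGenes = 200L, nRegions = 12L,
                            timepoints = .defaultTimepoints,
                            envelope = NULL,
                            fracConstruction = 0.3, fracPlasticity = 0.3,
                            nLineageBlocks = 4L, lineageSd = 0.25,
                            plantedCategorySize = 20L,
                            plantedPatternScale = 2,
                            nDistractorCategories = 10L,
                            nParalogPairs = 4L, paralogCor = -0.6,
                            breakawayRegion = NA_integer_,
                            breakawayFactor = 3.6, breakawayBase = 0.15,
                            nBreakawayGenes = 15L,
                            postnatalFrom = 5L,
                            noiseSd = 0.1,
                            baselineRange = c(1, 3),
                            seed = 1L) {
  nT <- length(timepoints)
  if (is.null(envelope)) envelope <- .defaultEnvelope(nT)
  if (length(envelope) != nT)
    stop("envelope must have one value per timepoint")
  if (any(envelope < 0)) stop("envelope must be non-negative")
  if (fracConstruction + fracPlasticity > 1 + 1e-12)
    stop("program fractions must sum to <= 1")
  if (!is.na(breakawayRegion) &&
      (breakawayRegion < 1L || breakawayRegion > nRegions))
    stop("breakawayRegion out of range")
  params <- list(nGenes = as.integer(nGenes), nRegions = as.integer(nRegions),
                 timepoints = as.character(timepoints), envelope = envelope,
                 fracConstruction = fracConstruction,
                 fracPlasticity = fracPlasticity,
                 nLineageBlocks = as.integer(nLineageBlocks),
                 lineageSd = lineageSd,
                 plantedCategorySize = as.integer(plantedCategorySize),
                 plantedPatternScale = plantedPatternScale,
                 nDistractorCategories = as.integer(nDistractorCategories),
                 nParalogPairs = as.integer(nParalogPairs),
                 paralogCor = paralogCor,
                 breakawayRegion = as.integer(breakawayRegion),
                 breakawayFactor = breakawayFactor,
                 breakawayBase = breakawayBase,
                 nBreakawayGenes = as.integer(nBreakawayGenes),
                 postnatalFrom = as.integer(postnatalFrom),
                 noiseSd = noiseSd, baselineRange = baselineRange,
                 seed = as.integer(seed))
  new("SyntheticConfig", params = params)
}

#' @describeIn SyntheticConfig-class compact display
#' @param object a SyntheticConfig.
#' @export
setMethod("show", "SyntheticConfig", function(object) {
  p <- object@params
  cat(sprintf("SyntheticConfig: %d genes x %d regions x %d timepoints, seed %d\n",
              p$nGenes, p$nRegions, length(p$timepoints), p$seed))
})

# program-specific temporal envelopes: the construction program carries the
# declining (embryonic) limb of the U, the plasticity program the rising
# (postnatal) limb; beyond its own limb each program stays at the U's floor.
.programEnvelopes <- function(envelope) {
  mid <- which.min(envelope)
  floorVal <- envelope[mid]
  early <- envelope; early[seq_along(envelope) > mid] <- floorVal
  late <- envelope; late[seq_along(envelope) < mid] <- floorVal
  list(construction = early, plasticity = late)
}

#' Generate a synthetic expression dataset with planted structure
#'
#' The value at `(g, r, t)` is
#' `baseline_g + env_g(t) * pattern_g(r) + block_b(r)(g) + noise`, clipped
#' at 0, where `pattern_g` is a fixed standard-normal region loading,
#' `env_g` the program envelope of gene `g` (construction genes follow the
#' declining limb of the U, plasticity genes the rising limb, null genes
#' are flat), and `block_b(g)` a gene loading shared by all regions of
#' lineage block `b`. Paralog pairs get region loadings with the configured
#' target correlation; breakaway driver genes get an extra loading on the
#' breakaway region that ramps up postnatally.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with elements `dataset` (an [ExpressionDataset-class]),
#'   `truth` (ground-truth list: `program` per gene, `originBlock` per
#'   region, `categories` (planted + distractor gene sets), `paralogPairs`,
#'   `breakaway` (region + driver genes), `envelope`), `annotationTable`
#'   (data.frame gene/term for the planted and distractor categories) and
#'   `ontologyTable` (data.frame child/parent/origin for the region
#'   blocks).
#' @examples
#' res <- generateDataset(syntheticConfig(nGenes = 50, nRegions = 6, seed = 7))
#' res$dataset
#' @export
generateDataset <- function(config) {
  p <- config@params
  set.seed(p$seed)
  nG <- p$nGenes; nR <- p$nRegions; tps <- p$timepoints; nT <- length(tps)
  genes <- sprintf("g%03d", seq_len(nG))
  regions <- sprintf("r%02d", seq_len(nR))

  # program assignment
  nCon <- round(p$fracConstruction * nG)
  nPla <- round(p$fracPlasticity * nG)
  program <- rep("null", nG)
  program[seq_len(nCon)] <- "construction"
  if (nPla > 0) program[nCon + seq_len(nPla)] <- "plasticity"
  names(program) <- genes

  envs <- .programEnvelopes(p$envelope)
  envMat <- matrix(0, nG, nT)            # gene x timepoint envelope
  if (any(program == "construction"))
    envMat[program == "construction", ] <-
      matrix(envs$construction, sum(program == "construction"), nT, byrow = TRUE)
  if (any(program == "plasticity"))
    envMat[program == "plasticity", ] <-
      matrix(envs$plasticity, sum(program == "plasticity"), nT, byrow = TRUE)

  # region loadings; paralog pairs get correlated loadings
  pattern <- matrix(rnorm(nG * nR), nG, nR, dimnames = list(genes, regions))
  paralogPairs <- NULL
  if (p$nParalogPairs > 0) {
    conGenes <- which(program == "construction")
    if (length(conGenes) < 2 * p$nParalogPairs)
      stop("not enough construction genes for the requested paralog pairs")
    pick <- conGenes[seq_len(2 * p$nParalogPairs)]
    a <- pick[seq_len(p$nParalogPairs) * 2 - 1]
    b <- pick[seq_len(p$nParalogPairs) * 2]
    rho <- p$paralogCor
    for (i in seq_len(p$nParalogPairs)) {
      # plant the *empirical* correlation: orthogonalize a fresh draw
      # against the partner loading, standardize both, and mix
      x <- pattern[a[i], ]
      z <- rnorm(nR)
      z <- z - mean(z) - cor(z, x) * sd(z) / sd(x) * (x - mean(x))
      xs <- (x - mean(x)) / sd(x)
      zs <- z / sd(z)
      pattern[b[i], ] <- rho * xs + sqrt(1 - rho^2) * zs
    }
    paralogPairs <- data.frame(geneA = genes[a], geneB = genes[b],
                               targetCor = rho, stringsAsFactors = FALSE)
  }

  # lineage blocks: contiguous region blocks sharing a gene-loading vector
  blockOf <- sort(rep_len(seq_len(p$nLineageBlocks), nR))
  originTags <- rep_len(c("forebrain-telencephalon", "forebrain-diencephalon",
                          "midbrain", "hindbrain"), p$nLineageBlocks)
  originBlock <- setNames(originTags[blockOf], regions)
  blockLoad <- matrix(rnorm(nG * p$nLineageBlocks, sd = p$lineageSd),
                      nG, p$nLineageBlocks)

  # breakaway region: driver genes carry an extra positive loading on one
  # region whose amplitude is multiplied by breakawayFactor at each
  # successive postnatal timepoint, so the region's specialization keeps
  # outpacing the brain-wide postnatal rise in dissimilarity.
  breakaway <- NULL
  rampVec <- rep(0, nT)
  if (!is.na(p$breakawayRegion)) {
    nPost <- nT - p$postnatalFrom + 1L
    rampVec[p$postnatalFrom:nT] <-
      p$breakawayBase * p$breakawayFactor^(seq_len(nPost) - 1L)
    drivers <- genes[nG - seq_len(p$nBreakawayGenes) + 1L]  # from null tail
    driverLoad <- runif(p$nBreakawayGenes, 2, 3)  # positive: no clipping loss
    breakaway <- list(region = regions[p$breakawayRegion],
                      drivers = drivers, factor = p$breakawayFactor)
  }

  # planted GO categories aligned with the programs + random distractors
  categories <- list()
  annRows <- list()
  if (p$plantedCategorySize > 0) {
    cs <- p$plantedCategorySize
    conPool <- genes[program == "construction"]
    plaPool <- genes[program == "plasticity"]
    if (length(conPool) >= cs)
      categories[["CAT:construction"]] <- conPool[seq_len(cs)]
    if (length(plaPool) >= cs)
      categories[["CAT:plasticity"]] <- plaPool[seq_len(cs)]
    for (i in seq_len(p$nDistractorCategories))
      categories[[sprintf("CAT:distractor%02d", i)]] <- sample(genes, cs)
  }
  # planted-category genes carry an amplified region loading so the
  # category forms a coherent, distinguishable contribution-profile
  # cluster rather than dissolving into its parent program
  plantedIds <- grep("^CAT:(construction|plasticity)$", names(categories),
                     value = TRUE)
  if (length(plantedIds) && p$plantedPatternScale != 1) {
    pg <- unique(unlist(categories[plantedIds], use.names = FALSE))
    pattern[pg, ] <- pattern[pg, ] * p$plantedPatternScale
  }

  baseline <- runif(nG, p$baselineRange[1], p$baselineRange[2])

  arr <- array(0, dim = c(nG, nR, nT), dimnames = list(genes, regions, tps))
  for (t in seq_len(nT)) {
    slice <- baseline + envMat[, t] * pattern + blockLoad[, blockOf]
    if (!is.null(breakaway) && rampVec[t] > 0) {
      ri <- p$breakawayRegion
      gi <- match(breakaway$drivers, genes)
      slice[gi, ri] <- slice[gi, ri] + rampVec[t] * driverLoad
    }
    if (p$noiseSd > 0)
      slice <- slice + matrix(rnorm(nG * nR, sd = p$noiseSd), nG, nR)
    arr[, , t] <- pmax(slice, 0)
  }

  for (cid in names(categories))
    annRows[[cid]] <- data.frame(gene = categories[[cid]], term = cid,
                                 stringsAsFactors = FALSE)
  annotationTable <- if (length(annRows)) do.call(rbind, c(annRows,
    list(make.row.names = FALSE))) else
    data.frame(gene = character(0), term = character(0))

  ontologyTable <- data.frame(child = regions, parent = "brain",
                              origin = originBlock, stringsAsFactors = FALSE)

  truth <- list(program = program, originBlock = originBlock,
                categories = categories,
                plantedCategoryIds = grep("^CAT:(construction|plasticity)$",
                                          names(categories), value = TRUE),
                paralogPairs = paralogPairs, breakaway = breakaway,
                envelope = p$envelope)
  list(dataset = ExpressionDataset(arr, species = "synthetic-A"),
       truth = truth, annotationTable = annotationTable,
       ontologyTable = ontologyTable)
}

#' Generate a time-warped second-species counterpart
#'
#' Emulates a second species measured on its own developmental timeline:
#' the counterpart's expression at warped timepoint `warp[i]` equals the
#' source expression at source timepoint `i` plus Gaussian noise;
#' counterpart timepoints between two mapped positions are linear
#' interpolations of the flanking source timepoints. An identity ortholog
#' map is emitted.
#'
#' @param dataset source [ExpressionDataset-class].
#' @param warp strictly increasing integer vector, one target position per
#'   source timepoint; the counterpart grid spans `min(warp):max(warp)`.
#' @param noiseSd additive Gaussian noise sd on the counterpart.
#' @param seed integer seed.
#' @param targetLabels optional labels for the counterpart timepoints
#'   (default `"H<position>"`).
#' @return list with `dataset` (counterpart [ExpressionDataset-class]) and
#'   `orthologs` (identity [OrthologMap-class]).
#' @export
generateCounterpart <- function(dataset, warp, noiseSd = 0, seed = 1L,
                                targetLabels = NULL) {
  nT <- length(timeLabels(dataset))
  if (length(warp) != nT)
    stop("warp must map every source timepoint")
  warp <- as.numeric(warp)
  if (any(diff(warp) <= 0))
    stop("warp must be strictly increasing (monotone)")
  grid <- seq(from = min(warp), to = max(warp))
  labs <- if (is.null(targetLabels)) sprintf("H%d", grid) else targetLabels
  if (length(labs) != length(grid))
    stop("targetLabels must match the counterpart grid length")
  v <- exprValues(dataset)
  set.seed(seed)
  out <- array(NA_real_, dim = c(dim(v)[1], dim(v)[2], length(grid)),
               dimnames = list(dimnames(v)[[1]], dimnames(v)[[2]], labs))
  for (j in seq_along(grid)) {
    pos <- grid[j]
    i <- findInterval(pos, warp)
    if (warp[i] == pos) {
      slice <- v[, , i]
    } else {                          # between warp[i] and warp[i+1]
      w <- (pos - warp[i]) / (warp[i + 1] - warp[i])
      slice <- (1 - w) * v[, , i] + w * v[, , i + 1]
    }
    if (noiseSd > 0)
      slice <- pmax(slice + matrix(rnorm(length(slice), sd = noiseSd),
                                   nrow(slice), ncol(slice)), 0)
    out[, , j] <- slice
  }
  orth <- new("OrthologMap",
              pairs = data.frame(source = geneIds(dataset),
                                 target = geneIds(dataset),
                                 stringsAsFactors = FALSE))
  list(dataset = ExpressionDataset(out, species = "synthetic-B"),
       orthologs = orth)
}
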