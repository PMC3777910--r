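#' @import methods
#' @importFrom stats cor sd median quantile p.adjust phyper wilcox.test kmeans
#'   lm coef aov rnorm runif approx complete.cases setNames cmdscale
#' @importFrom utils read.delim write.table head
NULL

#' Gene x region x timepoint expression dataset
#'
#' Container for spatially and temporally resolved expression densities:
#' a three-way array indexed by gene, region and developmental timepoint.
#' Missing measurements are explicit `NA` entries (never silent zeros) and
#' all observed values are non-negative. Timepoints are opaque ordered
#' labels (e.g. `"E11.5"` ... `"P56"`); their declared order is the
#' developmental order used by every downstream statistic.
#'
#' @slot values numeric 3-way array, `gene x region x timepoint`, with
#'   complete dimnames; `NA` marks a missing measurement.
#' @slot species single character label for the organism.
#'
#' @seealso [ExpressionDataset()] for construction, [readExpression()] to
#'   load from a long-format table.
#' @export
setClass("ExpressionDataset",
  representation(values = "array", species = "character"))

setValidity("ExpressionDataset", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("'values' must be a 3-way array (gene x region x timepoint)")
  dn <- dimnames(v)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    return("'values' must have complete dimnames on all three axes")
  for (ax in seq_len(3L))
    if (anyDuplicated(dn[[ax]]))
      return(sprintf("duplicated labels on axis %d", ax))
  if (any(v < 0, na.rm = TRUE))
    return("expression densities must be non-negative")
  if (length(object@species) != 1L)
    return("'species' must be a single label")
  TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values 3-way numeric array (`gene x region x timepoint`) with
#'   dimnames; `NA` entries mark missing measurements.
#' @param species organism label.
#' @return An [ExpressionDataset-class] object.
#' @examples
#' v <- array(runif(8), dim = c(2, 2, 2),
#'            dimnames = list(c("g1", "g2"), c("r1", "r2"), c("t1", "t2")))
#' ExpressionDataset(v, species = "mouse")
#' @export
ExpressionDataset <- function(values, species = "unspecified") {
  new("ExpressionDataset", values = values, species = as.character(species))
}

#' Rooted region ontology with embryonic-origin tags
#'
#' A rooted tree over anatomical region identifiers. Each node maps to its
#' parent (the root maps to `NA`) and carries an embryonic-origin tag
#' (e.g. forebrain-telencephalon, hindbrain), inherited from the nearest
#' tagged ancestor where not given explicitly.
#'
#' @slot parent named character; `parent[node]` is the parent id, `NA` for
#'   the root.
#' @slot origin named character; embryonic-origin tag per node.
#' @export
setClass("RegionOntology",
  representation(parent = "character", origin = "character"))

setValidity("RegionOntology", function(object) {
  nodes <- names(object@parent)
  if (is.null(nodes) || anyDuplicated(nodes))
    return("'parent' must be named by unique node ids")
  roots <- nodes[is.na(object@parent)]
  if (length(roots) != 1L)
    return(sprintf("ontology must have exactly one root (found %d)",
                   length(roots)))
  known <- object@parent[!is.na(object@parent)]
  if (!all(known %in% nodes))
    return("every parent id must itself be a node")
  # cycle check: walk up from each node, bounded by node count
  for (n in nodes) {
    cur <- n
    for (i in seq_along(nodes)) {
      cur <- object@parent[[cur]]
      if (is.na(cur)) break
    }
    if (!is.na(cur)) return("ontology contains a cycle")
  }
  if (!identical(sort(names(object@origin)), sort(nodes)))
    return("'origin' must tag every node")
  TRUE
})

#' Gene Ontology annotations with DAG
#'
#' Gene-to-category annotations together with the category DAG. On
#' construction via [readAnnotations()], annotations are propagated to all
#' ancestor categories (the true-path rule), so membership tests never need
#' to walk the DAG again.
#'
#' @slot gene2cat named list; for each gene, the character vector of
#'   annotated category ids (ancestors included).
#' @slot parents named list; for each category id, the character vector of
#'   parent category ids (empty for roots).
#' @slot catNames named character; human-readable name per category id.
#' @export
setClass("GeneAnnotation",
  representation(gene2cat = "list", parents = "list", catNames = "character"))

setValidity("GeneAnnotation", function(object) {
  cats <- names(object@parents)
  used <- unique(unlist(object@gene2cat, use.names = FALSE))
  if (length(used) && !all(used %in% cats))
    return("annotated categories must all exist in the DAG")
  TRUE
})

#' Ortholog gene correspondence between two species
#'
#' @slot pairs data.frame with character columns `source` and `target`;
#'   duplicate rows removed.
#' @export
setClass("OrthologMap", representation(pairs = "data.frame"))

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  if (!all(c("source", "target") %in% names(p)))
    return("'pairs' needs columns 'source' and 'target'")
  if (anyDuplicated(p[c("source", "target")]))
    return("duplicate ortholog pairs")
  TRUE
})

#' Per-timepoint inter-region dissimilarity matrices
#'
#' One symmetric region x region matrix per timepoint, with entries
#' `d(R1, R2) = 1 - PCC` of the two regions' gene-expression vectors
#' (pairwise-complete genes). Entries are `NA` where fewer than three
#' commonly observed genes exist or a region vector has zero variance.
#'
#' @slot matrices named list of symmetric numeric matrices, one per
#'   timepoint, each with region dimnames.
#' @export
setClass("DissimilaritySet", representation(matrices = "list"))

setValidity("DissimilaritySet", function(object) {
  for (tp in names(object@matrices)) {
    m <- object@matrices[[tp]]
    if (!is.matrix(m) || nrow(m) != ncol(m))
      return(sprintf("matrix at '%s' is not square", tp))
    if (!isTRUE(all.equal(m, t(m))))
      return(sprintf("matrix at '%s' is not symmetric", tp))
    rng <- range(m, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < -1e-8 || rng[2] > 2 + 1e-8))
      return(sprintf("dissimilarities at '%s' outside [0, 2]", tp))
  }
  TRUE
})

#' Configuration for the synthetic expression generator
#'
#' Bundles every knob of [generateDataset()]: dimensions, the temporal
#' envelope of region-specific signal, the split of genes into
#' "construction" (embryonic) and "plasticity" (postnatal) programs,
#' lineage blocks, planted GO categories, paralog pairs, an optional
#' postnatally diverging ("breakaway") region, the noise level and the
#' seed. See [syntheticConfig()] for defaults and units.
#'
#' @slot params named list of validated generator parameters.
#' @export
setClass("SyntheticConfig", representation(params = "list"))

#' @describeIn ExpressionDataset-class compact display
#' @param object an object of the documented class.
#' @export
setMethod("show", "ExpressionDataset", function(object) {
  d <- dim(object@values)
  nmiss <- sum(is.na(object@values))
  cat(sprintf(
    "ExpressionDataset (%s): %d genes x %d regions x %d timepoints; %d missing (%.1f%%)\n",
    object@species, d[1], d[2], d[3], nmiss, 100 * nmiss / length(object@values)))
  cat("timepoints:", paste(dimnames(object@values)[[3]], collapse = " "), "\n")
})

#' @describeIn RegionOntology-class compact display
#' @param object an object of the documented class.
#' @export
setMethod("show", "RegionOntology", function(object) {
  cat(sprintf("RegionOntology: %d nodes, %d leaves, root '%s'\n",
              length(object@parent), length(leafNodes(object)),
              names(object@parent)[is.na(object@parent)]))
})

#' @describeIn GeneAnnotation-class compact display
#' @param object an object of the documented class.
#' @export
setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation: %d genes, %d categories in DAG\n",
              length(object@gene2cat), length(object@parents)))
})

#' @describeIn DissimilaritySet-class compact display
#' @param object an object of the documented class.
#' @export
setMethod("show", "DissimilaritySet", function(object) {
  cat(sprintf("DissimilaritySet: %d timepoints (%s)\n",
              length(object@matrices),
              paste(names(object@matrices), collapse = " ")))
})

#' @describeIn OrthologMap-class compact display
#' @param object an object of the documented class.
#' @export
setMethod("show", "OrthologMap", function(object) {
  cat(sprintf("OrthologMap: %d pairs\n", nrow(object@pairs)))
})
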