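# Accessor generics: downstream code never touches slots directly.

#' Gene identifiers of a dataset
#' @param x an [ExpressionDataset-class].
#' @return character vector of gene ids, in declared order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname geneIds
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) dimnames(x@values)[[1]])

#' Region identifiers of a dataset
#' @param x an [ExpressionDataset-class].
#' @return character vector of region ids, in declared order.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname regionIds
#' @export
setMethod("regionIds", "ExpressionDataset", function(x) dimnames(x@values)[[2]])

#' Timepoint labels in developmental order
#' @param x an [ExpressionDataset-class] or [DissimilaritySet-class].
#' @return character vector of ordered timepoint labels.
#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))
#' @rdname timeLabels
#' @export
setMethod("timeLabels", "ExpressionDataset", function(x) dimnames(x@values)[[3]])
#' @rdname timeLabels
#' @export
setMethod("timeLabels", "DissimilaritySet", function(x) names(x@matrices))

#' Expression values as a 3-way array
#' @param x an [ExpressionDataset-class].
#' @return numeric array `gene x region x timepoint` (`NA` = missing).
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionDataset", function(x) x@values)

#' Species label
#' @param x an [ExpressionDataset-class].
#' @return single character label.
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))
#' @rdname speciesLabel
#' @export
setMethod("speciesLabel", "ExpressionDataset", function(x) x@species)

#' Per-timepoint dissimilarity matrices
#' @param x a [DissimilaritySet-class].
#' @return named list of symmetric matrices, one per timepoint.
#' @export
setGeneric("dissimMatrices", function(x) standardGeneric("dissimMatrices"))
#' @rdname dissimMatrices
#' @export
setMethod("dissimMatrices", "DissimilaritySet", function(x) x@matrices)

#' Leaf nodes of a region ontology
#' @param x a [RegionOntology-class].
#' @return character vector of leaf region ids.
#' @export
setGeneric("leafNodes", function(x) standardGeneric("leafNodes"))
#' @rdname leafNodes
#' @export
setMethod("leafNodes", "RegionOntology", function(x) {
  nodes <- names(x@parent)
  nodes[!(nodes %in% x@parent[!is.na(x@parent)])]
})

#' Embryonic-origin tag of ontology nodes
#' @param x a [RegionOntology-class].
#' @param nodes node ids (default: all).
#' @return named character vector of origin tags.
#' @export
setGeneric("originOf", function(x, nodes) standardGeneric("originOf"))
#' @rdname originOf
#' @export
setMethod("originOf", "RegionOntology", function(x, nodes) {
  if (missing(nodes)) return(x@origin)
  bad <- setdiff(nodes, names(x@origin))
  if (length(bad)) stop("unknown ontology nodes: ", paste(bad, collapse = ", "))
  x@origin[nodes]
})

#' Ortholog pairs as a data.frame
#' @param x an [OrthologMap-class].
#' @return data.frame with columns `source`, `target`.
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))
#' @rdname orthologPairs
#' @export
setMethod("orthologPairs", "OrthologMap", function(x) x@pairs)

#' Gene-to-category annotation list
#' @param x a [GeneAnnotation-class].
#' @return named list mapping each gene to its category ids (ancestors
#'   included).
#' @export
setGeneric("geneCategories", function(x) standardGeneric("geneCategories"))
#' @rdname geneCategories
#' @export
setMethod("geneCategories", "GeneAnnotation", function(x) x@gene2cat)

#' Genes annotated to one category
#' @param x a [GeneAnnotation-class].
#' @param category a category id.
#' @return character vector of gene ids annotated to `category` (directly
#'   or through a descendant).
#' @export
setGeneric("categoryGenes", function(x, category) standardGeneric("categoryGenes"))
#' @rdname categoryGenes
#' @export
setMethod("categoryGenes", "GeneAnnotation", function(x, category) {
  names(x@gene2cat)[vapply(x@gene2cat, function(cc) category %in% cc, logical(1))]
})
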