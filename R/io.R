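# Readers and writers for the long-format expression tables, region
# ontologies, GO annotations + OBO DAG, ortholog maps and protein FASTA.
# Dialect: UTF-8 TSV (CSV accepted by extension), header row required,
# '.' decimal, a missing (gene, region, timepoint) cell is encoded by row
# absence. Identifier matching is exact and case-sensitive throughout.

.delimFor <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a long-format expression table
#'
#' Reads a TSV/CSV with columns `gene`, `region`, `timepoint`, `value` into
#' an [ExpressionDataset-class]. Axis orders follow first appearance in the
#' file; the timepoint order of the file is taken as the developmental
#' order. Combinations absent from the file become `NA` (missing), never 0.
#'
#' @param path path to the table (`.tsv` or `.csv`).
#' @param species organism label stored on the dataset.
#' @return An [ExpressionDataset-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tregion\ttimepoint\tvalue",
#'              "g1\tr1\tE11.5\t0.5", "g1\tr1\tP4\t0.25"), tf)
#' readExpression(tf, species = "mouse")
#' @export
readExpression <- function(path, species = "unspecified") {
  df <- read.delim(path, sep = .delimFor(path), header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  need <- c("gene", "region", "timepoint", "value")
  if (!all(need %in% names(df)))
    stop("expression table must have columns ", paste(need, collapse = ", "))
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val) & !is.na(df$value))
  if (length(bad))
    stop(sprintf("malformed value at data line %d: '%s'", bad[1], df$value[bad[1]]))
  neg <- which(val < 0)
  if (length(neg))
    stop(sprintf("negative expression density at data line %d (%s)",
                 neg[1], df$value[neg[1]]))
  genes <- unique(df$gene); regions <- unique(df$region)
  tps <- unique(df$timepoint)
  key <- paste(df$gene, df$region, df$timepoint, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (gene, region, timepoint) row at data line %d: %s/%s/%s",
                 dup[1], df$gene[dup[1]], df$region[dup[1]], df$timepoint[dup[1]]))
  arr <- array(NA_real_, dim = c(length(genes), length(regions), length(tps)),
               dimnames = list(genes, regions, tps))
  arr[cbind(match(df$gene, genes), match(df$region, regions),
            match(df$timepoint, tps))] <- val
  ExpressionDataset(arr, species = species)
}

#' Write an expression dataset to the canonical long-format TSV
#'
#' Missing cells are omitted; values are printed with `%.17g` so that a
#' write/read/write cycle is byte-identical.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(dataset, path) {
  v <- exprValues(dataset)
  dn <- dimnames(v)
  idx <- which(!is.na(v), arr.ind = TRUE)
  # canonical order: timepoint within region within gene, in axis order
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  lines <- c("gene\tregion\ttimepoint\tvalue",
             sprintf("%s\t%s\t%s\t%.17g",
                     dn[[1]][idx[, 1]], dn[[2]][idx[, 2]], dn[[3]][idx[, 3]],
                     v[idx]))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a region ontology from a child-parent table
#'
#' Expects TSV/CSV columns `child`, `parent`, `origin` (origin may be
#' empty). The root is the unique node that appears as a parent but never
#' as a child, or a row whose parent field is empty. Empty origins are
#' inherited from the nearest tagged ancestor.
#'
#' @param path path to the table.
#' @return A [RegionOntology-class].
#' @export
readOntology <- function(path) {
  df <- read.delim(path, sep = .delimFor(path), header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!all(c("child", "parent") %in% names(df)))
    stop("ontology table must have columns child, parent[, origin]")
  if (!"origin" %in% names(df)) df$origin <- ""
  df$origin[is.na(df$origin)] <- ""
  parent <- setNames(df$parent, df$child)
  parent[parent == "" | is.na(parent)] <- NA_character_
  # parents never listed as children are implicit nodes
  implicit <- setdiff(parent[!is.na(parent)], names(parent))
  if (length(implicit) > 1L)
    stop("multiple roots: ", paste(implicit, collapse = ", "))
  if (length(implicit) == 1L)
    parent[implicit] <- NA_character_
  roots <- names(parent)[is.na(parent)]
  if (length(roots) == 0L) stop("ontology has no root")
  if (length(roots) > 1L)
    stop("multiple roots: ", paste(roots, collapse = ", "))
  # explicit origins, then inherit downwards
  origin <- setNames(rep(NA_character_, length(parent)), names(parent))
  tagged <- df$child[df$origin != ""]
  origin[tagged] <- df$origin[df$origin != ""]
  resolve <- function(n) {
    seen <- character(0)
    cur <- n
    while (!is.na(cur)) {
      if (cur %in% seen) stop("ontology contains a cycle through '", cur, "'")
      if (!is.na(origin[[cur]])) return(origin[[cur]])
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
    NA_character_
  }
  for (n in names(parent)) origin[n] <- resolve(n)
  origin[is.na(origin)] <- "untagged"
  new("RegionOntology", parent = parent, origin = origin)
}

#' Level-k cut of a region ontology
#'
#' Level 1 is the leaf set; level k maps each leaf to its ancestor `k - 1`
#' steps up (capped at the root). The cut is returned as a named list:
#' one element per cut node, holding the leaves it absorbs — a partition
#' of the leaf set at every level.
#'
#' @param ontology a [RegionOntology-class].
#' @param level integer >= 1.
#' @return named list of character vectors (leaves per cut node).
#' @export
levelCut <- function(ontology, level = 1L) {
  stopifnot(level >= 1L)
  leaves <- leafNodes(ontology)
  anc <- vapply(leaves, function(lf) {
    cur <- lf
    for (i in seq_len(level - 1L)) {
      p <- ontology@parent[[cur]]
      if (is.na(p)) break
      cur <- p
    }
    cur
  }, character(1))
  split(leaves, factor(anc, levels = unique(anc)))
}

#' Path distance between embryonic origins
#'
#' Distance on the fixed embryonic lineage tree with unit branch lengths:
#' telencephalon and diencephalon under the forebrain node, midbrain and
#' hindbrain directly under the root. Identical origins have distance 0.
#'
#' @param originA,originB origin tags among `"forebrain-telencephalon"`,
#'   `"forebrain-diencephalon"`, `"midbrain"`, `"hindbrain"`.
#' @return numeric path length.
#' @export
originTreeDistance <- function(originA, originB) {
  # node depth-paths to root of the 4-leaf lineage tree
  paths <- list(
    "forebrain-telencephalon" = c("forebrain-telencephalon", "forebrain", "root"),
    "forebrain-diencephalon"  = c("forebrain-diencephalon", "forebrain", "root"),
    "midbrain"                = c("midbrain", "root"),
    "hindbrain"               = c("hindbrain", "root"))
  if (!originA %in% names(paths)) stop("unknown origin tag: ", originA)
  if (!originB %in% names(paths)) stop("unknown origin tag: ", originB)
  if (originA == originB) return(0)
  pa <- paths[[originA]]; pb <- paths[[originB]]
  common <- intersect(pa, pb)[1]
  (match(common, pa) - 1) + (match(common, pb) - 1)
}

# --- minimal OBO 1.2 parser (id / name / is_a / is_obsolete) -----------------

.parseObo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  cur <- NULL
  inTerm <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id))
      terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)          # strip comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = NA_character_, parents = character(0),
                  obsolete = FALSE)
      inTerm <- TRUE
    } else if (grepl("^\\[", ln)) {    # other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      inTerm <- FALSE
    } else if (inTerm && nzchar(ln)) {
      if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
      else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
      else if (grepl("^is_a:", ln)) {
        tgt <- trimws(sub("^is_a:", "", ln))
        cur$parents <- c(cur$parents, strsplit(tgt, "[[:space:]]+")[[1]][1])
      } else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  terms
}

#' Read GO annotations and the GO DAG
#'
#' Loads a two-column gene-term table (TSV; GAF 2.x accepted, in which case
#' columns 2 and 5 are used) and an OBO 1.2 ontology file. Annotations are
#' propagated to all ancestor terms on load (true-path rule), so the result
#' is closed under the DAG. Terms absent from the OBO are dropped with a
#' warning.
#'
#' @param path gene-term table (columns `gene`, `term`; or a GAF whose
#'   lines start with `!` comments and carry >= 15 columns).
#' @param oboPath OBO 1.2 file defining the DAG.
#' @return A [GeneAnnotation-class].
#' @export
readAnnotations <- function(path, oboPath) {
  terms <- .parseObo(oboPath)
  parents <- lapply(terms, `[[`, "parents")
  catNames <- vapply(terms, `[[`, character(1), "name")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(new("GeneAnnotation", gene2cat = structure(list(), names = character(0)),
               parents = parents, catNames = catNames))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (ncol1 >= 15L) {                  # GAF: gene symbol col 3? spec: cols 2, 5
    gene <- vapply(fields, `[`, character(1), 2L)
    term <- vapply(fields, `[`, character(1), 5L)
  } else {
    hdr <- fields[[1]]
    if (identical(tolower(hdr[1:2]), c("gene", "term"))) fields <- fields[-1]
    gene <- vapply(fields, `[`, character(1), 1L)
    term <- vapply(fields, `[`, character(1), 2L)
  }
  known <- term %in% names(parents)
  if (any(!known)) {
    warning(sprintf("%d annotation(s) to terms absent from the OBO dropped (%s%s)",
                    sum(!known), paste(head(unique(term[!known]), 3), collapse = ", "),
                    if (length(unique(term[!known])) > 3) ", ..." else ""))
    gene <- gene[known]; term <- term[known]
  }
  g2c <- split(term, gene)
  g2c <- lapply(g2c, function(tt) propagateTerms(unique(tt), parents))
  new("GeneAnnotation", gene2cat = g2c, parents = parents, catNames = catNames)
}

#' Close a term set under DAG ancestry
#'
#' @param termIds character vector of category ids.
#' @param parents named list mapping each category to its parents.
#' @return the input ids plus all their ancestors, unique, sorted.
#' @export
propagateTerms <- function(termIds, parents) {
  out <- unique(termIds)
  queue <- out
  while (length(queue)) {
    nxt <- unique(unlist(parents[queue], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    queue <- nxt
  }
  sort(out)
}

#' All DAG descendants of a category
#'
#' @param annotation a [GeneAnnotation-class].
#' @param category category id.
#' @return character vector of strict descendants.
#' @export
termDescendants <- function(annotation, category) {
  parents <- annotation@parents
  children <- list()
  for (cid in names(parents))
    for (p in parents[[cid]])
      children[[p]] <- c(children[[p]], cid)
  out <- character(0)
  queue <- category
  while (length(queue)) {
    nxt <- unique(unlist(children[queue], use.names = FALSE))
    nxt <- setdiff(nxt, c(out, category))
    out <- c(out, nxt)
    queue <- nxt
  }
  out
}

#' Read an ortholog map
#'
#' Two-column TSV/CSV (header `source`, `target`, or headerless); duplicate
#' pairs are removed.
#'
#' @param path path to the table.
#' @return An [OrthologMap-class].
#' @export
readOrthologs <- function(path) {
  df <- read.delim(path, sep = .delimFor(path), header = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("ortholog table needs two columns")
  df <- df[, 1:2]
  names(df) <- c("source", "target")
  if (identical(unname(tolower(unlist(df[1, ]))), c("source", "target")))
    df <- df[-1, , drop = FALSE]
  df <- unique(df)
  rownames(df) <- NULL
  new("OrthologMap", pairs = df)
}

#' Read protein sequences from FASTA
#'
#' One amino-acid sequence per gene id; a duplicated id is an error (pick
#' one isoform per gene upstream).
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of sequences.
#' @export
readProteinSequences <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id in FASTA: ",
         ids[duplicated(ids)][1], " (one sequence per gene id required)")
  setNames(as.character(aas), ids)
}

#' Restrict a dataset to a subset of genes/regions/timepoints
#'
#' @param dataset an [ExpressionDataset-class].
#' @param genes,regions,timepoints identifiers to keep (default: all).
#'   Order of the retained axis follows the original dataset.
#' @return An [ExpressionDataset-class].
#' @export
subsetDataset <- function(dataset, genes = NULL, regions = NULL,
                          timepoints = NULL) {
  v <- exprValues(dataset)
  gi <- if (is.null(genes)) geneIds(dataset) else genes
  ri <- if (is.null(regions)) regionIds(dataset) else regions
  ti <- if (is.null(timepoints)) timeLabels(dataset) else timepoints
  bad <- c(setdiff(gi, geneIds(dataset)), setdiff(ri, regionIds(dataset)),
           setdiff(ti, timeLabels(dataset)))
  if (length(bad)) stop("unknown identifiers: ", paste(bad, collapse = ", "))
  gi <- geneIds(dataset)[geneIds(dataset) %in% gi]
  ri <- regionIds(dataset)[regionIds(dataset) %in% ri]
  ti <- timeLabels(dataset)[timeLabels(dataset) %in% ti]
  ExpressionDataset(v[gi, ri, ti, drop = FALSE], species = speciesLabel(dataset))
}
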