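# Orchestration: a seeded end-to-end run over the synthetic study
# conditions (simulate -> hourglass -> contributions/enrichment -> regions
# -> families -> cross-species), writing per-stage TSV/JSON outputs and a
# manifest, plus a plain-text report assembled from the manifest.

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  path
}

.deriveSeed <- function(masterSeed, stage) {
  # stable per-stage seed below 2^31, derived from the master seed
  offs <- c(simulate = 101L, hourglass = 211L, contrib = 307L,
            regions = 401L, families = 503L, xspecies = 601L)
  (as.integer(masterSeed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on a seeded synthetic
#' dataset (or user-supplied expression tables), writing each stage's
#' outputs under `outDir` and a JSON manifest recording package version,
#' seeds, parameters and per-stage output paths. Re-running with the same
#' configuration reproduces identical outputs for all deterministic stages.
#'
#' @param config named list (or path to a JSON file holding one) with
#'   optional entries: `seed` (master seed, default 1), `outDir`
#'   (default `tempdir()`), `stages` (subset of `"simulate"`,
#'   `"hourglass"`, `"contrib"`, `"regions"`, `"xspecies"`; default all),
#'   `synthetic` (arguments for [syntheticConfig()]), `exprPath`/`species`
#'   (load instead of simulate), `kGrid`, `restarts`, `threshold`,
#'   `focusRegion`, `warp`.
#' @return the manifest (named list), invisibly written to
#'   `outDir/manifest.json`.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- if (is.null(config$outDir)) file.path(tempdir(), "regiospec-run")
            else config$outDir
  stages <- if (is.null(config$stages))
    c("simulate", "hourglass", "contrib", "regions", "xspecies")
  else config$stages
  if (!is.null(config$exprPath) && !file.exists(config$exprPath))
    stop("validation error: exprPath does not exist: ", config$exprPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "regiospec",
                   version = as.character(utils::packageVersion("regiospec")),
                   masterSeed = seed, stages = list())

  truth <- NULL; annTab <- NULL
  if (!is.null(config$exprPath)) {
    dataset <- readExpression(config$exprPath,
                              species = config$species %||% "unspecified")
    manifest$input <- list(path = config$exprPath,
                           md5 = unname(tools::md5sum(config$exprPath)))
  } else if ("simulate" %in% stages) {
    scArgs <- config$synthetic %||% list()
    scArgs$seed <- .deriveSeed(seed, "simulate")
    sc <- do.call(syntheticConfig, scArgs)
    gen <- generateDataset(sc)
    dataset <- gen$dataset
    truth <- gen$truth
    annTab <- gen$annotationTable
    exprPath <- file.path(outDir, "expression.tsv")
    writeExpression(dataset, exprPath)
    .writeTsv(gen$ontologyTable, file.path(outDir, "ontology.tsv"))
    .writeTsv(annTab, file.path(outDir, "annotations.tsv"))
    manifest$stages$simulate <- list(
      seed = scArgs$seed,
      outputs = c("expression.tsv", "ontology.tsv", "annotations.tsv"),
      nGenes = length(geneIds(dataset)),
      nRegions = length(regionIds(dataset)))
  } else stop("no input: supply exprPath or include the simulate stage")

  if ("hourglass" %in% stages) {
    curve <- hourglassCurve(dataset)
    fit <- fitQuadratic(curve)
    dset <- dissimilaritySet(dataset)
    pAnova <- ageAnova(dset)
    .writeTsv(curve, file.path(outDir, "hourglass_curve.tsv"))
    jsonlite::write_json(list(quadratic = as.list(fit),
                              anovaP = pAnova),
                         file.path(outDir, "hourglass_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$hourglass <- list(
      outputs = c("hourglass_curve.tsv", "hourglass_fit.json"),
      meanCurve = curve$mean, anovaP = pAnova)
  }

  if ("contrib" %in% stages) {
    devTps <- setdiff(timeLabels(dataset), config$excludeTimepoints %||% character(0))
    prof <- contributionProfiles(dataset, timepoints = devTps)
    .writeTsv(data.frame(gene = rownames(prof), prof, check.names = FALSE),
              file.path(outDir, "contribution_profiles.tsv"))
    st <- list(outputs = "contribution_profiles.tsv")
    if (!is.null(annTab) && nrow(annTab)) {
      ann <- annotationFromTable(annTab)
      kGrid <- config$kGrid %||% seq(10L, min(50L, nrow(prof) - 1L), by = 5L)
      asg <- clusterProfiles(prof, kGrid = kGrid,
                             restarts = config$restarts %||% 10L,
                             seed = .deriveSeed(seed, "contrib"))
      ea <- enrichmentAnalysis(prof, asg, ann,
                               minGenes = config$minGenes %||% 10L,
                               threshold = config$threshold %||% 0.01,
                               embryonicTps = intersect(
                                 c("E11.5", "E13.5", "E15.5", "E18.5"), devTps),
                               postnatalTps = intersect(
                                 c("P4", "P14", "P28"), devTps))
      .writeTsv(ea$table, file.path(outDir, "enrichment_table.tsv"))
      .writeTsv(ea$enriched, file.path(outDir, "enriched_categories.tsv"))
      st$outputs <- c(st$outputs, "enrichment_table.tsv",
                      "enriched_categories.tsv")
      st$nEnriched <- nrow(ea$enriched)
      st$seed <- .deriveSeed(seed, "contrib")
    }
    manifest$stages$contrib <- st
  }

  if ("regions" %in% stages) {
    rseed <- .deriveSeed(seed, "regions")
    emb <- embedTimepoints(dataset, seed = rseed)
    for (tp in names(emb))
      .writeTsv(emb[[tp]]$coords,
                file.path(outDir, sprintf("embedding_%s.tsv", tp)))
    st <- list(seed = rseed,
               outputs = sprintf("embedding_%s.tsv", names(emb)),
               stress = vapply(emb, `[[`, numeric(1), "stress"))
    focus <- config$focusRegion %||%
      (if (!is.null(truth$breakaway)) truth$breakaway$region else
         regionIds(dataset)[1])
    idx <- regionSpecificIndex(dataset, focus)
    .writeTsv(idx, file.path(outDir, "region_index.tsv"))
    st$outputs <- c(st$outputs, "region_index.tsv")
    st$focusRegion <- focus
    st$regionIndex <- idx$index
    manifest$stages$regions <- st
  }

  if ("xspecies" %in% stages) {
    xseed <- .deriveSeed(seed, "xspecies")
    warp <- config$warp %||% seq(2L, length(timeLabels(dataset)) + 1L)
    cp <- generateCounterpart(dataset, warp = warp, noiseSd = 0, seed = xseed)
    cc <- crossCorrelation(dataset, cp$dataset, cp$orthologs)
    .writeTsv(data.frame(timepoint = rownames(cc$matrix), cc$matrix,
                         check.names = FALSE),
              file.path(outDir, "cross_correlation.tsv"))
    manifest$stages$xspecies <- list(
      seed = xseed, warp = warp, outputs = "cross_correlation.tsv",
      ridge = colnames(cc$matrix)[apply(cc$matrix, 1L, which.max)])
  }

  manifest$outDir <- outDir
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a GeneAnnotation from a two-column gene-term table
#'
#' Convenience constructor for annotation tables like the synthetic
#' generator's `annotationTable`: every term becomes a child of a single
#' synthetic root and annotations are propagated.
#'
#' @param annTab data.frame with columns `gene` and `term`.
#' @return A [GeneAnnotation-class].
#' @export
annotationFromTable <- function(annTab) {
  cats <- unique(annTab$term)
  parents <- c(setNames(rep(list(character(0)), 1), "CAT:root"),
               setNames(rep(list("CAT:root"), length(cats)), cats))
  g2c <- lapply(split(annTab$term, annTab$gene), function(tt)
    propagateTerms(unique(tt), parents))
  new("GeneAnnotation", gene2cat = g2c, parents = parents,
      catNames = setNames(c("root", cats), c("CAT:root", cats)))
}

#' Assemble a plain-text report from a run manifest
#'
#' Reads the manifest written by [runPipeline()] and produces a single
#' markdown summary covering the hourglass curve and fit, enrichment
#' results, region indices and the cross-correlation ridge. Stages missing
#' from the manifest are marked unavailable. Regeneration from an
#' unchanged manifest is byte-identical.
#'
#' @param manifest manifest list or path to `manifest.json`.
#' @param path output path (default `report.md` next to the manifest).
#' @return the report path, invisibly.
#' @export
makeReport <- function(manifest, path = NULL) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (is.null(path)) path <- file.path(manifest$outDir, "report.md")
  L <- c(sprintf("# regiospec run report (version %s, master seed %d)",
                 manifest$version, manifest$masterSeed), "")
  sec <- function(title, body) c(sprintf("## %s", title), "", body, "")
  st <- manifest$stages
  L <- c(L, sec("Hourglass curve",
    if (is.null(st$hourglass)) "unavailable" else c(
      sprintf("mean dissimilarity per timepoint: %s",
              paste(sprintf("%.4f", st$hourglass$meanCurve), collapse = ", ")),
      sprintf("age ANOVA p = %.3g", st$hourglass$anovaP))))
  L <- c(L, sec("Contribution and enrichment",
    if (is.null(st$contrib)) "unavailable" else
      sprintf("%s enriched categories after double FDR and hierarchy screen",
              if (is.null(st$contrib$nEnriched)) "not tested:" else
                st$contrib$nEnriched)))
  L <- c(L, sec("Region analysis",
    if (is.null(st$regions)) "unavailable" else c(
      sprintf("focus region: %s", st$regions$focusRegion),
      sprintf("region-specific index: %s",
              paste(sprintf("%.3f", st$regions$regionIndex), collapse = ", ")),
      sprintf("embedding stress: %s",
              paste(sprintf("%.3g", st$regions$stress), collapse = ", ")))))
  L <- c(L, sec("Cross-species",
    if (is.null(st$xspecies)) "unavailable" else
      sprintf("Spearman ridge (per source timepoint): %s",
              paste(st$xspecies$ridge, collapse = ", "))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(L, con, useBytes = TRUE)
  invisible(path)
}
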