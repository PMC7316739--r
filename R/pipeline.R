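#' Read or write a pipeline run configuration
#'
#' The run configuration is a YAML file with top-level fields:
#' \describe{
#'   \item{seed}{master integer seed; per-stage, per-contrast sub-seeds
#'     are derived deterministically from it.}
#'   \item{expression / metadata}{paths to the expression and metadata
#'     TSVs, or a `simulation` block (arguments of [simulationConfig()];
#'     `deSpec` as a list of size/group/logFC maps) to generate them.}
#'   \item{contrasts}{list of `"A:B"` strings, logFC oriented A - B.}
#'   \item{stability}{`k`, `nIter`, `nPerm`, `detectP`, `qCutoff`,
#'     `scope` (defaults 4, 100, 100, 0.05, 1e-4, contrast).}
#'   \item{gsea}{`gmt` path (optional), `nPerm`, `minSize`, `maxSize`,
#'     `weight`, `pCutoff`, `nTop` (defaults 1000, 15, 500, 1, 0.05,
#'     100).}
#'   \item{atlas}{`path` (long-format TSV, optional), `minSamples`,
#'     `fdrCutoff`, `fcCutoff`, `maxGenes` (defaults 3, 0.01, 2, 800).}
#' }
#'
#' @param path YAML file path.
#' @return the configuration as a named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config must declare a seed")
  cfg
}

#' @rdname readRunConfig
#' @param config configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

pipelineDefaults <- function(cfg) {
  st <- cfg$stability %||% list()
  st$k <- st$k %||% 4L
  st$nIter <- st$nIter %||% 100L
  st$nPerm <- st$nPerm %||% 100L
  st$detectP <- st$detectP %||% 0.05
  st$qCutoff <- st$qCutoff %||% 1e-4
  st$scope <- st$scope %||% "contrast"
  gs <- cfg$gsea %||% list()
  gs$nPerm <- gs$nPerm %||% 1000L
  gs$minSize <- gs$minSize %||% 15L
  gs$maxSize <- gs$maxSize %||% 500L
  gs$weight <- gs$weight %||% 1
  gs$pCutoff <- gs$pCutoff %||% 0.05
  gs$nTop <- gs$nTop %||% 100L
  at <- cfg$atlas %||% list()
  at$minSamples <- at$minSamples %||% 3L
  at$fdrCutoff <- at$fdrCutoff %||% 0.01
  at$fcCutoff <- at$fcCutoff %||% 2
  at$maxGenes <- at$maxGenes %||% 800L
  cfg$stability <- st
  cfg$gsea <- gs
  cfg$atlas <- at
  cfg
}

simConfigFromList <- function(sim, seed) {
  deSpec <- lapply(sim$deSpec %||% list(), function(b)
    list(size = b$size, group = b$group, logFC = b$logFC))
  simulationConfig(
    nTranscripts = sim$nTranscripts,
    groups = sim$groups %||% c("CTRL", "PD", "MSA-P", "MSA-C"),
    nPerGroup = sim$nPerGroup %||% 10L,
    genderBalance = sim$genderBalance %||% 0.5,
    baselineMeanRange = sim$baselineMeanRange %||% c(4, 12),
    baselineSd = sim$baselineSd %||% 0.5,
    varDf = sim$varDf %||% Inf,
    genderShift = sim$genderShift %||% 0,
    deSpec = deSpec,
    seed = sim$seed %||% deriveSeed(seed, "simulate"))
}

#' Run the full pipeline from a single configuration
#'
#' Executes the stages in dependency order — simulate (or load) the
#' expression experiment, resampling stability per contrast, sum-logFC
#' ranking, pre-ranked GSEA against a supplied GMT collection, consensus
#' region gene sets from an atlas table plus region-enrichment summaries —
#' writing every artifact plus a JSON manifest (parameters, seeds, file
#' MD5 hashes) into `outDir`. Reruns with the same configuration and seed
#' reproduce byte-identical tables.
#'
#' @param config configuration list (see [readRunConfig()]) or a path to
#'   a YAML file.
#' @param outDir output directory, created if needed.
#' @return (invisibly) a list with the per-contrast
#'   [StabilityResult-class] objects, GSEA tables, selections, overlap,
#'   region summaries and the manifest.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- pipelineDefaults(config)
  seed <- as.integer(cfg$seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, parameters = cfg[c("stability", "gsea",
                                                   "atlas")],
                   stages = list(), files = list())
  failStage <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  ## --- expression input -------------------------------------------------
  se <- tryCatch({
    if (!is.null(cfg$simulation)) {
      simCfg <- simConfigFromList(cfg$simulation, seed)
      sim <- simulateExpression(simCfg)
      writeExpression(sim, file.path(outDir, "expression.tsv"))
      writeSampleMetadata(sim, file.path(outDir, "metadata.tsv"))
      gt <- S4Vectors::metadata(sim)$groundTruth
      write.table(gt, file.path(outDir, "ground_truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      sim
    } else {
      x <- readExpression(cfg$expression)
      meta <- readSampleMetadata(cfg$metadata)
      asExpressionExperiment(x, meta)
    }
  }, error = function(e) failStage("input", e))
  manifest$stages$input <- list(
    nTranscripts = nrow(se), nSamples = ncol(se),
    simulated = !is.null(cfg$simulation))

  ## --- stability per contrast -------------------------------------------
  contrasts <- cfg$contrasts
  if (is.null(contrasts)) stop("run config must declare contrasts")
  stability <- list()
  rankings <- list()
  st <- cfg$stability
  for (cs in contrasts) {
    parts <- strsplit(cs, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("contrast '", cs, "' must have the form 'A:B'")
    key <- paste0(parts[1L], "_vs_", parts[2L])
    res <- tryCatch(
      runStability(se, parts[1L], parts[2L], k = st$k, nIter = st$nIter,
                   nPerm = st$nPerm, seed = seed,
                   detectP = st$detectP, qCutoff = st$qCutoff,
                   scope = st$scope),
      error = function(e) failStage(paste0("stability[", key, "]"), e))
    stability[[key]] <- res
    tabPath <- file.path(outDir, paste0("stability_", key, ".tsv"))
    write.table(stabilityTable(res), tabPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      subgroupDraws(res),
      file.path(outDir, paste0("draws_", key, ".json")),
      auto_unbox = TRUE, pretty = TRUE)
    rankings[[key]] <- rankedScores(res)
    rk <- data.frame(transcript_id = names(rankings[[key]]),
                     score = unname(rankings[[key]]))
    write.table(rk, file.path(outDir, paste0("ranking_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$stability[[key]] <- list(
      nSignificant = sum(stabilityTable(res)$significant),
      nIter = st$nIter, nPerm = st$nPerm)
  }

  ## --- GSEA --------------------------------------------------------------
  gs <- cfg$gsea
  selections <- list()
  if (!is.null(gs$gmt)) {
    collection <- readGMT(gs$gmt)
    for (key in names(rankings)) {
      res <- tryCatch(
        gseaPreranked(rankings[[key]], collection, nPerm = gs$nPerm,
                      seed = deriveSeed(seed, paste0("gsea:", key)),
                      minSize = gs$minSize, maxSize = gs$maxSize,
                      weight = gs$weight),
        error = function(e) failStage(paste0("gsea[", key, "]"), e))
      write.table(res, file.path(outDir, paste0("gsea_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      selections[[key]] <- selectTopSets(res, pCutoff = gs$pCutoff,
                                         nTop = gs$nTop)
      write.table(selections[[key]],
                  file.path(outDir, paste0("top_sets_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$gsea[[key]] <- list(nSets = nrow(res),
                                          nSelected = nrow(selections[[key]]))
    }
    if (length(selections) >= 2L) {
      ov <- do.call(overlapTopSets, selections)
      jsonlite::write_json(ov, file.path(outDir, "top_set_overlaps.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest$stages$overlap <- as.list(ov$counts)
    }
  }

  ## --- atlas region gene sets -------------------------------------------
  at <- cfg$atlas
  regionSummaries <- list()
  if (!is.null(at$path)) {
    atlas <- readAtlas(at$path)
    built <- tryCatch(
      buildRegionGeneSets(atlas, minSamples = at$minSamples,
                          fdrCutoff = at$fdrCutoff,
                          fcCutoff = at$fcCutoff,
                          maxGenes = at$maxGenes),
      error = function(e) failStage("atlas", e))
    writeGMT(built$collection, file.path(outDir, "region_sets.gmt"))
    write.table(built$provenance,
                file.path(outDir, "region_sets_provenance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (key in names(rankings)) {
      res <- tryCatch(
        gseaPreranked(rankings[[key]], built$collection, nPerm = gs$nPerm,
                      seed = deriveSeed(seed, paste0("region:", key)),
                      minSize = 1L, maxSize = length(rankings[[key]]) - 1L,
                      weight = gs$weight),
        error = function(e) failStage(paste0("regionGsea[", key, "]"), e))
      regionSummaries[[key]] <- summarizeRegionEnrichment(
        res, pCutoff = gs$pCutoff)
      write.table(regionSummaries[[key]],
                  file.path(outDir,
                            paste0("region_enrichment_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$atlas <- list(
      nSets = length(built$collection),
      regions = filterRegions(atlas, at$minSamples)$retained)
  }

  ## --- manifest ----------------------------------------------------------
  outFiles <- setdiff(list.files(outDir), "manifest.json")
  manifest$files <- lapply(setNames(outFiles, outFiles), function(f)
    unname(tools::md5sum(file.path(outDir, f))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(experiment = se, stability = stability,
                 selections = selections,
                 regionSummaries = regionSummaries, manifest = manifest))
}
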