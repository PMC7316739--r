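#' @import methods
#' @importFrom stats cor kruskal.test median p.adjust pnorm pt rchisq rnorm
#'   runif sd setNames smooth.spline predict var
#' @importFrom utils head read.delim write.table
NULL

#' Simulation configuration for a grouped expression cohort
#'
#' Describes a synthetic blood-style log2 expression study: a set of
#' sample groups of equal size with a declared gender balance, a
#' per-transcript baseline drawn on the log2-intensity scale, Gaussian
#' within-group noise, and an optional list of transcript blocks carrying
#' a group-specific log2 fold-change shift.
#'
#' @slot nTranscripts number of transcripts simulated.
#' @slot groups ordered character vector of group labels.
#' @slot nPerGroup samples per group.
#' @slot genderBalance proportion of male samples per group; must yield an
#'   integer number of each gender.
#' @slot baselineMeanRange length-2 numeric, uniform range of per-transcript
#'   baseline means (log2 intensity).
#' @slot baselineSd within-group noise SD on the log2 scale.
#' @slot varDf degrees of freedom of the scaled-inverse-chi-square spread of
#'   per-transcript SDs around `baselineSd`; `Inf` (default) means every
#'   transcript has SD exactly `baselineSd`.
#' @slot genderShift additive log2 shift applied to male samples (default 0;
#'   gender carries no expression effect).
#' @slot deSpec list of differential blocks, each
#'   `list(size =, group =, logFC =)`; blocks occupy consecutive disjoint
#'   transcript ranges starting at transcript 1.
#' @slot seed integer RNG seed; identical seeds give bit-identical output.
#'
#' @seealso [simulationConfig()], [simulateExpression()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nTranscripts = "integer",
    groups = "character",
    nPerGroup = "integer",
    genderBalance = "numeric",
    baselineMeanRange = "numeric",
    baselineSd = "numeric",
    varDf = "numeric",
    genderShift = "numeric",
    deSpec = "list",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nTranscripts < 1L)
    msg <- c(msg, "nTranscripts must be a positive integer")
  if (length(object@groups) < 2L || anyDuplicated(object@groups))
    msg <- c(msg, "groups must be >=2 unique labels")
  if (object@nPerGroup < 1L)
    msg <- c(msg, "nPerGroup must be positive")
  if (object@genderBalance < 0 || object@genderBalance > 1)
    msg <- c(msg, "genderBalance must lie in [0, 1]")
  nM <- object@nPerGroup * object@genderBalance
  if (abs(nM - round(nM)) > 1e-8)
    msg <- c(msg, sprintf(
      "nPerGroup (%d) x genderBalance (%g) must be an integer gender count",
      object@nPerGroup, object@genderBalance))
  if (length(object@baselineMeanRange) != 2L ||
      diff(object@baselineMeanRange) < 0)
    msg <- c(msg, "baselineMeanRange must be an increasing length-2 interval")
  if (object@baselineSd <= 0)
    msg <- c(msg, "baselineSd must be positive")
  if (object@varDf <= 0)
    msg <- c(msg, "varDf must be positive (possibly Inf)")
  for (i in seq_along(object@deSpec)) {
    b <- object@deSpec[[i]]
    if (!all(c("size", "group", "logFC") %in% names(b))) {
      msg <- c(msg, sprintf("deSpec[[%d]] needs fields size, group, logFC", i))
      next
    }
    if (!b$group %in% object@groups)
      msg <- c(msg, sprintf("deSpec[[%d]]: unknown group '%s'", i, b$group))
    if (b$size < 1)
      msg <- c(msg, sprintf("deSpec[[%d]]: block size must be positive", i))
  }
  tot <- sum(vapply(object@deSpec, function(b) as.integer(b$size), 1L))
  if (length(object@deSpec) && tot > object@nTranscripts)
    msg <- c(msg, sprintf(
      "deSpec blocks cover %d transcripts but only %d exist",
      tot, object@nTranscripts))
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for a multi-donor regional atlas
#'
#' Describes a synthetic brain-atlas-style dataset: several donors, each
#' contributing samples from a set of brain regions, with transcript blocks
#' overexpressed in a given region consistently across donors.
#'
#' @slot nDonors number of donors (>= 1).
#' @slot regions character vector of region labels.
#' @slot samplesPerRegion named integer vector, samples per region per donor
#'   (names are region labels).
#' @slot nTranscripts number of transcripts.
#' @slot baselineMeanRange uniform range of per-transcript baseline means.
#' @slot noiseSd within-region replicate noise SD (log2 units).
#' @slot donorSd SD of per-donor, per-transcript baseline offsets.
#' @slot regionBlocks list of `list(region =, size =, logFC =)` blocks;
#'   blocks occupy consecutive disjoint transcript ranges starting at 1.
#' @slot seed integer RNG seed.
#'
#' @seealso [atlasSimulationConfig()], [simulateAtlas()]
#' @exportClass AtlasSimulationConfig
setClass("AtlasSimulationConfig",
  representation(
    nDonors = "integer",
    regions = "character",
    samplesPerRegion = "integer",
    nTranscripts = "integer",
    baselineMeanRange = "numeric",
    noiseSd = "numeric",
    donorSd = "numeric",
    regionBlocks = "list",
    seed = "integer"
  )
)

setValidity("AtlasSimulationConfig", function(object) {
  msg <- character()
  if (object@nDonors < 1L) msg <- c(msg, "nDonors must be >= 1")
  if (length(object@regions) < 2L || anyDuplicated(object@regions))
    msg <- c(msg, "regions must be >=2 unique labels")
  if (!identical(sort(names(object@samplesPerRegion)), sort(object@regions)))
    msg <- c(msg, "samplesPerRegion must be named by exactly the region labels")
  if (any(object@samplesPerRegion < 1L))
    msg <- c(msg, "samplesPerRegion entries must be positive")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (object@donorSd < 0) msg <- c(msg, "donorSd must be non-negative")
  for (i in seq_along(object@regionBlocks)) {
    b <- object@regionBlocks[[i]]
    if (!all(c("region", "size", "logFC") %in% names(b))) {
      msg <- c(msg,
        sprintf("regionBlocks[[%d]] needs fields region, size, logFC", i))
      next
    }
    if (!b$region %in% object@regions)
      msg <- c(msg, sprintf("regionBlocks[[%d]]: unknown region '%s'",
                            i, b$region))
  }
  tot <- sum(vapply(object@regionBlocks, function(b) as.integer(b$size), 1L))
  if (length(object@regionBlocks) && tot > object@nTranscripts)
    msg <- c(msg, sprintf(
      "regionBlocks cover %d transcripts but only %d exist",
      tot, object@nTranscripts))
  if (length(msg)) msg else TRUE
})

#' Named collection of gene sets
#'
#' Ordered collection of named, non-empty gene/transcript sets with
#' free-text descriptions, mirroring the MSigDB GMT interchange format.
#'
#' @slot setNames unique set names, in file order.
#' @slot descriptions one description per set.
#' @slot members list of character vectors of unique member ids.
#'
#' @seealso [GeneSetCollection()], [readGMT()], [writeGMT()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(
    setNames = "character",
    descriptions = "character",
    members = "list"
  )
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  n <- length(object@setNames)
  if (anyDuplicated(object@setNames))
    msg <- c(msg, "set names must be unique")
  if (length(object@descriptions) != n || length(object@members) != n)
    msg <- c(msg, "setNames, descriptions and members must have equal length")
  empty <- vapply(object@members, length, 1L) == 0L
  if (any(empty))
    msg <- c(msg, sprintf("empty gene set(s): %s",
                          paste(object@setNames[empty], collapse = ", ")))
  dup <- vapply(object@members, anyDuplicated, 1L) > 0L
  if (any(dup))
    msg <- c(msg, sprintf("duplicated members within set(s): %s",
                          paste(object@setNames[dup], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Result of a resampling-stability analysis for one contrast
#'
#' Bundles the per-transcript stability table with the underlying observed
#' and permutation-null p-value profiles, the audited subgroup draws, and
#' the run parameters.
#'
#' @slot table `data.frame` with one row per transcript: `transcript_id`,
#'   `n_detected`, `sum_logFC`, `kw_H`, `kw_p`, `kw_q`, `significant`;
#'   sorted by decreasing `n_detected`, then decreasing `|sum_logFC|`,
#'   then id.
#' @slot observedP transcripts x iterations matrix of real-contrast p-values.
#' @slot observedLogFC matching matrix of per-iteration log2 fold changes.
#' @slot nullP transcripts x permutations matrix of label-permuted p-values.
#' @slot draws list of balanced subgroup draws (the audit trail).
#' @slot params list of run parameters (contrast, k, nIter, nPerm,
#'   thresholds, seed).
#'
#' @seealso [runStability()], [stabilityTable()]
#' @exportClass StabilityResult
setClass("StabilityResult",
  representation(
    table = "data.frame",
    observedP = "matrix",
    observedLogFC = "matrix",
    nullP = "matrix",
    draws = "list",
    params = "list"
  )
)

setValidity("StabilityResult", function(object) {
  msg <- character()
  need <- c("transcript_id", "n_detected", "sum_logFC",
            "kw_H", "kw_p", "kw_q", "significant")
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, paste("table must contain columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@observedP) != nrow(object@table))
    msg <- c(msg, "observedP rows must match table rows")
  if (length(msg)) msg else TRUE
})
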