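#' Build a simulation configuration
#'
#' Constructor with the study defaults: four groups (CTRL, PD, MSA-P,
#' MSA-C) of 10 samples each, gender-balanced 5M/5F, log2 baselines drawn
#' uniformly on \[4, 12\] and constant within-group SD 0.5.
#'
#' @param nTranscripts number of transcripts.
#' @param groups ordered group labels.
#' @param nPerGroup samples per group.
#' @param genderBalance male proportion per group; `nPerGroup *
#'   genderBalance` must be an integer.
#' @param baselineMeanRange uniform range of per-transcript baseline log2
#'   means.
#' @param baselineSd within-group SD on the log2 scale.
#' @param varDf df of the scaled-inverse-chi-square spread of per-transcript
#'   SDs; `Inf` = constant SD.
#' @param genderShift additive log2 shift for male samples (default 0).
#' @param deSpec list of blocks `list(size =, group =, logFC =)`, assigned
#'   to consecutive disjoint transcript ranges from transcript 1.
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nTranscripts = 500, seed = 1,
#'   deSpec = list(list(size = 20, group = "MSA-P", logFC = 1.5)))
#' sim <- simulateExpression(cfg)
#' @export
simulationConfig <- function(nTranscripts,
                             groups = c("CTRL", "PD", "MSA-P", "MSA-C"),
                             nPerGroup = 10L,
                             genderBalance = 0.5,
                             baselineMeanRange = c(4, 12),
                             baselineSd = 0.5,
                             varDf = Inf,
                             genderShift = 0,
                             deSpec = list(),
                             seed = 1L) {
  new("SimulationConfig",
      nTranscripts = as.integer(nTranscripts),
      groups = as.character(groups),
      nPerGroup = as.integer(nPerGroup),
      genderBalance = as.numeric(genderBalance),
      baselineMeanRange = as.numeric(baselineMeanRange),
      baselineSd = as.numeric(baselineSd),
      varDf = as.numeric(varDf),
      genderShift = as.numeric(genderShift),
      deSpec = deSpec,
      seed = as.integer(seed))
}

#' Simulate a grouped log2 expression experiment with known ground truth
#'
#' Generates a transcripts x samples log2 intensity matrix. Each transcript
#' has a baseline mean drawn uniformly from `baselineMeanRange` and
#' independent Gaussian within-group noise. Transcripts inside a `deSpec`
#' block have their mean shifted by the block's logFC in the affected group
#' only; all other transcripts have identical group means in expectation.
#' Gender and age are metadata only unless `genderShift` is nonzero.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2"`, colData columns `group`, `gender`, `age`, rowData column
#'   `block` (block index or `NA`), and
#'   `metadata(x)$groundTruth`: a `data.frame` (`transcript_id`, `group`,
#'   `logFC`) listing every injected shift (zero rows means a null design).
#' @export
simulateExpression <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nTranscripts
  nG <- length(config@groups)
  N <- nG * config@nPerGroup
  nM <- as.integer(round(config@nPerGroup * config@genderBalance))

  transcriptIds <- sprintf("TC%06d", seq_len(n))
  groupVec <- rep(config@groups, each = config@nPerGroup)
  sampleIds <- paste0(groupVec, "_",
                      sprintf("%02d", rep(seq_len(config@nPerGroup), nG)))
  gender <- rep(c(rep("M", nM), rep("F", config@nPerGroup - nM)), nG)
  age <- round(rnorm(N, mean = 65, sd = 5))

  baseline <- runif(n, config@baselineMeanRange[1], config@baselineMeanRange[2])
  sdT <- if (is.finite(config@varDf)) {
    config@baselineSd * sqrt(config@varDf / rchisq(n, df = config@varDf))
  } else rep(config@baselineSd, n)

  x <- baseline + matrix(rnorm(n * N), n, N) * sdT
  if (config@genderShift != 0)
    x[, gender == "M"] <- x[, gender == "M"] + config@genderShift

  block <- rep(NA_integer_, n)
  gt <- data.frame(transcript_id = character(), group = character(),
                   logFC = numeric(), stringsAsFactors = FALSE)
  at <- 0L
  for (i in seq_along(config@deSpec)) {
    b <- config@deSpec[[i]]
    idx <- at + seq_len(b$size)
    at <- at + as.integer(b$size)
    block[idx] <- i
    x[idx, groupVec == b$group] <- x[idx, groupVec == b$group] + b$logFC
    gt <- rbind(gt, data.frame(transcript_id = transcriptIds[idx],
                               group = b$group, logFC = b$logFC,
                               stringsAsFactors = FALSE))
  }

  dimnames(x) <- list(transcriptIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = x),
    colData = S4Vectors::DataFrame(
      sample_id = sampleIds, group = groupVec, gender = gender, age = age,
      row.names = sampleIds),
    rowData = S4Vectors::DataFrame(block = block, row.names = transcriptIds))
  S4Vectors::metadata(se)$groundTruth <- gt
  S4Vectors::metadata(se)$config <- config
  se
}

#' Build an atlas simulation configuration
#'
#' @param nDonors number of donors.
#' @param regions region labels.
#' @param samplesPerRegion samples per region per donor; a single integer is
#'   recycled across regions, or a named vector gives per-region counts.
#' @param nTranscripts number of transcripts.
#' @param baselineMeanRange uniform range of per-transcript baselines.
#' @param noiseSd within-region replicate noise SD (log2 units).
#' @param donorSd SD of per-donor baseline offsets (captures between-donor
#'   level differences; pairwise contrasts are within-donor so it cancels).
#' @param regionBlocks list of `list(region =, size =, logFC =)` blocks
#'   occupying consecutive disjoint transcript ranges from transcript 1.
#' @param seed integer RNG seed.
#' @return a validated [AtlasSimulationConfig-class].
#' @export
atlasSimulationConfig <- function(nDonors = 3L,
                                  regions = c("SNr", "GPE", "SP5", "RT"),
                                  samplesPerRegion = 3L,
                                  nTranscripts = 2000L,
                                  baselineMeanRange = c(4, 12),
                                  noiseSd = 0.25,
                                  donorSd = 0.1,
                                  regionBlocks = list(),
                                  seed = 1L) {
  spr <- samplesPerRegion
  if (is.null(names(spr)))
    spr <- setNames(rep(as.integer(spr), length.out = length(regions)),
                    regions)
  new("AtlasSimulationConfig",
      nDonors = as.integer(nDonors),
      regions = as.character(regions),
      samplesPerRegion = vapply(spr, as.integer, 1L),
      nTranscripts = as.integer(nTranscripts),
      baselineMeanRange = as.numeric(baselineMeanRange),
      noiseSd = as.numeric(noiseSd),
      donorSd = as.numeric(donorSd),
      regionBlocks = regionBlocks,
      seed = as.integer(seed))
}

#' Simulate multi-donor regional atlas expression
#'
#' Produces a long-format table (donor, region, sample, transcript, value)
#' of normalized log2 expression. Every donor shares the same transcript
#' baselines plus a donor-specific offset; transcripts in a region block
#' are elevated by the stated logFC in that region in every donor.
#'
#' @param config an [AtlasSimulationConfig-class].
#' @return a list with elements `atlas` (long-format `data.frame` with
#'   columns `donor`, `region`, `sample`, `transcript`, `value`) and
#'   `blocks` (named list, region label -> character vector of implanted
#'   transcript ids; the ground truth).
#' @export
simulateAtlas <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nTranscripts
  transcriptIds <- sprintf("TC%06d", seq_len(n))
  baseline <- runif(n, config@baselineMeanRange[1], config@baselineMeanRange[2])

  shift <- matrix(0, n, length(config@regions),
                  dimnames = list(transcriptIds, config@regions))
  blocks <- list()
  at <- 0L
  for (b in config@regionBlocks) {
    idx <- at + seq_len(b$size)
    at <- at + as.integer(b$size)
    shift[idx, b$region] <- shift[idx, b$region] + b$logFC
    blocks[[b$region]] <- c(blocks[[b$region]], transcriptIds[idx])
  }

  rows <- vector("list", config@nDonors)
  for (d in seq_len(config@nDonors)) {
    donorId <- sprintf("donor%02d", d)
    donorOffset <- rnorm(n, 0, config@donorSd)
    parts <- list()
    for (r in config@regions) {
      ns <- config@samplesPerRegion[[r]]
      for (s in seq_len(ns)) {
        vals <- baseline + donorOffset + shift[, r] +
          rnorm(n, 0, config@noiseSd)
        parts[[paste(r, s)]] <- data.frame(
          donor = donorId, region = r,
          sample = sprintf("%s_%s_%02d", donorId, r, s),
          transcript = transcriptIds, value = vals,
          stringsAsFactors = FALSE)
      }
    }
    rows[[d]] <- do.call(rbind, parts)
  }
  atlas <- do.call(rbind, rows)
  rownames(atlas) <- NULL
  list(atlas = atlas, blocks = blocks)
}
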