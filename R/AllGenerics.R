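#' @rdname GeneSetCollection-class
#' @param x,object a `GeneSetCollection`.
#' @export
setGeneric("geneSetNames", function(x) standardGeneric("geneSetNames"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSetDescriptions",
           function(x) standardGeneric("geneSetDescriptions"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSetMembers", function(x) standardGeneric("geneSetMembers"))

#' @rdname StabilityResult-class
#' @param x,object a `StabilityResult`.
#' @export
setGeneric("stabilityTable", function(x) standardGeneric("stabilityTable"))

#' @rdname StabilityResult-class
#' @export
setGeneric("observedPValues", function(x) standardGeneric("observedPValues"))

#' @rdname StabilityResult-class
#' @export
setGeneric("nullPValues", function(x) standardGeneric("nullPValues"))

#' @rdname StabilityResult-class
#' @export
setGeneric("subgroupDraws", function(x) standardGeneric("subgroupDraws"))

#' @rdname StabilityResult-class
#' @export
setGeneric("runParameters", function(x) standardGeneric("runParameters"))

setMethod("geneSetNames", "GeneSetCollection", function(x) x@setNames)
setMethod("geneSetDescriptions", "GeneSetCollection",
          function(x) setNames(x@descriptions, x@setNames))
setMethod("geneSetMembers", "GeneSetCollection",
          function(x) setNames(x@members, x@setNames))

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setNames))

#' @rdname GeneSetCollection-class
#' @param i set name or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) {
  if (is.character(i)) {
    j <- match(i, x@setNames)
    if (is.na(j)) stop("no gene set named '", i, "'")
    i <- j
  }
  x@members[[i]]
})

#' @rdname GeneSetCollection-class
#' @param j,...,drop ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@setNames)
    if (anyNA(idx))
      stop("unknown gene set(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  new("GeneSetCollection",
      setNames = x@setNames[i],
      descriptions = x@descriptions[i],
      members = x@members[i])
})

setMethod("show", "GeneSetCollection", function(object) {
  sizes <- vapply(object@members, length, 1L)
  cat("GeneSetCollection with", length(object@setNames), "sets\n")
  if (length(sizes))
    cat("  member counts: min", min(sizes), "| median", stats::median(sizes),
        "| max", max(sizes), "\n")
  show_n <- min(5L, length(object@setNames))
  for (i in seq_len(show_n))
    cat("  ", object@setNames[i], " (", sizes[i], ")\n", sep = "")
  if (length(object@setNames) > show_n)
    cat("  ...\n")
})

setMethod("stabilityTable", "StabilityResult", function(x) x@table)
setMethod("observedPValues", "StabilityResult", function(x) x@observedP)
setMethod("nullPValues", "StabilityResult", function(x) x@nullP)
setMethod("subgroupDraws", "StabilityResult", function(x) x@draws)
setMethod("runParameters", "StabilityResult", function(x) x@params)

setMethod("show", "StabilityResult", function(object) {
  p <- object@params
  cat("StabilityResult:", p$contrast %||% "", "\n")
  cat("  ", nrow(object@table), " transcripts | ",
      ncol(object@observedP), " resampling iterations | ",
      ncol(object@nullP), " permutations\n", sep = "")
  cat("  significant at kw_q <", format(p$qCutoff %||% NA), ":",
      sum(object@table$significant), "\n")
  cat("  top of table:\n")
  print(head(object@table, 5L), row.names = FALSE)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nTranscripts, "transcripts x",
      length(object@groups), "groups x", object@nPerGroup, "samples\n")
  cat("  groups:", paste(object@groups, collapse = ", "), "\n")
  cat("  baseline U(", object@baselineMeanRange[1], ",",
      object@baselineMeanRange[2], "), SD", object@baselineSd,
      if (is.finite(object@varDf)) paste0(" (varDf=", object@varDf, ")"),
      "\n", sep = " ")
  cat("  differential blocks:", length(object@deSpec),
      "| seed:", object@seed, "\n")
})

setMethod("show", "AtlasSimulationConfig", function(object) {
  cat("AtlasSimulationConfig:", object@nDonors, "donors x",
      length(object@regions), "regions,", object@nTranscripts,
      "transcripts\n")
  cat("  samples/region/donor:",
      paste(names(object@samplesPerRegion), object@samplesPerRegion,
            sep = "=", collapse = ", "), "\n")
  cat("  region blocks:", length(object@regionBlocks),
      "| seed:", object@seed, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
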