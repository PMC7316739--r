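#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file whose header row names the samples and
#' whose first column holds transcript ids. Non-numeric cells and (by
#' default) missing values are hard errors with the offending location;
#' silent imputation would corrupt the downstream rank statistics.
#'
#' @param path file path.
#' @param naAction `"error"` (default) or `"drop"` to remove rows with
#'   missing values (dropped ids are reported in a warning).
#' @return numeric matrix, transcripts x samples, with unique dimnames.
#' @export
readExpression <- function(path, naAction = c("error", "drop")) {
  naAction <- match.arg(naAction)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression file '", path, "' needs an id column plus >=1 sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated transcript id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sampleIds <- colnames(df)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicated sample id(s) in '", path, "': ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  x <- matrix(NA_real_, nrow(df), length(sampleIds),
              dimnames = list(ids, sampleIds))
  for (j in seq_along(sampleIds)) {
    raw <- df[[j + 1L]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & raw != "" & raw != "NA")
    if (length(bad))
      stop("non-numeric value '", raw[bad[1L]], "' at row '", ids[bad[1L]],
           "', column '", sampleIds[j], "' in '", path, "'")
    x[, j] <- v
  }
  if (anyNA(x)) {
    badRows <- which(rowSums(is.na(x)) > 0L)
    if (naAction == "error")
      stop("missing value(s) in '", path, "' at row(s): ",
           paste(head(ids[badRows], 5L), collapse = ", "),
           if (length(badRows) > 5L) ", ...")
    warning("dropping ", length(badRows), " row(s) with missing values")
    x <- x[-badRows, , drop = FALSE]
  }
  x
}

#' Write a log2 expression matrix as TSV
#'
#' @param x numeric matrix with dimnames, or a `SummarizedExperiment`
#'   (its `"log2"` assay is written).
#' @param path destination file.
#' @param idColumn name of the first (transcript id) column.
#' @export
writeExpression <- function(x, path, idColumn = "transcript_id") {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "log2")
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample metadata table
#'
#' The table must contain columns `sample_id`, `group`, `gender`, `age`;
#' gender labels are restricted to `M`/`F` and sample ids must be unique.
#'
#' @param path file path.
#' @param groups optional declared group set; labels outside it are an
#'   error.
#' @return `data.frame` with the four columns.
#' @export
readSampleMetadata <- function(path, groups = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gender", "age")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id(s) in '", path, "': ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  if (!all(df$gender %in% c("M", "F")))
    stop("gender labels must be 'M' or 'F' in '", path, "'")
  if (!is.null(groups) && !all(df$group %in% groups))
    stop("unknown group label(s) in '", path, "': ",
         paste(setdiff(df$group, groups), collapse = ", "))
  df[need]
}

#' @rdname readSampleMetadata
#' @param metadata a metadata `data.frame` (or the colData of a
#'   `SummarizedExperiment`).
#' @export
writeSampleMetadata <- function(metadata, path) {
  if (is(metadata, "SummarizedExperiment"))
    metadata <- as.data.frame(SummarizedExperiment::colData(metadata))
  write.table(metadata[c("sample_id", "group", "gender", "age")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble an expression experiment from matrix plus metadata
#'
#' Validates that the metadata covers exactly the matrix's samples, then
#' wraps both in a `SummarizedExperiment` (assay `"log2"`), the container
#' every analysis function in this package consumes.
#'
#' @param x numeric transcripts x samples matrix with dimnames.
#' @param metadata `data.frame` with `sample_id`, `group`, `gender`, `age`.
#' @return a `SummarizedExperiment`.
#' @export
asExpressionExperiment <- function(x, metadata) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry transcript and sample ids")
  if (!setequal(metadata$sample_id, colnames(x)) ||
      anyDuplicated(metadata$sample_id))
    stop("metadata sample ids must match the matrix columns exactly")
  metadata <- metadata[match(colnames(x), metadata$sample_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = x),
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id))
}

#' Construct a gene set collection
#'
#' @param members named list of character vectors (names are set names).
#' @param descriptions optional character vector of descriptions.
#' @return a [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(members, descriptions = NULL) {
  nm <- names(members)
  if (is.null(nm)) stop("members must be a named list")
  if (is.null(descriptions)) descriptions <- rep("", length(members))
  new("GeneSetCollection",
      setNames = nm,
      descriptions = as.character(descriptions),
      members = lapply(unname(members), as.character))
}

#' Read a GMT gene set collection
#'
#' One set per line: name, description, then member ids, tab-separated.
#' Duplicate members within a line are removed with a warning; lines with
#' fewer than three fields are an error naming the line number.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection-class], file order preserved.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nm <- character(length(lines))
  desc <- character(length(lines))
  members <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " in '", path,
           "' has fewer than 3 tab-separated fields")
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    mem <- f[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (anyDuplicated(mem)) {
      warning("duplicated member(s) in set '", f[1L], "' (line ", i,
              "); de-duplicated")
      mem <- unique(mem)
    }
    members[[i]] <- mem
  }
  if (anyDuplicated(nm))
    stop("duplicated set name(s) in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  new("GeneSetCollection", setNames = nm, descriptions = desc,
      members = members)
}

#' @rdname readGMT
#' @param collection a [GeneSetCollection-class].
#' @export
writeGMT <- function(collection, path) {
  lines <- vapply(seq_along(collection@setNames), function(i) {
    paste(c(collection@setNames[i], collection@descriptions[i],
            collection@members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a long-format atlas expression table
#'
#' Columns: `donor`, `region`, `sample`, `transcript`, `value`. Each
#' (donor, sample, transcript) combination must be unique and every sample
#' must map to exactly one region.
#'
#' @param path file path.
#' @return `data.frame` with the five columns.
#' @export
readAtlas <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("donor", "region", "sample", "transcript", "value")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("atlas '", path, "' lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$value))
    stop("atlas '", path, "': value column must be numeric")
  key <- paste(df$donor, df$sample, df$transcript)
  if (anyDuplicated(key))
    stop("atlas '", path, "': duplicated (donor, sample, transcript) rows")
  sampleRegion <- unique(df[c("sample", "region")])
  if (anyDuplicated(sampleRegion$sample))
    stop("atlas '", path, "': some sample maps to more than one region")
  df[need]
}

#' @rdname readAtlas
#' @param atlas long-format atlas `data.frame`.
#' @export
writeAtlas <- function(atlas, path) {
  write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
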