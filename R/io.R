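# Readers and writers for the plain-text interchange formats:
# expression matrices and reference spectra as TSV/CSV (first column = gene,
# header = samples/states), marker sets as GMT or JSON, housekeeping genes as
# one id per line with '#' comments. Gene identifiers are matched by exact
# string equality after whitespace trimming; no alias resolution is attempted.

.guessDelim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readTable <- function(path, delimiter) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expected a gene-id column plus >= 1 data column")
  ids <- trimws(df[[1L]])
  cols <- trimws(colnames(df)[-1L])
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(
    matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing value at gene '%s', column '%s'",
                 ids[bad[1L, 1L]], cols[bad[1L, 2L]]))
  }
  dimnames(num) <- list(ids, cols)
  num
}

#' Read a gene x sample TPM expression matrix
#'
#' Expects a delimited text file whose first column holds gene identifiers
#' and whose header row holds sample identifiers. Values must be numeric,
#' non-missing and non-negative (TPM scale). Rows sharing a gene identifier
#' are collapsed by summation (the usual provenance of such duplicates is
#' transcript-level quantification collapsed to genes, where abundances add).
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param delimiter Field delimiter; by default inferred from the file
#'   extension (`","` for `.csv`, `"\t"` otherwise).
#' @return An [ExpressionMatrix-class] with `stage = "tpm"`.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, delimiter = NULL) {
  delimiter <- .guessDelim(path, delimiter)
  num <- .readTable(path, delimiter)
  if (anyDuplicated(colnames(num)))
    stop("duplicated sample identifier(s): ",
         paste(unique(colnames(num)[duplicated(colnames(num))]), collapse = ", "))
  if (any(num < 0)) {
    i <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative TPM value at gene '%s', sample '%s'",
                 rownames(num)[i[1L]], colnames(num)[i[2L]]))
  }
  if (anyDuplicated(rownames(num))) {
    ndup <- sum(duplicated(rownames(num)))
    warning(ndup, " duplicated gene row(s) collapsed by sum")
    keep <- unique(rownames(num))
    num <- rowsum(num, group = rownames(num), reorder = FALSE)
    num <- num[keep, , drop = FALSE]
  }
  ExpressionMatrix(num, stage = "tpm")
}

.writeMatrix <- function(values, path, delimiter, idHeader) {
  header <- paste(c(idHeader, colnames(values)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i],
            sprintf("%.17g", values[i, ])), collapse = delimiter)
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write an ExpressionMatrix to delimited text
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces them exactly.
#'
#' @param x An [ExpressionMatrix-class].
#' @param path Output file path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, delimiter = "\t") {
  .writeMatrix(exprValues(x), path, delimiter, "gene")
}

#' Read marker gene sets from GMT or JSON
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>...` (the community
#' standard for gene sets); JSON files are a single object mapping state
#' names to arrays of gene identifiers. State names are validated against
#' [canonicalStates()].
#'
#' @param path Path to a `.gmt` or `.json` file (format decided by
#'   extension; anything not ending in `.json` is parsed as GMT).
#' @param strict If `TRUE` (default) an unknown state name is an error;
#'   otherwise such entries are dropped with a warning.
#' @return A [MarkerGeneSets-class] object.
#' @seealso [writeGeneSetsGMT()]
#' @export
readGeneSets <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    sets <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!is.list(sets)) stop("JSON gene sets must be an object of arrays")
    sets <- lapply(sets, as.character)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
      stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
    sets <- lapply(fields, function(f) f[-c(1L, 2L)])
    names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  }
  MarkerGeneSets(sets, strict = strict)
}

#' Write marker gene sets as GMT
#'
#' @param x A [MarkerGeneSets-class] object.
#' @param path Output file path.
#' @param description Description field written to every line (GMT column 2).
#' @return `path`, invisibly.
#' @export
writeGeneSetsGMT <- function(x, path, description = "TStateScore") {
  sets <- geneSets(x)
  lines <- vapply(names(sets), function(s) {
    paste(c(s, description, sets[[s]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a housekeeping gene list
#'
#' One gene identifier per line; `#` starts a comment; blank lines are
#' ignored; duplicates are removed with a warning.
#'
#' @param path Path to the list file.
#' @return A [HousekeepingList-class] object.
#' @export
readHousekeepingGenes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  HousekeepingList(lines[nzchar(lines)])
}

#' Write a housekeeping gene list
#'
#' @param x A [HousekeepingList-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeHousekeepingGenes <- function(x, path) {
  writeLines(hkGenes(x), path)
  invisible(path)
}

#' Read a reference spectrum
#'
#' Expects a delimited gene x state table (first column gene identifiers,
#' header row state names) of non-negative TPM-scale values.
#'
#' @inheritParams readExpressionMatrix
#' @return A [ReferenceSpectrum-class] object.
#' @seealso [writeReferenceSpectrum()], [buildReference()]
#' @export
readReferenceSpectrum <- function(path, delimiter = NULL) {
  delimiter <- .guessDelim(path, delimiter)
  num <- .readTable(path, delimiter)
  if (any(num < 0)) {
    i <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative reference value at gene '%s', state '%s'",
                 rownames(num)[i[1L]], colnames(num)[i[2L]]))
  }
  ReferenceSpectrum(num)
}

#' Write a reference spectrum to delimited text
#'
#' @param x A [ReferenceSpectrum-class] object.
#' @param path Output file path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
writeReferenceSpectrum <- function(x, path, delimiter = "\t") {
  .writeMatrix(refValues(x), path, delimiter, "gene")
}

#' Write scores as TSV plus a JSON provenance sidecar
#'
#' The TSV holds states as rows and samples as columns; `<path>.json`
#' records the seed, normalization mode, effective marker counts and any
#' warnings logged during scoring.
#'
#' @param x A [TCellScores-class] object.
#' @param path Output TSV path (the sidecar is written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
writeScores <- function(x, path) {
  .writeMatrix(stateScores(x), path, "\t", "state")
  md <- S4Vectors::metadata(x)
  side <- list(seed = md$seed, mode = md$mode, nBins = md$nBins,
               perBin = md$perBin, nBackground = md$nBackground,
               markerCounts = markerCounts(x),
               warnings = if (length(md$notes)) md$notes else character(0))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a state x sample score table written by [writeScores()]
#'
#' @param path Path to the score TSV.
#' @return Numeric state x sample matrix.
#' @export
readScores <- function(path) {
  .readTable(path, "\t")
}
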