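#' Canonical T cell state names
#'
#' The eight functional states the scorer knows about, in their canonical
#' order: Quiescence, Regulating, Proliferation, Helper, Cytotoxicity,
#' Progenitor_exhaustion, Terminal_exhaustion, Senescence. This order is also
#' the tie-break order used when calling a sample's dominant state.
#'
#' @return Character vector of length 8.
#' @examples
#' canonicalStates()
#' @export
canonicalStates <- function() {
  c("Quiescence", "Regulating", "Proliferation", "Helper", "Cytotoxicity",
    "Progenitor_exhaustion", "Terminal_exhaustion", "Senescence")
}

.EXPR_STAGES <- c("tpm", "log2", "corrected")

.checkDimnames <- function(v, what) {
  ids <- trimws(v)
  if (is.null(v) || length(v) == 0L)
    return(sprintf("%s identifiers are missing", what))
  if (any(is.na(ids) | !nzchar(ids)))
    return(sprintf("%s identifiers must be non-empty", what))
  if (anyDuplicated(ids))
    return(sprintf("duplicated %s identifiers: %s", what,
                   paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                         collapse = ", ")))
  NULL
}

#' ExpressionMatrix: a gene x sample expression container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single dense `expr` assay of non-negative values, tagged with a processing
#' `stage`: `"tpm"` (raw TPM), `"log2"` (log2(TPM+1)) or `"corrected"`
#' (log2 scale after housekeeping normalization). Stage tags let downstream
#' steps refuse input at the wrong point of the pipeline.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @seealso [ExpressionMatrix()], [exprValues()], [exprStage()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' is required")
  v <- SummarizedExperiment::assay(object, "expr")
  if (nrow(v) < 1L || ncol(v) < 1L)
    return("at least one gene and one sample are required")
  msg <- .checkDimnames(rownames(v), "gene")
  if (!is.null(msg)) return(msg)
  msg <- .checkDimnames(colnames(v), "sample")
  if (!is.null(msg)) return(msg)
  if (!is.numeric(v)) return("expression values must be numeric")
  if (anyNA(v)) return("missing expression values are not allowed")
  if (any(v < 0)) return("negative expression values are not allowed")
  stage <- S4Vectors::metadata(object)$stage
  if (is.null(stage) || !is.character(stage) || length(stage) != 1L ||
      !stage %in% .EXPR_STAGES)
    return(sprintf("stage must be one of %s",
                   paste(.EXPR_STAGES, collapse = ", ")))
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values Numeric gene x sample matrix with unique, non-empty row
#'   (gene) and column (sample) names. All values must be non-negative and
#'   non-missing.
#' @param stage Processing stage tag: `"tpm"`, `"log2"` or `"corrected"`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, stage = "tpm") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(rownames(values))) rownames(values) <- trimws(rownames(values))
  if (!is.null(colnames(values))) colnames(values) <- trimws(colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), metadata = list(stage = stage))
  methods::new("ExpressionMatrix", se)
}

#' MarkerGeneSets: state-specific marker gene sets
#'
#' Named list of marker gene identifiers, one entry per T cell state. State
#' names are validated against [canonicalStates()]; each set must contain at
#' least two unique genes (a rank score over a single marker is meaningless).
#'
#' @slot sets Named list of character vectors.
#' @seealso [MarkerGeneSets()], [readGeneSets()], [geneSets()]
#' @export
setClass("MarkerGeneSets", representation(sets = "list"))

setValidity("MarkerGeneSets", function(object) {
  sets <- object@sets
  if (length(sets) == 0L) return("at least one marker set is required")
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms))) return("sets must be named")
  if (anyDuplicated(nms)) return("duplicated state names")
  unknown <- setdiff(nms, canonicalStates())
  if (length(unknown))
    return(sprintf("unknown state name(s): %s (see canonicalStates())",
                   paste(unknown, collapse = ", ")))
  for (s in nms) {
    g <- sets[[s]]
    if (!is.character(g)) return(sprintf("set '%s' is not a character vector", s))
    if (anyDuplicated(g)) return(sprintf("set '%s' contains duplicated genes", s))
    if (length(g) < 2L)
      return(sprintf("set '%s' has %d gene(s); at least 2 are required",
                     s, length(g)))
  }
  TRUE
})

#' Construct MarkerGeneSets
#'
#' @param sets Named list mapping state names (see [canonicalStates()]) to
#'   character vectors of marker gene identifiers. Gene identifiers are
#'   whitespace-trimmed; duplicates within a set are removed with a warning.
#' @param strict If `TRUE` (default) an unknown state name is an error;
#'   otherwise unknown entries are dropped with a warning.
#' @return A [MarkerGeneSets-class] object.
#' @examples
#' MarkerGeneSets(list(Senescence = c("B3GAT1", "KLRG1", "CDKN2A")))
#' @export
MarkerGeneSets <- function(sets, strict = TRUE) {
  stopifnot(is.list(sets))
  unknown <- setdiff(names(sets), canonicalStates())
  if (length(unknown)) {
    if (strict)
      stop("unknown state name(s): ", paste(unknown, collapse = ", "),
           "; see canonicalStates()")
    warning("dropping unknown state name(s): ", paste(unknown, collapse = ", "))
    sets <- sets[setdiff(names(sets), unknown)]
  }
  sets <- lapply(sets, function(g) {
    g <- trimws(as.character(g))
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning("duplicated genes within a marker set were removed")
      g <- unique(g)
    }
    g
  })
  methods::new("MarkerGeneSets", sets = sets)
}

#' HousekeepingList: stably expressed genes used for normalization
#'
#' @slot genes Character vector of unique gene identifiers.
#' @seealso [HousekeepingList()], [readHousekeepingGenes()],
#'   [housekeepingCorrect()]
#' @export
setClass("HousekeepingList", representation(genes = "character"))

setValidity("HousekeepingList", function(object) {
  g <- object@genes
  if (length(g) == 0L) return("housekeeping list is empty")
  if (any(!nzchar(g))) return("empty gene identifiers")
  if (anyDuplicated(g)) return("duplicated gene identifiers")
  TRUE
})

#' Construct a HousekeepingList
#'
#' @param genes Character vector of gene identifiers; whitespace is trimmed
#'   and duplicates are removed with a warning.
#' @return A [HousekeepingList-class] object.
#' @export
HousekeepingList <- function(genes) {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)),
            " duplicated housekeeping gene(s) removed")
    genes <- unique(genes)
  }
  methods::new("HousekeepingList", genes = genes)
}

#' ReferenceSpectrum: per-state average expression profiles
#'
#' Gene x state matrix of non-negative TPM-scale values, typically averaged
#' from sorted single cells of the subtype that epitomizes each state. At
#' scoring time the spectrum caps each marker's contribution: a marker whose
#' sample expression falls below its reference level contributes only the
#' fraction sample/reference.
#'
#' @slot values Numeric gene x state matrix (TPM scale).
#' @seealso [ReferenceSpectrum()], [readReferenceSpectrum()],
#'   [buildReference()], [referenceWeights()]
#' @export
setClass("ReferenceSpectrum", representation(values = "matrix"))

setValidity("ReferenceSpectrum", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("reference values must be numeric")
  if (nrow(v) < 1L || ncol(v) < 1L)
    return("at least one gene and one state are required")
  msg <- .checkDimnames(rownames(v), "gene")
  if (!is.null(msg)) return(msg)
  msg <- .checkDimnames(colnames(v), "state")
  if (!is.null(msg)) return(msg)
  if (anyNA(v)) return("missing reference values are not allowed")
  if (any(v < 0)) return("negative reference values are not allowed")
  TRUE
})

#' Construct a ReferenceSpectrum
#'
#' @param values Numeric gene x state matrix on TPM scale, with unique gene
#'   rownames and state colnames.
#' @return A [ReferenceSpectrum-class] object.
#' @export
ReferenceSpectrum <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(rownames(values))) rownames(values) <- trimws(rownames(values))
  if (!is.null(colnames(values))) colnames(values) <- trimws(colnames(values))
  methods::new("ReferenceSpectrum", values = values)
}

#' CellCohort: labelled single-cell expression for pseudo-bulk construction
#'
#' @slot values Numeric gene x cell matrix, TPM-like non-negative scale.
#' @slot labels Character vector of subtype labels, named by cell identifier
#'   and aligned with the matrix columns (every cell carries exactly one
#'   label).
#' @seealso [CellCohort()], [makePseudobulk()], [buildReference()]
#' @export
setClass("CellCohort", representation(values = "matrix", labels = "character"))

setValidity("CellCohort", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("cell expression must be numeric")
  msg <- .checkDimnames(rownames(v), "gene")
  if (!is.null(msg)) return(msg)
  msg <- .checkDimnames(colnames(v), "cell")
  if (!is.null(msg)) return(msg)
  if (anyNA(v) || any(v < 0))
    return("cell expression must be non-negative and non-missing")
  lab <- object@labels
  if (length(lab) != ncol(v)) return("one label per cell is required")
  if (is.null(names(lab)) || !identical(names(lab), colnames(v)))
    return("labels must be named by cell id, in matrix column order")
  if (any(is.na(lab) | !nzchar(lab))) return("empty subtype labels")
  TRUE
})

#' Construct a CellCohort
#'
#' @param values Numeric gene x cell matrix.
#' @param labels Character vector of subtype labels, either named by cell id
#'   or positionally aligned with the matrix columns.
#' @return A [CellCohort-class] object.
#' @export
CellCohort <- function(values, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.character(labels)
  if (is.null(names(labels))) names(labels) <- colnames(values)
  labels <- labels[colnames(values)]
  methods::new("CellCohort", values = values, labels = labels)
}

#' BackgroundSample: a stratified random background gene draw
#'
#' Records the genes selected as the rank null, together with the draw
#' parameters (bins, genes per bin, seed) and the pooled-expression ordering
#' statistic that defined the bins, so a draw can be audited and reproduced.
#'
#' @slot genes Character vector of selected background gene identifiers.
#' @slot nBins Number of expression strata.
#' @slot perBin Genes drawn per stratum (after any shrinking).
#' @slot seed Seed used for the draw.
#' @slot stat Named numeric: the per-gene pooled expression used for binning.
#' @seealso [selectBackground()]
#' @export
setClass("BackgroundSample",
         representation(genes = "character", nBins = "integer",
                        perBin = "integer", seed = "integer",
                        stat = "numeric"))

setValidity("BackgroundSample", function(object) {
  if (anyDuplicated(object@genes)) return("background genes must be unique")
  if (length(object@genes) != object@nBins * object@perBin)
    return("background size must equal nBins * perBin")
  TRUE
})

#' TCellScores: state x sample score matrix with provenance
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `score` assay
#' holds one row per scored state and one column per sample. `rowData`
#' records the declared and effective (present in the input matrix) marker
#' counts per state; `metadata` records the background seed, normalization
#' mode, background dimensions and any warnings raised during scoring.
#'
#' @seealso [scoreTCellStates()], [stateScores()], [markerCounts()]
#' @export
setClass("TCellScores", contains = "SummarizedExperiment")

setValidity("TCellScores", function(object) {
  if (!"score" %in% SummarizedExperiment::assayNames(object))
    return("assay 'score' is required")
  md <- S4Vectors::metadata(object)
  for (f in c("seed", "mode"))
    if (is.null(md[[f]])) return(sprintf("metadata field '%s' is required", f))
  v <- SummarizedExperiment::assay(object, "score")
  if (anyNA(v)) return("missing scores are not allowed")
  if (identical(md$mode, "unit") && (any(v < 0) || any(v > 1)))
    return("unit-mode scores must lie in [0, 1]")
  TRUE
})
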