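#' @name accessors
#' @title Accessors for TStateScore classes
#' @description Slot access for the package's S4 containers. Use these rather
#'   than `@`: the internal representation is not part of the API.
#' @param x An object of the documented class.
NULL

#' @describeIn accessors The gene x sample expression values of an
#'   [ExpressionMatrix-class].
#' @export
exprValues <- function(x) {
  stopifnot(methods::is(x, "ExpressionMatrix"))
  SummarizedExperiment::assay(x, "expr")
}

#' @describeIn accessors The processing stage tag (`"tpm"`, `"log2"` or
#'   `"corrected"`) of an [ExpressionMatrix-class].
#' @export
exprStage <- function(x) {
  stopifnot(methods::is(x, "ExpressionMatrix"))
  S4Vectors::metadata(x)$stage
}

#' @describeIn accessors Named list of marker gene vectors in a
#'   [MarkerGeneSets-class].
#' @export
geneSets <- function(x) {
  stopifnot(methods::is(x, "MarkerGeneSets"))
  x@sets
}

#' @describeIn accessors Gene identifiers in a [HousekeepingList-class].
#' @export
hkGenes <- function(x) {
  stopifnot(methods::is(x, "HousekeepingList"))
  x@genes
}

#' @describeIn accessors Gene x state matrix of a [ReferenceSpectrum-class]
#'   (TPM scale).
#' @export
refValues <- function(x) {
  stopifnot(methods::is(x, "ReferenceSpectrum"))
  x@values
}

#' @describeIn accessors State names of a [ReferenceSpectrum-class].
#' @export
refStates <- function(x) colnames(refValues(x))

#' @describeIn accessors Gene x cell matrix of a [CellCohort-class].
#' @export
cohortValues <- function(x) {
  stopifnot(methods::is(x, "CellCohort"))
  x@values
}

#' @describeIn accessors Cell subtype labels (named by cell id) of a
#'   [CellCohort-class].
#' @export
cellLabels <- function(x) {
  stopifnot(methods::is(x, "CellCohort"))
  x@labels
}

#' @describeIn accessors Selected gene identifiers of a
#'   [BackgroundSample-class].
#' @export
backgroundGenes <- function(x) {
  stopifnot(methods::is(x, "BackgroundSample"))
  x@genes
}

#' @describeIn accessors State x sample score matrix of a
#'   [TCellScores-class].
#' @export
stateScores <- function(x) {
  stopifnot(methods::is(x, "TCellScores"))
  SummarizedExperiment::assay(x, "score")
}

#' @describeIn accessors Per-state declared and effective marker counts of a
#'   [TCellScores-class], as a data.frame.
#' @export
markerCounts <- function(x) {
  stopifnot(methods::is(x, "TCellScores"))
  as.data.frame(SummarizedExperiment::rowData(x))
}

setMethod("names", "MarkerGeneSets", function(x) names(x@sets))

setMethod("length", "MarkerGeneSets", function(x) length(x@sets))

setMethod("[[", "MarkerGeneSets", function(x, i) x@sets[[i]])

setMethod("show", "ExpressionMatrix", function(object) {
  v <- exprValues(object)
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (stage: %s)\n",
              nrow(v), ncol(v), exprStage(object)))
  cat("  samples:", paste(utils::head(colnames(v), 5), collapse = ", "),
      if (ncol(v) > 5) "..." else "", "\n")
})

setMethod("show", "MarkerGeneSets", function(object) {
  n <- lengths(object@sets)
  cat(sprintf("MarkerGeneSets: %d state(s)\n", length(n)))
  for (s in names(n)) cat(sprintf("  %-22s %d genes\n", s, n[[s]]))
})

setMethod("show", "HousekeepingList", function(object) {
  cat(sprintf("HousekeepingList: %d genes\n", length(object@genes)))
})

setMethod("show", "ReferenceSpectrum", function(object) {
  v <- object@values
  cat(sprintf("ReferenceSpectrum: %d genes x %d states\n", nrow(v), ncol(v)))
  cat("  states:", paste(colnames(v), collapse = ", "), "\n")
})

setMethod("show", "CellCohort", function(object) {
  cat(sprintf("CellCohort: %d genes x %d cells, %d subtype(s)\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@labels))))
})

setMethod("show", "BackgroundSample", function(object) {
  cat(sprintf("BackgroundSample: %d genes (%d bins x %d per bin, seed %d)\n",
              length(object@genes), object@nBins, object@perBin, object@seed))
})

setMethod("show", "TCellScores", function(object) {
  v <- stateScores(object)
  md <- S4Vectors::metadata(object)
  cat(sprintf("TCellScores: %d state(s) x %d sample(s) [mode %s, seed %d]\n",
              nrow(v), ncol(v), md$mode, md$seed))
  print(round(v[, seq_len(min(5L, ncol(v))), drop = FALSE], 3))
  if (ncol(v) > 5) cat("  ...", ncol(v) - 5, "more sample(s)\n")
})
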