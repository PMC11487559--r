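#' Pseudo-bulk sampling design for one subtype
#'
#' Number of pseudo-bulk replicates and cells per draw for a subtype with
#' `nCells` cells: `reps = max(1, floor(nCells / repsDivisor))` and
#' `drawSize = ceiling(fraction * nCells)`.
#'
#' @param nCells Number of cells of the subtype.
#' @param fraction Fraction of cells averaged per pseudo-bulk sample
#'   (default 0.6).
#' @param repsDivisor The replicate count is the cell count divided by this
#'   (default 5, i.e. one fifth of the cells), floored, with a minimum of 1.
#' @return List with integer elements `reps` and `drawSize`.
#' @examples
#' pseudobulkDesign(10)  # 2 replicates of 6 cells each
#' @export
pseudobulkDesign <- function(nCells, fraction = 0.6, repsDivisor = 5L) {
  stopifnot(fraction > 0, fraction <= 1, repsDivisor >= 1)
  list(reps = max(1L, as.integer(nCells %/% repsDivisor)),
       drawSize = as.integer(ceiling(fraction * nCells)))
}

#' Build pseudo-bulk samples from a labelled cell cohort
#'
#' Emulates purified bulk samples from single cells: for each subtype with
#' c cells, `max(1, floor(c / repsDivisor))` pseudo-bulk samples are
#' generated, each the per-gene arithmetic mean (on the linear expression
#' scale, no re-normalization) of `ceiling(fraction * c)` cells drawn
#' uniformly without replacement. Samples are named `subtype_rep`.
#' Subtypes with fewer than 2 cells are skipped with a warning.
#'
#' @param cohort A [CellCohort-class].
#' @param fraction Fraction of cells per draw (default 0.6).
#' @param repsDivisor Divisor for the replicate count (default 5).
#' @param seed Integer seed making the draws reproducible (default 1).
#' @return List with `expression` (an [ExpressionMatrix-class],
#'   `stage = "tpm"`) and `labels` (sample name -> subtype).
#' @examples
#' v <- matrix(rexp(500), 50, 10,
#'   dimnames = list(paste0("g", 1:50), paste0("c", 1:10)))
#' pb <- makePseudobulk(CellCohort(v, rep("Tn", 10)), seed = 1)
#' ncol(exprValues(pb$expression))  # 2
#' @export
makePseudobulk <- function(cohort, fraction = 0.6, repsDivisor = 5L,
                           seed = 1L) {
  stopifnot(methods::is(cohort, "CellCohort"),
            fraction > 0, fraction <= 1)
  v <- cohortValues(cohort)
  labels <- cellLabels(cohort)
  subtypes <- sort(unique(labels))
  cols <- list()
  outLabels <- character(0)
  withr::with_seed(as.integer(seed), {
    for (st in subtypes) {
      cells <- names(labels)[labels == st]
      if (length(cells) < 2L) {
        warning("subtype '", st, "' has fewer than 2 cells; skipped")
        next
      }
      d <- pseudobulkDesign(length(cells), fraction, repsDivisor)
      for (r in seq_len(d$reps)) {
        drawn <- sample(cells, d$drawSize)
        nm <- paste0(st, "_", r)
        cols[[nm]] <- rowMeans(v[, drawn, drop = FALSE])
        outLabels[nm] <- st
      }
    }
  })
  if (!length(cols)) stop("no subtype had enough cells for pseudo-bulk")
  mat <- do.call(cbind, cols)
  rownames(mat) <- rownames(v)
  list(expression = ExpressionMatrix(mat, stage = "tpm"),
       labels = outLabels)
}

#' Build a reference spectrum from labelled cells
#'
#' Averages (arithmetic mean, linear scale) the expression profiles of all
#' cells mapped to each target state. Any external refinement of the labels
#' (e.g. splitting exhausted cells into progenitor and terminal stages along
#' a trajectory) is supplied through `stateMap`.
#'
#' @param cohort A [CellCohort-class].
#' @param stateMap Named character vector mapping subtype labels to state
#'   names; subtypes not named are ignored.
#' @return A [ReferenceSpectrum-class] with one column per mapped state.
#' @examples
#' v <- matrix(rexp(300), 30, 10,
#'   dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
#' co <- CellCohort(v, rep(c("Tn", "Treg"), each = 5))
#' buildReference(co, c(Tn = "Quiescence", Treg = "Regulating"))
#' @export
buildReference <- function(cohort, stateMap) {
  stopifnot(methods::is(cohort, "CellCohort"),
            is.character(stateMap), !is.null(names(stateMap)))
  v <- cohortValues(cohort)
  labels <- cellLabels(cohort)
  states <- unique(unname(stateMap))
  cols <- matrix(0, nrow(v), length(states),
                 dimnames = list(rownames(v), states))
  for (s in states) {
    subtypes <- names(stateMap)[stateMap == s]
    cells <- names(labels)[labels %in% subtypes]
    if (!length(cells))
      stop("state '", s, "' has no mapped cells in the cohort")
    cols[, s] <- rowMeans(v[, cells, drop = FALSE])
  }
  ReferenceSpectrum(cols)
}
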