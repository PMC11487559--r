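# Synthetic cohort generator. Emulates the kinds of validation inputs the
# scorer is meant for -- bulk cohorts of samples dominated by one state with
# that state's markers shifted up, plus self-consistent marker sets,
# housekeeping genes and reference spectrum -- so every pipeline stage can
# be exercised without any external download. It deliberately does not model
# scRNA-seq count noise (dropout, overdispersion).

.expandPerState <- function(x, states, what, integer = FALSE) {
  nms <- names(x)
  x <- if (integer) as.integer(x) else as.numeric(x)
  names(x) <- nms
  if (length(x) == 1L && is.null(nms))
    return(stats::setNames(rep(x, length(states)), states))
  if (is.null(nms) || !all(states %in% nms))
    stop(what, " must be a scalar or a vector named by every state")
  x[states]
}

#' Simulate a bulk expression cohort with planted state effects
#'
#' Generates a self-consistent bundle of scorer inputs. Gene-level baseline
#' log2-TPM means are drawn from a normal distribution (i.e. a log-normal
#' TPM profile, giving the skewed dynamic range that expression-stratified
#' background binning assumes). Each sample is assigned a dominant state in
#' round-robin order over `states`; the markers of that state are shifted up
#' by the state's log2 `effectSize`. Housekeeping genes get near-zero
#' inter-sample noise (`hkNoiseSD`), so correction factors stay near 1
#' unless a library-size distortion is planted via `sampleScaleSD`. The
#' reference spectrum is built from the generator's own per-state mean
#' profiles, so the planted truth and the reference agree.
#'
#' @param nGenes Total number of genes; must cover markers plus housekeeping
#'   genes with room for background.
#' @param nSamples Number of samples.
#' @param states States to simulate (default all of [canonicalStates()]).
#' @param markersPerState Markers per state: scalar or named vector
#'   (default 12, within the 5-38 range typical of curated state signatures).
#' @param effectSize Planted log2 shift of a sample's dominant-state
#'   markers: scalar or named vector (default 2).
#' @param hkCount Number of housekeeping genes (default 500).
#' @param noiseSD Per-gene, per-sample log2 noise SD for non-housekeeping
#'   genes (default 0.5).
#' @param baselineLog2Mean,baselineLog2SD Location and scale of the gene-
#'   level baseline means on the log2 TPM scale (defaults 1 and 1).
#' @param hkNoiseSD Inter-sample noise SD of housekeeping genes
#'   (default 0.01).
#' @param sampleScaleSD SD of a per-sample global log2 shift emulating
#'   library-size distortion (default 0, i.e. none).
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   it.
#' @return List with elements `expression` ([ExpressionMatrix-class],
#'   `stage = "tpm"`), `markers` ([MarkerGeneSets-class]), `housekeeping`
#'   ([HousekeepingList-class]), `reference` ([ReferenceSpectrum-class]) and
#'   `truth` (named character, sample -> planted dominant state).
#' @examples
#' sim <- simulateCohort(nGenes = 1200, nSamples = 4, markersPerState = 5,
#'                       hkCount = 100, seed = 1)
#' sim$truth
#' @export
simulateCohort <- function(nGenes = 12000L, nSamples = 16L,
                           states = canonicalStates(),
                           markersPerState = 12L, effectSize = 2,
                           hkCount = 500L, noiseSD = 0.5,
                           baselineLog2Mean = 1, baselineLog2SD = 1,
                           hkNoiseSD = 0.01, sampleScaleSD = 0,
                           seed = 1L) {
  stopifnot(nSamples >= 1L, length(states) >= 1L)
  nMark <- .expandPerState(markersPerState, states, "markersPerState",
                           integer = TRUE)
  if (any(nMark < 2L)) stop("each state needs at least 2 markers")
  eff <- .expandPerState(effectSize, states, "effectSize")
  if (any(eff < 0)) stop("effect sizes must be non-negative")
  needed <- sum(nMark) + hkCount + 50L
  if (nGenes < needed)
    stop("nGenes = ", nGenes, " is infeasible; at least ", needed,
         " genes are required for ", sum(nMark), " markers plus ", hkCount,
         " housekeeping genes")

  genes <- sprintf("g%05d", seq_len(nGenes))
  samples <- sprintf("s%03d", seq_len(nSamples))
  truth <- stats::setNames(rep_len(states, nSamples), samples)

  withr::with_seed(as.integer(seed), {
    mu <- stats::rnorm(nGenes, baselineLog2Mean, baselineLog2SD)
    special <- sample.int(nGenes, sum(nMark) + hkCount)
    hkIdx <- special[seq_len(hkCount)]
    markIdx <- split(special[-seq_len(hkCount)],
                     rep(seq_along(states), nMark))
    names(markIdx) <- states

    noise <- matrix(stats::rnorm(nGenes * nSamples, 0, noiseSD),
                    nGenes, nSamples)
    noise[hkIdx, ] <- stats::rnorm(hkCount * nSamples, 0, hkNoiseSD)
    logExpr <- mu + noise
    if (sampleScaleSD > 0) {
      shift <- stats::rnorm(nSamples, 0, sampleScaleSD)
      logExpr <- sweep(logExpr, 2L, shift, "+")
    }
    for (j in seq_len(nSamples)) {
      s <- truth[[j]]
      logExpr[markIdx[[s]], j] <- logExpr[markIdx[[s]], j] + eff[[s]]
    }
  })

  tpm <- pmax(2^logExpr - 1, 0)
  dimnames(tpm) <- list(genes, samples)

  refLog <- matrix(mu, nGenes, length(states),
                   dimnames = list(genes, states))
  for (s in states) refLog[markIdx[[s]], s] <- refLog[markIdx[[s]], s] + eff[[s]]
  refTpm <- pmax(2^refLog - 1, 0)

  list(expression = ExpressionMatrix(tpm, stage = "tpm"),
       markers = MarkerGeneSets(lapply(markIdx, function(i) genes[i])),
       housekeeping = HousekeepingList(genes[hkIdx]),
       reference = ReferenceSpectrum(refTpm),
       truth = truth)
}

#' Simulate a labelled single-cell cohort
#'
#' Per-cell expression is the subtype's mean profile plus cell-level log2
#' noise; each subtype gets a disjoint block of marker genes shifted up by
#' its effect size. Intended to feed [makePseudobulk()] and
#' [buildReference()].
#'
#' @param nGenes Number of genes.
#' @param cellsPerSubtype Named integer vector: cells per subtype (each at
#'   least 2).
#' @param subtypeEffects Log2 marker shift per subtype: scalar or vector
#'   named by subtype (default 2).
#' @param markersPerSubtype Marker genes per subtype (default 20).
#' @param noiseSD Cell-level log2 noise SD (default 0.5); 0 makes all cells
#'   of a subtype identical.
#' @param baselineLog2Mean,baselineLog2SD Baseline mean distribution, as in
#'   [simulateCohort()].
#' @param seed Integer seed.
#' @return A [CellCohort-class].
#' @examples
#' co <- simulateCellCohort(500, c(Tn = 10, Treg = 6), seed = 1)
#' table(cellLabels(co))
#' @export
simulateCellCohort <- function(nGenes = 3000L, cellsPerSubtype,
                               subtypeEffects = 2, markersPerSubtype = 20L,
                               noiseSD = 0.5, baselineLog2Mean = 1,
                               baselineLog2SD = 1, seed = 1L) {
  stopifnot(is.numeric(cellsPerSubtype), !is.null(names(cellsPerSubtype)))
  if (any(cellsPerSubtype < 2L)) stop("each subtype needs at least 2 cells")
  subtypes <- names(cellsPerSubtype)
  eff <- .expandPerState(subtypeEffects, subtypes, "subtypeEffects")
  need <- markersPerSubtype * length(subtypes)
  if (nGenes < need + 50L)
    stop("nGenes too small; at least ", need + 50L, " genes are required")
  genes <- sprintf("g%05d", seq_len(nGenes))
  nCells <- sum(cellsPerSubtype)
  labels <- rep(subtypes, cellsPerSubtype)
  cells <- paste0(labels, "_c", unlist(lapply(cellsPerSubtype, seq_len)))

  withr::with_seed(as.integer(seed), {
    mu <- stats::rnorm(nGenes, baselineLog2Mean, baselineLog2SD)
    markIdx <- split(sample.int(nGenes, need),
                     rep(seq_along(subtypes), each = markersPerSubtype))
    names(markIdx) <- subtypes
    logExpr <- mu + matrix(stats::rnorm(nGenes * nCells, 0, noiseSD),
                           nGenes, nCells)
    for (j in seq_len(nCells))
      logExpr[markIdx[[labels[j]]], j] <-
        logExpr[markIdx[[labels[j]]], j] + eff[[labels[j]]]
  })
  tpm <- pmax(2^logExpr - 1, 0)
  dimnames(tpm) <- list(genes, cells)
  CellCohort(tpm, stats::setNames(labels, cells))
}
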