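# The scoring core. For one sample and one state, the marker set's
# within-sample expression ranks against a stratified random background are
# summarised by a Mann-Whitney U statistic,
#   U = sum(R.marker) - n(n+1)/2,
# and normalized to a rank score; the score is then capped marker-wise by a
# reference spectrum so that a high value must come from broadly elevated
# markers, not one extreme outlier.

#' Rank score from marker ranks (Mann-Whitney U)
#'
#' Computes `U = sum(markerRanks) - n(n+1)/2` over a combined panel of
#' `nMarkers` markers and `nBackground` background genes, then normalizes:
#'
#' * `mode = "unit"` (default): `U / (nMarkers * nBackground)`, the standard
#'   Mann-Whitney normalization. The value is the probability that a
#'   randomly chosen marker outranks a randomly chosen background gene (ties
#'   counted half) and is guaranteed to lie in \[0, 1\].
#' * `mode = "printed"`: `U / (nMarkers + nBackground)`, the divisor as
#'   printed in the method's defining formula; retained for formula-level
#'   reproduction but not bounded by 1.
#'
#' @param markerRanks Numeric vector (or markers x samples matrix) of the
#'   markers' ranks within the combined panel, as produced by
#'   [rankExpression()].
#' @param nBackground Number of background genes in the panel.
#' @param mode `"unit"` or `"printed"`.
#' @return Numeric score (one per sample column if a matrix was given).
#' @examples
#' r <- rankExpression(c(5, 1, 4, 3, 2))  # markers are the first two genes
#' markerUScore(r[1:2], nBackground = 3, mode = "unit")     # 0.5
#' markerUScore(r[1:2], nBackground = 3, mode = "printed")  # 0.6
#' @export
markerUScore <- function(markerRanks, nBackground,
                         mode = c("unit", "printed")) {
  mode <- match.arg(mode)
  n <- if (is.matrix(markerRanks)) nrow(markerRanks) else length(markerRanks)
  if (n < 2L)
    stop("at least 2 markers are required to compute a rank score")
  if (nBackground < 1L) stop("at least 1 background gene is required")
  total <- if (is.matrix(markerRanks)) colSums(markerRanks)
           else sum(markerRanks)
  U <- total - n * (n + 1) / 2
  switch(mode,
         unit = U / (n * nBackground),
         printed = U / (n + nBackground))
}

#' Reference-spectrum marker weights
#'
#' For each marker, compares the sample's expression `sp` with the reference
#' spectrum's `ref` on the same scale: the weight is 1 when `sp >= ref` and
#' `sp / ref` otherwise, so a marker under-expressed relative to its
#' reference contributes proportionally less. A marker with `ref = 0`
#' receives weight 1 (an absent reference level cannot penalize; the
#' `sp >= ref` branch covers `sp = ref = 0`).
#'
#' @param sp Numeric vector of the markers' sample expression.
#' @param ref Numeric vector of the same markers' reference expression, on
#'   the same scale as `sp`.
#' @return Numeric vector of weights in \[0, 1\].
#' @export
referenceWeights <- function(sp, ref) {
  if (length(sp) != length(ref))
    stop("sp and ref must have equal length")
  if (any(sp < 0) || any(ref < 0))
    stop("negative expression values are not allowed")
  w <- ifelse(ref <= 0 | sp >= ref, 1, sp / ref)
  w
}

#' Combine a rank score with reference weights
#'
#' The final state score is the rank score multiplied by the mean marker
#' weight; with all weights at 1 it equals the rank score, and it can never
#' exceed it.
#'
#' @param uScore Rank score from [markerUScore()] (scalar or per-sample
#'   vector).
#' @param weights Numeric vector (or markers x samples matrix) of weights
#'   from [referenceWeights()].
#' @return Numeric final score.
#' @export
weightedScore <- function(uScore, weights) {
  if (length(weights) == 0L) stop("weights must be non-empty")
  wbar <- if (is.matrix(weights)) colMeans(weights) else mean(weights)
  uScore * wbar
}

#' Score T cell states across samples
#'
#' Runs the full pipeline on a TPM matrix: log2(TPM+1) transform,
#' housekeeping normalization, one seeded stratified background draw shared
#' by all states and samples, then for each state: the state's markers are
#' removed from the background, each sample's combined background-plus-marker
#' panel is ranked, the marker ranks give a Mann-Whitney rank score, and the
#' score is multiplied by the mean reference weight of the markers (the
#' reference spectrum is placed on the log2(TPM+1) scale for the
#' comparison; no housekeeping correction is applied to it).
#'
#' Markers absent from the input matrix are dropped from both the rank score
#' and the weight mean; a state with fewer than 2 present markers is skipped
#' with a warning (or is an error when `strict = TRUE`). If the matrix has
#' fewer than `nBins * perBin` genes plus the largest marker set, `perBin`
#' is shrunk with a warning (an effective `perBin` below 5 is an error).
#'
#' @param m An [ExpressionMatrix-class] with `stage = "tpm"`.
#' @param sets A [MarkerGeneSets-class].
#' @param ref A [ReferenceSpectrum-class]; must contain a column for every
#'   scored state.
#' @param hk A [HousekeepingList-class].
#' @param seed Integer seed for the background draw (default 1).
#' @param mode Normalization mode, `"unit"` (default, scores in \[0, 1\]) or
#'   `"printed"`; see [markerUScore()].
#' @param strict If `TRUE`, a state with fewer than 2 present markers is an
#'   error instead of being skipped.
#' @param nBins,perBin Background stratification parameters, see
#'   [selectBackground()].
#' @param minHK Passed to [housekeepingCorrect()].
#' @return A [TCellScores-class] object: assay `score` (states x samples),
#'   `rowData` columns `nMarkers` (declared) and `nPresent` (found in the
#'   matrix), and metadata `seed`, `mode`, `nBins`, `perBin`,
#'   `nBackground` and `notes` (warnings log).
#' @examples
#' sim <- simulateCohort(nGenes = 1500, nSamples = 6, markersPerState = 5,
#'                       hkCount = 100, effectSize = 3, seed = 7)
#' res <- scoreTCellStates(sim$expression, sim$markers, sim$reference,
#'                         sim$housekeeping, seed = 7, nBins = 10, perBin = 50)
#' stateScores(res)[, 1:3]
#' @export
scoreTCellStates <- function(m, sets, ref, hk, seed = 1L,
                             mode = c("unit", "printed"), strict = FALSE,
                             nBins = 50L, perBin = 100L, minHK = 50L) {
  stopifnot(methods::is(m, "ExpressionMatrix"),
            methods::is(sets, "MarkerGeneSets"),
            methods::is(ref, "ReferenceSpectrum"),
            methods::is(hk, "HousekeepingList"))
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  notes <- character(0)
  note <- function(msg) {
    notes <<- c(notes, msg)
    warning(msg, call. = FALSE)
  }

  corrected <- housekeepingCorrect(log2Transform(m), hk, minHK = minHK)
  cv <- exprValues(corrected)

  allSets <- geneSets(sets)
  missingStates <- setdiff(names(allSets), refStates(ref))
  if (length(missingStates))
    stop("reference spectrum lacks state column(s): ",
         paste(missingStates, collapse = ", "))

  # keep canonical ordering for the result rows (and dominance tie-breaks)
  stateOrder <- intersect(canonicalStates(), names(allSets))
  allSets <- allSets[stateOrder]

  maxSet <- max(lengths(allSets))
  nBins <- as.integer(nBins)
  perBin <- as.integer(perBin)
  if (nrow(cv) < nBins * perBin + maxSet) {
    newPerBin <- (nrow(cv) - maxSet) %/% nBins
    if (newPerBin < 5L)
      stop("too few genes (", nrow(cv), ") for ", nBins,
           " background bins; an effective per-bin draw of ", newPerBin,
           " is below the minimum of 5")
    note(sprintf(
      "matrix has %d genes, fewer than nBins * perBin + largest marker set; perBin shrunk from %d to %d",
      nrow(cv), perBin, newPerBin))
    perBin <- newPerBin
  }
  bg <- selectBackground(corrected, nBins = nBins, perBin = perBin, seed = seed)
  bgGenes <- backgroundGenes(bg)

  refLog <- log2(refValues(ref) + 1)

  scores <- list()
  nPresent <- integer(0)
  for (state in names(allSets)) {
    markers <- allSets[[state]]
    present <- intersect(markers, rownames(cv))
    if (length(present) < length(markers))
      note(sprintf("state %s: %d of %d markers absent from the matrix",
                   state, length(markers) - length(present), length(markers)))
    if (length(present) < 2L) {
      if (strict)
        stop("state ", state, " has fewer than 2 markers present in the matrix")
      note(sprintf("state %s skipped: fewer than 2 markers present", state))
      next
    }
    panelBg <- setdiff(bgGenes, markers)
    panel <- c(panelBg, present)
    sub <- cv[panel, , drop = FALSE]
    ranks <- apply(sub, 2L, rankExpression)
    markerIdx <- seq.int(length(panelBg) + 1L, length(panel))
    u <- markerUScore(ranks[markerIdx, , drop = FALSE],
                      nBackground = length(panelBg), mode = mode)
    rv <- rep(0, length(present))
    inRef <- present %in% rownames(refLog)
    rv[inRef] <- refLog[present[inRef], state]
    spm <- cv[present, , drop = FALSE]
    w <- sweep(spm, 1L, rv, "/")
    w <- pmin(w, 1)
    w[rv <= 0, ] <- 1
    scores[[state]] <- weightedScore(u, w)
    nPresent[state] <- length(present)
  }
  if (!length(scores))
    stop("no state could be scored: every marker set had fewer than 2 ",
         "markers present")

  mat <- do.call(rbind, scores)
  colnames(mat) <- colnames(cv)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = mat),
    rowData = S4Vectors::DataFrame(
      nMarkers = lengths(allSets)[rownames(mat)],
      nPresent = nPresent[rownames(mat)]),
    metadata = list(
      seed = seed, mode = mode, nBins = nBins, perBin = bg@perBin,
      nBackground = length(bgGenes), notes = notes))
  methods::new("TCellScores", se)
}
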