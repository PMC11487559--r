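# Shared fixtures and independent oracles.

# Brute-force Mann-Whitney win fraction: the probability that a random
# marker value exceeds a random background value, ties counted half.
# Independent of the rank-based implementation it checks.
bruteWinFraction <- function(marker, background) {
  wins <- sum(outer(marker, background, ">")) +
    0.5 * sum(outer(marker, background, "=="))
  wins / (length(marker) * length(background))
}

# A small corrected-stage matrix with known, deterministic values.
toyCorrected <- function(nGenes = 100, nSamples = 3) {
  v <- matrix(rep(seq(nGenes, 1), nSamples), nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              paste0("s", seq_len(nSamples))))
  ExpressionMatrix(v, stage = "corrected")
}

# Default small simulation used across tests: big enough to leave room for
# a reduced background (10 bins x 50 genes) next to the marker sets.
smallSim <- function(seed = 1, effectSize = 2, nSamples = 8,
                     nGenes = 1500, markersPerState = 6, hkCount = 120, ...) {
  simulateCohort(nGenes = nGenes, nSamples = nSamples,
                 markersPerState = markersPerState, hkCount = hkCount,
                 effectSize = effectSize, seed = seed, ...)
}

smallScore <- function(sim, seed = 1, nBins = 10, perBin = 50, ...) {
  scoreTCellStates(sim$expression, sim$markers, sim$reference,
                   sim$housekeeping, seed = seed,
                   nBins = nBins, perBin = perBin, minHK = 50, ...)
}

writeTempLines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
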