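test_that("rank score reproduces the worked two-marker example in both modes", {
  vals <- c(5, 1, 4, 3, 2)       # markers first (5, 1), background (4, 3, 2)
  r <- rankExpression(vals)
  expect_equal(markerUScore(r[1:2], nBackground = 3, mode = "unit"), 0.5)
  expect_equal(markerUScore(r[1:2], nBackground = 3, mode = "printed"), 0.6)
})

test_that("rank score attains its bounds at the extremes", {
  r <- rankExpression(c(10, 9, 8, 3, 2, 1))  # markers = top 3
  expect_equal(markerUScore(r[1:3], nBackground = 3, mode = "unit"), 1)
  r2 <- rankExpression(c(1, 2, 8, 9, 10))    # markers = bottom 2
  expect_equal(markerUScore(r2[1:2], nBackground = 3, mode = "unit"), 0)
  expect_error(markerUScore(5, nBackground = 3), "at least 2 markers")
})

test_that("unit-mode rank score equals the brute-force pairwise win fraction", {
  set.seed(11)
  for (i in 1:200) {
    nm <- sample(3:10, 1)
    nb <- sample(20:200, 1)
    # duplicate-prone values so tie handling is exercised
    vals <- sample(seq(0, 5, by = 0.5), nm + nb, replace = TRUE)
    marker <- vals[seq_len(nm)]
    background <- vals[-seq_len(nm)]
    r <- rankExpression(vals)
    got <- markerUScore(r[seq_len(nm)], nBackground = nb, mode = "unit")
    expect_equal(got, bruteWinFraction(marker, background), tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("reference weights follow the capped-ratio rule", {
  expect_equal(referenceWeights(c(2, 3), c(2, 3)), c(1, 1))
  expect_equal(referenceWeights(c(1, 2), c(2, 4)), c(0.5, 0.5))
  expect_equal(referenceWeights(c(0, 5), c(0, 0)), c(1, 1))
  expect_equal(referenceWeights(c(3, 1), c(2, 4)), c(1, 0.25))
  expect_error(referenceWeights(c(-1, 1), c(1, 1)), "negative")
})

test_that("final score is the rank score times the mean weight, never above it", {
  expect_equal(weightedScore(0.8, c(1, 1, 1)), 0.8)
  expect_equal(weightedScore(0.8, c(0.25, 0.75)), 0.4)
  expect_equal(weightedScore(0, c(0.1, 0.9)), 0)
  set.seed(3)
  for (i in 1:50) {
    u <- runif(1)
    w <- runif(sample(2:10, 1))
    expect_lte(weightedScore(u, w), u + 1e-15)
  }
})

test_that("planted marker up-regulation raises the state's score", {
  sim <- smallSim(seed = 21, effectSize = c(
    Quiescence = 0, Regulating = 0, Proliferation = 0, Helper = 0,
    Cytotoxicity = 3, Progenitor_exhaustion = 0, Terminal_exhaustion = 0,
    Senescence = 0), nSamples = 16)
  res <- smallScore(sim, seed = 21)
  sc <- stateScores(res)["Cytotoxicity", ]
  groupA <- names(sim$truth)[sim$truth == "Cytotoxicity"]
  groupB <- setdiff(names(sc), groupA)
  expect_gt(mean(sc[groupA]), mean(sc[groupB]))
})

test_that("scoring is deterministic for a fixed seed", {
  sim <- smallSim(seed = 5)
  a <- smallScore(sim, seed = 2)
  b <- smallScore(sim, seed = 2)
  expect_identical(stateScores(a), stateScores(b))
  expect_identical(S4Vectors::metadata(a)$seed, 2L)
})

test_that("unit-mode scores always lie in [0, 1] and rows follow canonical order", {
  sim <- smallSim(seed = 33, effectSize = 4)
  res <- smallScore(sim, seed = 33)
  v <- stateScores(res)
  expect_true(all(v >= 0 & v <= 1))
  expect_identical(rownames(v), canonicalStates())
  expect_identical(dim(v), c(8L, 8L))
})

test_that("monotone transforms of a sample's column leave its rank score unchanged", {
  sim <- smallSim(seed = 14, nSamples = 4)
  corrected <- housekeepingCorrect(log2Transform(sim$expression),
                                   sim$housekeeping, minHK = 50)
  bg <- selectBackground(corrected, nBins = 10, perBin = 50, seed = 1)
  markers <- geneSets(sim$markers)$Helper
  panel <- c(setdiff(backgroundGenes(bg), markers), markers)
  col <- exprValues(corrected)[panel, 2]
  nb <- length(panel) - length(markers)
  mIdx <- seq.int(nb + 1, length(panel))
  base <- markerUScore(rankExpression(col)[mIdx], nBackground = nb)
  for (f in list(function(x) 2 * x + 1, function(x) x^3, function(x) exp(x))) {
    expect_equal(markerUScore(rankExpression(f(col))[mIdx], nBackground = nb),
                 base, tolerance = 1e-12)
  }
})

test_that("raising every marker in one sample never lowers its rank score", {
  set.seed(99)
  for (i in 1:20) {
    nb <- 50
    nm <- 5
    vals <- rexp(nb + nm)
    mIdx <- seq_len(nm)
    # markers placed after the background in the panel
    panel <- c(vals[-mIdx], vals[mIdx])
    before <- markerUScore(rankExpression(panel)[nb + seq_len(nm)],
                           nBackground = nb)
    bumped <- panel
    bumped[nb + seq_len(nm)] <- bumped[nb + seq_len(nm)] + runif(1, 0, 2)
    after <- markerUScore(rankExpression(bumped)[nb + seq_len(nm)],
                          nBackground = nb)
    expect_gte(after, before - 1e-12)
  }
})

test_that("states with too few present markers are skipped or error under strict", {
  sim <- smallSim(seed = 8, nSamples = 4)
  sets <- geneSets(sim$markers)
  sets$Helper <- c("not_a_gene_1", "not_a_gene_2", sets$Helper[1])
  badSets <- MarkerGeneSets(sets)
  warns <- testthat::capture_warnings(
    res <- scoreTCellStates(sim$expression, badSets, sim$reference,
                            sim$housekeeping, seed = 1, nBins = 10,
                            perBin = 50, minHK = 50))
  expect_true(any(grepl("Helper skipped", warns)))
  expect_false("Helper" %in% rownames(stateScores(res)))
  expect_identical(nrow(stateScores(res)), 7L)
  expect_error(
    suppressWarnings(
      scoreTCellStates(sim$expression, badSets, sim$reference,
                       sim$housekeeping, seed = 1, nBins = 10, perBin = 50,
                       minHK = 50, strict = TRUE)),
    "fewer than 2 markers")
})

test_that("a reference spectrum missing a requested state is an error", {
  sim <- smallSim(seed = 8, nSamples = 4)
  ref <- ReferenceSpectrum(refValues(sim$reference)[, -4])  # drop Helper
  expect_error(
    scoreTCellStates(sim$expression, sim$markers, ref, sim$housekeeping,
                     seed = 1, nBins = 10, perBin = 50, minHK = 50),
    "lacks state column.*Helper")
})

test_that("scores are stable across background seeds (rank ordering preserved)", {
  sim <- simulateCohort(nGenes = 12000, nSamples = 10, markersPerState = 10,
                        hkCount = 400, effectSize = 2, seed = 77)
  ranks <- lapply(1:6, function(s) {
    v <- stateScores(scoreTCellStates(sim$expression, sim$markers,
                                      sim$reference, sim$housekeeping,
                                      seed = s))
    apply(v, 1, rank)  # samples x states, per-state sample ranks
  })
  for (i in 1:5) {
    for (j in (i + 1):6) {
      rho <- diag(cor(ranks[[i]], ranks[[j]], method = "spearman"))
      expect_true(all(rho >= 0.95))
    }
  }
})

test_that("permuting input gene rows leaves the scores unchanged", {
  sim <- smallSim(seed = 4, nSamples = 4)
  res <- smallScore(sim, seed = 6)
  v <- exprValues(sim$expression)
  set.seed(1)
  perm <- ExpressionMatrix(v[sample(nrow(v)), ], stage = "tpm")
  resPerm <- scoreTCellStates(perm, sim$markers, sim$reference,
                              sim$housekeeping, seed = 6,
                              nBins = 10, perBin = 50, minHK = 50)
  expect_equal(stateScores(resPerm), stateScores(res), tolerance = 1e-12)
})
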