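test_that("rocAUC matches hand-counted and degenerate cases", {
  expect_equal(rocAUC(c(10, 9, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rocAUC(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_error(rocAUC(c(3, 1), c(TRUE, TRUE)), "both classes")
  expect_equal(rocAUC(c(1, 2, 3, 4), c("a", "b", "a", "b"), positive = "b"),
               0.75)
  expect_error(rocAUC(c(1, 2), c("a", "b")), "positive")
})

test_that("rocAUC equals the brute-force pairwise probability on random instances", {
  set.seed(19)
  for (i in 1:500) {
    nPos <- sample(2:15, 1)
    nNeg <- sample(2:15, 1)
    scores <- sample(seq(0, 1, by = 0.1), nPos + nNeg, replace = TRUE)
    labels <- c(rep(TRUE, nPos), rep(FALSE, nNeg))
    expect_equal(rocAUC(scores, labels),
                 bruteWinFraction(scores[labels], scores[!labels]),
                 tolerance = 1e-12)
  }
})

test_that("rocAUC is complementary under label flip for tie-free scores", {
  set.seed(20)
  for (i in 1:50) {
    scores <- rnorm(12)
    labels <- sample(c(rep(TRUE, 5), rep(FALSE, 7)))
    expect_equal(rocAUC(scores, labels) + rocAUC(scores, !labels), 1,
                 tolerance = 1e-12)
  }
})

test_that("rocAUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- rnorm(40)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  expect_equal(rocAUC(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

mkScores <- function(v, samples = sprintf("s%d", seq_len(ncol(v)))) {
  colnames(v) <- samples
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = v), metadata = list(seed = 1L, mode = "unit"))
  methods::new("TCellScores", se)
}

test_that("dominant-state proportions sum to 1 and handle unique maxima", {
  v <- rbind(Quiescence = c(0.9, 0.2, 0.8),
             Helper     = c(0.1, 0.7, 0.2))
  res <- mkScores(v)
  out <- dominantStateProportions(res, c(s1 = "g1", s2 = "g1", s3 = "g2"))
  expect_equal(rowSums(out$proportions), c(g1 = 1, g2 = 1))
  expect_equal(out$proportions["g1", ], c(Quiescence = 0.5, Helper = 0.5))
  expect_equal(out$proportions["g2", ], c(Quiescence = 1, Helper = 0))
  expect_false(any(out$ties))
})

test_that("exact dominance ties break by canonical row order and are flagged", {
  v <- rbind(Quiescence = c(0.5, 0.3),
             Helper     = c(0.5, 0.6))
  out <- dominantStateProportions(mkScores(v), c("g", "g"))
  expect_identical(unname(out$dominant), c("Quiescence", "Helper"))
  expect_identical(unname(out$ties), c(TRUE, FALSE))
  expect_equal(unname(out$proportions["g", ]), c(0.5, 0.5))
})

test_that("property: dominance rows sum to one on random score matrices", {
  set.seed(30)
  for (i in 1:20) {
    v <- matrix(runif(8 * 9), 8, 9,
                dimnames = list(canonicalStates(), NULL))
    out <- dominantStateProportions(mkScores(v),
                                    sample(c("a", "b", "c"), 9, replace = TRUE))
    expect_equal(unname(rowSums(out$proportions)),
                 rep(1, nrow(out$proportions)), tolerance = 1e-12)
  }
})

test_that("rank-sum comparison behaves at the null, the extreme, and under label swap", {
  vSame <- rbind(Quiescence = rep(c(0.4, 0.5, 0.6), 2))
  g <- rep(c("a", "b"), each = 3)
  outSame <- compareGroups(mkScores(vSame, sprintf("s%d", 1:6)), g)
  expect_gt(outSame$p.value, 0.9)

  # disjoint ranges at n = 10 vs 10: exact two-sided minimum 2 / C(20, 10)
  vSep <- rbind(Helper = c(1:10, 101:110) / 200)
  g2 <- rep(c("a", "b"), each = 10)
  outSep <- compareGroups(mkScores(vSep, sprintf("s%d", 1:20)), g2)
  expect_equal(outSep$p.value, 2 / choose(20, 10), tolerance = 1e-12)

  swapped <- compareGroups(mkScores(vSep, sprintf("s%d", 1:20)),
                           ifelse(g2 == "a", "b", "a"))
  expect_equal(swapped$p.value, outSep$p.value, tolerance = 1e-15)

  expect_error(compareGroups(mkScores(vSep, sprintf("s%d", 1:20)),
                             rep("a", 20)), "two groups")
  expect_error(compareGroups(mkScores(vSame, sprintf("s%d", 1:6)),
                             c("a", "a", "a", "a", "a", "b")),
               "at least 2")
})

test_that("BH adjustment is added on request and preserves raw p-values", {
  set.seed(40)
  v <- matrix(runif(8 * 12), 8, 12, dimnames = list(canonicalStates(), NULL))
  res <- mkScores(v)
  g <- rep(c("a", "b"), each = 6)
  raw <- compareGroups(res, g)
  adj <- compareGroups(res, g, adjust = TRUE)
  expect_identical(adj$p.value, raw$p.value)
  expect_equal(adj$p.adj, p.adjust(raw$p.value, "BH"))
})
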