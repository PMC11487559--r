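#' Stratified background gene sampling
#'
#' Draws the background genes against which marker ranks are compared.
#' Genes are ordered by pooled expression (mean of the corrected values
#' across all samples), split from high to low into `nBins` contiguous
#' expression strata of near-equal size, and `perBin` genes are drawn
#' uniformly without replacement from each stratum. Stratifying by
#' expression keeps the background's expression distribution representative
#' of the whole matrix while capping the total number of ranks (default
#' 50 x 100 = 5000 genes). Pooling the ordering statistic across samples
#' makes the background identical for every sample, which the shared rank
#' matrix requires.
#'
#' If `perBin` exceeds the smallest stratum, the per-stratum draw is shrunk
#' to the smallest stratum size, with a warning. The draw is fully
#' determined by `seed`.
#'
#' @param m An [ExpressionMatrix-class] with `stage = "corrected"`.
#' @param nBins Number of expression strata (default 50).
#' @param perBin Genes drawn per stratum (default 100).
#' @param seed Integer seed for the draw (default 1).
#' @return A [BackgroundSample-class] object.
#' @examples
#' v <- matrix(rexp(4000), 1000, 4,
#'   dimnames = list(sprintf("g%04d", 1:1000), paste0("s", 1:4)))
#' bg <- selectBackground(ExpressionMatrix(v, stage = "corrected"),
#'                        nBins = 10, perBin = 20, seed = 1)
#' length(backgroundGenes(bg))  # 200
#' @export
selectBackground <- function(m, nBins = 50L, perBin = 100L, seed = 1L) {
  stopifnot(methods::is(m, "ExpressionMatrix"))
  if (exprStage(m) != "corrected")
    stop("selectBackground expects stage 'corrected', got '", exprStage(m), "'")
  nBins <- as.integer(nBins)
  perBin <- as.integer(perBin)
  seed <- as.integer(seed)
  v <- exprValues(m)
  G <- nrow(v)
  if (G < nBins)
    stop("matrix has ", G, " genes but ", nBins, " bins were requested")
  stat <- rowMeans(v)
  # tie-break by gene id so the draw is invariant to input row order
  ord <- order(-stat, rownames(v))
  bins <- split(ord, ceiling(seq_along(ord) * nBins / G))
  minSize <- min(lengths(bins))
  if (perBin > minSize) {
    warning("perBin ", perBin, " exceeds the smallest bin (", minSize,
            " genes); shrinking the per-bin draw to ", minSize)
    perBin <- as.integer(minSize)
  }
  sel <- withr::with_seed(seed,
    unlist(lapply(bins, function(idx) sample(idx, perBin)), use.names = FALSE))
  methods::new("BackgroundSample",
               genes = rownames(v)[sel], nBins = nBins, perBin = perBin,
               seed = seed, stat = stats::setNames(stat, rownames(v)))
}

#' Within-sample expression ranks
#'
#' Ascending ranks (highest expression receives the largest rank) with ties
#' assigned the average of their rank span, the Mann-Whitney convention.
#'
#' @param x Numeric vector: one sample's expression over the combined
#'   background-plus-marker gene panel.
#' @return Numeric vector of ranks, a permutation of `1..length(x)` up to
#'   tie averaging.
#' @examples
#' rankExpression(c(1, 1, 1, 9))  # 2 2 2 4
#' @export
rankExpression <- function(x) {
  rank(x, ties.method = "average")
}
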