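#' Log2-transform a TPM matrix
#'
#' Replaces every value v by log2(v + 1), the variance-stabilizing transform
#' applied before any ranking or normalization.
#'
#' @param m An [ExpressionMatrix-class] with `stage = "tpm"`.
#' @return An [ExpressionMatrix-class] with `stage = "log2"`.
#' @examples
#' m <- ExpressionMatrix(matrix(c(0, 1, 3, 7), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' exprValues(log2Transform(m))
#' @export
log2Transform <- function(m) {
  stopifnot(methods::is(m, "ExpressionMatrix"))
  if (exprStage(m) != "tpm")
    stop("log2Transform expects stage 'tpm', got '", exprStage(m), "'")
  ExpressionMatrix(log2(exprValues(m) + 1), stage = "log2")
}

#' Housekeeping-gene normalization across samples
#'
#' Rescales every sample so that all samples share the same mean
#' housekeeping-gene expression, making rank scores comparable across
#' samples with different global expression levels. With HKbar_j the mean
#' log2 expression of the housekeeping genes present in sample j, sample j's
#' column is multiplied by `mean_j(HKbar_j) / HKbar_j`. After correction
#' every sample's housekeeping mean equals the pre-correction global mean,
#' so applying the correction twice is a no-op.
#'
#' Housekeeping genes absent from the matrix are ignored (with a warning
#' reporting how many); at least `minHK` must be present for the correction
#' to be meaningful.
#'
#' @param m An [ExpressionMatrix-class] with `stage = "log2"`.
#' @param hk A [HousekeepingList-class].
#' @param minHK Minimum number of housekeeping genes that must be present in
#'   the matrix (default 50); fewer is an error.
#' @return An [ExpressionMatrix-class] with `stage = "corrected"`. The
#'   per-sample correction factors are stored in
#'   `S4Vectors::metadata(.)$correctionFactors` for audit.
#' @export
housekeepingCorrect <- function(m, hk, minHK = 50L) {
  stopifnot(methods::is(m, "ExpressionMatrix"),
            methods::is(hk, "HousekeepingList"))
  if (exprStage(m) != "log2")
    stop("housekeepingCorrect expects stage 'log2', got '", exprStage(m), "'")
  v <- exprValues(m)
  present <- intersect(hkGenes(hk), rownames(v))
  nAbsent <- length(hkGenes(hk)) - length(present)
  if (length(present) < minHK)
    stop("only ", length(present), " housekeeping gene(s) present in the ",
         "matrix; at least ", minHK, " are required")
  if (nAbsent > 0L)
    warning(nAbsent, " housekeeping gene(s) absent from the matrix were ignored")
  hkMeans <- colMeans(v[present, , drop = FALSE])
  if (any(hkMeans <= 0))
    stop("sample '", colnames(v)[which(hkMeans <= 0)[1L]],
         "' has zero mean housekeeping expression; cannot correct")
  factors <- mean(hkMeans) / hkMeans
  out <- ExpressionMatrix(sweep(v, 2L, factors, "*"), stage = "corrected")
  S4Vectors::metadata(out)$correctionFactors <- factors
  out
}
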