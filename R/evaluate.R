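#' ROC AUC by the rank formula
#'
#' The area under the ROC curve computed as the Mann-Whitney probability
#' that a positive sample's score exceeds a negative one's (ties counted
#' half) -- the same normalization the state scores themselves use.
#'
#' @param scores Numeric vector of scores.
#' @param labels Class labels: a logical vector (`TRUE` = positive), or any
#'   two-level vector together with `positive` naming the positive level.
#' @param positive The positive level when `labels` is not logical.
#' @return AUC in \[0, 1\].
#' @examples
#' rocAUC(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
rocAUC <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!is.logical(labels)) {
    lev <- unique(labels)
    if (length(lev) > 2L) stop("labels must have at most two levels")
    if (is.null(positive))
      stop("for non-logical labels, give the positive level via 'positive'")
    labels <- labels == positive
  }
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Per-group distribution of dominant states
#'
#' For every sample, the dominant state is the row of the score matrix with
#' the maximum score; exact ties are broken by the result's canonical row
#' order and flagged. Returns, per group, the fraction of samples dominated
#' by each state (rows sum to 1).
#'
#' @param result A [TCellScores-class] object.
#' @param groups Group assignment: named character vector (sample -> group)
#'   or a vector aligned with the result's samples. Every sample must be
#'   grouped.
#' @return List with `proportions` (group x state matrix of fractions),
#'   `dominant` (named character, sample -> winning state) and `ties`
#'   (named logical, sample had an exact tie for the maximum).
#' @export
dominantStateProportions <- function(result, groups) {
  stopifnot(methods::is(result, "TCellScores"))
  v <- stateScores(result)
  samples <- colnames(v)
  if (!is.null(names(groups))) {
    if (!all(samples %in% names(groups)))
      stop("every sample must appear in 'groups'")
    groups <- groups[samples]
  } else if (length(groups) != length(samples)) {
    stop("'groups' must be named by sample or aligned with the samples")
  }
  groups <- as.character(groups)

  win <- apply(v, 2L, which.max)            # first max = canonical order
  ties <- apply(v, 2L, function(x) sum(x == max(x)) > 1L)
  dominant <- stats::setNames(rownames(v)[win], samples)
  names(ties) <- samples

  tab <- table(factor(groups), factor(dominant, levels = rownames(v)))
  prop <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  list(proportions = prop, dominant = dominant, ties = ties)
}

#' Two-group rank-sum comparison of state scores
#'
#' Applies a two-sided Wilcoxon rank-sum test to each state's scores
#' between two groups: exact distribution when the combined sample size is
#' at most 20 (and no ties force an approximation), normal approximation
#' with continuity correction otherwise.
#'
#' @param result A [TCellScores-class] object.
#' @param groups Two-level group assignment, named by sample or aligned
#'   with the result's samples; each group needs at least 2 samples.
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted p-value
#'   column across the tested states.
#' @return data.frame with columns `state`, `n1`, `n2`, `statistic`
#'   (rank-sum W), `p.value` and, when `adjust = TRUE`, `p.adj`.
#' @export
compareGroups <- function(result, groups, adjust = FALSE) {
  stopifnot(methods::is(result, "TCellScores"))
  v <- stateScores(result)
  samples <- colnames(v)
  if (!is.null(names(groups))) {
    if (!all(samples %in% names(groups)))
      stop("every sample must appear in 'groups'")
    groups <- groups[samples]
  } else if (length(groups) != length(samples)) {
    stop("'groups' must be named by sample or aligned with the samples")
  }
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L)
    stop("exactly two groups are required, got ", length(lev))
  n1 <- sum(groups == lev[1L])
  n2 <- sum(groups == lev[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  rows <- lapply(rownames(v), function(s) {
    x <- v[s, groups == lev[1L]]
    y <- v[s, groups == lev[2L]]
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = (n1 + n2) <= 20L, correct = TRUE))
    data.frame(state = s, n1 = n1, n2 = n2,
               statistic = unname(ht$statistic), p.value = ht$p.value)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p.adj <- stats::p.adjust(out$p.value, method = "BH")
  rownames(out) <- NULL
  out
}
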