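# Cohort-level inference: exact/approximate Wilcoxon signed-rank test and
# the tumor occurrence frequency map.

# Exact null distribution of 2*W over sign assignments, by generating-
# function convolution over the (doubled, hence integer) ranks.
.wilcoxExactP <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # probabilities over 2W = 0..total
  p <- numeric(total + 1L)
  p[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), p[seq_len(total + 1L - r)])
    p <- (p + shifted) / 2
  }
  w2 <- round(2 * w)
  lower <- sum(p[seq_len(w2 + 1L)])               # P(2W <= w2)
  upper <- sum(p[seq.int(w2 + 1L, total + 1L)])   # P(2W >= w2)
  min(1, 2 * min(lower, upper))
}

.wilcoxNormalP <- function(w, ranks) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
  if (w == mu) z <- 0
  2 * stats::pnorm(-abs(z))
}

#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Paired two-sided test. Zero differences are dropped (classic Wilcoxon
#' policy) or kept in the ranking and then discarded (Pratt). Absolute
#' differences are ranked with mid-ranks for ties; W is the sum of ranks of
#' positive differences. For `n_effective <= exactLimit` the two-sided
#' p-value comes from the exact distribution over all 2^n sign assignments
#' (computed by convolution); above it, from the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y paired samples; or differences in `x` with `y = NULL`.
#' @param zeroMethod "wilcoxon" (drop zero differences) or "pratt".
#' @param exactLimit largest n_effective for the exact path (default 20).
#' @return A [WilcoxonResult-class].
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5), rep(0, 5)) # W = 15, p = 0.0625
#' @export
wilcoxonSignedRank <- function(x, y = NULL,
                               zeroMethod = c("wilcoxon", "pratt"),
                               exactLimit = 20L) {
  zeroMethod <- match.arg(zeroMethod)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("x and y must have equal length")
    x - y
  }
  d <- d[is.finite(d)]
  if (!length(d) || all(d == 0))
    stop("all differences are zero; the signed-rank test is undefined")
  nZero <- sum(d == 0)
  if (zeroMethod == "wilcoxon") {
    d <- d[d != 0]
    ranks <- rank(abs(d))
    nZero <- 0
  } else {
    ranks <- rank(abs(d))
    ranks <- ranks[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  if (n < 5)
    warning("fewer than 5 non-zero differences; the test has little power")
  w <- sum(ranks[d > 0])
  if (n <= exactLimit) {
    p <- .wilcoxExactP(w, ranks)
    method <- "exact"
  } else {
    p <- .wilcoxNormalP(w, ranks)
    method <- "normal_approximation"
  }
  new("WilcoxonResult", nEffective = n, nZero = nZero, statistic = w,
      pValue = max(p, .Machine$double.xmin), method = method)
}

#' Cohort test of parallel vs perpendicular growth
#'
#' Pairs each patient's fraction of voxels with folded angle below the
#' parallel threshold against the fraction above the perpendicular
#' threshold, and applies the Wilcoxon signed-rank test. Patients with empty
#' angle maps are excluded with a warning.
#'
#' @param summaries list of [AlignmentSummary-class].
#' @param ... passed to [wilcoxonSignedRank()].
#' @return A [WilcoxonResult-class].
#' @export
testParallelVsPerpendicular <- function(summaries, ...) {
  if (is(summaries, "AlignmentSummary")) summaries <- list(summaries)
  empty <- vapply(summaries, function(s) s@empty, logical(1))
  if (any(empty)) {
    warning(sprintf("excluding %d patient(s) with no detectable vectors",
                    sum(empty)))
    summaries <- summaries[!empty]
  }
  if (!length(summaries)) stop("no patients with detectable vectors")
  x <- vapply(summaries, function(s) s@fractions[["lt20"]], numeric(1))
  y <- vapply(summaries, function(s) s@fractions[["gt70"]], numeric(1))
  wilcoxonSignedRank(x, y, ...)
}

#' Tumor occurrence frequency map
#'
#' Voxel-wise count, over the cohort, of binary tumor masks in template
#' space.
#'
#' @param masks list of binary [ScalarVolume-class] on the template grid.
#' @return A [FrequencyMap-class].
#' @export
frequencyMap <- function(masks) {
  if (is(masks, "ScalarVolume")) masks <- list(masks)
  stopifnot(length(masks) >= 1)
  ref <- masks[[1]]
  acc <- array(0, volDim(ref))
  for (m in masks) {
    if (!.sameGrid(ref@affine, volDim(ref), m@affine, volDim(m)))
      stop("frequencyMap: all masks must live on the template grid")
    acc <- acc + (m@data != 0)
  }
  new("FrequencyMap",
      counts = scalarVolume(acc, ref@affine),
      nPatients = length(masks))
}
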