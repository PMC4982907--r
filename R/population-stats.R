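#' Pearson chi-square test on a 2x2 contingency table
#'
#' One-degree-of-freedom Pearson chi-square, by default without Yates'
#' continuity correction (the correction only shrinks the statistic and
#' is switchable).
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return List: `statistic`, `p.value`, `correct`.
#' @export
chiSquare2x2 <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins must be positive")
  ## the asymptotic Pearson test is used regardless of expected counts
  ## (suppresses the small-count warning; callers see the counts)
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p.value = unname(res$p.value),
       correct = correct)
}

#' Wilcoxon-Mann-Whitney rank test
#'
#' Two-sided by default. Uses the exact null distribution when the
#' smaller sample has at most 8 observations and there are no ties, and
#' the normal approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exactMax Largest min(n, m) for which the exact null is used
#'   (default 8).
#' @return List: `U` (Mann-Whitney U of sample `a`), `p.value`, `exact`.
#' @export
rankSumTest <- function(a, b, exactMax = 8) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && min(length(a), length(b)) <= exactMax
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = FALSE))
  list(U = unname(res$statistic), p.value = res$p.value,
       exact = use_exact)
}

#' Proportion with a Wilson 95% confidence interval
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return List: `proportion`, `lower`, `upper`.
#' @export
fractionWithCI <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("'n' must be positive")
  stopifnot(k >= 0, k <= n)
  ci <- suppressWarnings(
    stats::prop.test(k, n, conf.level = conf, correct = FALSE))$conf.int
  list(proportion = k / n, lower = ci[1], upper = ci[2])
}

#' Mean and standard error of per-replicate fractions
#'
#' Summary across replicate retinas: mean of the per-retina fractions and
#' its standard error (sd / sqrt(n)).
#'
#' @param fractions Per-replicate fractions.
#' @return List: `mean`, `se`, `n`.
#' @export
replicateFractionSummary <- function(fractions) {
  stopifnot(length(fractions) >= 1)
  list(mean = mean(fractions),
       se = if (length(fractions) > 1)
         stats::sd(fractions) / sqrt(length(fractions)) else NA_real_,
       n = length(fractions))
}

#' Grid-based density mask of a labeled-cell map
#'
#' Bins one channel's cells on a square grid and keeps the grid cells
#' whose count is at least `minDensity` times the peak count; the mask is
#' the union of qualifying cells. Used to restrict co-labeling analyses
#' to the densely labeled areas of a retina.
#'
#' @param map A [LabeledCellMap-class].
#' @param channel Channel defining the density.
#' @param cellSize Grid spacing (um, > 0; default 100).
#' @param minDensity Fraction of the peak density required (default
#'   0.25).
#' @return A `DensityMask` list: `x0`, `y0`, `cellSize`, `keep` (logical
#'   matrix), `counts`.
#' @export
densityMask <- function(map, channel, cellSize = 100, minDensity = 0.25) {
  stopifnot(is(map, "LabeledCellMap"), cellSize > 0)
  pts <- channelPoints(map, channel)
  if (!nrow(pts)) {
    return(structure(list(x0 = 0, y0 = 0, cellSize = cellSize,
                          keep = matrix(logical(0), 0, 0),
                          counts = matrix(integer(0), 0, 0)),
                     class = "DensityMask"))
  }
  x0 <- floor(min(pts[, 1]) / cellSize) * cellSize
  y0 <- floor(min(pts[, 2]) / cellSize) * cellSize
  ix <- floor((pts[, 1] - x0) / cellSize) + 1L
  iy <- floor((pts[, 2] - y0) / cellSize) + 1L
  nx <- max(ix)
  ny <- max(iy)
  counts <- matrix(0L, nx, ny)
  for (i in seq_along(ix))
    counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  keep <- counts >= minDensity * max(counts)
  structure(list(x0 = x0, y0 = y0, cellSize = cellSize, keep = keep,
                 counts = counts),
            class = "DensityMask")
}

#' Does a density mask contain given positions?
#'
#' @param mask A `DensityMask` from [densityMask()].
#' @param x,y Positions (um).
#' @return Logical vector.
#' @export
maskContains <- function(mask, x, y) {
  stopifnot(inherits(mask, "DensityMask"))
  if (!length(mask$keep)) return(rep(FALSE, length(x)))
  ix <- floor((x - mask$x0) / mask$cellSize) + 1L
  iy <- floor((y - mask$y0) / mask$cellSize) + 1L
  ok <- ix >= 1L & ix <= nrow(mask$keep) & iy >= 1L & iy <= ncol(mask$keep)
  out <- rep(FALSE, length(x))
  out[ok] <- mask$keep[cbind(ix[ok], iy[ok])]
  out
}

#' Fraction of reference-labeled cells that also carry a test label
#'
#' Restricted to a density mask when one is given: the estimator of the
#' double-labeled fraction within the densely labeled area.
#'
#' @param map A [LabeledCellMap-class].
#' @param refChannel Reference channel (denominator).
#' @param testChannel Test channel (numerator label).
#' @param mask Optional `DensityMask`; when given, only reference cells
#'   inside the mask count.
#' @return Fraction in \[0, 1\], or `NA_real_` (with a message) when no
#'   reference cell lies in the mask.
#' @export
colabelFraction <- function(map, refChannel, testChannel, mask = NULL) {
  stopifnot(is(map, "LabeledCellMap"))
  cl <- map@cells
  ref_col <- paste0("label_", refChannel)
  test_col <- paste0("label_", testChannel)
  for (col in c(ref_col, test_col))
    if (!col %in% names(cl)) stop("unknown channel column: ", col)
  keep <- cl[[ref_col]]
  if (!is.null(mask))
    keep <- keep & maskContains(mask, cl$x_um, cl$y_um)
  if (!any(keep)) {
    message("no reference-channel cells inside the mask")
    return(NA_real_)
  }
  mean(cl[[test_col]][keep])
}
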