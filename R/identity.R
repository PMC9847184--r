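#' Pairwise marker differences between varieties
#'
#' For every variety pair, counts loci at which both calls are observed and
#' the unordered allele pairs differ ((A,T) equals (T,A); (A,A) differs from
#' (A,T)). Loci missing in either variety are excluded from both the
#' difference and the compared-locus count.
#'
#' @param x a [GenotypeMatrix-class] with at least two varieties.
#' @return a [DifferenceMatrix-class].
#' @export
pairwiseDifferences <- function(x) {
  if (ncol(x) < 2) stop("need at least two varieties")
  g <- genotypeStrings(x)
  n <- ncol(g)
  d <- matrix(0L, n, n, dimnames = list(colnames(g), colnames(g)))
  k <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    gi <- g[, i]
    for (j in (i + 1):n) {
      both <- !is.na(gi) & !is.na(g[, j])
      d[i, j] <- d[j, i] <- sum(gi[both] != g[both, j])
      k[i, j] <- k[j, i] <- sum(both)
    }
  }
  diag(k) <- nrow(g)
  new("DifferenceMatrix", differences = d, compared = k,
      nLoci = nrow(g))
}

setMethod("show", "DifferenceMatrix", function(object) {
  n <- nrow(object@differences)
  ut <- object@differences[upper.tri(object@differences)]
  cat("DifferenceMatrix:", n, "varieties,", object@nLoci, "loci\n")
  if (length(ut))
    cat(sprintf("  differences per pair: mean %.1f, range %d-%d\n",
                mean(ut), min(ut), max(ut)))
})

#' @describeIn pairwiseDifferences accessors for the two count matrices and
#'   panel size.
#' @param dm a [DifferenceMatrix-class].
#' @export
differenceCounts <- function(dm) dm@differences

#' @rdname pairwiseDifferences
#' @export
comparedCounts <- function(dm) dm@compared

#' @rdname pairwiseDifferences
#' @export
panelSize <- function(dm) dm@nLoci

#' Distribution of per-pair marker-difference percentages
#'
#' Per-pair percentage = differences / total panel loci x 100 (the fixed
#' panel denominator, so pairs with missing data are comparable). Bins are
#' half-open [lo, hi) of \code{binWidth} percent; the last bin is closed at
#' 100. Restricting \code{varieties} profiles a subpopulation.
#'
#' @param dm a [DifferenceMatrix-class].
#' @param nLoci denominator, default the panel size recorded in \code{dm}.
#' @param binWidth bin width in percent (default 10).
#' @param varieties optional subset of variety names/indices.
#' @return data.frame: bin_lo, bin_hi, count.
#' @export
differenceDistribution <- function(dm, nLoci = panelSize(dm), binWidth = 10,
                                   varieties = NULL) {
  d <- dm@differences
  if (!is.null(varieties)) d <- d[varieties, varieties, drop = FALSE]
  pct <- d[upper.tri(d)] / nLoci * 100
  lo <- seq(0, 100 - binWidth, by = binWidth)
  hi <- lo + binWidth
  count <- vapply(seq_along(lo), function(i) {
    if (i == length(lo)) sum(pct >= lo[i] & pct <= hi[i])
    else sum(pct >= lo[i] & pct < hi[i])
  }, integer(1))
  data.frame(bin_lo = lo, bin_hi = hi, count = count)
}

#' Concordance of two marker systems in variety discrimination
#'
#' Ordinary least squares of per-pair SNP differences on per-pair SSR
#' differences over the strict upper triangles, quantifying how linearly
#' related the two fingerprinting systems are.
#'
#' @param dmX,dmY [DifferenceMatrix-class] objects over the same varieties
#'   in the same order (e.g. SSR panel and SNP panel).
#' @return list: slope, intercept, r.squared (squared Pearson correlation).
#' @export
markerConcordance <- function(dmX, dmY) {
  if (!identical(dimnames(dmX@differences), dimnames(dmY@differences)))
    stop("difference matrices must cover the same varieties in order")
  ut <- upper.tri(dmX@differences)
  x <- dmX@differences[ut]
  y <- dmY@differences[ut]
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0
        else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r.squared = r2)
}

#' Variety pairs not resolved by the panel
#'
#' Under distinctness-testing practice, two varieties are separable when
#' they differ at a minimum number of markers (default 1).
#'
#' @param dm a [DifferenceMatrix-class].
#' @param minDifferences pairs with fewer differing markers are reported.
#' @return data.frame: variety1, variety2, differences, compared.
#' @export
unresolvedPairs <- function(dm, minDifferences = 1L) {
  d <- dm@differences
  idx <- which(upper.tri(d) & d < minDifferences, arr.ind = TRUE)
  data.frame(variety1 = rownames(d)[idx[, 1]],
             variety2 = colnames(d)[idx[, 2]],
             differences = d[idx],
             compared = dm@compared[idx],
             stringsAsFactors = FALSE)
}
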