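#' Observed allele frequencies at a locus
#'
#' Frequencies are computed over the 2 x (non-missing varieties) allele
#' draws at the locus; they sum to 1 over the observed allele set.
#'
#' @param x a [GenotypeMatrix-class].
#' @param locus marker id or row index.
#' @return named numeric vector of allele frequencies (empty if every call
#'   is missing).
#' @export
alleleFrequencies <- function(x, locus) {
  a <- alleleA(x)[locus, ]
  b <- alleleB(x)[locus, ]
  draws <- c(a, b)
  draws <- draws[!is.na(draws)]
  if (!length(draws)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(draws)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Polymorphism information content
#'
#' The default is gene diversity, \eqn{PIC = 1 - \sum p_i^2}, whose biallelic
#' maximum is 0.50. Botstein's estimator
#' \eqn{1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2} (biallelic maximum 0.375)
#' is available via \code{method}.
#'
#' @param p numeric vector of allele frequencies (must sum to 1).
#' @param method "gene_diversity" (default) or "botstein".
#' @return PIC value in [0, 1).
#' @examples
#' pic(c(0.5, 0.5))            # 0.50
#' pic(rep(0.25, 4))           # 0.75
#' pic(c(0.5, 0.5), "botstein") # 0.375
#' @export
pic <- function(p, method = c("gene_diversity", "botstein")) {
  method <- match.arg(method)
  if (!length(p)) return(0)
  if (abs(sum(p) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  gd <- 1 - sum(p^2)
  if (method == "gene_diversity") return(gd)
  sq <- p^2
  gd - (sum(sq)^2 - sum(sq^2))
}

#' Observed heterozygosity of a locus
#'
#' Fraction of non-missing varieties whose two alleles differ.
#'
#' @inheritParams alleleFrequencies
#' @return fraction in [0, 1]; \code{NaN} when every call is missing.
#' @export
locusHeterozygosity <- function(x, locus) {
  a <- alleleA(x)[locus, ]
  b <- alleleB(x)[locus, ]
  keep <- !is.na(a)
  mean(a[keep] != b[keep])
}

#' Observed heterozygosity of a variety
#'
#' Fraction of that variety's non-missing loci at which it is heterozygous.
#'
#' @param x a [GenotypeMatrix-class].
#' @param variety variety name or column index.
#' @return fraction in [0, 1]; \code{NaN} when every call is missing.
#' @export
varietyHeterozygosity <- function(x, variety) {
  a <- alleleA(x)[, variety]
  b <- alleleB(x)[, variety]
  keep <- !is.na(a)
  mean(a[keep] != b[keep])
}

#' Missing-call rates
#'
#' @param x a [GenotypeMatrix-class].
#' @return list with \code{perLocus} and \code{perVariety} named numeric
#'   vectors of missing fractions.
#' @export
missingRates <- function(x) {
  m <- is.na(alleleA(x))
  list(perLocus = rowMeans(m), perVariety = colMeans(m))
}

#' Per-locus diversity statistics
#'
#' @param x a [GenotypeMatrix-class].
#' @param picMethod passed to [pic()].
#' @return a \link[S4Vectors]{DataFrame} with one row per marker: type,
#'   number of observed alleles, PIC, observed heterozygosity, missing rate.
#' @export
locusStats <- function(x, picMethod = "gene_diversity") {
  ids <- markerIds(x)
  nAll <- numeric(length(ids)); PIC <- numeric(length(ids))
  He <- numeric(length(ids))
  for (i in seq_along(ids)) {
    p <- alleleFrequencies(x, i)
    nAll[i] <- length(p)
    PIC[i] <- if (length(p)) pic(p, picMethod) else NA_real_
    He[i] <- locusHeterozygosity(x, i)
  }
  DataFrame(marker_id = ids, type = markerType(x), n_alleles = nAll,
            PIC = PIC, He_obs = He, missing = missingRates(x)$perLocus,
            row.names = ids)
}

#' Quality-control filter on loci
#'
#' Drops loci with low informativeness or high missing rate, the panel-
#' cleanup step applied to raw fingerprints before diversity analysis.
#'
#' @param x a [GenotypeMatrix-class].
#' @param minPic loci with PIC < \code{minPic} are removed (default 0.1).
#' @param maxMissing loci with missing rate > \code{maxMissing} are removed
#'   (default 0.20).
#' @param picMethod passed to [pic()].
#' @return list: \code{matrix} the filtered [GenotypeMatrix-class] (marker
#'   order preserved) and \code{removed} a DataFrame of dropped loci with
#'   their offending statistics.
#' @export
qcFilterLoci <- function(x, minPic = 0.1, maxMissing = 0.20,
                         picMethod = "gene_diversity") {
  st <- locusStats(x, picMethod)
  drop <- (!is.na(st$PIC) & st$PIC < minPic) | st$missing > maxMissing
  list(matrix = x[!drop, ], removed = st[drop, , drop = FALSE])
}

#' Convert SSR fragment sizes to repeat numbers
#'
#' Capillary/amplicon SSR genotypes are often reported as fragment sizes;
#' Bruvo's distance needs repeat counts. Conversion is
#' \code{round((size - offset) / motifLength)} per locus.
#'
#' @param sizes numeric vector/matrix of fragment sizes (bp).
#' @param offset per-locus non-repeat amplicon length (bp).
#' @param motifLength repeat-unit length (2-6).
#' @return repeat numbers, same shape as \code{sizes}.
#' @export
sizeToRepeats <- function(sizes, offset, motifLength) {
  if (any(motifLength < 1)) stop("motifLength must be positive")
  round((sizes - offset) / motifLength)
}
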