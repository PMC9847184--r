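#' @importFrom GenomicRanges GRanges mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Per-population SNP-index (reference-allele frequency)
#'
#' For every SNP locus and population, the fraction of non-missing allele
#' draws equal to the panel's reference allele.
#'
#' @param x a [GenotypeMatrix-class]; only SNP markers are used, and their
#'   panel must carry a \code{ref} column.
#' @param labels population label per variety (named or in column order);
#'   NA labels are excluded.
#' @return list: \code{index} (loci x populations matrix of reference-allele
#'   frequencies, NaN when no calls), \code{nAlleles} (matching matrix of
#'   observed allele counts), \code{panel} (the SNP marker metadata).
#' @export
snpIndex <- function(x, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  keep <- !is.na(labels)
  x <- x[, keep]; labels <- labels[keep]
  snp <- markerType(x) == "SNP"
  x <- x[snp, ]
  panel <- markerPanel(x)
  if (!("ref" %in% colnames(panel)))
    stop("SNP panel must have a 'ref' column")
  pops <- sort(unique(labels))
  A <- alleleA(x); B <- alleleB(x)
  idx <- matrix(NA_real_, nrow(x), length(pops),
                dimnames = list(rownames(x), pops))
  nall <- matrix(0L, nrow(x), length(pops), dimnames = dimnames(idx))
  for (p in pops) {
    sel <- labels == p
    a <- A[, sel, drop = FALSE]; b <- B[, sel, drop = FALSE]
    nobs <- rowSums(!is.na(a)) * 2L
    nref <- rowSums(a == panel$ref, na.rm = TRUE) +
      rowSums(b == panel$ref, na.rm = TRUE)
    idx[, p] <- nref / nobs
    nall[, p] <- nobs
  }
  list(index = idx, nAlleles = nall, panel = panel)
}

#' Sliding-window SNP-index track
#'
#' Averages per-population SNP-indices over windows (default 100 kb, step
#' 10 kb) along each chromosome and reports the per-window delta-SNP-index
#' \code{|popA - popB|}. Windows are half-open \code{[start, start +
#' window)} starting at position 1; the last window is truncated at the
#' chromosome end; windows with no SNP carry NA, not 0. The mean is
#' unweighted over the SNPs in the window.
#'
#' @param pft output of [snpIndex()]; its panel must have chrom and pos.
#' @param popA,popB column names of the two populations to contrast.
#' @param window,step window and step sizes in bp.
#' @param seqlengths optional named chromosome lengths; defaults to the
#'   last SNP position per chromosome.
#' @return a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{indexA}, \code{indexB}, \code{delta}, \code{nSnps}.
#' @export
windowTrack <- function(pft, popA, popB, window = 100000L, step = 10000L,
                        seqlengths = NULL) {
  panel <- pft$panel
  if (!all(c("chrom", "pos") %in% colnames(panel)))
    stop("panel must have chrom and pos for windowing")
  ia <- pft$index[, popA]; ib <- pft$index[, popB]
  chroms <- unique(panel$chrom)
  out <- lapply(chroms, function(ch) {
    sel <- panel$chrom == ch
    pos <- panel$pos[sel]
    len <- if (!is.null(seqlengths) && ch %in% names(seqlengths))
      seqlengths[[ch]] else max(pos)
    starts <- seq(1L, max(1L, len), by = step)
    ends <- pmin(starts + window - 1L, len)
    mA <- mB <- rep(NA_real_, length(starts))
    ns <- integer(length(starts))
    for (w in seq_along(starts)) {
      inw <- pos >= starts[w] & pos < starts[w] + window
      ns[w] <- sum(inw)
      if (ns[w]) {
        mA[w] <- mean(ia[sel][inw], na.rm = TRUE)
        mB[w] <- mean(ib[sel][inw], na.rm = TRUE)
      }
    }
    data.frame(chrom = ch, start = starts, end = ends, indexA = mA,
               indexB = mB, delta = abs(mA - mB), nSnps = ns)
  })
  df <- do.call(rbind, out)
  gr <- GRanges(factor(df$chrom, levels = chroms),
                IRanges(df$start, df$end))
  mcols(gr) <- DataFrame(df[, c("indexA", "indexB", "delta", "nSnps")])
  gr
}

#' Alternatively fixed SNP loci between two populations
#'
#' Loci whose delta-SNP-index \code{|indexA - indexB|} reaches \code{1 -
#' tol}, i.e. (at tol = 0) loci fixed for the reference allele in one
#' population and the alternative in the other. A minimum observed allele
#' count guards against spurious fixation in tiny samples.
#'
#' @param pft output of [snpIndex()].
#' @param popA,popB population column names.
#' @param tol tolerance off exact fixation (default 0).
#' @param minAlleles minimum observed allele draws per population
#'   (default 10).
#' @return data.frame: marker_id, indexA, indexB, delta.
#' @export
fixedDifferences <- function(pft, popA, popB, tol = 0, minAlleles = 10L) {
  ia <- pft$index[, popA]; ib <- pft$index[, popB]
  delta <- abs(ia - ib)
  hit <- !is.na(delta) & delta >= 1 - tol &
    pft$nAlleles[, popA] >= minAlleles & pft$nAlleles[, popB] >= minAlleles
  data.frame(marker_id = rownames(pft$index)[hit],
             indexA = ia[hit], indexB = ib[hit], delta = delta[hit],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate diagnostic marker genotypes for a target population
#'
#' Given candidate markers and the diagnostic genotype each should show
#' (typically the homozygous population-specific allele, e.g. "A/A";
#' heterozygotes do not count as carriers), reports per-marker and combined
#' (logical AND across markers) sensitivity and specificity against the
#' target population. Varieties with a missing call at a marker are not
#' carriers of it.
#'
#' @param markers character vector of marker ids.
#' @param genotypes character vector of diagnostic genotypes, one per
#'   marker, as "a/b" (order-insensitive).
#' @param x a [GenotypeMatrix-class].
#' @param labels population label per variety; varieties with NA label are
#'   excluded from the evaluation.
#' @param target the label of the target population.
#' @return data.frame with one row per marker plus a "combined" row:
#'   marker, genotype, carriers, carriersInTarget, sensitivity,
#'   specificity.
#' @export
evaluateDiagnostic <- function(markers, genotypes, x, labels, target) {
  stopifnot(length(markers) == length(genotypes))
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  keep <- !is.na(labels)
  x <- x[, keep]; labels <- labels[keep]
  inTarget <- labels == target
  if (!any(inTarget)) stop("no variety carries the target label")
  g <- genotypeStrings(x)
  norm <- vapply(strsplit(genotypes, "/"), function(p) {
    o <- order(allele_order(p))
    paste(p[o], collapse = "/")
  }, "")
  carrier <- matrix(FALSE, length(markers), ncol(x))
  for (m in seq_along(markers)) {
    if (!markers[m] %in% rownames(g)) stop("unknown marker: ", markers[m])
    gm <- g[markers[m], ]
    carrier[m, ] <- !is.na(gm) & gm == norm[m]
  }
  row_of <- function(car, name, gt) {
    data.frame(marker = name, genotype = gt,
               carriers = sum(car),
               carriersInTarget = sum(car & inTarget),
               sensitivity = sum(car & inTarget) / sum(inTarget),
               specificity = 1 - sum(car & !inTarget) / sum(!inTarget),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(markers), function(m)
    row_of(carrier[m, ], markers[m], norm[m])))
  if (length(markers) > 1) {
    all_c <- apply(carrier, 2, all)
    out <- rbind(out, row_of(all_c, "combined", paste(norm, collapse = "+")))
  }
  out
}
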