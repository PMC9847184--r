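#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData
NULL

MISSING_TOKEN <- "./."

#' GenotypeMatrix: variety fingerprints at a marker panel
#'
#' An S4 container for diploid variety fingerprints, extending
#' \linkS4class{SummarizedExperiment}. Rows are markers (SSR or SNP), columns
#' are varieties. Two character assays, \code{alleleA} and \code{alleleB},
#' hold the unordered allele pair of each call: SSR alleles are non-negative
#' integer repeat numbers (stored as character), SNP alleles are bases
#' A/C/G/T. A missing call has \code{NA} in both assays; a cell is never
#' half-missing. Marker metadata (type, chromosome, 1-based position, motif
#' for SSRs, reference allele for SNPs) lives in \code{rowData}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no additional slots.
#' @seealso [GenotypeMatrix()] for construction, [readGenotypes()],
#'   [genotypesFromVcf()] for I/O, [locusStats()] for diversity statistics.
#' @name GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("alleleA", "alleleB") %in% an))
    return("assays 'alleleA' and 'alleleB' are required")
  a <- SummarizedExperiment::assay(object, "alleleA")
  b <- SummarizedExperiment::assay(object, "alleleB")
  if (!is.character(a) || !is.character(b))
    msg <- c(msg, "allele assays must be character matrices")
  if (!identical(is.na(a), is.na(b)))
    msg <- c(msg, "a cell must be fully observed or fully missing")
  rd <- SummarizedExperiment::rowData(object)
  if (!("type" %in% colnames(rd)))
    msg <- c(msg, "rowData must have a 'type' column")
  else if (!all(rd$type %in% c("SSR", "SNP")))
    msg <- c(msg, "marker type must be 'SSR' or 'SNP'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "marker ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "variety names must be unique")
  if (nrow(rd) > 0 && "type" %in% colnames(rd)) {
    snp <- rd$type == "SNP"
    if (any(snp)) {
      v <- c(a[snp, , drop = FALSE], b[snp, , drop = FALSE])
      if (!all(v %in% c("A", "C", "G", "T", NA)))
        msg <- c(msg, "SNP alleles must be A/C/G/T")
    }
    ssr <- rd$type == "SSR"
    if (any(ssr)) {
      v <- c(a[ssr, , drop = FALSE], b[ssr, , drop = FALSE])
      v <- v[!is.na(v)]
      if (length(v) && any(is.na(suppressWarnings(as.numeric(v))) |
                           suppressWarnings(as.numeric(v)) < 0))
        msg <- c(msg, "SSR alleles must be non-negative repeat numbers")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DifferenceMatrix: pairwise marker-difference counts between varieties
#'
#' Symmetric integer matrix of differing-marker counts per variety pair, with
#' a companion matrix of the number of loci actually compared (both calls
#' observed). The total panel size is kept so percentages can use the fixed
#' panel denominator.
#'
#' @slot differences symmetric integer matrix, zero diagonal.
#' @slot compared symmetric integer matrix of compared-locus counts.
#' @slot nLoci integer, total panel size.
#' @exportClass DifferenceMatrix
setClass("DifferenceMatrix",
  representation(differences = "matrix", compared = "matrix",
                 nLoci = "integer"))

setValidity("DifferenceMatrix", function(object) {
  d <- object@differences; k <- object@compared
  if (!identical(dim(d), dim(k))) return("dimension mismatch")
  if (nrow(d) != ncol(d)) return("matrices must be square")
  if (any(diag(d) != 0)) return("diagonal must be zero")
  if (!isTRUE(all.equal(d, t(d))) || !isTRUE(all.equal(k, t(k))))
    return("matrices must be symmetric")
  if (any(d > k)) return("differences cannot exceed compared loci")
  if (any(k > object@nLoci)) return("compared loci cannot exceed panel size")
  TRUE
})

#' AmovaResult: three-level analysis of molecular variance
#'
#' @slot results data.frame with one row per stratum (among populations,
#'   among varieties within populations, within varieties) plus a total row;
#'   columns Df, SS, MS, sigma (variance component), percent.
#' @slot phi named numeric: PhiST, PhiIS, PhiIT.
#' @slot nPopulations integer.
#' @exportClass AmovaResult
setClass("AmovaResult",
  representation(results = "data.frame", phi = "numeric",
                 nPopulations = "integer"))

#' CoreSetResult: outcome of minimal discriminating marker-set selection
#'
#' @slot markers character, selected marker ids in selection order.
#' @slot curve data.frame resolution curve: one row per selection step with
#'   the marker added and the cumulative pair/variety resolution rates.
#' @slot unresolved data.frame of variety pairs left unresolved.
#' @slot pairRate,varietyRate numeric final resolution metrics.
#' @exportClass CoreSetResult
setClass("CoreSetResult",
  representation(markers = "character", curve = "data.frame",
                 unresolved = "data.frame", pairRate = "numeric",
                 varietyRate = "numeric"))
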