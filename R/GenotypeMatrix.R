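#' Build a GenotypeMatrix from allele matrices
#'
#' @param alleleA,alleleB character matrices (markers x varieties) holding the
#'   two alleles of each call; \code{NA} in both marks a missing call. Row
#'   names are marker ids, column names variety names.
#' @param panel marker metadata: a data.frame or DataFrame with at least a
#'   \code{type} column ("SSR"/"SNP"); optional \code{chrom}, \code{pos}
#'   (1-based), \code{motif} (SSR), \code{ref} (SNP). If \code{NULL}, marker
#'   type is inferred from the alleles (A/C/G/T = SNP, numeric = SSR).
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' a <- matrix(c("10", "A", "12", "A"), 2, 2,
#'             dimnames = list(c("ssr1", "snp1"), c("v1", "v2")))
#' b <- matrix(c("10", "T", "12", "A"), 2, 2,
#'             dimnames = list(c("ssr1", "snp1"), c("v1", "v2")))
#' gm <- GenotypeMatrix(a, b)
#' markerType(gm)
#' @export
GenotypeMatrix <- function(alleleA, alleleB, panel = NULL) {
  stopifnot(is.matrix(alleleA), is.matrix(alleleB),
            identical(dim(alleleA), dim(alleleB)))
  mode(alleleA) <- "character"
  mode(alleleB) <- "character"
  # store each pair in sorted order so unordered comparison is cheap
  swap <- !is.na(alleleA) & !is.na(alleleB) &
    allele_order(alleleB) < allele_order(alleleA)
  if (any(swap)) {
    tmp <- alleleA[swap]
    alleleA[swap] <- alleleB[swap]
    alleleB[swap] <- tmp
  }
  if (is.null(panel)) {
    obs <- ifelse(is.na(alleleA[, 1]), alleleB[, 1], alleleA[, 1])
    first <- apply(alleleA, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) x[1] else "A"
    })
    panel <- DataFrame(type = ifelse(first %in% c("A", "C", "G", "T"),
                                     "SNP", "SSR"))
  }
  panel <- as(panel, "DataFrame")
  rownames(panel) <- rownames(alleleA)
  se <- SummarizedExperiment(
    assays = list(alleleA = alleleA, alleleB = alleleB),
    rowData = panel)
  new("GenotypeMatrix", se)
}

# numeric order for SSR repeat numbers, lexicographic for bases
allele_order <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  ifelse(is.na(n), match(x, c("A", "C", "G", "T", x)), n)
}

#' @describeIn GenotypeMatrix-accessors first (smaller) allele matrix
#' @export
alleleA <- function(x) SummarizedExperiment::assay(x, "alleleA")

#' @describeIn GenotypeMatrix-accessors second allele matrix
#' @export
alleleB <- function(x) SummarizedExperiment::assay(x, "alleleB")

#' Accessors for GenotypeMatrix
#'
#' @param x a [GenotypeMatrix-class].
#' @name GenotypeMatrix-accessors
#' @return \code{markerPanel} the rowData DataFrame; \code{markerIds},
#'   \code{varietyNames} character vectors; \code{markerType} "SSR"/"SNP"
#'   per marker; \code{genotypeStrings} a markers x varieties character
#'   matrix of normalized "a/b" calls (alleles sorted, \code{NA} missing).
NULL

#' @rdname GenotypeMatrix-accessors
#' @export
markerPanel <- function(x) SummarizedExperiment::rowData(x)

#' @rdname GenotypeMatrix-accessors
#' @export
markerIds <- function(x) rownames(x)

#' @rdname GenotypeMatrix-accessors
#' @export
varietyNames <- function(x) colnames(x)

#' @rdname GenotypeMatrix-accessors
#' @export
markerType <- function(x) {
  t <- SummarizedExperiment::rowData(x)$type
  names(t) <- rownames(x)
  t
}

#' @rdname GenotypeMatrix-accessors
#' @export
genotypeStrings <- function(x) {
  a <- alleleA(x)
  g <- matrix(paste(a, alleleB(x), sep = "/"), nrow(a),
              dimnames = dimnames(a))
  g[is.na(a)] <- NA_character_
  g
}

setMethod("show", "GenotypeMatrix", function(object) {
  ty <- table(factor(markerType(object), c("SSR", "SNP")))
  cat("GenotypeMatrix:", ncol(object), "varieties x", nrow(object),
      "markers (", ty[["SSR"]], "SSR,", ty[["SNP"]], "SNP )\n")
  mis <- mean(is.na(alleleA(object)))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mis))
})

#' Read a variety genotype table
#'
#' Reads the package's genotype dialect: a CSV/TSV with variety names in the
#' first column and one column per marker; cells are "a/b" calls ("./." for
#' missing). SSR alleles are repeat numbers, SNP alleles bases.
#'
#' @param path file to read (delimiter inferred from extension, ".csv" =
#'   comma, otherwise tab).
#' @param panel optional marker metadata passed to [GenotypeMatrix()]; must
#'   cover every column marker id when given.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, panel = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("genotype table needs a variety column and markers")
  varieties <- df[[1]]
  if (anyDuplicated(varieties))
    stop("duplicated variety names: ",
         paste(unique(varieties[duplicated(varieties)]), collapse = ", "))
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- varieties
  bad <- !grepl("^[^/]+/[^/]+$", cells)
  if (any(bad)) stop("malformed genotype cells, e.g. '",
                     cells[which(bad)[1]], "'")
  a <- sub("/.*$", "", cells)
  b <- sub("^.*/", "", cells)
  a[cells == MISSING_TOKEN] <- NA
  b[cells == MISSING_TOKEN] <- NA
  ok <- is.na(a) | grepl("^([0-9]+|[ACGT])$", a) & grepl("^([0-9]+|[ACGT])$", b)
  if (!all(ok)) stop("unknown allele token in cell '", cells[which(!ok)[1]], "'")
  if (!is.null(panel)) {
    ids <- if (!is.null(rownames(panel))) rownames(panel) else panel$marker_id
    miss <- setdiff(colnames(cells), ids)
    if (length(miss)) stop("markers absent from panel: ",
                           paste(miss, collapse = ", "))
    panel <- panel[match(colnames(cells), ids), , drop = FALSE]
  }
  GenotypeMatrix(t(a), t(b), panel = panel)
}

#' Write a variety genotype table
#'
#' Inverse of [readGenotypes()]: writes varieties as rows, markers as
#' columns, calls as "a/b" with "./." for missing.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output file; ".csv" writes comma-separated, else tab.
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(x, path) {
  g <- genotypeStrings(x)
  g[is.na(g)] <- MISSING_TOKEN
  df <- data.frame(variety = colnames(g), t(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import SNP genotypes from a VCF
#'
#' Decodes GT fields of a biallelic-SNP VCF into a [GenotypeMatrix-class];
#' samples become varieties. Half-missing calls (e.g. "0/.") are treated as
#' missing. Multi-allelic or non-SNP records are dropped with a message.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [GenotypeMatrix-class] of SNP markers with \code{chrom},
#'   \code{pos} and \code{ref} in its panel.
#' @export
genotypesFromVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!all(snp)) {
    message("dropping ", sum(!snp), " non-biallelic-SNP record(s)")
    fix <- fix[snp, , drop = FALSE]
    gt <- gt[snp, , drop = FALSE]
  }
  alleles <- cbind(fix$REF, fix$ALT)
  decode <- function(slot) {
    idx <- suppressWarnings(as.integer(slot)) + 1L
    out <- alleles[cbind(rep(seq_len(nrow(gt)), ncol(gt)), as.vector(idx))]
    matrix(out, nrow(gt), dimnames = dimnames(gt))
  }
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  A <- decode(a1); B <- decode(a2)
  half <- xor(is.na(A), is.na(B))
  A[half] <- NA; B[half] <- NA
  ids <- if (!is.null(fix$ID) && !all(is.na(fix$ID)) && !any(fix$ID == "."))
    fix$ID else paste0(fix$CHROM, "_", fix$POS)
  dimnames(A) <- dimnames(B) <- list(ids, colnames(gt))
  panel <- DataFrame(type = "SNP", chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF,
                     row.names = ids)
  GenotypeMatrix(A, B, panel = panel)
}

#' Subset helper keeping the GenotypeMatrix class
#'
#' @param x a [GenotypeMatrix-class].
#' @param markers,varieties indices, names or logical masks; \code{NULL}
#'   keeps everything.
#' @return a [GenotypeMatrix-class].
#' @export
subsetGenotypes <- function(x, markers = NULL, varieties = NULL) {
  if (!is.null(markers)) x <- x[markers, ]
  if (!is.null(varieties)) x <- x[, varieties]
  x
}
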