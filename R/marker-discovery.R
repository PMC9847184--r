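#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   vcountPattern readDNAStringSet writeXStringSet width
NULL

#' Configuration for perfect-marker screening
#'
#' Thresholds of the "perfect" SSR/SNP filters: a marker passes only if its
#' repeat tract or SNP site plus both flanks are free of other variation,
#' the flank is unique in the genome, and (SSRs) every accession's major
#' allele is supported by a clear majority of reads.
#'
#' @param flankBp flank length screened on each side (bp).
#' @param majorAlleleReadFreq minimum per-accession major-SSR-allele read
#'   frequency; accessions at or below it fail the locus.
#' @param maxMissing,maxHet,minMaf SNP thresholds: missing rate < 0.1,
#'   heterozygosity < 0.1, minor allele frequency > 0.05.
#' @param minRepeats named vector: minimum repeat count per motif length
#'   ("2".."6").
#' @param maxTractBp SSR tracts must be shorter than this (bp).
#' @param countFilteredVariants if TRUE (default) VCF records with
#'   FILTER != PASS still count as variation in a flank.
#' @param mergeRevComp if TRUE, canonical SSR motifs also minimize over the
#'   reverse-complement rotations (AG and CT merge). Default FALSE: strand
#'   is respected.
#' @return a list with class "PerfectFilterConfig".
#' @export
perfectFilterConfig <- function(flankBp = 50L, majorAlleleReadFreq = 0.7,
                                maxMissing = 0.1, maxHet = 0.1,
                                minMaf = 0.05,
                                minRepeats = c("2" = 5L, "3" = 4L, "4" = 3L,
                                               "5" = 3L, "6" = 3L),
                                maxTractBp = 50L,
                                countFilteredVariants = TRUE,
                                mergeRevComp = FALSE) {
  stopifnot(flankBp > 0, majorAlleleReadFreq > 0, majorAlleleReadFreq < 1,
            maxMissing > 0, maxMissing < 1, maxHet > 0, maxHet < 1,
            minMaf > 0, minMaf < 1,
            all(c("2", "3", "4", "5", "6") %in% names(minRepeats)))
  structure(list(flankBp = as.integer(flankBp),
                 majorAlleleReadFreq = majorAlleleReadFreq,
                 maxMissing = maxMissing, maxHet = maxHet, minMaf = minMaf,
                 minRepeats = minRepeats, maxTractBp = as.integer(maxTractBp),
                 countFilteredVariants = countFilteredVariants,
                 mergeRevComp = mergeRevComp),
            class = "PerfectFilterConfig")
}

# lexicographically smallest rotation of a motif (optionally also over the
# reverse complement's rotations)
canonicalMotif <- function(motif, mergeRevComp = FALSE) {
  rot <- function(m) {
    ch <- strsplit(m, "")[[1]]
    k <- length(ch)
    vapply(seq_len(k),
           function(i) paste(ch[c(i:k, seq_len(i - 1))[seq_len(k)]],
                             collapse = ""), "")
  }
  cands <- rot(motif)
  if (mergeRevComp)
    cands <- c(cands,
               rot(as.character(reverseComplement(DNAString(motif)))))
  min(cands)
}

# TRUE unless the motif is an exact power of a shorter unit
isPrimitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d != 0) next
    if (identical(strrep(substr(motif, 1, d), k / d), motif)) return(FALSE)
  }
  TRUE
}

#' Scan a genome for perfect SSR tracts
#'
#' Finds maximal perfect tandem repeats of primitive 2-6 bp motifs. Tracts
#' containing N are excluded, tract length is \code{n_repeats x motif
#' length} (partial trailing copies are not counted) and must stay below
#' \code{config$maxTractBp}; overlapping candidate tracts of different
#' periods are resolved in favour of the longer tract (then the leftmost,
#' then the shorter motif). Motifs are reported as the lexicographically
#' smallest rotation on the given strand.
#'
#' @param genome a \link[Biostrings]{DNAStringSet} or named character vector
#'   of uppercase DNA (N allowed).
#' @param config a [perfectFilterConfig()].
#' @return data.frame of SSR loci: chrom, start, end (1-based inclusive),
#'   motif, n_repeats, tract_len.
#' @examples
#' scanSSRs(c(chr = "CCATATATATATGG"))
#' @export
scanSSRs <- function(genome, config = perfectFilterConfig()) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome)) && length(genome))
    names(genome) <- paste0("seq", seq_along(genome))
  out <- lapply(names(genome), function(chrom) {
    s <- genome[[chrom]]
    if (grepl("[^ACGTN]", s)) stop("non-DNA character in sequence ", chrom)
    scan_one_sequence(s, chrom, config)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), motif = character(),
                      n_repeats = integer(), tract_len = integer())
  rownames(res) <- NULL
  res
}

scan_one_sequence <- function(s, chrom, config) {
  L <- nchar(s)
  if (L < 4) return(NULL)
  ch <- strsplit(s, "")[[1]]
  cand <- list()
  for (k in 2:6) {
    minrep <- as.integer(config$minRepeats[[as.character(k)]])
    if (L < k * minrep) next
    eq <- ch[(k + 1):L] == ch[seq_len(L - k)]     # eq[i]: s[i+k] == s[i]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= k * (minrep - 1L))) {
      span_start <- starts[ri]                     # position in s
      span_len <- r$lengths[ri] + k
      n <- span_len %/% k
      if (n < minrep) next
      tract_len <- n * k
      if (tract_len >= config$maxTractBp) next
      motif <- substr(s, span_start, span_start + k - 1L)
      if (grepl("N", substr(s, span_start, span_start + span_len - 1L),
                fixed = TRUE)) next
      if (!isPrimitive(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = chrom, start = span_start,
        end = span_start + tract_len - 1L,
        motif = canonicalMotif(motif, config$mergeRevComp),
        n_repeats = n, tract_len = tract_len)
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  # longest first, then leftmost, then shortest motif; drop overlaps
  cand <- cand[order(-cand$tract_len, cand$start, nchar(cand$motif)), ]
  keep <- logical(nrow(cand))
  covered_end <- integer(0); covered_start <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ov <- any(cand$start[i] <= covered_end & cand$end[i] >= covered_start)
    if (!ov) {
      keep[i] <- TRUE
      covered_start <- c(covered_start, cand$start[i])
      covered_end <- c(covered_end, cand$end[i])
    }
  }
  cand <- cand[keep, ]
  cand[order(cand$start), ]
}

#' Is the flanking window of a site unique in the genome?
#'
#' Extracts the \code{[pos - flankBp, pos + flankBp]} window, masks the
#' focal base to N (so either allele matches) and counts exact occurrences
#' over both strands of the whole genome. Unique means exactly one
#' occurrence; a window whose reverse complement also occurs (including a
#' palindromic window matching itself on the minus strand) is not unique.
#'
#' @param genome a \link[Biostrings]{DNAStringSet} or named character vector.
#' @param chrom,pos site (1-based).
#' @param flankBp flank length; window off a contig end returns FALSE.
#' @return logical.
#' @export
flankIsUnique <- function(genome, chrom, pos, flankBp = 50L) {
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
  if (!chrom %in% names(genome)) stop("unknown sequence: ", chrom)
  L <- width(genome)[match(chrom, names(genome))]
  if (pos - flankBp < 1 || pos + flankBp > L) return(FALSE)
  win <- substr(as.character(genome[[chrom]]), pos - flankBp, pos + flankBp)
  substr(win, flankBp + 1L, flankBp + 1L) <- "N"
  pat <- DNAString(win)
  n <- sum(vcountPattern(pat, genome, fixed = "subject")) +
    sum(vcountPattern(reverseComplement(pat), genome, fixed = "subject"))
  n == 1L
}

#' Perfect-SSR filter
#'
#' A tract passes only if the tract plus both flanks carry no SNP, no indel
#' and no other SSR tract, the full flank exists on the contig, and every
#' accession's major-allele read frequency exceeds the configured threshold.
#'
#' @param locus one row of [scanSSRs()] output (or a list with chrom,
#'   start, end).
#' @param variants variant catalog as returned by [readVariants()]
#'   (data.frame chrom, pos, ref, alt, filter); records overlapping the
#'   region by their REF length count.
#' @param majorFreq per-accession major-allele read frequencies for this
#'   locus: a numeric vector (one value per accession), NA = no reads.
#' @param config a [perfectFilterConfig()].
#' @param contigLengths named integer vector of sequence lengths.
#' @param ssrLoci optional full [scanSSRs()] table used to detect other
#'   tracts in the flanks.
#' @return list: \code{pass} logical, \code{reasons} character vector among
#'   "flank_off_contig", "variant_in_flank", "ssr_in_flank",
#'   "low_major_freq", "no_coverage".
#' @export
filterPerfectSSR <- function(locus, variants, majorFreq, config,
                             contigLengths, ssrLoci = NULL) {
  fl <- config$flankBp
  reasons <- character()
  lo <- locus$start - fl
  hi <- locus$end + fl
  if (lo < 1 || hi > contigLengths[[locus$chrom]])
    reasons <- c(reasons, "flank_off_contig")
  v <- variants[variants$chrom == locus$chrom, , drop = FALSE]
  if (!config$countFilteredVariants && "filter" %in% names(v))
    v <- v[v$filter %in% c("PASS", ".", NA), , drop = FALSE]
  if (nrow(v)) {
    vend <- v$pos + nchar(v$ref) - 1L
    if (any(v$pos <= hi & vend >= lo))
      reasons <- c(reasons, "variant_in_flank")
  }
  if (!is.null(ssrLoci)) {
    o <- ssrLoci[ssrLoci$chrom == locus$chrom &
                   !(ssrLoci$start == locus$start &
                       ssrLoci$end == locus$end), , drop = FALSE]
    if (nrow(o) && any(o$start <= hi & o$end >= lo))
      reasons <- c(reasons, "ssr_in_flank")
  }
  f <- unlist(majorFreq, use.names = FALSE)
  if (any(is.na(f))) reasons <- c(reasons, "no_coverage")
  if (any(!is.na(f) & f <= config$majorAlleleReadFreq))
    reasons <- c(reasons, "low_major_freq")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Perfect-SNP filter
#'
#' A biallelic SNP candidate passes if its missing rate and heterozygosity
#' are below, and its minor allele frequency above, the configured
#' thresholds; no other variant lies within the flank; and the flanking
#' window is unique in the genome (both strands).
#'
#' @param candidate list/one-row data.frame: chrom, pos, ref, alt,
#'   missing_rate, het_rate, maf (e.g. a row of [snpCandidates()]).
#' @param variants variant catalog ([readVariants()]); the candidate's own
#'   record is ignored.
#' @param genome \link[Biostrings]{DNAStringSet} (or named character) for
#'   the flank-uniqueness check.
#' @param config a [perfectFilterConfig()].
#' @return list: \code{pass} logical, \code{reasons} among "multiallelic",
#'   "high_missing", "high_het", "low_maf", "variant_in_flank",
#'   "flank_not_unique".
#' @export
filterPerfectSNP <- function(candidate, variants, genome,
                             config = perfectFilterConfig()) {
  reasons <- character()
  if (grepl(",", candidate$alt) || nchar(candidate$ref) != 1 ||
      nchar(gsub(",", "", candidate$alt)) != nchar(candidate$alt) ||
      nchar(candidate$alt) != 1)
    return(list(pass = FALSE, reasons = "multiallelic"))
  if (candidate$missing_rate >= config$maxMissing)
    reasons <- c(reasons, "high_missing")
  if (candidate$het_rate >= config$maxHet)
    reasons <- c(reasons, "high_het")
  if (candidate$maf <= config$minMaf)
    reasons <- c(reasons, "low_maf")
  v <- variants[variants$chrom == candidate$chrom &
                  variants$pos != candidate$pos, , drop = FALSE]
  if (!config$countFilteredVariants && "filter" %in% names(v))
    v <- v[v$filter %in% c("PASS", ".", NA), , drop = FALSE]
  if (nrow(v)) {
    vend <- v$pos + nchar(v$ref) - 1L
    if (any(v$pos <= candidate$pos + config$flankBp &
              vend >= candidate$pos - config$flankBp))
      reasons <- c(reasons, "variant_in_flank")
  }
  if (!flankIsUnique(genome, candidate$chrom, candidate$pos, config$flankBp))
    reasons <- c(reasons, "flank_not_unique")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Summarize SNP candidates from an accession cohort
#'
#' Computes per-site missing rate, heterozygosity and minor allele frequency
#' from a SNP [GenotypeMatrix-class] (e.g. imported from a cohort VCF with
#' [genotypesFromVcf()]), yielding the per-candidate evidence consumed by
#' [filterPerfectSNP()].
#'
#' @param x a SNP [GenotypeMatrix-class] whose panel has chrom, pos, ref.
#' @return data.frame: marker_id, chrom, pos, ref, alt, missing_rate,
#'   het_rate, maf.
#' @export
snpCandidates <- function(x) {
  a <- alleleA(x); b <- alleleB(x)
  panel <- markerPanel(x)
  n <- ncol(x)
  res <- lapply(seq_len(nrow(x)), function(i) {
    obs <- !is.na(a[i, ])
    p <- alleleFrequencies(x, i)
    ref <- if ("ref" %in% colnames(panel)) panel$ref[i] else names(p)[1]
    alt <- setdiff(names(p), ref)
    maf <- if (length(p) < 2) 0 else min(p)
    data.frame(marker_id = rownames(x)[i],
               chrom = if ("chrom" %in% colnames(panel)) panel$chrom[i]
                       else NA_character_,
               pos = if ("pos" %in% colnames(panel)) panel$pos[i]
                     else NA_integer_,
               ref = ref, alt = paste(alt, collapse = ","),
               missing_rate = 1 - mean(obs),
               het_rate = if (any(obs)) mean(a[i, obs] != b[i, obs]) else 1,
               maf = maf)
  })
  do.call(rbind, res)
}

#' Read a variant catalog from VCF
#'
#' @param path VCF file.
#' @return data.frame: chrom, pos (1-based), ref, alt (comma-joined),
#'   filter.
#' @export
readVariants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT,
             filter = if ("FILTER" %in% names(fix)) fix$FILTER else ".",
             stringsAsFactors = FALSE)
}

#' Write a marker-panel table
#'
#' @param panel data.frame of markers (e.g. discovery output with pass/fail
#'   and reason codes).
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeMarkerPanel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
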