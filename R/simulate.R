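#' Synthetic variety-panel configuration
#'
#' Defines the conditions of the simulated fingerprinting study. The
#' defaults emulate a 259-variety diploid panel genotyped at 129 SSR + 159
#' SNP loci: two deeply diverged subpopulations (divergence F = 0.55 under
#' the Balding-Nichols model) plus admixed hybrids, strong inbreeding (most
#' varieties near-homozygous), SSR allele counts on 2-15 with mean about
#' 5.3, locus-specific missing rates up to 0.29 (SSR) and 0.06 (SNP), and
#' two planted alternatively-fixed subspecies-diagnostic SNPs.
#'
#' @param nPop1,nPop2,nAdmixed variety counts: thick-skinned-type
#'   population, thin-skinned-type population, admixed hybrids.
#' @param nSsr,nSnp marker counts.
#' @param nChrom,chromLength genome layout for marker positions (bp).
#' @param F Balding-Nichols divergence between the two populations.
#' @param selfing inbreeding coefficient: heterozygote probability is
#'   scaled by (1 - selfing).
#' @param ssrLadderMean mean size of the generating repeat-number ladder
#'   per SSR locus (2 + Poisson, capped at 15). Divergence and drift leave
#'   only part of the ladder observable; the default of 12 makes the
#'   observed allele count per locus across the panel average about 5.3
#'   (range within 2-15).
#' @param ssrMissingRange,snpMissingRange per-locus missing-rate ranges
#'   (uniform draws).
#' @param nFixedSnp number of planted alternatively-fixed diagnostic SNPs;
#'   these loci are generated fully homozygous and complete, and they are
#'   the only panel SNPs allowed to come out alternatively fixed (loci that
#'   fix by drift in the realized sample are redrawn).
#' @param seed RNG seed carried in the configuration.
#' @return list with class "SimConfig".
#' @export
simConfig <- function(nPop1 = 125L, nPop2 = 103L, nAdmixed = 31L,
                      nSsr = 129L, nSnp = 159L,
                      nChrom = 12L, chromLength = 2000000L,
                      F = 0.55, selfing = 0.85,
                      ssrLadderMean = 12,
                      ssrMissingRange = c(0, 0.29),
                      snpMissingRange = c(0, 0.06),
                      nFixedSnp = 2L, seed = 1L) {
  stopifnot(nPop1 > 0, nPop2 > 0, nAdmixed >= 0, nSsr >= 0, nSnp > 0,
            F > 0, F < 1, selfing >= 0, selfing <= 1,
            all(ssrMissingRange >= 0), all(ssrMissingRange <= 1),
            all(snpMissingRange >= 0), all(snpMissingRange <= 1),
            nFixedSnp >= 0, nFixedSnp <= nSnp, ssrLadderMean >= 2)
  structure(list(nPop1 = as.integer(nPop1), nPop2 = as.integer(nPop2),
                 nAdmixed = as.integer(nAdmixed), nSsr = as.integer(nSsr),
                 nSnp = as.integer(nSnp), nChrom = as.integer(nChrom),
                 chromLength = as.integer(chromLength), F = F,
                 selfing = selfing, ssrLadderMean = ssrLadderMean,
                 ssrMissingRange = ssrMissingRange,
                 snpMissingRange = snpMissingRange,
                 nFixedSnp = as.integer(nFixedSnp),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulate per-population allele frequencies (Balding-Nichols)
#'
#' SNP loci: ancestral reference frequency p ~ Uniform(0.05, 0.95), each
#' population's frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F). SSR loci: the
#' analogous Dirichlet draw over the locus's repeat-number ladder, with
#' ancestral weights themselves Dirichlet(1).
#'
#' @param cfg a [simConfig()]; its seed is set before drawing.
#' @return list: \code{panel} (marker metadata DataFrame, sorted by
#'   chromosome and position), \code{snp} (per-SNP list: ref, alt, p1, p2),
#'   \code{ssr} (per-SSR list: alleles, p1, p2), \code{plantedFixed}
#'   (marker ids of the diagnostic loci).
#' @export
simulateFrequencies <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  nM <- cfg$nSsr + cfg$nSnp
  ids <- c(sprintf("MeSSR%03d", seq_len(cfg$nSsr)),
           sprintf("MeSNP%03d", seq_len(cfg$nSnp)))
  type <- rep(c("SSR", "SNP"), c(cfg$nSsr, cfg$nSnp))
  chrom <- sprintf("chr%02d", sample.int(cfg$nChrom, nM, replace = TRUE))
  pos <- sample.int(cfg$chromLength, nM, replace = TRUE)
  ord <- order(chrom, pos)
  ids <- ids[ord]; type <- type[ord]; chrom <- chrom[ord]; pos <- pos[ord]
  shape <- (1 - cfg$F) / cfg$F

  snpIdx <- which(type == "SNP")
  planted <- if (cfg$nFixedSnp > 0)
    sort(sample(snpIdx, cfg$nFixedSnp)) else integer(0)
  snp <- vector("list", nM); ssr <- vector("list", nM)
  ref <- rep(NA_character_, nM); motif <- rep(NA_character_, nM)
  for (i in seq_len(nM)) {
    if (type[i] == "SNP") {
      al <- sample(c("A", "C", "G", "T"), 2)
      p <- stats::runif(1, 0.05, 0.95)
      if (i %in% planted) {
        p1 <- 1; p2 <- 0       # ref fixed in pop1, alt fixed in pop2
      } else {
        p1 <- stats::rbeta(1, p * shape, (1 - p) * shape)
        p2 <- stats::rbeta(1, p * shape, (1 - p) * shape)
      }
      snp[[i]] <- list(ref = al[1], alt = al[2], p1 = p1, p2 = p2)
      ref[i] <- al[1]
    } else {
      k <- min(2L + stats::rpois(1, cfg$ssrLadderMean - 2), 15L)
      alleles <- sample(5:25, 1) + seq_len(k) - 1L
      anc <- rdirichlet1(rep(1, k))
      ssr[[i]] <- list(alleles = alleles,
                       p1 = rdirichlet1(anc * shape),
                       p2 = rdirichlet1(anc * shape))
      motif[i] <- paste(sample(c("A", "C", "G", "T"), 2), collapse = "")
    }
  }
  panel <- DataFrame(type = type, chrom = chrom, pos = pos,
                     motif = motif, ref = ref, row.names = ids)
  list(panel = panel, snp = snp, ssr = ssr,
       plantedFixed = ids[planted])
}

# one population's genotype draws at one locus: returns 2 x n allele codes
draw_genotypes <- function(alleles, p, n, selfing) {
  ibd <- stats::runif(n) < selfing
  a1 <- sample(alleles, n, replace = TRUE, prob = p)
  a2 <- sample(alleles, n, replace = TRUE, prob = p)
  a2[ibd] <- a1[ibd]
  rbind(a1, a2)
}

#' Simulate a variety genotype matrix
#'
#' Draws pure-population varieties with inbreeding-adjusted genotype
#' probabilities (heterozygote probability scaled by 1 - selfing), admixed
#' varieties from per-variety mixture frequencies q p1 + (1-q) p2 with q ~
#' Uniform(0.3, 0.7), injects per-locus missing calls, and keeps the
#' planted diagnostic SNPs complete, fully homozygous and alternatively
#' fixed. Non-planted SNP loci that come out alternatively fixed between
#' the realized pure populations are redrawn (then forced heterozygous in
#' one variety if fixation persists), so the planted loci are exactly the
#' panel's fixed differences.
#'
#' @param freqs output of [simulateFrequencies()].
#' @param cfg the same [simConfig()]; \code{cfg$seed + 1} is set before
#'   drawing.
#' @return list: \code{genotypes} ([GenotypeMatrix-class]), \code{labels}
#'   (pop1/pop2/admixed per variety), \code{q} (membership matrix),
#'   \code{plantedFixed} (marker ids).
#' @export
simulateGenotypes <- function(freqs, cfg = simConfig()) {
  set.seed(cfg$seed + 1L)
  panel <- freqs$panel
  nM <- nrow(panel)
  n <- cfg$nPop1 + cfg$nPop2 + cfg$nAdmixed
  labels <- rep(c("pop1", "pop2", "admixed"),
                c(cfg$nPop1, cfg$nPop2, cfg$nAdmixed))
  vnames <- sprintf("V%03d", seq_len(n))
  names(labels) <- vnames
  qmix <- stats::runif(cfg$nAdmixed, 0.3, 0.7)
  q <- matrix(NA_real_, n, 2, dimnames = list(vnames, c("pop1", "pop2")))
  q[labels == "pop1", 1] <- stats::runif(cfg$nPop1, 0.85, 0.99)
  q[labels == "pop2", 1] <- 1 - stats::runif(cfg$nPop2, 0.85, 0.99)
  q[labels == "admixed", 1] <- qmix
  q[, 2] <- 1 - q[, 1]

  A <- matrix(NA_character_, nM, n, dimnames = list(rownames(panel), vnames))
  B <- A
  i1 <- labels == "pop1"; i2 <- labels == "pop2"; ia <- labels == "admixed"
  planted <- rownames(panel) %in% freqs$plantedFixed
  missRate <- ifelse(panel$type == "SSR",
                     stats::runif(nM, cfg$ssrMissingRange[1],
                                  cfg$ssrMissingRange[2]),
                     stats::runif(nM, cfg$snpMissingRange[1],
                                  cfg$snpMissingRange[2]))
  missRate[planted] <- 0

  draw_locus <- function(i) {
    if (panel$type[i] == "SNP") {
      al <- c(freqs$snp[[i]]$ref, freqs$snp[[i]]$alt)
      p1 <- c(freqs$snp[[i]]$p1, 1 - freqs$snp[[i]]$p1)
      p2 <- c(freqs$snp[[i]]$p2, 1 - freqs$snp[[i]]$p2)
    } else {
      al <- as.character(freqs$ssr[[i]]$alleles)
      p1 <- freqs$ssr[[i]]$p1
      p2 <- freqs$ssr[[i]]$p2
    }
    s <- if (planted[i]) 1 else cfg$selfing
    g <- matrix(NA_character_, 2, n)
    g[, i1] <- draw_genotypes(al, p1, sum(i1), s)
    g[, i2] <- draw_genotypes(al, p2, sum(i2), s)
    if (any(ia)) {
      adm <- vapply(qmix, function(qi)
        draw_genotypes(al, qi * p1 + (1 - qi) * p2, 1L, s)[, 1], character(2))
      g[, ia] <- adm
    }
    g
  }
  alt_fixed <- function(g, i) {
    # alternatively fixed between the realized pure populations?
    if (panel$type[i] != "SNP") return(FALSE)
    u1 <- unique(c(g[1, i1], g[2, i1]))
    u2 <- unique(c(g[1, i2], g[2, i2]))
    length(u1) == 1 && length(u2) == 1 && u1 != u2
  }
  for (i in seq_len(nM)) {
    g <- draw_locus(i)
    if (!planted[i]) {
      tries <- 0L
      while (alt_fixed(g, i) && tries < 10L) {
        g <- draw_locus(i)
        tries <- tries + 1L
      }
      if (alt_fixed(g, i)) {
        al <- c(freqs$snp[[i]]$ref, freqs$snp[[i]]$alt)
        g[, which(i1)[1]] <- al      # force one heterozygote
      }
    }
    miss <- stats::runif(n) < missRate[i]
    g[, miss] <- NA
    A[i, ] <- g[1, ]; B[i, ] <- g[2, ]
  }
  gm <- GenotypeMatrix(A, B, panel = panel)
  list(genotypes = gm, labels = labels, q = q,
       plantedFixed = freqs$plantedFixed)
}

#' Simulate a complete fingerprinting study
#'
#' Convenience wrapper: [simulateFrequencies()] then [simulateGenotypes()]
#' under the configuration's seed.
#'
#' @param cfg a [simConfig()].
#' @return the [simulateGenotypes()] list, plus \code{freqs} and
#'   \code{config}.
#' @export
simulateFingerprints <- function(cfg = simConfig()) {
  freqs <- simulateFrequencies(cfg)
  out <- simulateGenotypes(freqs, cfg)
  out$freqs <- freqs
  out$config <- cfg
  out
}

#' Simulate a toy genome, variant catalog and SSR read-frequency table
#'
#' Builds a small single-contig genome with planted marker-discovery
#' fixtures: clean SSR tracts, an SSR with a variant in its flank, an SSR
#' too close to the contig end, a tandem SSR pair contaminating each
#' other's flanks, SSRs failing the major-allele read-frequency rule, and
#' SNP candidates that are clean, flank-contaminated, or inside a
#' duplicated segment. A ground-truth manifest records the expected filter
#' outcome of every planted feature.
#'
#' @param seed RNG seed for the background sequence.
#' @param nAccessions accessions in the major-allele frequency table.
#' @param dir if non-NULL, writes genome.fa, variants.vcf,
#'   major_freq.csv and manifest.json there.
#' @return list: \code{genome} (\link[Biostrings]{DNAStringSet}),
#'   \code{variants} (data.frame), \code{candidates} (SNP candidate
#'   data.frame), \code{majorFreq} (matrix loci x accessions),
#'   \code{manifest} (data.frame).
#' @export
simulateGenomeAndVcf <- function(seed = 1L, nAccessions = 12L, dir = NULL) {
  set.seed(seed)
  L <- 12000L
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  stamp <- function(seq, at, what) {
    w <- strsplit(what, "")[[1]]
    seq[at:(at + length(w) - 1L)] <- w
    seq
  }
  tract <- function(motif, n) strrep(motif, n)
  # guard bases around each tract stop accidental extension
  feats <- list(
    list(id = "ssr_clean_di",   at = 500L,  seq = paste0("CC", tract("AT", 8), "GG"),
         start = 502L, len = 16L, pass = TRUE,  reason = ""),
    list(id = "ssr_clean_tri",  at = 1500L, seq = paste0("CC", tract("AAG", 6), "TT"),
         start = 1502L, len = 18L, pass = TRUE,  reason = ""),
    list(id = "ssr_clean_tetra", at = 2500L, seq = paste0("CC", tract("ACGT", 4), "GG"),
         start = 2502L, len = 16L, pass = TRUE,  reason = ""),
    list(id = "ssr_flank_snp",  at = 3500L, seq = paste0("CC", tract("AG", 7), "TT"),
         start = 3502L, len = 14L, pass = FALSE, reason = "variant_in_flank"),
    list(id = "ssr_near_end",   at = 20L,   seq = paste0("CC", tract("CT", 6), "GG"),
         start = 22L, len = 12L, pass = FALSE, reason = "flank_off_contig"),
    list(id = "ssr_pair_a",     at = 4500L, seq = paste0("CC", tract("GA", 6), "TT"),
         start = 4502L, len = 12L, pass = FALSE, reason = "ssr_in_flank"),
    list(id = "ssr_pair_b",     at = 4545L, seq = paste0("GG", tract("TC", 6), "GG"),
         start = 4547L, len = 12L, pass = FALSE, reason = "ssr_in_flank"),
    list(id = "ssr_low_freq",   at = 5200L, seq = paste0("CC", tract("CA", 7), "GG"),
         start = 5202L, len = 14L, pass = FALSE, reason = "low_major_freq"),
    list(id = "ssr_no_cov",     at = 5600L, seq = paste0("CC", tract("GT", 7), "AA"),
         start = 5602L, len = 14L, pass = FALSE, reason = "no_coverage"))
  for (f in feats) s <- stamp(s, f$at, f$seq)

  # break any accidental background tract so the planted tracts are the
  # only SSRs in the genome (keeps the manifest authoritative)
  planted_rng <- vapply(feats, function(f) c(f$start, f$start + f$len - 1L),
                        integer(2))
  repeat {
    found <- scanSSRs(stats::setNames(paste(s, collapse = ""), "chrA"))
    extra <- found[!(found$start %in% planted_rng[1, ] &
                       found$end %in% planted_rng[2, ]), , drop = FALSE]
    if (!nrow(extra)) break
    for (r in seq_len(nrow(extra))) {
      mid <- (extra$start[r] + extra$end[r]) %/% 2L
      s[mid] <- setdiff(c("A", "C", "G", "T"), s[mid])[1]
    }
  }

  snps <- list(
    list(id = "snp_clean", pos = 6000L, pass = TRUE, reason = "",
         missing = 0, het = 0, maf = 0.25),
    list(id = "snp_neighbor", pos = 7000L, pass = FALSE,
         reason = "variant_in_flank", missing = 0, het = 0, maf = 0.25),
    list(id = "snp_dup", pos = 8000L, pass = FALSE,
         reason = "flank_not_unique", missing = 0, het = 0, maf = 0.25),
    list(id = "snp_low_maf", pos = 9000L, pass = FALSE,
         reason = "low_maf", missing = 0, het = 0, maf = 0.04))
  # duplicate a 150-bp block around snp_dup elsewhere in the genome
  block <- s[7925:8075]
  s[10500:(10500 + length(block) - 1L)] <- block
  genome <- DNAStringSet(paste(s, collapse = ""))
  names(genome) <- "chrA"

  ref_at <- function(p) s[p]
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  variants <- data.frame(
    chrom = "chrA",
    pos = c(3490L, 7020L, vapply(snps, function(x) x$pos, integer(1))),
    ref = c(ref_at(3490), ref_at(7020),
            vapply(snps, function(x) ref_at(x$pos), "")),
    alt = c(other(ref_at(3490)), other(ref_at(7020)),
            vapply(snps, function(x) other(ref_at(x$pos)), "")),
    filter = "PASS", stringsAsFactors = FALSE)

  candidates <- do.call(rbind, lapply(snps, function(x)
    data.frame(marker_id = x$id, chrom = "chrA", pos = x$pos,
               ref = ref_at(x$pos), alt = other(ref_at(x$pos)),
               missing_rate = x$missing, het_rate = x$het, maf = x$maf,
               stringsAsFactors = FALSE)))

  ssr_ids <- vapply(feats, function(f) f$id, "")
  majorFreq <- matrix(1, length(feats), nAccessions,
                      dimnames = list(ssr_ids,
                                      sprintf("acc%02d", seq_len(nAccessions))))
  majorFreq["ssr_low_freq", 3] <- 0.65
  majorFreq["ssr_no_cov", 5] <- NA

  manifest <- rbind(
    do.call(rbind, lapply(feats, function(f)
      data.frame(id = f$id, type = "SSR", start = f$start,
                 end = f$start + f$len - 1L, expect_pass = f$pass,
                 expect_reason = f$reason, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(snps, function(x)
      data.frame(id = x$id, type = "SNP", start = x$pos, end = x$pos,
                 expect_pass = x$pass, expect_reason = x$reason,
                 stringsAsFactors = FALSE))))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeXStringSet(genome, file.path(dir, "genome.fa"))
    write_minimal_vcf(variants, file.path(dir, "variants.vcf"))
    utils::write.csv(data.frame(locus = rownames(majorFreq), majorFreq,
                                check.names = FALSE),
                     file.path(dir, "major_freq.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  list(genome = genome, variants = variants, candidates = candidates,
       majorFreq = majorFreq, manifest = manifest)
}

# minimal sites-only VCF writer for simulated catalogs
write_minimal_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.", variants$chrom,
                     variants$pos, variants$ref, variants$alt,
                     variants$filter), con)
  invisible(path)
}
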