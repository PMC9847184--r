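test_that("SSR scanner reads simple tracts and applies the motif rules", {
  # direct tract reading
  res <- scanSSRs(c(chr = "CCATATATATATGG"))
  expect_equal(nrow(res), 1)
  expect_equal(res$motif, "AT")
  expect_equal(res$n_repeats, 5)
  expect_equal(c(res$start, res$end), c(3, 12))

  # mononucleotide runs are outside the 2-6 bp motif rule
  expect_equal(nrow(scanSSRs(c(chr = "AAAAAAAA"))), 0)

  # tracts of 50 bp or more are excluded
  long <- paste0("CC", strrep("AG", 30), "TT")
  expect_equal(nrow(scanSSRs(stats::setNames(long, "chr"))), 0)
  ok <- paste0("CC", strrep("AG", 24), "TT")  # 48 bp
  expect_equal(scanSSRs(stats::setNames(ok, "chr"))$tract_len, 48)

  # N inside a tract kills it; empty genome gives empty output
  expect_equal(nrow(scanSSRs(c(chr = "CCATATNTATATGG"))), 0)
  expect_equal(nrow(scanSSRs(character(0))), 0)
  expect_error(scanSSRs(c(chr = "ACGTXACGT")), "non-DNA")
})

test_that("SSR scanner matches the brute-force enumerator on random sequences", {
  set.seed(42)
  for (rep in 1:100) {
    # random sequence with occasional planted repeats so tracts are common
    s <- random_dna(5000)
    for (p in sample(4500, 3)) {
      motif <- paste(sample(c("A", "C", "G", "T"), sample(2:4, 1),
                            replace = TRUE), collapse = "")
      substr(s, p, p + nchar(motif) * 6 - 1) <- strrep(motif, 6)
    }
    got <- scanSSRs(stats::setNames(s, "chr"))
    want <- oracle_scan_ssrs(s)
    expect_equal(got[, c("start", "end", "motif", "n_repeats", "tract_len")],
                 want, info = paste("rep", rep))
  }
})

test_that("motifs are canonicalized to the smallest rotation", {
  a <- scanSSRs(c(chr = "CCGAGAGAGAGAGATT"))
  b <- scanSSRs(c(chr = "CCAGAGAGAGAGAGTT"))
  expect_equal(a$motif, "AG")
  expect_equal(b$motif, "AG")
  expect_equal(a$tract_len, b$tract_len)
})

test_that("flank uniqueness counts occurrences over both strands", {
  set.seed(7)
  x <- random_dna(10000)
  g <- Biostrings::DNAStringSet(c(chrA = x))
  expect_true(flankIsUnique(g, "chrA", 5000, 50))
  # duplicated genome: nothing is unique
  g2 <- Biostrings::DNAStringSet(c(chrA = x, chrB = x))
  expect_false(flankIsUnique(g2, "chrA", 5000, 50))
  # reverse-complement copy elsewhere also defeats uniqueness
  win <- substr(x, 4950, 5050)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  g3 <- Biostrings::DNAStringSet(c(chrA = paste0(x, random_dna(100), rc)))
  expect_false(flankIsUnique(g3, "chrA", 5000, 50))
  # window off the contig end
  expect_false(flankIsUnique(g, "chrA", 10, 50))
})

test_that("perfect filters reproduce the planted manifest of the toy genome", {
  fx <- simulateGenomeAndVcf(seed = 1)
  sc <- scanSSRs(as.character(fx$genome))
  cl <- stats::setNames(Biostrings::width(fx$genome), names(fx$genome))
  man <- fx$manifest

  # the scan recovers exactly the planted tracts
  ssr_man <- man[man$type == "SSR", ]
  expect_setequal(sc$start, ssr_man$start)
  expect_setequal(sc$end, ssr_man$end)

  for (i in seq_len(nrow(sc))) {
    id <- ssr_man$id[match(sc$start[i], ssr_man$start)]
    r <- filterPerfectSSR(sc[i, ], fx$variants, fx$majorFreq[id, ],
                          perfectFilterConfig(), cl, ssrLoci = sc)
    expect_equal(r$pass, ssr_man$expect_pass[ssr_man$id == id], info = id)
    if (!r$pass)
      expect_true(ssr_man$expect_reason[ssr_man$id == id] %in% r$reasons,
                  info = id)
  }
  snp_man <- man[man$type == "SNP", ]
  for (i in seq_len(nrow(fx$candidates))) {
    r <- filterPerfectSNP(fx$candidates[i, ], fx$variants, fx$genome)
    id <- fx$candidates$marker_id[i]
    expect_equal(r$pass, snp_man$expect_pass[snp_man$id == id], info = id)
    if (!r$pass)
      expect_true(snp_man$expect_reason[snp_man$id == id] %in% r$reasons,
                  info = id)
  }
})

test_that("SNP filter flags threshold violations and multiallelic records", {
  g <- Biostrings::DNAStringSet(c(chrA = {set.seed(3); random_dna(2000)}))
  novar <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      filter = character())
  cand <- data.frame(chrom = "chrA", pos = 1000, ref = "A", alt = "C",
                     missing_rate = 0.05, het_rate = 0.05, maf = 0.2)
  expect_true(filterPerfectSNP(cand, novar, g)$pass)

  low <- cand; low$maf <- 0.04
  r <- filterPerfectSNP(low, novar, g)
  expect_false(r$pass); expect_equal(r$reasons, "low_maf")

  multi <- cand; multi$alt <- "C,G"
  expect_equal(filterPerfectSNP(multi, novar, g)$reasons, "multiallelic")

  hm <- cand; hm$missing_rate <- 0.15; hm$het_rate <- 0.2
  expect_setequal(filterPerfectSNP(hm, novar, g)$reasons,
                  c("high_missing", "high_het"))
})

test_that("tightening thresholds never grows the SNP pass set", {
  set.seed(11)
  g <- Biostrings::DNAStringSet(c(chrA = random_dna(5000)))
  novar <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      filter = character())
  cands <- data.frame(chrom = "chrA", pos = seq(200, 4800, by = 150),
                      ref = "A", alt = "C",
                      missing_rate = runif(31, 0, 0.2),
                      het_rate = runif(31, 0, 0.2),
                      maf = runif(31, 0, 0.5))
  pass_with <- function(cfg) {
    vapply(seq_len(nrow(cands)), function(i)
      filterPerfectSNP(cands[i, ], novar, g, cfg)$pass, logical(1))
  }
  loose <- pass_with(perfectFilterConfig())
  tight <- pass_with(perfectFilterConfig(maxMissing = 0.05, maxHet = 0.05,
                                         minMaf = 0.1))
  expect_true(all(tight <= loose))
})

test_that("simulated variant catalogs round-trip through VCF on disk", {
  dir <- tempfile("fix")
  fx <- simulateGenomeAndVcf(seed = 2, dir = dir)
  v <- readVariants(file.path(dir, "variants.vcf"))
  expect_equal(v[, c("chrom", "pos", "ref", "alt")],
               fx$variants[, c("chrom", "pos", "ref", "alt")])
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(g), as.character(fx$genome),
               ignore_attr = TRUE)
})
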