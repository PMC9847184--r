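make_snp_gm <- function(calls, ref, pos = NULL, chrom = "chr01") {
  # calls: list of marker -> character vector "a/b"
  m <- do.call(rbind, calls)
  dimnames(m) <- list(names(calls), sprintf("v%02d", seq_len(ncol(m))))
  a <- sub("/.*", "", m); b <- sub(".*/", "", m)
  a[m == "./."] <- NA; b[m == "./."] <- NA
  panel <- S4Vectors::DataFrame(type = "SNP",
                                chrom = rep_len(chrom, nrow(m)),
                                pos = if (is.null(pos)) seq_len(nrow(m))
                                      else pos,
                                ref = ref, row.names = rownames(m))
  GenotypeMatrix(a, b, panel = panel)
}

test_that("SNP-index is the per-population reference-allele fraction", {
  gm <- make_snp_gm(list(s1 = c("A/A", "A/A", "T/T", "T/T"),
                         s2 = c("A/A", "A/T", "T/T", "./."),
                         s3 = c("G/G", "G/G", "G/G", "G/G")),
                    ref = c("A", "A", "G"))
  lab <- stats::setNames(c("p1", "p1", "p2", "p2"), varietyNames(gm))
  pft <- snpIndex(gm, lab)
  expect_equal(pft$index["s1", "p1"], 1)      # all hom-ref
  expect_equal(pft$index["s1", "p2"], 0)      # all hom-alt
  # ref/ref + ref/alt + alt/alt -> 3/6 reference draws
  one_pop <- make_snp_gm(list(s = c("A/A", "A/T", "T/T")), ref = "A")
  pf1 <- snpIndex(one_pop, stats::setNames(rep("p", 3), varietyNames(one_pop)))
  expect_equal(pf1$index["s", "p"], 0.5)
  # missing calls drop from the denominator
  expect_equal(pft$index["s2", "p2"], 0)
  expect_equal(pft$nAlleles["s2", "p2"], 2)
})

test_that("pooled SNP-index lies between the per-population indices", {
  set.seed(71)
  gm <- random_gm(12, 30, type = "SNP")
  panel <- S4Vectors::DataFrame(type = rep("SNP", 12), chrom = "chr01",
                                pos = seq_len(12),
                                ref = alleleA(gm)[, 1])
  gm <- GenotypeMatrix(alleleA(gm), alleleB(gm), panel = panel)
  lab2 <- stats::setNames(rep(c("p1", "p2"), each = 15), varietyNames(gm))
  labPooled <- stats::setNames(rep("all", 30), varietyNames(gm))
  sep <- snpIndex(gm, lab2)$index
  pooled <- snpIndex(gm, labPooled)$index
  lo <- pmin(sep[, 1], sep[, 2]); hi <- pmax(sep[, 1], sep[, 2])
  expect_true(all(pooled[, 1] >= lo - 1e-12 & pooled[, 1] <= hi + 1e-12))
})

test_that("window track averages SNP-indices in 100kb/10kb sliding windows", {
  set.seed(73)
  pos <- sort(sample(1:500000, 25))
  calls <- lapply(seq_len(25), function(i)
    sample(c("A/A", "A/T", "T/T"), 8, TRUE))
  names(calls) <- sprintf("s%02d", 1:25)
  gm <- make_snp_gm(calls, ref = rep("A", 25), pos = pos)
  lab <- stats::setNames(rep(c("p1", "p2"), each = 4), varietyNames(gm))
  pft <- snpIndex(gm, lab)
  tr <- windowTrack(pft, "p1", "p2")
  df <- as.data.frame(tr)
  # every window against a direct windowing oracle
  for (r in seq_len(nrow(df))) {
    inw <- pos >= df$start[r] & pos < df$start[r] + 100000
    expect_equal(df$nSnps[r], sum(inw))
    if (any(inw)) {
      expect_equal(df$indexA[r], mean(pft$index[inw, "p1"]))
      expect_equal(df$delta[r],
                   abs(mean(pft$index[inw, "p1"]) - mean(pft$index[inw, "p2"])))
    } else {
      expect_true(is.na(df$indexA[r]))  # empty windows are null, not 0
    }
  }
  expect_true(all(diff(df$start) == 10000))
  # single SNP in a window reproduces that SNP's index
  lone <- make_snp_gm(list(s = c("A/A", "A/T")), ref = "A", pos = 50)
  pl <- snpIndex(lone, stats::setNames(c("p1", "p2"), varietyNames(lone)))
  trl <- windowTrack(pl, "p1", "p2", window = 100, step = 100)
  expect_equal(as.data.frame(trl)$indexA[1], 1)
})

test_that("fixed differences are the delta-SNP-index = 1 loci", {
  gm <- make_snp_gm(list(
    fixed = c(rep("A/A", 6), rep("T/T", 6)),
    near = c(rep("A/A", 5), "A/T", rep("T/T", 6)),
    boring = rep("G/G", 12)),
    ref = c("A", "A", "G"))
  lab <- stats::setNames(rep(c("p1", "p2"), each = 6), varietyNames(gm))
  pft <- snpIndex(gm, lab)
  fd <- fixedDifferences(pft, "p1", "p2")
  expect_equal(fd$marker_id, "fixed")
  expect_equal(fd$delta, 1)
  # (0.99, 0) style near-fixation is not reported at tol = 0
  expect_false("near" %in% fd$marker_id)
  expect_true("near" %in%
                fixedDifferences(pft, "p1", "p2", tol = 0.1)$marker_id)
  # the minimum-allele guard suppresses tiny samples
  expect_equal(nrow(fixedDifferences(pft, "p1", "p2", minAlleles = 13)), 0)
  # consistency: delta = 1 implies membership in the tol = 0 list
  delta <- abs(pft$index[, "p1"] - pft$index[, "p2"])
  expect_setequal(fd$marker_id, names(delta)[!is.na(delta) & delta == 1])
})

test_that("diagnostic marker evaluation scores carriers against the target", {
  gm <- make_snp_gm(list(
    d1 = c(rep("A/A", 4), rep("G/G", 4)),
    d2 = c(rep("T/T", 4), rep("C/C", 4)),
    noise = rep("A/T", 8)),
    ref = c("G", "C", "A"))
  lab <- stats::setNames(rep(c("tgt", "other"), each = 4), varietyNames(gm))
  one <- evaluateDiagnostic("d1", "A/A", gm, lab, "tgt")
  expect_equal(one$sensitivity, 1)
  expect_equal(one$specificity, 1)
  # heterozygotes are not carriers
  zero <- evaluateDiagnostic("noise", "A/A", gm, lab, "tgt")
  expect_equal(zero$sensitivity, 0)
  # two-marker AND
  both <- evaluateDiagnostic(c("d1", "d2"), c("A/A", "T/T"), gm, lab, "tgt")
  comb <- both[both$marker == "combined", ]
  expect_equal(comb$sensitivity, 1)
  expect_equal(comb$specificity, 1)
  expect_equal(comb$carriers, 4)
  # an imperfect marker: one target variety lacks the genotype
  gm2 <- make_snp_gm(list(d = c("A/A", "A/A", "A/G", "G/G")), ref = "G")
  lab2 <- stats::setNames(c("tgt", "tgt", "tgt", "other"), varietyNames(gm2))
  r <- evaluateDiagnostic("d", "A/A", gm2, lab2, "tgt")
  expect_equal(r$sensitivity, 2 / 3)
  expect_equal(r$specificity, 1)
})
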