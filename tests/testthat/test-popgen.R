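test_that("Bruvo locus distance follows the closed form and minimizes matchings", {
  expect_equal(bruvoDistance(c(10, 10), c(10, 10)), 0)
  expect_equal(bruvoDistance(c(10, 10), c(11, 11)), 0.5)
  # matching minimization: min((d(10,11)+d(12,12))/2, (d(10,12)+d(12,11))/2)
  expect_equal(bruvoDistance(c(10, 12), c(11, 12)), 0.25)
  # symmetry, identity, bound, translation invariance
  set.seed(43)
  for (rep in 1:25) {
    g1 <- sample(5:20, 2, replace = TRUE)
    g2 <- sample(5:20, 2, replace = TRUE)
    d <- bruvoDistance(g1, g2)
    expect_equal(d, bruvoDistance(g2, g1))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(bruvoDistance(g1 + 7, g2 + 7), d)
    expect_equal(bruvoDistance(g1, g1[2:1]), 0)
  }
})

test_that("Bruvo matrix averages locus distances and handles SNPs as mismatches", {
  gm <- gm_from_strings(list(s1 = c("10/10", "11/11"),
                             s2 = c("10/12", "11/12")),
                        type = c("SSR", "SSR"))
  D <- bruvoMatrix(gm)
  expect_equal(D[1, 2], (0.5 + 0.25) / 2)
  expect_equal(D[1, 1], 0)
  expect_equal(D, t(D))

  # SNP loci: 0 / 0.5 / 1 by the best allele pairing
  snp <- gm_from_strings(list(a = c("A/A", "A/T"), b = c("C/C", "G/G"),
                              c = c("A/T", "T/A")),
                         type = rep("SNP", 3))
  Ds <- bruvoMatrix(snp)
  expect_equal(Ds[1, 2], mean(c(0.5, 1, 0)))

  # identical matrices give zero; missing loci drop out of the mean
  same <- gm_from_strings(list(a = c("10/11", "10/11")), type = "SSR")
  expect_equal(bruvoMatrix(same)[1, 2], 0)
  holey <- gm_from_strings(list(a = c("./.", "10/10"), b = c("10/10", "11/11")),
                           type = c("SSR", "SSR"))
  expect_equal(bruvoMatrix(holey)[1, 2], 0.5)

  # random fixture vs per-locus averaging oracle
  set.seed(47)
  gmr <- random_gm(8, 5, type = sample(c("SNP", "SSR"), 8, replace = TRUE),
                   missing = 0.1)
  Dr <- bruvoMatrix(gmr)
  a <- alleleA(gmr); b <- alleleB(gmr); ty <- markerType(gmr)
  for (i in 1:4) for (j in (i + 1):5) {
    ds <- c()
    for (l in 1:8) {
      if (is.na(a[l, i]) || is.na(a[l, j])) next
      if (ty[l] == "SSR") {
        ds <- c(ds, bruvoDistance(as.numeric(c(a[l, i], b[l, i])),
                                  as.numeric(c(a[l, j], b[l, j]))))
      } else {
        m1 <- (as.integer(a[l, i] != a[l, j]) + as.integer(b[l, i] != b[l, j])) / 2
        m2 <- (as.integer(a[l, i] != b[l, j]) + as.integer(b[l, i] != a[l, j])) / 2
        ds <- c(ds, min(m1, m2))
      }
    }
    expect_equal(Dr[i, j], mean(ds))
  }
})

test_that("neighbor joining recovers small trees exactly", {
  # three taxa: closed-form branch lengths
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  pl <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(pl, d)
  x <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(x, (3 + 4 - 5) / 2)

  # additive 6-leaf distances are reproduced exactly (topology and lengths)
  set.seed(53)
  for (rep in 1:20) {
    gen <- ape::rtree(6, br = function(n) runif(n, 0.1, 1))
    D <- ape::cophenetic.phylo(gen)
    rec <- njTree(D)
    expect_equal(ape::dist.topo(ape::unroot(gen), rec), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }

  # identical taxa form a zero-length cherry
  d2 <- matrix(c(0, 0, 2, 2, 0, 0, 2, 2, 2, 2, 0, 1, 2, 2, 1, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr2 <- njTree(d2)
  expect_true(all(tr2$edge.length >= 0))
  expect_equal(ape::cophenetic.phylo(tr2)["a", "b"], 0)
})

test_that("AMOVA matches the explicit sums-of-squares oracle on a hand fixture", {
  # 12 samples, 2 populations, 4 loci, complete data
  set.seed(59)
  labels <- rep(c("p1", "p2"), each = 6)
  alleleList <- lapply(1:4, function(l) {
    rbind(c(sample(c("A", "A", "T"), 6, TRUE), sample(c("G", "T"), 6, TRUE)),
          c(sample(c("A", "A", "T"), 6, TRUE), sample(c("G", "T"), 6, TRUE)))
  })
  a <- do.call(rbind, lapply(alleleList, function(g) g[1, ]))
  b <- do.call(rbind, lapply(alleleList, function(g) g[2, ]))
  dimnames(a) <- dimnames(b) <- list(paste0("L", 1:4), paste0("s", 1:12))
  gm <- GenotypeMatrix(a, b, panel = S4Vectors::DataFrame(type = rep("SNP", 4)))

  # this fixture's HWE-random individuals give a negative among-variety
  # component, which must be reported and flagged, not hidden
  expect_warning(res <- amova(gm, stats::setNames(labels, colnames(a))),
                 "negative variance")
  want <- oracle_amova_ss(alleleList, labels)
  tab <- amovaTable(res)
  expect_equal(tab$SS[1], want$SS_AP)
  expect_equal(tab$SS[2], want$SS_AI)
  expect_equal(tab$SS[3], want$SS_WI)
  expect_equal(tab$SS[4], want$SS_T)
  expect_equal(tab$Df[1:3], c(1, 10, 12))
  expect_equal(sum(tab$percent[1:3]), 100, tolerance = 0.001)

  # variance components follow from the mean squares
  n_c <- (12 - (36 + 36) / 12) / 1
  ms <- c(want$SS_AP / 1, want$SS_AI / 10, want$SS_WI / 12)
  sig_c <- ms[3]; sig_b <- (ms[2] - ms[3]) / 2
  sig_a <- (ms[1] - ms[2]) / (2 * n_c)
  expect_equal(tab$sigma[1:3], c(sig_a, sig_b, sig_c))
  expect_equal(unname(phiStatistics(res)["PhiST"]),
               sig_a / (sig_a + sig_b + sig_c))
})

test_that("AMOVA degenerate partitions behave as expected", {
  # populations fixed for different alleles, all homozygous:
  # 100% among-population variance
  gm <- gm_from_strings(list(
    m1 = c(rep("A/A", 5), rep("T/T", 5)),
    m2 = c(rep("C/C", 5), rep("G/G", 5))))
  lab <- rep(c("p1", "p2"), each = 5)
  res <- amova(gm, stats::setNames(lab, varietyNames(gm)))
  expect_equal(amovaTable(res)$percent[1], 100)
  expect_equal(unname(phiStatistics(res)["PhiST"]), 1)

  # single population is rejected; size-1 populations are dropped
  expect_error(amova(gm, stats::setNames(rep("p1", 10), varietyNames(gm))))
  lab2 <- c(rep("p1", 5), rep("p2", 4), "p3")
  expect_warning(res2 <- amova(gm, stats::setNames(lab2, varietyNames(gm))),
                 "size 1")

  # label permutation on structureless data pushes the among-population
  # share toward zero
  set.seed(61)
  gmr <- random_gm(20, 40)
  rl <- stats::setNames(sample(rep(c("p1", "p2"), each = 20)),
                        varietyNames(gmr))
  resr <- amova(gmr, rl)
  expect_lt(abs(amovaTable(resr)$percent[1]), 10)
})

test_that("Weir-Cockerham Fst hits the degenerate anchors", {
  # alternatively fixed populations: theta = 1
  gm <- gm_from_strings(list(
    m1 = c(rep("A/A", 8), rep("T/T", 8)),
    m2 = c(rep("10/10", 8), rep("14/14", 8))),
    type = c("SNP", "SSR"))
  lab <- stats::setNames(rep(c("p1", "p2"), each = 8), varietyNames(gm))
  expect_equal(pairwiseFst(gm, lab)["p1", "p2"], 1)

  # same frequencies in both populations: theta near 0
  set.seed(67)
  a <- matrix(sample(c("A", "T"), 50 * 400, TRUE, prob = c(0.6, 0.4)), 50)
  b <- matrix(sample(c("A", "T"), 50 * 400, TRUE, prob = c(0.6, 0.4)), 50)
  dimnames(a) <- dimnames(b) <- list(paste0("L", 1:50), paste0("s", 1:400))
  gm2 <- GenotypeMatrix(a, b, panel = S4Vectors::DataFrame(type = rep("SNP", 50)))
  lab2 <- stats::setNames(rep(c("p1", "p2"), each = 200), colnames(a))
  expect_lt(abs(pairwiseFst(gm2, lab2)["p1", "p2"]), 0.02)
})

test_that("membership classification applies the 70% rule with >= boundary", {
  q <- rbind(v1 = c(0.95, 0.05), v2 = c(0.6, 0.4), v3 = c(0.70, 0.30),
             v4 = c(0.1, 0.9))
  colnames(q) <- c("pop1", "pop2")
  lab <- classifyMembership(q)
  expect_equal(unname(lab), c("pop1", "admixed", "pop1", "pop2"))
  expect_error(classifyMembership(rbind(c(0.5, 0.4))), "sum to 1")
})
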