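#' Bruvo's distance between two diploid SSR genotypes
#'
#' Per allele pair \eqn{d(x, y) = 1 - 2^{-|x - y|}} in repeat units; the
#' locus distance is the minimum over the two perfect matchings of the
#' alleles of the mean per-pair distance. Bounded by 1, invariant under
#' adding a constant to all repeat numbers.
#'
#' @param g1,g2 numeric length-2 vectors of repeat numbers (unordered).
#' @return distance in [0, 1].
#' @examples
#' bruvoDistance(c(10, 10), c(10, 10))  # 0
#' bruvoDistance(c(10, 10), c(11, 11))  # 0.5
#' bruvoDistance(c(10, 12), c(11, 12))  # 0.25
#' @export
bruvoDistance <- function(g1, g2) {
  stopifnot(length(g1) == 2, length(g2) == 2,
            all(g1 >= 0), all(g2 >= 0))
  d <- function(x, y) 1 - 2^(-abs(x - y))
  m1 <- (d(g1[1], g2[1]) + d(g1[2], g2[2])) / 2
  m2 <- (d(g1[1], g2[2]) + d(g1[2], g2[1])) / 2
  min(m1, m2)
}

#' Bruvo-type distance matrix over a genotype matrix
#'
#' Per-pair distance is the mean of per-locus distances over loci observed
#' in both varieties. SSR loci use [bruvoDistance()] on repeat numbers; SNP
#' loci contribute the mismatch distance under the best allele pairing
#' (0, 0.5 or 1 -- half the number of differing alleles), keeping one
#' distance on [0, 1] across marker types.
#'
#' @param x a [GenotypeMatrix-class].
#' @return symmetric numeric matrix with variety names, zero diagonal.
#' @export
bruvoMatrix <- function(x) {
  type <- markerType(x)
  a <- alleleA(x); b <- alleleB(x)
  ssr <- type == "SSR"
  # numeric encoding; SNP bases get arbitrary distinct codes (mismatch only)
  enc <- function(m) {
    out <- suppressWarnings(matrix(as.numeric(m), nrow(m)))
    snp <- !ssr
    out[snp, ] <- match(m[snp, , drop = FALSE], c("A", "C", "G", "T"))
    dimnames(out) <- dimnames(m)
    out
  }
  A <- enc(a); B <- enc(b)
  n <- ncol(A)
  D <- matrix(0, n, n, dimnames = list(colnames(A), colnames(A)))
  pair_d <- function(x1, x2, is_ssr) {
    out <- numeric(length(x1))
    out[is_ssr] <- 1 - 2^(-abs(x1[is_ssr] - x2[is_ssr]))
    out[!is_ssr] <- as.numeric(x1[!is_ssr] != x2[!is_ssr])
    out
  }
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      both <- !is.na(A[, i]) & !is.na(A[, j])
      if (!any(both)) { D[i, j] <- D[j, i] <- NA_real_; next }
      s <- ssr[both]
      m1 <- (pair_d(A[both, i], A[both, j], s) +
               pair_d(B[both, i], B[both, j], s)) / 2
      m2 <- (pair_d(A[both, i], B[both, j], s) +
               pair_d(B[both, i], A[both, j], s)) / 2
      D[i, j] <- D[j, i] <- mean(pmin(m1, m2))
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Saitou-Nei Q criterion, via
#' \code{\link[ape]{nj}}); negative branch lengths are then clamped to zero
#' with the deficit moved to the sister edge (same parent node), preserving
#' path lengths through the parent.
#'
#' @param d symmetric distance matrix with taxon names (or a
#'   \code{\link[stats]{dist}}).
#' @return an \code{\link[ape]{ape}} "phylo" tree (unrooted).
#' @export
njTree <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sisters))
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
  }
  tr
}

#' Label varieties from an admixture membership (Q) table
#'
#' A variety is assigned to its highest-membership population when that
#' coefficient reaches the threshold (>= convention at the boundary), and
#' is "admixed" otherwise.
#'
#' @param q numeric matrix/data.frame, one row per variety, one column per
#'   population; rows must sum to 1 (tolerance 0.01).
#' @param threshold membership needed for assignment (default 0.7).
#' @return named character vector of population labels or "admixed".
#' @export
classifyMembership <- function(q, threshold = 0.7) {
  q <- as.matrix(q)
  if (any(abs(rowSums(q) - 1) > 0.01))
    stop("membership rows must sum to 1")
  if (is.null(colnames(q))) colnames(q) <- paste0("pop", seq_len(ncol(q)))
  top <- max.col(q, ties.method = "first")
  lab <- ifelse(q[cbind(seq_len(nrow(q)), top)] >= threshold,
                colnames(q)[top], "admixed")
  stats::setNames(lab, rownames(q))
}

# allele count table per population for one locus: rows = alleles,
# cols = pops; plus per-pop counts of heterozygote carriers
locus_pop_counts <- function(a, b, labels) {
  pops <- sort(unique(labels))
  obs <- !is.na(a)
  alleles <- sort(unique(c(a[obs], b[obs])))
  counts <- sapply(pops, function(p) {
    sel <- labels == p & obs
    tab <- table(factor(c(a[sel], b[sel]), levels = alleles))
    as.integer(tab)
  })
  counts <- matrix(counts, nrow = length(alleles),
                   dimnames = list(alleles, pops))
  list(alleles = alleles, counts = counts, pops = pops)
}

#' Three-level analysis of molecular variance (AMOVA)
#'
#' Partitions allele-level molecular variance among populations, among
#' varieties within populations, and within varieties, from per-locus
#' sums of squares of allele mismatch distances (0/1), summed over loci.
#' Variance components follow the standard expected-mean-square
#' coefficients for unbalanced designs; Phi statistics are reported.
#' Degrees of freedom are k-1, n-k and n for k populations and n diploid
#' varieties.
#'
#' @param x a [GenotypeMatrix-class].
#' @param labels population label per variety (named or in column order);
#'   varieties labelled "admixed" or NA are excluded, as are populations of
#'   size 1 (with a warning).
#' @return an [AmovaResult-class].
#' @export
amova <- function(x, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  keep <- !is.na(labels) & labels != "admixed"
  labels <- labels[keep]
  x <- x[, keep]
  sizes <- table(labels)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding population(s) of size 1: ",
            paste(drop, collapse = ", "))
    keep <- !(labels %in% drop)
    labels <- labels[keep]
    x <- x[, keep]
    sizes <- table(labels)
  }
  k <- length(sizes)
  if (k < 2) stop("need at least two populations")
  n <- ncol(x)
  A <- alleleA(x); B <- alleleB(x)

  ss_group <- function(countmat) {
    # SS of mismatch distances within allele groups: (N - sum c^2 / N) / 2
    tot <- colSums(countmat)
    ok <- tot > 0
    sum((tot[ok] - colSums(countmat[, ok, drop = FALSE]^2) / tot[ok]) / 2)
  }
  SS_T <- 0; SS_WP <- 0; SS_WI <- 0
  for (l in seq_len(nrow(x))) {
    a <- A[l, ]; b <- B[l, ]
    obs <- !is.na(a)
    if (!any(obs)) next
    lc <- locus_pop_counts(a, b, labels)
    SS_T <- SS_T + ss_group(matrix(rowSums(lc$counts), ncol = 1))
    SS_WP <- SS_WP + ss_group(lc$counts)
    SS_WI <- SS_WI + sum(a[obs] != b[obs]) / 2
  }
  SS_AP <- SS_T - SS_WP
  SS_AI <- SS_WP - SS_WI
  df <- c(k - 1, n - k, n)
  MS <- c(SS_AP, SS_AI, SS_WI) / df
  N <- n
  n_c <- (N - sum(sizes^2) / N) / (k - 1)
  sig_c <- MS[3]
  sig_b <- (MS[2] - MS[3]) / 2
  sig_a <- (MS[1] - MS[2]) / (2 * n_c)
  sig <- c(sig_a, sig_b, sig_c)
  tot <- sum(sig)
  pct <- 100 * sig / tot
  phi <- c(PhiST = sig_a / tot,
           PhiIS = sig_b / (sig_b + sig_c),
           PhiIT = (sig_a + sig_b) / tot)
  res <- data.frame(
    source = c("Among populations", "Among varieties within populations",
               "Within varieties", "Total"),
    Df = c(df, sum(df)),
    SS = c(SS_AP, SS_AI, SS_WI, SS_T),
    MS = c(MS, NA),
    sigma = c(sig, tot),
    percent = c(pct, 100))
  if (any(sig < 0))
    warning("negative variance component(s); interpret with caution")
  new("AmovaResult", results = res, phi = phi, nPopulations = as.integer(k))
}

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (", object@nPopulations, "populations )\n")
  df <- object@results
  df$SS <- round(df$SS, 2); df$MS <- round(df$MS, 2)
  df$sigma <- round(df$sigma, 3); df$percent <- round(df$percent, 1)
  print(df, row.names = FALSE)
  cat(sprintf("Phi_ST = %.3f  Phi_IS = %.3f  Phi_IT = %.3f\n",
              object@phi["PhiST"], object@phi["PhiIS"],
              object@phi["PhiIT"]))
})

#' @describeIn amova the stratum table of an AMOVA result.
#' @param object an [AmovaResult-class].
#' @export
amovaTable <- function(object) object@results

#' @rdname amova
#' @export
phiStatistics <- function(object) object@phi

# Weir-Cockerham variance components for one allele at one locus,
# two-or-more populations; returns c(a, b, c)
wc_components <- function(p_i, h_i, n_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a, b, c)
}

#' Pairwise Weir-Cockerham Fst between populations
#'
#' Multiallelic Weir-Cockerham theta per locus, combined as a ratio of sums
#' over alleles and loci, for every population pair.
#'
#' @param x a [GenotypeMatrix-class].
#' @param labels population label per variety; "admixed"/NA excluded.
#' @return symmetric matrix of pairwise theta with population names; NA
#'   when a pair shares no polymorphic locus.
#' @export
pairwiseFst <- function(x, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  keep <- !is.na(labels) & labels != "admixed"
  labels <- labels[keep]
  x <- x[, keep]
  pops <- sort(unique(labels))
  if (length(pops) < 2) stop("need at least two populations")
  A <- alleleA(x); B <- alleleB(x)
  out <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  diag(out) <- 0
  for (pi in seq_len(length(pops) - 1)) {
    for (pj in (pi + 1):length(pops)) {
      sel <- labels %in% pops[c(pi, pj)]
      num <- 0; den <- 0
      for (l in seq_len(nrow(x))) {
        a <- A[l, sel]; b <- B[l, sel]; lab <- labels[sel]
        obs <- !is.na(a)
        n_i <- vapply(pops[c(pi, pj)],
                      function(p) sum(obs & lab == p), numeric(1))
        if (any(n_i < 2)) next
        alleles <- unique(c(a[obs], b[obs]))
        if (length(alleles) < 2) next
        for (al in alleles) {
          p_i <- vapply(pops[c(pi, pj)], function(p) {
            s <- obs & lab == p
            sum((a[s] == al) + (b[s] == al)) / (2 * sum(s))
          }, numeric(1))
          h_i <- vapply(pops[c(pi, pj)], function(p) {
            s <- obs & lab == p
            mean(xor(a[s] == al, b[s] == al))
          }, numeric(1))
          comp <- wc_components(p_i, h_i, n_i)
          num <- num + comp[1]
          den <- den + sum(comp)
        }
      }
      out[pi, pj] <- out[pj, pi] <- if (den > 0) num / den else NA_real_
    }
  }
  out
}
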