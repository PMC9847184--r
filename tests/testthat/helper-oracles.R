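# Independent oracles and fixture builders used across the test files.

# Brute-force SSR tract enumerator: direct substring comparisons, written
# independently of the run-length scanner it checks.
oracle_scan_ssrs <- function(seq, minRepeats = c("2" = 5L, "3" = 4L,
                                                 "4" = 3L, "5" = 3L,
                                                 "6" = 3L),
                             maxTract = 50L) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  sub <- function(i, n) paste(ch[i:(i + n - 1)], collapse = "")
  primitive <- function(m) {
    k <- nchar(m)
    for (d in seq_len(k - 1))
      if (k %% d == 0 && strrep(substr(m, 1, d), k / d) == m) return(FALSE)
    TRUE
  }
  canon <- function(m) {
    k <- nchar(m)
    min(vapply(seq_len(k), function(i)
      paste(substring(m, c(i:k, seq_len(i - 1)), c(i:k, seq_len(i - 1))),
            collapse = ""), ""))
  }
  cand <- list()
  for (k in 2:6) {
    minrep <- minRepeats[[as.character(k)]]
    i <- 1
    while (i + k * minrep - 1 <= L) {
      # left-maximal start for period k
      if (i > 1 && ch[i - 1] == ch[i - 1 + k]) { i <- i + 1; next }
      m <- sub(i, k)
      n <- 1
      while (i + (n + 1) * k - 1 <= L && sub(i + n * k, k) == m) n <- n + 1
      if (n >= minrep && n * k < maxTract && primitive(m) &&
          !grepl("N", sub(i, n * k), fixed = TRUE)) {
        cand[[length(cand) + 1]] <- data.frame(
          start = i, end = i + n * k - 1, motif = canon(m),
          n_repeats = n, tract_len = n * k)
      }
      i <- i + 1
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), n_repeats = integer(),
                      tract_len = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$tract_len, cand$start, nchar(cand$motif)), ]
  keep <- rep(FALSE, nrow(cand))
  cs <- integer(0); ce <- integer(0)
  for (r in seq_len(nrow(cand))) {
    if (!any(cand$start[r] <= ce & cand$end[r] >= cs)) {
      keep[r] <- TRUE
      cs <- c(cs, cand$start[r]); ce <- c(ce, cand$end[r])
    }
  }
  cand <- cand[keep, ]
  cand <- cand[order(cand$start), ]
  rownames(cand) <- NULL
  cand
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# small random GenotypeMatrix: SNP and/or SSR markers, optional missing
random_gm <- function(nMarkers, nVarieties, type = "SNP", missing = 0,
                      nAllelesSsr = 4) {
  a <- matrix(NA_character_, nMarkers, nVarieties,
              dimnames = list(sprintf("m%02d", seq_len(nMarkers)),
                              sprintf("v%02d", seq_len(nVarieties))))
  b <- a
  types <- rep_len(type, nMarkers)
  for (i in seq_len(nMarkers)) {
    pool <- if (types[i] == "SNP") sample(c("A", "C", "G", "T"), 2)
            else as.character(sample(5:20, nAllelesSsr))
    a[i, ] <- sample(pool, nVarieties, replace = TRUE)
    b[i, ] <- sample(pool, nVarieties, replace = TRUE)
  }
  miss <- matrix(stats::runif(nMarkers * nVarieties) < missing,
                 nMarkers, nVarieties)
  a[miss] <- NA; b[miss] <- NA
  GenotypeMatrix(a, b, panel = S4Vectors::DataFrame(type = types))
}

# genotype matrix from explicit "a/b" string rows (markers x varieties)
gm_from_strings <- function(rows, varieties = NULL, type = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(varieties)) varieties <- sprintf("v%02d", seq_len(ncol(m)))
  dimnames(m) <- list(names(rows), varieties)
  a <- sub("/.*", "", m); b <- sub(".*/", "", m)
  a[m == "./."] <- NA; b[m == "./."] <- NA
  panel <- if (is.null(type)) NULL else S4Vectors::DataFrame(type = type)
  GenotypeMatrix(a, b, panel = panel)
}

# direct per-pair difference counting used as the identity-module oracle
oracle_pair_diff <- function(gm) {
  g <- genotypeStrings(gm)
  n <- ncol(g)
  d <- matrix(0L, n, n); k <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { k[i, j] <- nrow(g); next }
    for (l in seq_len(nrow(g))) {
      if (!is.na(g[l, i]) && !is.na(g[l, j])) {
        k[i, j] <- k[i, j] + 1L
        if (g[l, i] != g[l, j]) d[i, j] <- d[i, j] + 1L
      }
    }
  }
  list(d = d, k = k)
}

# exhaustive minimal cover by bitmask enumeration (independent of
# exhaustiveCoreSet's combn loop)
oracle_min_cover <- function(gm) {
  g <- genotypeStrings(gm)
  n <- ncol(g); m <- nrow(g)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- matrix(FALSE, m, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    gi <- g[, pairs[p, 1]]; gj <- g[, pairs[p, 2]]
    res[, p] <- !is.na(gi) & !is.na(gj) & gi != gj
  }
  target <- colSums(res) > 0
  if (!any(target)) return(0L)
  bits <- 2^(seq_len(m) - 1)
  masks <- seq_len(2^m - 1)
  popcount <- vapply(masks, function(x) sum(bitwAnd(x, bits) > 0), integer(1))
  for (mask in masks[order(popcount)]) {
    sel <- which(bitwAnd(mask, bits) > 0)
    if (all(colSums(res[sel, , drop = FALSE]) > 0 | !target))
      return(length(sel))
  }
  m
}

# hand AMOVA from explicit pairwise allele mismatches (Excoffier SS form)
oracle_amova_ss <- function(alleleList, labels) {
  # alleleList: per locus, a 2 x n character matrix of alleles (no NA)
  n <- length(labels)
  ss_of <- function(vals) {
    N <- length(vals)
    tot <- 0
    for (i in seq_len(N - 1)) for (j in (i + 1):N)
      tot <- tot + as.integer(vals[i] != vals[j])
    tot / N
  }
  SS_T <- SS_WP <- SS_WI <- 0
  for (g in alleleList) {
    SS_T <- SS_T + ss_of(c(g[1, ], g[2, ]))
    for (p in unique(labels)) {
      sel <- labels == p
      SS_WP <- SS_WP + ss_of(c(g[1, sel], g[2, sel]))
    }
    for (i in seq_len(n)) SS_WI <- SS_WI + ss_of(g[, i])
  }
  list(SS_T = SS_T, SS_AP = SS_T - SS_WP, SS_AI = SS_WP - SS_WI,
       SS_WI = SS_WI)
}
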