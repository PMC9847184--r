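# marker x pair resolution matrix helpers --------------------------------

# indices of the strict upper triangle as two vectors
pair_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

# logical markers x pairs matrix: marker resolves pair (both observed,
# genotypes unequal)
resolves_matrix <- function(g, pairs) {
  gi <- g[, pairs$i, drop = FALSE]
  gj <- g[, pairs$j, drop = FALSE]
  !is.na(gi) & !is.na(gj) & gi != gj
}

#' Resolution metrics of a marker subset
#'
#' \code{pairRate} is the fraction of variety pairs separated by at least
#' one marker of the subset; \code{varietyRate} is the fraction of varieties
#' separable from every other variety (the distinctness rate used for core
#' sets).
#'
#' @param x a [GenotypeMatrix-class].
#' @param subset marker ids or indices (may be empty).
#' @return list: pairRate, varietyRate, unresolved (data.frame of pairs).
#' @export
resolutionRate <- function(x, subset) {
  n <- ncol(x)
  pairs <- pair_index(n)
  npairs <- length(pairs$i)
  if (length(subset) == 0) {
    resolved <- rep(FALSE, npairs)
  } else {
    g <- genotypeStrings(x)[subset, , drop = FALSE]
    resolved <- colSums(resolves_matrix(g, pairs)) > 0
  }
  un <- data.frame(variety1 = colnames(x)[pairs$i[!resolved]],
                   variety2 = colnames(x)[pairs$j[!resolved]],
                   stringsAsFactors = FALSE)
  bad <- unique(c(pairs$i[!resolved], pairs$j[!resolved]))
  list(pairRate = if (npairs) mean(resolved) else 1,
       varietyRate = (n - length(bad)) / n,
       unresolved = un)
}

#' Greedy minimal discriminating marker set
#'
#' Iteratively picks the marker separating the most still-unresolved variety
#' pairs (a marker separates a pair only when both calls are observed and
#' unequal), until no marker helps or the stop rule fires. Ties are broken
#' by higher PIC, then lower missing rate, then panel order, making the
#' selection deterministic.
#'
#' @param x a [GenotypeMatrix-class] with at least two varieties.
#' @param stop stop rule: \code{NULL} (default) runs until every resolvable
#'   pair is resolved; \code{list(k = n)} stops after n markers;
#'   \code{list(targetRate = r, metric = "variety"|"pair")} stops when the
#'   metric reaches r.
#' @return a [CoreSetResult-class].
#' @export
greedyCoreSet <- function(x, stop = NULL) {
  if (ncol(x) < 2) stop("need at least two varieties")
  g <- genotypeStrings(x)
  n <- ncol(g)
  pairs <- pair_index(n)
  res <- resolves_matrix(g, pairs)
  st <- locusStats(x)
  ord <- order(-st$PIC, st$missing, seq_len(nrow(x)))  # tie-break priority
  rank <- integer(nrow(x)); rank[ord] <- seq_len(nrow(x))

  unresolved <- rep(TRUE, ncol(res))
  resolvable <- colSums(res) > 0
  selected <- integer(0)
  curve <- list()
  total_pairs <- length(unresolved)
  repeat {
    gains <- rowSums(res[, unresolved, drop = FALSE])
    gains[selected] <- 0L
    if (max(gains) == 0L) break
    best <- which(gains == max(gains))
    best <- best[which.min(rank[best])]
    selected <- c(selected, best)
    unresolved <- unresolved & !res[best, ]
    pr <- 1 - sum(unresolved) / total_pairs
    badv <- unique(c(pairs$i[unresolved], pairs$j[unresolved]))
    vr <- (n - length(badv)) / n
    curve[[length(curve) + 1]] <- data.frame(
      step = length(selected), marker = rownames(g)[best],
      pairRate = pr, varietyRate = vr)
    if (!is.null(stop)) {
      if (!is.null(stop$k) && length(selected) >= stop$k) break
      if (!is.null(stop$targetRate)) {
        metric <- if (identical(stop$metric, "pair")) pr else vr
        if (metric >= stop$targetRate) break
      }
    }
    if (!any(unresolved & resolvable)) break
  }
  curve <- if (length(curve)) do.call(rbind, curve)
           else data.frame(step = integer(), marker = character(),
                           pairRate = numeric(), varietyRate = numeric())
  un <- data.frame(variety1 = colnames(g)[pairs$i[unresolved]],
                   variety2 = colnames(g)[pairs$j[unresolved]],
                   stringsAsFactors = FALSE)
  final_pr <- if (nrow(curve)) curve$pairRate[nrow(curve)] else 0
  final_vr <- if (nrow(curve)) curve$varietyRate[nrow(curve)] else
    resolutionRate(x, integer(0))$varietyRate
  new("CoreSetResult", markers = rownames(g)[selected], curve = curve,
      unresolved = un, pairRate = final_pr, varietyRate = final_vr)
}

setMethod("show", "CoreSetResult", function(object) {
  cat("CoreSetResult:", length(object@markers), "markers selected\n")
  cat(sprintf("  pair resolution %.4f, variety resolution %.4f\n",
              object@pairRate, object@varietyRate))
  if (nrow(object@unresolved))
    cat("  unresolved pairs:", nrow(object@unresolved), "\n")
})

#' @describeIn greedyCoreSet selected marker ids of a result.
#' @param object a [CoreSetResult-class].
#' @export
coreMarkers <- function(object) object@markers

#' @rdname greedyCoreSet
#' @export
resolutionCurve <- function(object) object@curve

#' Exhaustive minimal discriminating marker set
#'
#' Finds the smallest marker subset resolving every resolvable variety pair
#' by enumerating subsets in increasing size (lexicographic order breaks
#' ties). Minimal test-set cover is NP-hard, so the panel is capped; this is
#' the verification oracle for [greedyCoreSet()] on small instances.
#'
#' @param x a [GenotypeMatrix-class].
#' @param maxPanel refuse panels larger than this (default 15).
#' @return character vector of marker ids (smallest covering subset), or
#'   character(0) if no pair is resolvable.
#' @export
exhaustiveCoreSet <- function(x, maxPanel = 15L) {
  m <- nrow(x)
  if (m > maxPanel)
    stop("panel too large for exhaustive search (", m, " > ", maxPanel, ")")
  g <- genotypeStrings(x)
  pairs <- pair_index(ncol(g))
  res <- resolves_matrix(g, pairs)
  target <- colSums(res) > 0            # resolvable pairs
  if (!any(target)) return(character(0))
  for (size in seq_len(m)) {
    combs <- utils::combn(m, size)
    for (ci in seq_len(ncol(combs))) {
      sub <- combs[, ci]
      if (all(colSums(res[sub, , drop = FALSE]) > 0 | !target))
        return(rownames(g)[sub])
    }
  }
  rownames(g)                            # unreachable
}
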