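#' Run the full fingerprinting workflow
#'
#' Chains the package's stages over a genotype matrix (simulated under
#' \code{cfg} when none is given): QC filtering, per-locus diversity
#' statistics, pairwise-difference variety identification per marker
#' system, SSR/SNP concordance, greedy core-set selection, Bruvo distance
#' and neighbor-joining tree, AMOVA and pairwise Fst over the population
#' labels, and the SNP-index / delta-SNP-index scan with diagnostic-marker
#' evaluation. All artifacts are plain text (TSV/CSV/JSON/Newick) so runs
#' are diffable; an audit log of resolved parameters is written alongside.
#'
#' @param outDir output directory (created if needed).
#' @param cfg a [simConfig()]; its seed drives the whole run.
#' @param genotypes optionally, a precomputed [GenotypeMatrix-class] to
#'   analyse instead of simulating (then \code{labels} and \code{q} must be
#'   given; no planted-marker truth is available).
#' @param labels,q population labels and membership matrix when
#'   \code{genotypes} is supplied.
#' @param minPic,maxMissing QC thresholds (see [qcFilterLoci()]).
#' @param coreTargetRate stop rule for the core sets (variety-rate target).
#' @param membershipThreshold passed to [classifyMembership()].
#' @return (invisibly) a list of all stage results plus \code{summary}, a
#'   flat named list of the run's headline numbers (also written as
#'   summary.json).
#' @export
runPipeline <- function(outDir, cfg = simConfig(), genotypes = NULL,
                        labels = NULL, q = NULL,
                        minPic = 0.1, maxMissing = 0.20,
                        coreTargetRate = 0.99,
                        membershipThreshold = 0.7) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  planted <- character(0)
  if (is.null(genotypes)) {
    sim <- simulateFingerprints(cfg)
    genotypes <- sim$genotypes
    labels <- sim$labels
    q <- sim$q
    planted <- sim$plantedFixed
  } else if (is.null(labels) || is.null(q)) {
    stop("labels and q are required with precomputed genotypes")
  }
  audit <- list(config = unclass(cfg), minPic = minPic,
                maxMissing = maxMissing, coreTargetRate = coreTargetRate,
                membershipThreshold = membershipThreshold,
                nVarieties = ncol(genotypes), nMarkers = nrow(genotypes))
  jsonlite::write_json(audit, file.path(outDir, "run_parameters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeGenotypes(genotypes, file.path(outDir, "genotypes.tsv"))

  ## membership labelling from Q, QC, diversity
  qLabels <- classifyMembership(q, membershipThreshold)
  qc <- qcFilterLoci(genotypes, minPic = minPic, maxMissing = maxMissing)
  gm <- qc$matrix
  stats <- locusStats(gm)
  utils::write.table(as.data.frame(stats),
                     file.path(outDir, "locus_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## identification: per-system difference matrices + concordance
  type <- markerType(gm)
  gmSsr <- gm[type == "SSR", ]
  gmSnp <- gm[type == "SNP", ]
  dmSsr <- if (nrow(gmSsr) > 0) pairwiseDifferences(gmSsr) else NULL
  dmSnp <- pairwiseDifferences(gmSnp)
  histSsr <- if (!is.null(dmSsr)) differenceDistribution(dmSsr) else NULL
  histSnp <- differenceDistribution(dmSnp)
  utils::write.csv(histSnp, file.path(outDir, "difference_hist_snp.csv"),
                   row.names = FALSE)
  conc <- NULL
  if (!is.null(dmSsr)) {
    utils::write.csv(histSsr, file.path(outDir, "difference_hist_ssr.csv"),
                     row.names = FALSE)
    conc <- markerConcordance(dmSsr, dmSnp)
  }

  ## core marker sets
  coreSnp <- greedyCoreSet(gmSnp, stop = list(targetRate = coreTargetRate,
                                              metric = "variety"))
  coreSsr <- if (nrow(gmSsr) > 1)
    greedyCoreSet(gmSsr, stop = list(targetRate = coreTargetRate,
                                     metric = "variety")) else NULL
  utils::write.table(resolutionCurve(coreSnp),
                     file.path(outDir, "core_set_snp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coreSsr))
    utils::write.table(resolutionCurve(coreSsr),
                       file.path(outDir, "core_set_ssr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## population analysis on the labelled (non-admixed) varieties
  bruvo <- bruvoMatrix(gm)
  utils::write.table(bruvo, file.path(outDir, "bruvo_distances.tsv"),
                     sep = "\t", quote = FALSE)
  tree <- njTree(bruvo)
  ape::write.tree(tree, file.path(outDir, "nj_tree.nwk"))
  am <- amova(gm, qLabels)
  utils::write.table(amovaTable(am), file.path(outDir, "amova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fst <- pairwiseFst(gm, qLabels)
  utils::write.table(fst, file.path(outDir, "fst.tsv"),
                     sep = "\t", quote = FALSE)

  ## population-specific SNP scan (pure populations only)
  pureLabels <- ifelse(qLabels == "admixed", NA, qLabels)
  pft <- snpIndex(gm, pureLabels)
  pops <- colnames(pft$index)
  track <- windowTrack(pft, pops[1], pops[2])
  trackDf <- as.data.frame(track)[, c("seqnames", "start", "end", "indexA",
                                      "indexB", "delta", "nSnps")]
  names(trackDf)[1] <- "chrom"
  utils::write.table(trackDf, file.path(outDir, "snp_index_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fixed <- fixedDifferences(pft, pops[1], pops[2])
  utils::write.table(fixed, file.path(outDir, "fixed_differences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  diag <- NULL
  if (nrow(fixed) > 0) {
    gstr <- genotypeStrings(gm)
    # diagnostic genotype: the homozygous genotype of the minor-index pop
    dg <- vapply(fixed$marker_id, function(m) {
      gts <- gstr[m, !is.na(pureLabels) & pureLabels == pops[2]]
      gts <- gts[!is.na(gts)]
      names(sort(table(gts), decreasing = TRUE))[1]
    }, "")
    diag <- evaluateDiagnostic(fixed$marker_id, dg, gm, pureLabels, pops[2])
    jsonlite::write_json(diag, file.path(outDir, "diagnostic_markers.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  summary <- list(
    n_varieties = ncol(genotypes),
    n_markers_after_qc = nrow(gm),
    n_loci_removed_qc = nrow(qc$removed),
    mean_alleles_per_ssr = if (nrow(gmSsr))
      mean(stats$n_alleles[stats$type == "SSR"]) else NA,
    snp_pic_max = max(stats$PIC[stats$type == "SNP"], na.rm = TRUE),
    concordance_r2 = if (!is.null(conc)) conc$r.squared else NA,
    core_snp_size = length(coreMarkers(coreSnp)),
    core_snp_variety_rate = coreSnp@varietyRate,
    core_ssr_size = if (!is.null(coreSsr))
      length(coreMarkers(coreSsr)) else NA,
    amova_among_pop_pct = amovaTable(am)$percent[1],
    fst_pop1_pop2 = fst[pops[1], pops[2]],
    n_fixed_differences = nrow(fixed),
    planted_recovered = all(planted %in% fixed$marker_id) &&
      (length(planted) == 0 || nrow(fixed) == length(planted)))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genotypes = genotypes, labels = labels, qLabels = qLabels,
                 qc = qc, stats = stats, dmSsr = dmSsr, dmSnp = dmSnp,
                 histSsr = histSsr, histSnp = histSnp, concordance = conc,
                 coreSsr = coreSsr, coreSnp = coreSnp, bruvo = bruvo,
                 tree = tree, amova = am, fst = fst, pft = pft,
                 track = track, fixed = fixed, diagnostics = diag,
                 planted = planted, summary = summary))
}
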