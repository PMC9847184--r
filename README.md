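# melonprint

DNA fingerprinting and population analysis of crop varieties with
"perfect" SSR and SNP marker panels, built around melon (*Cucumis melo*)
variety identification.

Variety registration offices receive hundreds of near-identical commercial
varieties; field inspection takes a growing season, while a fingerprint at
a well-chosen marker panel takes a day. The catch is marker quality:
microsatellites (SSRs) and SNPs embedded in repetitive or polymorphic
flanking sequence genotype unreliably. A **perfect marker** is one whose
repeat tract or SNP site plus both 50-bp flanks carry no other variation,
whose flanking window is unique in the genome (both strands), and — for
SSRs — whose major allele is supported by a read frequency above 0.7 in
every accession of a resequencing cohort. Perfect SNPs additionally
require missing rate < 0.1, heterozygosity < 0.1 and minor allele
frequency > 0.05.

`melonprint` implements the complete analysis path around such panels:

* **Discovery** — a maximal-tract SSR scanner (primitive 2–6 bp motifs,
  tract length < 50 bp) and the perfect-SSR / perfect-SNP filters against
  a FASTA genome plus a VCF variant catalog, with exact flank-uniqueness
  counting.
* **Genotype matrix** — an S4 `GenotypeMatrix` (a `SummarizedExperiment`)
  of unordered diploid allele pairs, CSV/TSV/VCF I/O, and per-locus
  statistics: allele frequencies, PIC (as gene diversity, `1 − Σp²`, so a
  biallelic SNP tops out at 0.50), observed heterozygosity, missing
  rates, QC filtering.
* **Identification** — pairwise marker-difference matrices, bimodal
  difference-percentage histograms, SSR-vs-SNP concordance (OLS / R²),
  unresolved-pair reports.
* **Core sets** — greedy minimal discriminating marker selection with
  deterministic tie-breaks, an exhaustive small-instance oracle, and
  pair-/variety-level resolution metrics.
* **Population genetics** — Bruvo's distance (`d = 1 − 2^(−|Δrepeats|)`,
  minimized over allele pairings), neighbor-joining trees, three-level
  AMOVA with Φ statistics, pairwise Weir–Cockerham F<sub>ST</sub>, and Q-matrix
  membership labelling (70% rule).
* **Diagnostic markers** — per-population SNP-index, 100 kb/10 kb
  sliding-window ΔSNP-index tracks, alternatively fixed locus discovery,
  and sensitivity/specificity of diagnostic genotypes.
* **Synthetic data** — a seeded Balding–Nichols generator emulating a
  259-variety two-subspecies panel (129 SSR + 159 SNP, F = 0.55, strong
  inbreeding, planted diagnostic SNPs), plus a toy genome/VCF generator
  with a ground-truth manifest for the discovery filters.

## Worked example

Simulate a small two-population panel, profile it, and select a core set:

```r
library(melonprint)

cfg <- simConfig(nPop1 = 12, nPop2 = 10, nAdmixed = 3,
                 nSsr = 8, nSnp = 12, nFixedSnp = 1, seed = 99)
sim <- simulateFingerprints(cfg)
sim$genotypes
#> GenotypeMatrix: 25 varieties x 20 markers ( 8 SSR, 12 SNP )
#>   missing calls: 8.4%

head(as.data.frame(locusStats(sim$genotypes)), 3)
#>          marker_id type n_alleles       PIC     He_obs missing
#> MeSNP011  MeSNP011  SNP         2 0.4395085 0.04347826    0.08
#> MeSSR001  MeSSR001  SSR         3 0.4062500 0.05000000    0.20
#> MeSSR008  MeSSR008  SSR         4 0.5711111 0.06666667    0.40

pairwiseDifferences(sim$genotypes)
#> DifferenceMatrix: 25 varieties, 20 loci
#>   differences per pair: mean 6.7, range 1-12

greedyCoreSet(sim$genotypes)
#> CoreSetResult: 8 markers selected
#>   pair resolution 1.0000, variety resolution 1.0000

lab <- ifelse(sim$labels == "admixed", NA, sim$labels)
fixedDifferences(snpIndex(sim$genotypes, lab), "pop1", "pop2")
#>   marker_id indexA indexB delta
#> 1  MeSNP002      1      0     1
```

Every pair of the 25 varieties differs at 1–12 of the 20 markers, so the
panel separates all of them; 8 greedily chosen markers already resolve
every pair, and the planted subspecies-diagnostic SNP is recovered as the
panel's single ΔSNP-index = 1 locus. `runPipeline(dir, cfg)` chains all
stages (QC → statistics → identification → core sets → tree/AMOVA/F<sub>ST</sub> →
SNP-index scan) and writes plain-text artifacts plus a `summary.json`.

For marker discovery, `simulateGenomeAndVcf()` builds a toy genome whose
manifest records which planted SSRs/SNPs must pass or fail each filter —
see `scanSSRs()`, `filterPerfectSSR()`, `filterPerfectSNP()`,
`flankIsUnique()`.

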