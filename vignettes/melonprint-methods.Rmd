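---
title: "Perfect-marker fingerprinting of crop varieties: models and methods"
author: "melonprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfect-marker fingerprinting of crop varieties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melonprint)
```

# The problem

Commercial crop varieties — here melon (*Cucumis melo*), with its two deeply
diverged cultivated subspecies, thick-skinned ssp. *melo* and thin-skinned
ssp. *agrestis* — are legally distinct entities whose identity must be
verifiable without growing the plant. DNA fingerprinting at a fixed marker
panel does this, but only if the markers genotype robustly across hundreds
of varieties. Markers embedded in repetitive or polymorphic flanking
sequence amplify unreliably; that is the motivation for *perfect* markers:
SSR tracts or SNP sites whose site and 50-bp flanks are free of any other
variation, whose flanking window occurs exactly once in the genome, and
(for SSRs) whose major allele is supported by a clear majority of reads in
every accession of a resequencing cohort.

`melonprint` implements the full analysis path around such panels:
perfect-marker discovery from a genome plus a multi-sample variant catalog;
a genotype-matrix data model with per-locus diversity statistics; pairwise
fingerprint comparison and minimal core-set selection; Bruvo-distance
trees, AMOVA and F~ST~; and a per-population SNP-index scan for
subspecies-diagnostic loci. A seeded generator produces synthetic panels
with the statistical structure this kind of study assumes, so every stage
is testable end to end without external data.

# Marker discovery

## SSR scanning

The scanner reports maximal perfect tandem repeats of primitive 2–6 bp
motifs. A motif is *primitive* when it is not a power of a shorter unit
(`ATAT` is stored as `AT`); reported motifs are canonicalized to the
lexicographically smallest rotation on the given strand. Reverse-complement
motifs are *not* merged by default (`AG` and `CT` stay distinct), because
strand collapsing changes panel bookkeeping downstream; a configuration
flag enables it. Tract length is `n_repeats * motif length` — a trailing
partial copy neither counts nor extends the tract — and tracts of 50 bp or
more are discarded, as over-long repeats genotype poorly. Tracts containing
`N` are dropped. When candidate tracts of different periods overlap, the
longer tract wins, then the leftmost, then the shorter motif; this makes
the output a deterministic function of the sequence, which the test suite
exploits by comparing against a brute-force enumerator on random sequences.

Minimum repeat counts are not biologically canonical; the defaults (5 for
dinucleotide motifs, 4 for trinucleotide, 3 for 4–6 bp) follow common SSR
mining practice and are configurable, since they directly control panel
size.

## Perfect filters

An SSR passes when (i) the tract plus both 50-bp flanks contain no SNP, no
indel, and no other SSR tract; (ii) the full flank exists on the contig
(loci near contig ends fail rather than shrink their window); and (iii)
every accession's major-allele read frequency exceeds 0.7. The read
frequencies are consumed as a precomputed per-accession table; deriving
them from raw reads is upstream of this package's inputs. An accession
with no reads at the locus fails the 0.7 rule with reason `no_coverage`.

A SNP passes when its missing rate is below 0.1, heterozygosity below 0.1,
and minor allele frequency above 0.05 across the cohort; when no other
variant lies within 50 bp; and when its 101-bp flanking window is unique in
the genome. Heterozygosity here is the per-locus fraction of heterozygous
accessions (the per-accession reading would conflate sample quality with
locus quality). Uniqueness is realized as an exact occurrence count of the
window — focal base masked so either allele matches — over both strands,
rather than alignment-based mappability: the exact count is deterministic,
dependency-free, and checkable by a naive scan. A window whose reverse
complement also occurs, including a palindromic window matching itself on
the minus strand, is not unique. VCF records with a non-PASS FILTER still
count as variation in a flank by default (a failed call still marks an
unstable site); this too is configurable.

All coordinates in the package are 1-based and inclusive.

# The genotype matrix and diversity statistics

Fingerprints live in a `GenotypeMatrix`, a `SummarizedExperiment` with
markers as rows, varieties as columns, and two character assays holding the
unordered allele pair of each call (SSR alleles are integer repeat numbers;
SNP alleles bases). A cell is fully observed or fully missing; missing
cells are excluded from numerator and denominator of every statistic and
never imputed. Fragment-size SSR genotypes convert to repeat numbers via
`round((size - offset) / motifLength)` per locus.

Polymorphism information content is computed as gene diversity,
$PIC = 1 - \sum_i p_i^2$, whose biallelic maximum is 0.50 — the convention
under which a SNP's PIC can reach 0.50, matching how such panels are
usually summarized. Botstein's estimator
$1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ (biallelic maximum 0.375) is
available as an option. QC removes loci with PIC below 0.1 or missing rate
above 0.20 by default; these thresholds are operational choices, exposed as
arguments.

# Variety identification

Two varieties differ at a locus when their unordered allele pairs differ:
`A/T` equals `T/A`, but `A/A` differs from `A/T`. A pair with a missing
call at a locus is not compared at that locus. Difference *percentages*
are taken against the full panel size, not the per-pair compared count, so
pairs with different missingness remain comparable; both denominators are
retained in the `DifferenceMatrix`. The difference-percentage histogram
uses half-open 10%-wide bins (last bin closed); on two-population panels it
is bimodal, with within-population pairs forming the low mode.

## Core marker sets

Selecting the smallest marker subset under which (nearly) every variety has
a unique multilocus genotype is minimal test-set cover, which is NP-hard.
The package uses the standard greedy algorithm: repeatedly pick the marker
resolving the most still-unresolved pairs, breaking ties by higher PIC,
then lower missing rate, then panel order — deterministic, and biased
toward markers that stay informative as the panel is reused. A pair with a
missing call at a marker is *not* resolved by it (conservative, matching
variety-certification caution). An exhaustive enumerator capped at 15
markers serves as the verification oracle; on random instances the greedy
solution is checked against the exhaustive optimum and the
$1 + \ln(\text{pairs})$ approximation bound. Because tie-breaking in any
such program is implementation-specific, the *membership* of a core set is
not a meaningful reproduction target — only its achieved resolution is.
Resolution is reported both pair-wise (fraction of separable pairs) and
variety-wise (fraction of varieties separable from every other variety);
the variety-wise reading is the stricter and is used for stop rules.

# Population analysis

## Bruvo distance

Per allele pair, $d(x, y) = 1 - 2^{-|x-y|}$ in repeat units; the locus
distance minimizes the mean pair distance over the two perfect matchings
of the diploid alleles, and the variety distance averages loci observed in
both varieties. The distance is bounded by 1 and invariant under
translating all repeat numbers. SNP loci inside a combined matrix
contribute half the number of differing alleles in the best pairing (0,
0.5, 1) — a mismatch version of the same matching construction — keeping
one distance on [0, 1] across marker types. Mixed-ploidy genome
addition/loss models are out of scope: genotypes are strictly diploid.

## Neighbor joining

Tree construction is canonical neighbor joining (via `ape::nj`); negative
branch lengths are clamped to zero with the deficit moved to the sister
edge, preserving path lengths through the parent node. On additive
distances the output reproduces the generating tree exactly, which the
tests verify over random 6-leaf trees.

## AMOVA

The three-level partition (among populations / among varieties within
populations / within varieties) is computed from per-locus sums of squares
of allele-level mismatch distances (0/1), summed over loci, with variance
components from the standard expected-mean-square coefficients for
unbalanced designs and degrees of freedom $k-1$, $n-k$, $n$. Mismatch is
the default allele-level distance because it makes the partition exactly
the classical molecular-variance decomposition for multiallelic data;
percentages are components over their total, and $\Phi_{ST}$, $\Phi_{IS}$,
$\Phi_{IT}$ are reported. Negative components (possible when individuals
are less inbred than their population average) are reported and flagged,
never truncated. Varieties labelled admixed are excluded, as are
populations of size 1.

## F~ST~

The pairwise fixation index uses the Weir–Cockerham estimator
$\hat\theta$, extended to multiallelic loci by treating each allele as a
biallelic contrast and combining as a ratio of sums over alleles and loci.
This estimator is chosen over an AMOVA-based $\Phi$ for the pairwise table
because its small-sample corrections make parameter recovery testable: on
Balding–Nichols simulations it recovers the generating $F$ within ±0.05 at
200 diploid samples per population and 200 loci, which is asserted in the
acceptance suite at $F \in \{0.1, 0.3, 0.55\}$.

## Membership labelling

Admixture inference itself (STRUCTURE-style MCMC) is out of scope; Q
matrices are consumed as input. A variety is assigned to its
highest-membership population when that coefficient reaches 0.7, and is
"admixed" otherwise; exactly 0.7 assigns (≥ convention).

# Population-specific markers

The SNP-index of a population at a locus is its reference-allele frequency
computed from genotype calls (read-depth-based indices belong to the
upstream pipeline). The ΔSNP-index is the absolute difference between two
populations — absolute difference, not a ratio, since only |difference| = 1
corresponds to alternative fixation. Windows of 100 kb sliding by 10 kb
start at position 1, are half-open, truncate at the chromosome end, and
average SNP-indices unweighted; windows without SNPs carry NA rather than
0, so empty regions cannot masquerade as undifferentiated ones.
Alternatively fixed loci (ΔSNP-index ≥ 1 − tol, default tol = 0) require a
minimum of 10 observed alleles per population, guarding against fixation
by small-sample accident. Diagnostic markers default to the homozygous
population-specific genotype; heterozygotes and missing calls are not
carriers. Sensitivity and specificity are evaluated against
subspecies-labelled varieties only — admixed varieties have no subspecies
truth to score against.

# The synthetic study

The generator emulates a 259-variety commercial panel genotyped at 129 SSR
and 159 SNP loci: 125 varieties in a thick-skinned-type population, 103 in
a thin-skinned-type population, and 31 admixed hybrids with mixture
coefficients uniform on (0.3, 0.7). Divergence follows the
Balding–Nichols model at $F = 0.55$: each subpopulation's allele frequency
is a Beta (SNP) or Dirichlet (SSR) draw around the ancestral frequency
with concentration $(1-F)/F$. SSR mutation dynamics are approximated by
Dirichlet draws over a repeat-number ladder rather than an explicit
stepwise-mutation coalescent — sufficient for distance and statistics
testing, though it reproduces no realistic allele-size autocorrelation.
The ladder averages 12 states (2 + Poisson, capped at 15), calibrated so
the *observed* allele count per SSR across the panel averages about 5.3
with range inside 2–15 after drift prunes the ladder. Varieties are inbred
with selfing coefficient 0.85 (heterozygote probability scaled by
$1 - s$), making most varieties near-homozygous. Per-locus missing rates
are uniform up to 0.29 (SSR) and 0.06 (SNP).

Two SNP loci are planted alternatively fixed between the two pure
populations, generated fully homozygous and complete — emulating validated
subspecies-diagnostic assays. The generator's contract is that these are
*exactly* the panel's fixed differences: a non-planted locus that drifts to
alternative fixation in the realized sample is redrawn (at most 10
attempts, then one variety is forced heterozygous). This mirrors a panel
in which exactly two markers attain ΔSNP-index 1 and keeps
"recovers the planted loci" a well-defined check rather than a
probabilistic one. Everything is driven by one seed in the configuration;
equal configurations give identical output.

What passing tests on this generator do *not* show: behaviour under
linkage disequilibrium (loci are independent), under genotyping error
(calls are error-free apart from missingness), under null-allele dropout,
or under the SSR homoplasy produced by real stepwise mutation. Results on
real panels inherit none of these guarantees.

# Numerical and design notes

* Problem sizes in the test suite are chosen to keep the full run within a
  few minutes: 100 random 5-kb sequences for the scanner oracle, 50 random
  8×12 instances for core-set verification, 200 loci × 200/population for
  F~ST~ recovery, and the full 259 × 288 panel for the end-to-end run.
* Degenerate inputs: an empty genome scans to an empty table; non-DNA
  characters are rejected; an empty marker subset has resolution 0; a
  single population is an error for AMOVA/F~ST~; duplicated varieties are
  reported as permanently unresolved pairs, never silently dropped.
* The pipeline writes only plain-text artifacts (TSV/CSV/JSON/Newick) plus
  an audit log of resolved parameters, so runs are diffable and the
  determinism of a seed is a byte-level statement.
* Known limitations: no genotype imputation or phasing; diploid only; no
  bootstrap support on trees; flank uniqueness is exact-match, so it does
  not model near-duplications that would still confuse PCR primers.
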