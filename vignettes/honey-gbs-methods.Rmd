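---
title: "Methods: colony-level genotyping from honey eDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-level genotyping from honey eDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeyGBS)
```

## The problem

A honey-bee colony is a superorganism: one queen, a dozen or so drone
fathers, and tens of thousands of genetically distinct workers. Honey
produced by the colony contains environmental DNA from a large, unknown
subset of those workers, so a targeted amplicon assay sequenced deeply on
honey eDNA observes, at each panel SNP, a mixture of allele copies from
many individuals. The quantity of interest is therefore not a diploid
genotype but the **colony allele frequency** — the mean alternative-allele
dosage of the contributing workers divided by two. This package estimates
that frequency from read counts, quality-controls it, quantifies its
repeatability, and uses it to place colonies among the *Apis mellifera*
evolutionary lineages (A, C, M, O) and to report trait-associated marker
frequencies.

The panel mixes 97 ancestry-informative SNPs with 24 trait-associated
SNPs (3 calmness, 3 gentleness, 18 varroa resistance), 121 markers in
total. Panel file order is canonical: it fixes the column order of every
count and frequency matrix.

## Allele-frequency estimation

For a cell with `ref` and `alt` supporting reads, the estimator is the
raw ratio `100 * alt / (ref + alt)` percent, reported only when total
depth reaches `min_dp`. The default `min_dp = 1` deliberately equates
"called" with "covered by at least one read"; production variant callers
apply their own internal models, and the raw ratio is this package's
documented, transparent stand-in. At the depths of this assay (hundreds
to tens of thousands of reads per marker) the binomial sampling error of
the ratio is small: at depth DP and true mixture frequency `q` the RMSE
is `100 * sqrt(q(1-q)/DP)`, which the test suite verifies by simulation.

Sequencing error with per-read rate `e` biases the observed mixture to
`q = f(1-e) + (1-f)e`, i.e. a mean error of `100 e (1-2f)` percentage
points — at the default `e = 0.005` under half a point, negligible
relative to colony-sampling noise.

Allele-copy accounting (`allele_copies`) records how many chromosomal
allele observations back an estimate: ploidy × individuals, so four
diploid larvae contribute 8 copies, one pool of 35 workers 70, ten
reference bees 20. Honey matrices refuse this accounting — the number of
contributing bees is unknown (plausibly thousands) and guessing would
misstate the estimate's resolution.

## Marker matching and missingness

VCF records are matched to panel markers exactly on
`(chrom, pos, ref, alt)`. A site whose alleles are swapped relative to
the panel is reported missing with a warning and never flipped: a silent
flip converts frequency `f` into `1-f` and corrupts every downstream
statistic. In multi-allelic records only the panel alt allele's depth is
used; other alternative alleles contribute to neither count. A marker
absent from a VCF, or present without usable depth fields, is an explicit
missing cell — distinct from a reported zero-coverage `(0, 0)` cell. Both
an absent record and a no-call genotype at a panel site are accepted as
missing, since upstream callers differ in which they emit.

## Call-rate QC

The sample call rate is the fraction of panel markers called in a sample;
the SNP call rate is the fraction of samples calling a marker. Both are
defined purely by depth (`DP >= min_dp`), which makes two invariants
exact and testable: the mean sample call rate equals the mean SNP call
rate (both equal the populated-cell fraction), and raising `min_dp` can
never raise any call rate. Markers strictly below a 90 % call rate are
flagged, optionally within a stratum of matrix types — the interesting
stratum in practice being the honey matrices, where degraded template
makes a reproducible handful of amplicons underperform.

## Duplicate-aliquot concordance

Repeatability is measured on pairs of aliquots of the same DNA source
extracted and sequenced independently. Plain correlation is the wrong
instrument: two aliquot vectors can correlate perfectly while disagreeing
by a systematic shift. The package therefore uses the two-way,
absolute-agreement, single-measurement intraclass correlation, ICC(A,1),
computed from the two-way ANOVA mean squares with the shared markers as
targets and the two aliquots as raters. Markers missing in either aliquot
are dropped pairwise (the honey samples the statistic matters most for
are exactly the ones with missing markers, so listwise behaviour must be
explicit). Two boundary conventions are fixed: fewer than three shared
markers is an error, and two constant, equal vectors return 1 with a
logged message. Aliquot pairs also report Pearson/Spearman correlations
and outlier markers, defaulting to an absolute frequency difference above
20 percentage points — a reporting threshold for inspection, not a
statistical test, as no principled value exists for it.

Which ICC variant the "degree of agreement" framework prescribes is a
genuine design choice; absolute agreement (A,1) is chosen because it is
the variant that operationalises the stated reason for rejecting plain
correlation, and the choice is documented rather than asserted as
canonical. An independent `aov()`-based oracle checks the closed-form
implementation to 1e-10 in the tests.

## Ancestry: combined matrix, MDS, assignment

GBS samples are combined with two kinds of reference rows — previously
genotyped individual bees and WGS-derived genotypes, both encoded as
0/50/100 — restricted to the 97 ancestry markers. With the validation
cohort's 61 samples plus 450 + 161 references this is a 672 × 97 matrix.
Missing cells are imputed with the column (marker) mean over all rows:
deterministic, keeps every marker, and at the observed missingness
(tenths of a percent, concentrated in honey rows) perturbs distances
negligibly. A column missing everywhere is dropped with a warning.

Classical (Torgerson) MDS is run on Euclidean distances between rows on
the percent scale — no per-marker standardisation, since the frequency
scale is already common to all markers. The implementation delegates the
double-centring eigendecomposition to `stats::cmdscale` and adds the
package's contracts on top: requesting more dimensions than positive
eigenvalues is an error; negative eigenvalues are truncated at zero for
variance-explained shares; and each axis's reflection indeterminacy is
fixed by making the largest-magnitude coordinate positive (ties broken
toward the largest row index), so repeated runs and row permutations
yield bit-identical geometry. Whether distances are computed on the
percent or proportion scale only rescales the embedding and changes no
assignment.

Lineage assignment formalises the visual reading of an MDS plot as
nearest-centroid classification: reference rows define one centroid per
lineage, each query is assigned to the nearest centroid, and the ratio of
nearest to second-nearest distance measures decisiveness. Ratios above
`tau = 0.8` flag a sample as potentially admixed — sitting between
clusters rather than inside one. The default is deliberately
conservative: unadmixed colonies at realistic divergence produce ratios
around 0.5, so 0.8 flags only genuinely intermediate samples. Ties are
broken lexicographically with a warning. Mitotypes, being maternally
inherited and assayed independently, provide the cross-check: a sample
assigned to lineage M with a C1 mitotype is `discordant` — the classic
signature of maternal introgression; multiple recorded mitotypes give
`mixed`, none `unavailable`.

## Trait markers

For the 24 trait-associated markers the report gives per-group mean
frequencies on the 0–1 scale and a fixation classification: `fixed_ref`
if every non-missing frequency in the group is at or below `tol`,
`fixed_alt` at or above `100 - tol`, else `segregating`. `tol` defaults
to 0 (strict fixation, matching how fixed markers present in deep data);
the summary counts markers fixed for the reference allele in every group
simultaneously. When duplicates are excluded, each duplicate group keeps
the aliquot with the highest call rate (ties: most reads, then smallest
sample id) — the same retention rule used for group means.

## The simulator: what it emulates, and what not

The generator exists so every statistical claim above can be tested
against known truth. Its layers:

- **Lineage differentiation.** Ancestral frequencies are Uniform(0.05,
  0.95) per marker; lineage frequencies follow the Balding–Nichols model
  `Beta(p(1-F)/F, (1-p)(1-F)/F)`, the minimal standard model with mean
  `p` and variance `p(1-p)F`. Divergence defaults to `F = 0.2` per
  lineage, which separates the four lineage clusters in the first MDS
  dimensions about as crisply as real ancestry-informative panels do
  (these markers are selected for high differentiation, so the
  appropriate F is high).
- **Colony founding.** The queen draws two alleles per marker from her
  lineage; each of 12 drone fathers (a typical effective mating number)
  draws a haploid genotype, from a second lineage with probability
  `alpha`; each worker combines one uniformly chosen queen allele with
  the allele of one uniformly chosen father. The colony truth is the
  realised mean worker dosage / 2, recomputed from the workers — never
  the expectation. Honey colonies default to 1000 realised workers
  (honey aggregates DNA of thousands of bees), sequenced pools use 35,
  single larvae 1.
- **Sequencing.** Depth is negative-binomial per marker with tier means
  of 26,450× (larva), 17,480× (worker pool), 5,560× (honeycomb honey)
  and 1,140× (bulk honey) — the order-of-magnitude gradient of DNA
  quality across matrices — and dispersion `size = 2`, reflecting the
  very high depth variability of multiplexed amplicon runs. ALT reads
  are binomial with the error-folded success probability. Dropout is
  logistic in log depth with additive offsets for honey matrices (+3.5)
  and for six named fragile markers (+4.5); the offsets were chosen once
  so that bee-derived tiers genotype essentially completely, honey tiers
  keep non-fragile markers at or above roughly 95 % call rate, and the
  fragile markers fall below 90 % exactly in the honey stratum —
  reproducing the assay's observed QC signature without inventing a
  mechanistic degradation model.
- **Duplicates and mitotypes.** Duplicate aliquots redraw sequencing
  noise from the same colony truth. Mitotypes map deterministically from
  the maternal lineage (C → "C1"); the cohort builder overrides the
  recorded label where the emulated biology calls for it — the
  *A. m. mellifera* colonies carry C1 (introgressed maternal line) and
  admixed apiaries record comma-joined sets — since the mtDNA assay is
  independent of the nuclear panel and arrives as a label.

What the simulator does **not** model, and hence what passing tests do
not show about real data: amplicon primer bias and PCR duplicates,
per-base quality and strand artefacts, unequal DNA contributions of
individual workers to honey (the equal-contribution assumption is an
idealisation; real honey mixes workers of unknown, skewed proportions),
recombination and mutation, the csd locus, and trait-marker fixation
patterns (frequencies are drawn from the same continuous model as
ancestry markers, so exact fixation across groups is rare in simulation;
the fixation logic is exercised on constructed fixtures instead).
Subspecies of the same lineage are likewise not separable by
construction, matching the panel's real granularity.

## Numerical and reproducibility choices

All randomness flows from explicit integer seeds; the cohort builder
derives per-colony and per-sample sub-seeds from one base seed via a
fixed linear stream, so identical inputs give bit-identical VCFs and the
pipeline manifest's MD5 hashes reproduce exactly. Degenerate inputs have
defined behaviour throughout: empty panels, singleton duplicate groups,
honey rows with individual counts, constant vectors in correlations,
zero-variance ICC inputs, collinear MDS configurations, lineages without
references, and unmapped mitotype labels all either error with a named
cause or return a documented convention.

Problem sizes in the tests and drivers — a 61-sample cohort, 611
reference rows, 80–200 recovery colonies, 50 duplicate pairs, 100
admixed/unadmixed colonies — were chosen as the smallest sets at which
the sampling distributions of the checked statistics are comfortably
inside their asserted bounds; the full suite runs in well under a minute.

## Known limitations

The raw-ratio estimator ignores the variant caller's error model, so
absolute frequencies from real Ion Torrent data will differ slightly from
this package's estimates on the same VCFs when the caller's AF field
disagrees with the AD ratio. Nearest-centroid assignment is a
formalisation of cluster reading, not a model-based admixture estimate —
for admixture *proportions* a likelihood method (STRUCTURE/ADMIXTURE
class) is the right tool. The admixture flag's sensitivity depends on
`tau`, the MDS dimensionality and the divergence of the lineages
involved; at `tau = 0.8` it favours specificity. Lineage Y is accepted as
a label but ships with no simulation defaults.
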