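---
title: "Inbreeding and genetic load from multi-sample VCFs: methods and design"
author: "conskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inbreeding and genetic load from multi-sample VCFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedures `conskit` implements,
the assumptions behind them, the defaults and why they were chosen, and
what the synthetic-data generator does and does not emulate. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The analysis pipeline

`conskit` targets the standard desk analysis of a small-population
resequencing cohort: from a jointly called multi-sample VCF, derive (i) a
quality-filtered biallelic autosomal SNP set, (ii) a non-consanguineous
subset of individuals, (iii) per-individual genetic diversity, (iv)
run-of-homozygosity (ROH) based inbreeding coefficients, and (v)
ancestral-polarized counts of putatively deleterious genotypes. The
central container is `GenotypeCohort`, a `RangedSummarizedExperiment`
with an alternate-allele dosage assay (0/1/2/NA), per-genotype depth,
per-site QC annotations in the row data and species/outgroup labels in
the column data.

### Hard filtering

`applySiteFilters()` removes a site when any criterion fires:
`QD < 2.0`, `FS > 60.0`, `MQ < 40.0`, `ReadPosRankSum < -8.0`,
`SB >= -1.0`, `QUAL < 30`, genotype missingness > 0.20, minor-allele
frequency < 0.05, non-biallelic or non-SNV alleles, non-autosomal
location, or overlap with an excluded-region BED (CpG islands are the
typical use). Per-genotype depth below 3 masks the call *before*
missingness and allele frequency are computed, because a low-depth
genotype is uninformative rather than reference-supporting.

Three decisions deserve comment:

- **`SB >= -1.0` is applied verbatim.** As printed this criterion fires
  for essentially any annotated strand-bias value (typical SB values are
  well above −1), which is why the filter warns loudly when the rule
  removes more than half of all sites, and why the threshold is a plain
  config field (`filterConfig(sbMax = ...)`) for users who consider it a
  transcription artifact of the upstream tooling. Sites lacking an SB
  annotation skip the rule.
- **A missing INFO annotation skips that rule for that site** (with a
  summary message) rather than removing the site; this matches common
  hard-filter practice, where annotations such as `ReadPosRankSum` are
  undefined for sites without heterozygous carriers.
- **Missingness and allele frequency use all samples in the file** as
  denominator. With a single multi-species VCF this is the only
  unambiguous reading; per-species frequencies enter later, in the
  polarization step, where they are explicitly per-species.

The removal tally attributes each removed site to the *first* rule that
fired, in the fixed order: `not_autosome`, `not_biallelic_snv`,
`excluded_region`, `QD`, `FS`, `MQ`, `ReadPosRankSum`, `SB`, `QUAL`,
`missingness`, `MAF` — structural rules first, then site QC, then
genotype-derived rules. The tally plus the retained count always equals
the input count, filtering is idempotent, and loosening any single
threshold can only grow the retained set; all three properties are
tested.

### Kinship and pruning

`kinshipCoefficient()` implements the robust between-family estimator
from identity-by-state counts over jointly non-missing sites:

$$\varphi = \frac{N_{het,het} - 2\,N_{IBS0}}{N_{het,i} + N_{het,j}}$$

where $N_{IBS0}$ counts opposite-homozygote sites. The estimator needs
no allele-frequency estimates, is exact at 0.5 for duplicates, has
expectation ≈0.25 for parent–offspring and full-sib pairs and ≈0 for
unrelated individuals of one homogeneous population. In strongly inbred
cohorts unrelated pairs fall far *below* zero (heterozygotes are rare,
opposite homozygotes are not), which is exactly why the
"retain only pairs with φ < 0" rule is a workable non-consanguinity
criterion in such cohorts.

`pruneRelated()` removes individuals greedily: while any within-group
pair sits at or above the threshold (default 0), drop the individual
with the most such pairs, breaking ties toward lower sequencing depth
and then lexicographically. The published analyses this mirrors state
the retention rule but not the removal order; greedy maximum-degree
removal is the standard minimal-removal heuristic and is documented here
as a package choice. Kinship is estimated within species/population
groups only.

### Windowed diversity

Heterozygosity and pairwise mismatch are computed in non-overlapping
100-kb tiles ("sliding window with no step" is read as tiling). Per
window, He is $100 \times n_{het} / \mathrm{span}$ — a percentage per
bp. The denominator is the full window span, not the callable-site
count: with a VCF-only numerator this is the convention that produces
values on the 0.03–0.07% scale familiar from endangered-primate and
felid genomes. Incomplete terminal windows are computed but excluded
from genome-wide means by default (`completeOnly = FALSE` to include
them).

Pairwise mismatch uses the dosage distance $|g_i - g_j|/2$ per site
(opposite homozygotes 1, het vs hom 0.5, identical 0; het–het 0). The
unphased alternative — the expected allele difference of one randomly
drawn allele per individual, which scores het–het as 0.5 — is available
via `convention = "allele"`; the in-house scripts such analyses
historically used are unpublished, so both conventions are provided and
the default is stated.

### Runs of homozygosity

`scoreSnps()` slides windows of 20 consecutive SNPs; a window passes
with at most 1 heterozygous and at most 50 missing calls. Each SNP's
*hit fraction* is the proportion of passing windows among those covering
it (edge SNPs use only the windows that exist; a chromosome with fewer
than 20 SNPs yields no windows and no calls). `callRohSegments()` turns
maximal runs of SNPs with hit fraction ≥ 0.05 into segments, emitted
when they span ≥ 100 kb, contain ≥ 25 SNPs, and have ≥ 1 SNP per 10 kb.
Segment bounds are the first/last contributing SNP positions, which
makes comparison against planted truth well defined.

Numerical notes:

- The 0.05 hit-fraction threshold and 25-SNP minimum are the scanning
  tool's conventional defaults rather than published parameters; they
  are exposed in `rohScanParams()`.
- With 20-SNP windows, the 50-missing-call gate can never fire; it is
  retained verbatim for fidelity and flagged with a message.
- The scan is validated against an exhaustive window-enumeration oracle
  on instances of up to 200 SNPs (50 random instances in the acceptance
  suite), and against planted tracts for boundary accuracy.

`froh()` divides summed segment length by genome length (the autosome
total from the chromosome table), partitioning exactly (in bp) into
short (100 kb–1 Mb) and long (>1 Mb) components; the long component is
the recent-inbreeding indicator. `generationsFromLength()` dates a
segment of genetic length $L$ cM at $g = 100/(2L)$ generations, with
physical length converted at 1 Mb = 1 cM by default (`cmPerMb`
configurable); a 1-Mb ROH therefore dates to ~50 generations.

### Genetic load

`classifyEffects()` maps SnpEff-style terms to classes — LOF
(stop gained/lost, start lost, frameshift, splice donor/acceptor),
missense, synonymous — taking the most severe class at multi-effect
sites (LOF > missense > synonymous > other). `polarizeSites()` calls an
allele ancestral iff its within-species frequency among non-missing
genotypes is strictly above 0.5 *and* at least one outgroup individual
is homozygous for it; everything else is unpolarized and excluded from
load counts. The strict inequality at 0.5, the per-species computation,
and dropping (rather than species-major-rescuing) unpolarized sites are
deliberate readings of an underspecified rule and are fixed here so
tests can be exact.

`individualLoad()` counts, per individual, polarized sites homozygous
for the derived allele by class, the number of distinct genes with ≥1
homozygous-derived LOF, and ratios against the synonymous class. The
default ratio denominator is the individual's *homozygous-derived*
synonymous count, matching the "homozygous-derived LOF to synonymous"
phrasing of the load literature; `denominator = "all_synonymous"`
switches to the count of polarized synonymous sites. Note one systematic
consequence of the polarization rule worth knowing when interpreting
ratios: sites whose derived allele has drifted above frequency 0.5
within the species are censored, and censoring is strongest for the
class with the highest derived-homozygote fraction, which shifts ratios
relative to naive expectations. `candidateGeneScreen()` lists, per
group, genes carrying ≥1 homozygous-derived LOF in ≥1 retained
individual. `overlapFractions()` computes the fractions of a site set
falling in short ROH, long ROH, or outside, the quantity behind
ROH–load overlap figures.

### Group reporting

`summarizeGroups()` produces per-group mean/sd/n and two-sided
Mann–Whitney rank-sum p-values for all group pairs — exact when both
groups have ≤25 observations and no ties, normal approximation with
continuity correction otherwise. "Wilcox test" is read as the
two-sample rank-sum test since compared groups are distinct individuals.
No multiple-testing correction is applied by default, mirroring how such
comparisons are conventionally reported; `adjust = "BH"` is available.

## The synthetic cohort generator

`simulateCohort()` emulates the *statistical structure* the pipeline
consumes, with exact truth accounting, not the evolutionary process that
produced it:

- **SNPs** are placed uniformly at an expected density (default
  10⁻³/bp, a realistic joint-call density for a mammal cohort).
- **Neutral genotypes** are Hardy–Weinberg draws from a symmetric
  Beta($a$,$a$) allele-frequency spectrum. The shape $a$ is calibrated
  so the expected per-site heterozygote probability equals
  `hetRateTheta / snpDensity` ($a = h/(1-2h)$, degenerating to a point
  mass at 0.5 when $h = 0.5$); with the default θ = 4.3 × 10⁻⁴/bp the
  planted genome-wide He is 0.043% — the scale observed in endangered
  primates. When θ is not specified the spectrum is the U-shaped
  Beta(0.5, 0.5). Calibration is what makes the heterozygosity-recovery
  test exact in expectation; θ is defined *outside* autozygous tracts.
- **Autozygous tracts** are forced-homozygous runs (the single IBD
  allele is drawn from the site frequency) totalling exactly
  `targetFroh` × chromosome length per chromosome, with lengths from a
  configurable distribution (default lognormal, meanlog = log(400 kb),
  sdlog = 0.8, giving a long-ROH share of total ROH consistent with
  strongly inbred primate genomes) and ordered-uniform placement: gaps
  are an exchangeable Dirichlet split of the non-tract residue, which is
  the gap distribution of uniform non-overlapping placement but with
  exact accounting and no rejection loops at high autozygosity. An
  optional per-SNP error rate plants heterozygous calls inside tracts to
  stress the caller's one-het tolerance (default 0).
- **Relationships** are gamete-dropped (parent–offspring shares exactly
  one allele everywhere; full sibs share 0/1/2 alleles with probability
  ¼/½/¼); related samples receive no tracts, since forced homozygosity
  would corrupt the pedigree IBD structure.
- **Effect sites** receive ANN-style annotations and gene identifiers
  (consecutive blocks of 3 sites per gene within a chromosome), with
  each individual forced homozygous-derived with a per-class probability
  (defaults 0.30/0.35/0.45 for LOF/missense/synonymous over 60/600/8000
  sites — chosen once so homozygous-LOF/synonymous ratios land on the
  sub-percent scale reported for wild primate cohorts). The true
  ancestral allele is recorded; truth load counts apply the polarization
  definition to the generator's own realized matrices, so the load
  module's zero-tolerance recovery test exercises the whole
  VCF-write/read/classify/polarize/count chain.
- **Outgroups** are homozygous-ancestral with probability 0.95 per site
  (otherwise homozygous-derived), approximating well-diverged outgroup
  genomes with occasional lineage-specific substitutions.
- **QC fields** (QUAL, QD, FS, MQ, ReadPosRankSum; per-genotype DP of
  3 + Poisson(9), mean 12× as in a mid-coverage study) are emitted at
  pass levels, with `corruptQcFrac` available to plant failing sites for
  the filter's negative cases. SB is not emitted, so the verbatim
  strand-bias rule is exercised only by hand-written fixtures.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: linkage disequilibrium and
recombination maps (sites are independent given the tract structure),
population structure and drift (one frequency spectrum per cohort),
selection, genotype-calling error beyond the optional tract het rate,
reference bias, and callability gaps. Recovery results on synthetic
cohorts validate the *implementations*; they do not certify accuracy on
sequencing data with those additional complications.

Determinism: the seed fully determines the cohort, its truth set, and
the serialized VCF bytes (up to the `fileDate` header line).

## Problem sizes and tolerances

The test and acceptance workloads were sized to exercise each statistic
at the scale where its sampling noise is well inside the stated
tolerance: F_ROH recovery on 10-individual, 30-Mb cohorts at target
autozygosity 0.3/0.5/0.7 (tolerance ±0.05 absolute; observed bias is an
order of magnitude smaller, dominated by segment-boundary overhang of a
few SNP gaps per tract); kinship recovery on 50,000 sites (duplicates
±0.01, first-degree ±0.03, unrelated ±0.02); heterozygosity recovery on
10-Mb genomes (5% relative); load recovery exact on a 20-sample cohort;
ROH-caller equivalence against the brute-force oracle on 50 instances of
≤200 SNPs; rank-sum exactness on the 3-vs-3 configuration where the
two-sided p-value is 0.1 by enumeration of all 20 assignments.

## Known limitations

- The ROH scan is a consensus heuristic, not an HMM; very short gaps
  between planted tracts can merge into one called segment (harmless for
  F_ROH, visible in segment counts), and segment boundaries overhang
  planted tract edges by a few inter-SNP gaps in homozygote-dense
  backgrounds.
- The kinship estimator is the between-family form; within-family or
  structure-corrected estimators are out of scope.
- Polarization ignores sites where both alleles could satisfy the
  outgroup condition but neither exceeds 0.5 species frequency; no
  probabilistic ancestral reconstruction is attempted.
- INDELs are not analyzed; they are removed with the non-SNV tally.
- The generator's feasibility check rejects per-site heterozygote
  probabilities above 0.5; heterozygosity rates that high are outside
  the model family.
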