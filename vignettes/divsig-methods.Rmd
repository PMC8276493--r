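---
title: "Detecting signatures of selection in divergently selected lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting signatures of selection in divergently selected lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divsig)
```

## The problem

Divergent selection experiments breed two lines from one base population in
opposite directions for a single criterion over a known number of
generations. Loci that contributed to the response leave *signatures of
selection*: local patterns of variation that depart from what drift alone
would produce. Because a signature can express itself in several ways,
`divsig` combines three complementary statistics, each sensitive to a
different pattern:

* **Runs of homozygosity (ROH)** — local loss of variation. A swept region
  fixes a haplotype, so many animals of a line become homozygous across the
  same stretch of markers.
* **Windowed Weir–Cockerham FST** — allele-frequency differentiation
  between the two lines.
* **varLD** — differences in the local linkage-disequilibrium structure of
  two cohorts, compared through the eigenvalue spectra of windowed
  r² matrices.

A fourth ingredient is the experimental design itself: cohorts genotyped at
two generations allow *validation*. A region flagged in the earlier
analysis counts as a true signature only if the same method flags an
overlapping region when the full analysis is rerun on the later
generation's cohorts. Finally, validated regions are crossed with an
annotated variant table to surface genes carrying functional mutations,
with the strongest candidates being INDELs fixed divergently between the
lines.

## Genotype model and quality control

Genotypes are alt-allele dosages in {0, 1, 2} with an explicit missing
code, read from VCF (GT field) or a PLINK-text dialect whose MAP file
carries six columns (chromosome, id, cM, position, ref, alt) so the allele
assignment round-trips. Multi-allelic VCF sites are skipped rather than
split: array data of this kind is biallelic and splitting would add
untested surface. Positions are 1-based inclusive internally (the VCF
convention); every exported interval file uses BED (0-based half-open).

QC follows array practice: samples below a 97% call rate are removed
first, then SNPs with minor allele frequency below 0.05 or missingness
above 0.05, computed on the retained samples. The filter is idempotent.
No imputation is performed; downstream statistics use per-SNP effective
sample sizes instead, so missingness shrinks `n` rather than biasing
frequencies.

## Runs of homozygosity

The caller is a scanning-window algorithm. For each chromosome, all
windows of `window_snps` (default 50) consecutive SNPs are enumerated; a
window passes when it holds at most `max_het_in_window` (1) heterozygotes
and `max_missing_in_window` (0) missing calls. A SNP qualifies when it is
homozygous and at least `min_hom_window_fraction` (0.05) of the windows
covering it pass. Maximal runs of qualifying SNPs are split where adjacent
qualifying SNPs lie more than `max_gap_kb` (1000 kb) apart, and a run is a
ROH when it holds at least `min_snps_in_roh` (50) SNPs at no more than
`max_kb_per_snp` (30) kb per SNP. Two parameterization choices deserve
mention:

* Windows are SNP-count windows. At typical array density a 50-SNP window
  spans roughly 500 kb, but only the SNP count is enforced; a dual
  bp-and-SNP constraint would be underdetermined.
* The homozygous-window proportion defaults to the fraction 0.05 (5%), the
  conventional default of scanning-window ROH callers. The much stricter
  literal 0.0005 remains reachable through `roh_params()`.

Per-line consensus counts how many individuals' ROH cover each SNP.
Consensus regions are maximal runs of SNPs with total coverage of at least
`min_count` (default 2). For the signature rule — a region must be shared
by at least a fraction (default 50%) of the animals of *both* lines —
region-level counts need an aggregation convention, which the run
structure does not dictate. `divsig` refines at SNP resolution: the rule
returns maximal runs of consecutive SNPs whose per-line coverage meets
both thresholds, and a region's reported per-line count is the minimum
per-SNP coverage across it (the number of animals whose ROH spans the
region at its weakest point). Without the per-SNP detail the rule falls
back to a region-level predicate, which is what the explicit absolute
thresholds (e.g. 70/65 animals) exercise.

## Windowed FST and the drift-versus-selection rule

Per SNP, the two-population Weir–Cockerham variance components are

* `a` — among populations,
* `b` — among individuals within populations,
* `c` — within individuals (half the averaged observed heterozygosity),

computed from per-population sample size, allele frequency and observed
heterozygote frequency (no Hardy–Weinberg assumption: `h` is the observed
dosage-1 fraction). Windows tile each chromosome from position 1 with
width 500 kb and step 250 kb; the window statistic is the ratio of sums
`sum(a) / sum(a+b+c)`, the "weighted" form that accounts for unequal and
per-SNP-varying sample sizes. Windows with fewer than 10 informative SNPs
are dropped; trailing partial windows are kept when they pass that filter.
Negative estimates are retained so that the genome-wide percentile is
taken over the estimator's actual distribution.

A window is *relevant* when its value is equal or above the genome-wide
99.9th percentile, computed with the linear-interpolation (type 7)
definition. Relevant windows are then classified with the minor-allele
frequency rule: the tracked allele of each SNP is the minor allele in the
base population, tracked in all three cohorts so that direction of change
is comparable; the window frequency is the mean over its base-polymorphic
SNPs. With changes `dh = f_high − f_base` and `dl = f_low − f_base`,
the window is drift if either line is unchanged (within `epsilon`, default
0.01 — the rule needs a numeric tolerance for "no change") or if both
lines moved in the same direction; opposite movements give selection.
Windows without base-polymorphic SNPs stay unclassified. The window-level
aggregation (mean of per-SNP tracked frequencies) is the package's choice;
a median variant would behave almost identically at these window sizes.

## varLD

For each cohort comparison (Base–High, Base–Low, High–Low), sliding
windows of 50 SNPs with a step of one SNP are scored as the sum of
absolute differences of the descending-sorted eigenvalues of the two
cohorts' windowed r² matrices. r² is the squared Pearson correlation of
dosage vectors (composite LD; phase is unknown on arrays). Two numerical
conventions keep windows aligned across cohorts: SNPs with zero dosage
variance in a cohort get zero off-diagonal entries (dropping them would
desynchronise the windows), and trailing windows with fewer than 50 SNPs
are dropped. Raw scores are standardized per chromosome by mean and
*sample* standard deviation (n−1); when a chromosome's scores are all
equal the standardized scores are set to zero with a warning.

Relevance again means equal or above the comparison's genome-wide 99.9th
percentile of standardized scores. Regions relevant in both Base–High and
Base–Low are selection candidates (their base-pair intersections, at least
1 bp); regions relevant only in High–Low are attributed to drift.

## Validation and reporting

Validation is per method, never across methods: the generation-11 FST
regions can only be confirmed by the generation-13 FST rerun, and so on.
The rerun recomputes every threshold on the later generation's own
distributions. A putative interval becomes a true signature when it
overlaps any same-method interval of the rerun by at least 1 bp, keeping
its original coordinates. True sets are merged per method, unioned, and
intersected with a gene annotation (BED or GFF3 gene features); a gene is
reported when its interval overlaps the union by at least 1 bp — with BED
half-open semantics an adjacent gene does not qualify.

## Functional-variant prioritization

The annotated variant table is a flat TSV with one row per
(variant, gene, effect); the effect vocabulary is fixed to 14 classes
(upstream, downstream, intergenic, 3'UTR, 5'UTR, intron, splicing,
synonymous, missense, frameshift, inframe, ncRNA exon, stop gained, start
lost) and unknown strings are load errors naming the string. A variant is
*functional* (affects the transcription unit) when any effect is a UTR,
missense, frameshift or splicing annotation; stop-gained, start-lost and
inframe classes qualify only behind an explicit flag, keeping the default
strict. Line genotypes are pool consensus calls printed as diploid-style
pairs over {0 = reference, 1 = alternative, 2 = novel allele absent from
the reference}; a variant is *fixed divergent* when both line genotypes
are homozygous and share no allele, which covers both 1/1 vs 0/0 and the
novel-allele case 1/1 vs 2/2. Effect tabulation counts
(variant, gene, effect) combinations, so a variant annotated on two genes
contributes two effects but one variant.

The GO helper assigns each GO description to the first pathway whose
keyword it contains (case-insensitive substring), with non-matching
descriptions falling into "Other Processes"; percentages are pathway
counts over the total number of descriptions, times 100. First-match
assignment guarantees the percentages sum to 100; the multi-assignment
mode can exceed 100 and flags itself in the output.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` produces the statistical structure the analysis
assumes: a base population, two lines diverged from it by Wright–Fisher
reproduction with multiplicative selection at planted loci, and cohorts
sampled without replacement at configured generations from one continuous
run (so the later cohorts descend from the same lineages as the earlier
ones, as in a real experiment).

* **Founders and LD.** SNP positions are uniform per chromosome; founder
  allele frequencies are Beta(0.5, 0.5), conditioned polymorphic among the
  founder haplotypes. Base individuals are founder mosaics with Poisson
  crossovers (Haldane model, default 1 cM/Mb), so r² decays with physical
  distance. Default scale: 2 chromosomes × 50 Mb × 2000 SNPs, 40 founder
  haplotypes, 100 diploids per line (the base holds 200 so the lines split
  from disjoint halves). Default cohort draws are 60 base animals, 70/65
  (high/low) at the first sampled generation and 46/49 at the second,
  echoing realistic line-cohort proportions at desk scale.
* **Selection.** Fitness is multiplicative over planted loci:
  dosage of the favored allele maps to 1, 1+s, 1+2s. The default locus
  mode is `divergent`: the alt allele is favored in the favored line and
  the ref allele equally favored in the other line. This mirrors the
  two-sided nature of a divergent experiment and matters for the MAF rule:
  with one-sided selection the unfavored line moves only by drift, and its
  direction of change relative to the base is a coin flip, so the
  selection-versus-drift classification of even a perfect sweep would be
  near-random. One-sided selection remains available (`mode = "one_line"`).
* **Standing variants of single origin.** When a planted locus forces a
  founder frequency `p0`, carriers of the favored allele share one donor
  haplotype around the locus over identity-by-descent tracts whose
  one-sided lengths are exponential with mean `1/(age × r)`
  (`sweep_origin_age_gens`, default 100 generations — about 1 Mb at
  1 cM/Mb). This is the standard decay of an ancestral haplotype and is
  what makes a sweep *detectable* by window statistics: selection refixes
  one local haplotype, and the signature is sharpest at the focal SNP.
  Setting the age to 0 places the favored allele on unrelated founder
  backgrounds, which leaves the focal SNP strongly differentiated but
  produces almost no window-level signature — useful as a negative
  control, not as the default emulation.
* **Not emulated.** Mutation after generation 0, overlapping generations,
  mate choice, pedigree structure, genotyping error and array ascertainment
  are absent; genotypes are complete (the QC and statistics tolerate
  missingness, the generator simply does not produce it). Passing tests on
  this generator therefore show that the machinery detects the patterns it
  targets under idealized conditions, not that real-data artefacts are
  handled.

The annotated-variant generator is separate and lighter: it lays out
non-overlapping genes, scatters SNVs/INDELs over the effect vocabulary,
and plants a known number of fixed-divergent functional INDELs whose keys
it returns as truth; decoys are constrained never to satisfy all three
filter criteria at once.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (quantile type 7) everywhere a
  genome-wide threshold is taken; ties at the threshold are kept
  ("equal or above").
* Standardization: sample standard deviation (n−1).
* Monomorphic SNPs: undefined allele frequencies propagate as `NaN`,
  never silently as 0; per-SNP FST with a non-positive denominator is
  excluded from window sums; zero-variance SNPs contribute zero r².
* Chromosomes shorter than one window produce no windows and no calls,
  logged but not an error; thresholds exceeding line sizes produce an
  empty result with a warning; an all-samples-fail QC is an explicit
  error.
* Every stochastic entry point takes a seed and restores the caller's RNG
  state, so identical configurations give byte-identical outputs.

## Problem sizes used by the test suite

The suite exercises the full pipeline at desk scale: drift calibration
and sweep recovery run ten replicates of the default 2 × 2000-SNP,
100-per-line configuration over 11 and 13 generations; the drift closed
form is checked at N = 30 over 50 replicates of a 60-SNP chromosome; ROH
oracle equivalence uses twenty 300-SNP chromosomes with planted
homozygous tracts; the ROH consensus recovery scenario uses a denser
1500-SNP, 10-Mb chromosome so that the fixed haplotype region exceeds the
50-SNP ROH minimum. These sizes are the package's chosen compromise
between statistical resolution and a suite that runs in minutes.

## Known limitations

* The desk-scale genome holds a few hundred FST windows, so the 99.9th
  percentile threshold sits essentially at the maximum window; detection
  of a planted sweep is an honest top-1 contest, which is why the
  stochastic recovery checks are stated as at-least-7-of-10 properties
  rather than certainties.
* Consensus-ROH region counts depend on the documented min-over-region
  aggregation; other conventions (e.g. counting animals overlapping any
  part of the region) would give larger counts for long regions.
* varLD scores are compared through sorted eigenvalue spectra, so two LD
  matrices that differ only by a permutation similarity are
  indistinguishable — inherent to the statistic, not an implementation
  artefact.
* The GO helper is a keyword matcher over description strings, not an
  ontology traversal; it inherits the dictionary's blind spots.
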