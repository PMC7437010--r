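---
title: "Tracking pooled mutant populations with barseqpop: models, parameters, and validation"
author: "barseqpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking pooled mutant populations with barseqpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqpop)
```

## The setting

A pooled, barcoded deletion collection — several thousand strains, each
deleted for one gene and tagged with a strain-specific DNA barcode — is
grown as one community through a seed train and into production-style
cultivations (shake flasks, a batch bioreactor, fed-batch bioreactors under
different feeding regimes and pH set points). Sequencing the barcode
amplicon at intervals (Bar-seq) turns each sample into a vector of barcode
counts: a snapshot of the community's composition. Selection imposed by the
cultivation environment shows up as mutants drifting down in relative
abundance, disappearing below the detection limit, or rising; the analysis
task is to quantify those dynamics and attach statistical statements to
them.

`barseqpop` implements that analysis end to end, together with a simulator
that generates the same kind of experiment with a known fitness landscape,
so every stage can be validated against planted ground truth.

## From reads to abundances

**Counting rule.** A read contributes one count to a gene only if the
barcode extracted after an exact occurrence of the upstream flank matches a
catalog barcode perfectly, at full length (`countReads()`). There is no
fuzzy matching and no quality filtering: substitution errors make a read
silently drop out, which biases totals slightly down but never
cross-assigns reads between genes. Barcodes shared by more than one gene
are removed from the catalog up front (`loadCatalog()`), because a count
for them has no unambiguous owner. The real amplicon layout of any given
protocol is not fixed here, so the flank sequence and barcode length are
arguments, not constants.

**Starting-pool filter.** Genes with fewer than 10 counts in the t0 sample
(the end of the seed train) are dropped (`filterT0()`, threshold
configurable). Counts this small cannot be distinguished from sampling
noise, and a gene that starts undetectable cannot be tracked. The retained
set becomes the *gene universe* for every downstream statistic; a gene
missing from a later sample stays in the table with count 0, keeping "not
detected" an observable state rather than a missing value.

**Normalization.** Every count is increased by a pseudocount (default 10)
and divided by the per-sample total of the *adjusted* counts
(`normalizeAbundance()`):

$$a_{gs} = \frac{c_{gs} + p}{\sum_{g'} (c_{g's} + p)}.$$

The pseudocount keeps abundances strictly positive (no division by zero,
no undefined fold changes for undetected mutants). Dividing by the
adjusted rather than the raw total is a deliberate choice: it makes each
sample an exact composition (rows sum to 1), which is what Bray–Curtis and
the ordination stack assume. The alternative — dividing by the raw total —
differs by a factor of $1 + pG/N_s$ per sample and does not change any
rank-based statistic, but leaves compositions that sum to slightly more
than 1.

## Diversity and similarity over time

*Detection* is a thresholded state: gene $g$ is detected in sample $s$ when
$c_{gs} \ge n$, with $n = 10$ by default and the scan list
$\{1, 5, 10, 20\}$ used when the conclusion should be shown to be
threshold-robust. *Richness* is the number of detected genes.
`lossWindows()` differences the detection sets of consecutive timepoints
within a condition and reports, per threshold, the genes lost and gained in
each window plus the window of maximal loss — the localization of a
"mass-extinction" event. Loss here means a detection-state transition, not
permanent extinction: a mutant hovering at the threshold can be lost and
regained, which is why gains are tracked too (their telescoping sum is a
tested invariant).

`pearsonMatrix()` correlates samples on raw counts, the convention for
seed-train robustness checks. Raw-count correlation is depth-sensitive —
two samples of the same pool at very different depths correlate slightly
below 1 — so an abundance-based variant is available behind a flag
(`useAbundance = TRUE`).

## Beta diversity

The ecology stack is implemented in the package (vegan serves as an
independent cross-check in the test suite, never as the implementation).

**Bray–Curtis** (`brayCurtis()`):
$d_{ij} = 1 - 2\sum_g \min(x_{ig},x_{jg}) / \sum_g (x_{ig}+x_{jg})$,
bounded in $[0,1]$, 0 for identical compositions, 1 for disjoint support.

**PCoA** (`pcoa()`): eigendecomposition of the Gower-centered
$-\tfrac12 D^{(2)}$. Bray–Curtis matrices are generally not
Euclidean-embeddable, so negative eigenvalues occur; they are kept in the
result rather than silently dropped, because the dispersion analysis needs
them.

**NMDS** (`nmds()`): minimizes Kruskal stress-1
$\sqrt{\sum (d_{ij}-\hat d_{ij})^2 / \sum d_{ij}^2}$ where $\hat d$ is the
pool-adjacent-violators isotonic regression of the configuration distances
on the observed dissimilarity ranks (primary tie treatment: tied observed
dissimilarities may take distinct disparities). Numerical choices:

* one start from the PCoA configuration plus `nRestarts - 1` random
  Gaussian starts (default 20 total); the best final stress wins;
* within a restart, a gradient step (analytic stress gradient) is accepted
  only if it lowers the freshly re-isotonized stress, with backtracking
  halving of the step size — so the per-restart stress trace is
  non-increasing *by construction*, which the tests assert directly;
* convergence at relative improvement below `tol` ($10^{-7}$) or a
  vanishing gradient; non-convergence returns the best configuration with
  a warning flag, never silently;
* the seed argument makes the whole procedure reproducible bit for bit.

A known behaviour, not a defect: when the data form tight, cleanly
separated clusters (e.g. many nearly identical timepoints of an unstressed
reactor against a few strongly diverged ones), stress-1 has degenerate
near-zero minima that collapse clusters to points. Independent
implementations reproduce the same near-zero stress on such inputs.
Ordinations of strongly clustered Bar-seq data should therefore be read as
cluster diagrams, and the stress value not over-interpreted.

**PERMANOVA** (`permanova()`): Anderson's decomposition
$SS_{total} = \sum_{i<j} d_{ij}^2/n$, $SS_{within}$ analogous within
groups, $F = (SS_B/(a-1))/(SS_W/(n-a))$, with significance by permuting
labels. Repeated measures are the crux: sampling the same reactor over
time makes free shuffles invalid. The paper-style phrase "corrected for
repeated measures" is realized here as *restricted permutations*:

* `strata` absent — free shuffles;
* `strata` given and labels vary within strata (e.g. testing *time*) —
  labels are shuffled only within each stratum (reactor);
* `strata` given and labels constant within strata (e.g. testing *feeding
  regime*, a whole-reactor property) — entire strata exchange labels, so
  the exchangeable unit is the reactor and no permutation ever splits a
  reactor's time series. The test suite asserts this on the permutation
  traces themselves.

When the number of distinct label arrangements is no larger than the
requested permutation count, the test enumerates them all and the p-value
is exact (fraction of arrangements, identity included, with
$F^* \ge F$); otherwise $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, which
never returns 0. Tested properties: exact agreement with a brute-force
enumeration on a 3+3 design, type-I error inside the 95% binomial band at
$\alpha = 0.05$ under a neutral simulation, and super-uniformity of null
p-values. One term is tested at a time; multi-factor models with
interactions are out of scope.

**Beta dispersion** (`betaDispersion()`): each sample's distance to its
group centroid in full PCoA space, with the squared imaginary-axis
component subtracted from the squared real-axis component and the result
floored at 0 — the standard correction when the dissimilarity is
non-Euclidean. Centroids, not spatial medians. The global comparison uses
the classical one-way ANOVA F with both the F-distribution p-value and a
permutation p-value; pairwise group comparisons are permutation tests with
Benjamini–Hochberg adjustment. Permutation tests are distribution-free and
reuse the same machinery as the global test, which is why they stand in
for a parametric post-hoc (Tukey HSD) here. Groups of one sample keep
their (zero) distance but are excluded from the tests.

## Selection calls and enrichment

`classifySelection()` compares one condition between two timepoints and
assigns exactly one status per gene, in this order:

1. **lost** — count at the later timepoint below `lossThreshold`
   (default 10), regardless of the abundance trend;
2. **depleted** — relative abundance dropped by at least
   `depletionFraction` (default 50%);
3. **enriched** — relative abundance rose at least `enrichmentFold`-fold
   (default 2); the qualitative "more fit" notion is not standardized, so
   this knob is an explicit interpretation;
4. **retained** — everything else.

The comparison uses pseudocounted relative abundances (not raw counts),
since read depth varies between samples. `compareConditions()` builds the
full inclusion–exclusion partition (Venn regions) of per-condition gene
sets. `hypergeometricEnrichment()` tests each annotation term with at
least one hit via the upper-tail hypergeometric p-value, reports fold
enrichment $(k/n)/(K/N)$, and adjusts across tested terms with the
Benjamini–Hochberg step-up rule (`bhAdjust()`; `stats::p.adjust` is the
oracle in its tests). Two deliberate choices: the background is the
post-filter gene universe — the genes the experiment could actually have
observed — rather than the whole genome, avoiding detection-bias
inflation; and $m$ in BH is the number of terms actually tested (those
with $\ge 1$ hit), matching common list-analysis tools. There is no
GO-DAG ancestor propagation; the annotation is whatever local table is
supplied.

## The simulator

`simulateTrajectory()` advances a haploid selection model: within a phase
of $g$ generations, $x_i \leftarrow x_i (1+s_i)^g$ followed by
renormalization, where $s_i$ is the per-generation selection coefficient
of mutant $i$ in that phase ($s=0$ neutral, $s<0$ deleterious,
$(1+s) > 0$ enforced). Optional multinomial bottlenecks at phase
boundaries model serial-transfer dilution; the recorded sample at a
boundary is the pre-transfer culture. `sampleReads()` adds sequencing
noise as a single multinomial draw at the requested depth, and
`emitFastq()` goes one level deeper, writing one synthetic read per count
(random prefix + flank + barcode + random suffix, constant quality) with
independent per-base substitution on the barcode (`errorRate`) and,
separately, on the flank (`flankErrorRate`) — the first gives the
closed-form recovered fraction $(1-e)^L$ under perfect-match counting,
the second exercises flank-miss dropout.

`presetStudyDesign()` emits the study layout the analysis is meant for: a
shared two-stage seed train, two shake flasks and a batch bioreactor
sampled to 72 h, and four fed-batch bioreactors (CF4, CF6, DF4, DF6)
sampled at 0/5/24/33/48/72/119 h. Planted stress: a late 48–72 h phase
with negative $s$ for CF4 (default $-0.35$) and DF4 (weaker, $-0.15$),
and for CF6 both a 33–48 h onset ($-0.35$) and the strongest late phase
($-0.75$) — an abstraction of ethanol accumulation under an overfed
constant-rate regime, strongest where overfeeding is worst. Defaults
chosen once for the simulated conditions: 3000 genes (2000 in the heavier
validation runs), 5% of the pool planted as stress-sensitive, initial
abundances log-normal with $\sigma = 1$ (an uneven pool, as real
collections are), generations per phase 5 (seed stages), 7 (batch,
split 2/3/2 across its sampled windows) and 6 (each fed-batch interval) —
cultivations are specified in hours, so generation counts are abstractions
exposed as configuration.

What the simulator does **not** emulate: mechanistic fermentation (no
OD/DO/glucose/ethanol dynamics — stress is a phase property, not a state
variable), genetic drift beyond the optional bottleneck, mutation,
barcode-specific amplification bias, and chimeric or indel-bearing reads.
Passing tests therefore demonstrate that the statistics recover planted
compositional dynamics under multinomial sampling noise; they do not
certify behaviour under PCR bias or other real-library artifacts.

## Validation scale and reproducibility

The test suite validates each operation against independent brute-force
oracles (pairwise-loop Bray–Curtis, enumerated hypergeometric tails,
literal step-up BH, membership-key Venn partitions, enumerated PERMANOVA)
and the whole stack against planted truth. The heavier end-to-end checks
run at 2000 genes, 100 planted stress-sensitive mutants and
$2\times10^6$ reads per sample — deep enough that detection noise is
negligible against the planted effects, small enough to run in seconds —
and the PERMANOVA calibration uses 500 replicates of a 12-sample neutral
design at 199 permutations. `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-supplied seed and writes the
headline numbers as JSON.

Every stochastic entry point takes an explicit seed and is bit-for-bit
reproducible given it; `runPipeline()` records seeds, per-stage checksums
and warnings in its report, and rerunning a config reproduces identical
outputs.

## Known limitations

* Exact matching only: no edit-distance rescue of errored barcodes, no
  UMIs, no paired-end merging; totals are slightly deflated at realistic
  error rates (by $\approx 1-(1-e)^L$), uniformly across genes.
* One PERMANOVA term at a time; variance fractions from sequential
  single-factor runs are not a joint decomposition.
* The enrichment stage tests a flat term table; hierarchical ontologies
  must be flattened by the caller.
* NMDS stress can be degenerate-near-zero for strongly clustered data
  (see above).
* The loss/gain bookkeeping is threshold-based and therefore inherits the
  threshold's sensitivity to depth differences between samples; comparing
  loss windows across samples of very different depth warrants the
  threshold-robustness scan.
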