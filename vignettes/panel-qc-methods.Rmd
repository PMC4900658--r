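---
title: "Methods: SNP panel selection and QC genotyping for inbred germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP panel selection and QC genotyping for inbred germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelqc)
```

## The problem

Breeding programs and genebanks regenerate, multiply and distribute inbred
lines continuously, and every cycle is a chance for seed-lot contamination,
residual segregation, or plain mislabeling. `panelqc` implements a
genotype-based quality-control workflow for such collections: score the
informativeness of a large SNP marker set, select a small panel that still
distinguishes every line in the collection, verify the identity of incoming
samples against reference profiles, and decide how many individual plants
per entry must be genotyped to detect contamination at a required
probability.

Two nested panels serve different purposes. A **broad QC** panel (tens of
markers) identifies each entry uniquely and measures its residual
heterogeneity; a **rapid QC** panel (around ten markers, nested inside the
broad panel) cheaply flags mislabeled seed packets or plots on single-plex
platforms.

## Marker statistics

Calls are stored as minor-allele counts (0 = homozygous major, 1 =
heterozygous, 2 = homozygous minor, `NA` = missing); every statistic is
invariant to the major/minor orientation, which is assigned by observed
frequency at load time (ties broken alphabetically). For a biallelic marker
with allele frequencies $p$ and $q = 1 - p$ counted over non-missing calls
(homozygote = two copies, heterozygote = one of each):

* **MAF** $= \min(p, q) \le 0.5$;
* **heterogeneity** = fraction of heterozygous calls among *non-missing*
  calls — in a (possibly pooled-tissue) inbred profile this measures
  residual non-fixation rather than outcrossing;
* **missing rate** = missing calls over *all* entries (a deliberately
  different denominator, so the two rates are not complementary);
* **PIC** $= 1 - (p^2 + q^2) - 2p^2q^2$, the biallelic closed form of the
  Botstein index, maximal at $0.375$ when $p = q = 0.5$;
* **coverage** = mean sequencing reads per allele, carried as metadata;
* **mutation class**: A/G-or-T/C (transitions), A/C-or-G/T, A/T-or-C/G.

Linkage disequilibrium $r^2 = D^2 / (p_A q_A p_B q_B)$ is computed from
entries homozygous at both loci, each treated as one two-locus haplotype.
Heterozygous calls are dropped rather than phased: the panels targeted here
are $\ge 95\%$ homozygous, so a composite estimator would buy complexity
for almost no haplotype information. This is a documented assumption, not a
claim about the best general-purpose estimator.

## Identity metrics

The per-locus **allele-sharing distance** between two diploid genotypes is
$2 - (\text{shared alleles})$, i.e. 0 for identical genotypes, 1 when one
allele matches, 2 for opposite homozygotes. Pairwise distance averages this
over the markers at which *both* entries have calls, so it ranges over
$[0, 2]$; a pair with no jointly non-missing marker is reported as
undefined rather than silently 0 or 2, since either default would fabricate
identity or difference. **Similarity** (shared alleles over compared
alleles) satisfies $s = 1 - d/2$ exactly when computed on the same marker
set, and is the statistic used in blind tests.

Entries are clustered by complete linkage (`stats::hclust`) and embedded by
classical metric scaling (`stats::cmdscale`). The Newick serialization uses
branch lengths of parent merge height minus child merge height and orders
children by their lexicographically smallest leaf label, so the emitted
string is invariant to input order — useful for byte-stable pipelines.

## Panel selection

The selection pipeline mirrors how a QC panel is actually built:

1. **Filter** by thresholds. The default `filter_thresholds()` is the
   stringent end-stage rule set — coverage in $[2, 15]$ reads per allele,
   missing rate $\le 0.20$, heterogeneity $\le 0.06$, chromosome placement
   required. A coarse first screen would use missing $\le 0.40$,
   MAF $\ge 0.05$, heterogeneity $\le 0.10$. Every removed marker is
   reported with the first rule that removed it.
2. **Group** markers by PCA + K-means (`prcomp`, `kmeans`, markers as
   observations, entries as variables; missing calls mean-imputed per
   marker; centered, not scaled). Defaults: 3 components, $k = 5$ groups,
   $\ge 10$ restarts under a fixed seed. The embedding dimension is not
   sharply determined by the method; 3 components retain the structure
   K-means needs while keeping the grouping stable across seeds.
3. **Allocate** a selection across groups: `RANDOM` (no stratification),
   `PG` (proportional to group size), `NG` (equal), or `PGD` (proportional
   to each group's mean centroid-to-other-centroids distance — the
   interpretation of "average group distance" used here, isolated in one
   function so an alternative can be substituted). Counts use
   largest-remainder rounding, always sum to the request, and give every
   group at least one marker when the total allows.
4. **Spread uniformly** across the genome: per-chromosome quotas
   proportional to chromosome length (largest remainder), equal-width bins
   per chromosome, the marker nearest each bin midpoint (ties to the lower
   position), empty bins forfeiting to the nearest occupied bin.
5. **Evaluate** a candidate panel by the proportion of entry pairs it
   fails to distinguish. A pair is *distinguished* only by a jointly
   non-missing, mismatching marker; pairs with zero overlap count as
   undistinguished — the conservative choice for QC, where "no evidence of
   difference" must not pass as "verified different".
6. **Optimize** by replicated random resampling (default 2,000 reps):
   random subsets of the target size, each forced to contain the
   mandatory (e.g. trait-specific) markers, ranked by (i) full
   discrimination, (ii) largest minimum pairwise mismatch count,
   (iii) largest mean, (iv) draw order. The max–min key targets the
   hardest pair, which is what breaks first when a marker assay fails.
   `select_rapid_panel()` reruns the same search with the broad panel as
   the candidate pool, so rapid panels are nested by construction.

Trait-specific markers for introgressed conversions (e.g. quality-protein
or herbicide-resistance conversions) are found by a case-control allele
test: per marker a 2×2 allele-count table (trait class × allele) and the
Pearson chi-square without continuity correction on 1 df — the
conventional form for allele-count tables; the correction is omitted
because counts here are allele counts (2N), not individuals.

## Blind test, purity, and sampling

`assign_identity()` ranks reference entries by similarity to a query
profile; the verdict is `MISLABELED` when an expected label is not the top
match and `AMBIGUOUS` when the top two similarities tie within $10^{-9}$
(an absolute window chosen for float-stable determinism, far below any
biologically meaningful difference). No similarity floor is imposed for
declaring a match; real deployments should inspect the reported values,
since a mislabeled sample typically shows a large gap (e.g. 0.95 to the
true line versus 0.60 to its label).

`count_off_types()` scores each individual of an entry against the entry's
reference profile. An individual is an off-type when its mismatching
jointly non-missing panel calls exceed `mismatch_tolerance` (default 1,
absorbing a single genotyping error on a ten-marker rapid panel; the
per-individual tolerance is a package choice, stated openly, as the
upstream procedure defines only the per-entry rule). The entry passes QC
when at most `threshold` (default 2) off-types are found, otherwise it is
flagged for retesting.

Sampling design uses the binomial detection model
$P = 1 - (1 - p)^n$ for the probability that a sample of $n$ individuals
contains at least one off-type at population off-type proportion $p$
(marker detection assumed perfect), its inversion
$n = \lceil \log(1 - P_\text{target}) / \log(1 - p) \rceil$, and the
Bayesian upper limit on $p$ after observing $k$ off-types in $n$: the
0.95 quantile of the Beta$(k + a,\; n - k + b)$ posterior. The default
prior is Jeffreys $(a, b) = (0.5, 0.5)$, which yields the familiar
$\approx 2\%$ upper bound for one off-type in 192 individuals; the uniform
prior is one argument away. Published values for *two* off-types (2.5% at
$n = 192$, 5% at $n = 96$) are **not** reproduced by the Jeffreys
equal-tail quantile (which gives 2.9% and 5.7%); the prior/interval
convention behind those figures is ambiguous, so both priors are exposed
and no silent adjustment is made.

```{r sampling}
detection_table(c(48, 96, 192, 384), c(0.001, 0.01, 0.02, 0.05, 0.1))
bayes_upper_limit(k = 1, n = 192)          # Jeffreys
bayes_upper_limit(k = 2, n = 192)          # the ambiguous published case
```

## The synthetic panel generator

`simulate_reference_panel()` emulates the marker profile of a filtered
genotyping-by-sequencing maize inbred panel, and its defaults are fixed
study conditions, not tuning knobs:

* residual heterogeneity 0.05 and missing rate 0.18 per call — the levels
  observed in such data after a first coarse filter;
* global minor-allele frequencies from Beta(1.3, 5.5) clipped to
  $[0.02, 0.5]$, giving a right-skewed distribution with mean MAF near
  0.16–0.19;
* substitution classes at probabilities (0.607, 0.195, 0.198) — the
  transition-rich composition typical of SNP discovery in maize;
* population structure: group allele frequencies uniform within
  `divergence` (default 0.2) of the global frequency, truncated to
  $[0, 1]$ — a truncated-spread model chosen over an explicit F-model
  because the tests need recoverable structure, not demographic fidelity;
* ten chromosomes with approximate maize physical lengths; positions
  uniform;
* per-marker depth Gamma with mean 8 and dispersion 0.5, spreading enough
  mass outside $[2, 15]$ that the coverage filter genuinely bites.

What the generator does **not** emulate: linkage disequilibrium decay and
recombination (markers are independent), allele-frequency correlation
between groups beyond the shared global frequency, genotyping error that
correlates with depth, and multi-allelic sites. Tests passing on this
generator therefore demonstrate correctness of the algorithms under
idealized independence, and structure recovery under planted structure —
not calibrated performance on any real collection.

`simulate_regenerations()` models seed-increase drift (each non-missing
call changes with the drift probability; homozygotes flip, heterozygotes
fix randomly) and optional phenotypic purification (each heterozygous call
fixes with probability 0.5 per cycle, halving expected heterogeneity — the
pattern seen when a 12% heterogeneity source drops to ~2–3% over
regenerations). `inject_off_types()` plants contamination and label swaps
and records every event, so detection can be scored against exact truth.

## Numerical and degenerate-input choices

* Largest-remainder apportionment everywhere a total is split
  proportionally; deficits from too-small groups reallocate to groups with
  spare capacity and are reported.
* `k = n` grouping degenerates to singleton groups directly rather than
  calling K-means.
* Markers with all calls missing carry `NA` statistics, are flagged, and
  never survive filtering.
* Distance pairs with zero marker overlap are `NA`; tree building and
  ordination refuse such matrices with an instruction to widen the marker
  set.
* The acceptance-style simulation sizes used in the test suite (panels of
  tens of lines × hundreds of markers, resampling in the hundreds to low
  thousands of reps, 1,000-replicate sampling checks) were chosen as the
  smallest sizes at which the Monte-Carlo error bounds in the tests are
  meaningful; all stochastic assertions use 3-standard-error windows under
  fixed seeds.

## Limitations

* The per-individual `mismatch_tolerance` and the declare-a-match policy
  are configuration, not statistics; they should be set from the platform
  error rate.
* LD, PCoA and clustering are descriptive aids here; no significance
  machinery is attached.
* The resampling search is stochastic; it provably contains the optimum
  only on instances small enough to enumerate (and is tested against
  exhaustive enumeration there). For production panels, rep counts in the
  thousands are cheap and recommended.
* Panel discrimination is evaluated on the reference collection supplied;
  adding new lines to a collection can invalidate a previously optimal
  panel.
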