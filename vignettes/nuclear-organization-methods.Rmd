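---
title: "Models and methods behind nucorg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucorg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucorg)
```

nucorg packages the statistics of three assays used to study nuclear
organization in budding yeast: the three-zone perinuclear position assay,
locus-level binding calls from tiling ChIP arrays, and replicate
differential-expression comparisons. This vignette explains each model,
its assumptions, the tunable parameters and why they default as they do,
what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## The three-zone position assay

A lacO/GFP-tagged locus is imaged in living cells and its distance to the
nuclear envelope is recorded in the focal plane in which the spot is
brightest, together with the nuclear diameter in that plane. The score is
the dimensionless ratio

$$x = \frac{\text{distance to envelope}}{\text{diameter}} \in [0, 0.5],$$

with 0 at the envelope and 0.5 at the centre. Because measurement happens
in a single focal plane, the natural null geometry is two-dimensional: a
spot positioned at random in the nucleus is uniform over the *disc*
cross-section, not over a sphere. The disc of unit diameter is divided
into three concentric regions of equal area; solving
$\pi(R^2 - r^2) = \pi R^2 / 3$ with $R = 1/2$ gives the boundaries on the
ratio scale

$$b_1 = \tfrac{1}{2}\bigl(1 - \sqrt{2/3}\bigr) \approx 0.0918, \qquad
  b_2 = \tfrac{1}{2}\bigl(1 - \sqrt{1/3}\bigr) \approx 0.2113,$$

so a random spot lands in each zone with probability 1/3 — the familiar
"33% line" on zone histograms. `zone_boundaries()` returns these values;
an analytic test requires the three areas to agree within $10^{-9}$.

Choices worth making explicit:

* **Bins are half-open toward the centre**: zone 1 is $[0, b_1)$, zone 2
  $[b_1, b_2)$, zone 3 $[b_2, 0.5]$. A ratio falling exactly on a boundary
  goes to the inner zone, deterministically. With continuous measurements
  this affects essentially nothing, but it makes binning reproducible to
  the bit.
* **Spots outside the nucleus** (distance > radius) are measurement
  errors. They are *dropped with a warning naming the cells*, never
  clamped to 0.5 — silently repairing impossible records would hide
  scoring problems.
* **The χ² test runs on raw counts**, not on percentages: expected counts
  are $(n/3, n/3, n/3)$ on 2 df. For 2 df the upper-tail p-value has the
  closed form $p = e^{-\chi^2/2}$, which the tests verify to $10^{-9}$ —
  a useful cross-check that the statistic and its reference distribution
  are wired correctly.
* **Between-condition comparisons** (`zone_test_between()`) use the plain
  Pearson χ² on the 2×3 table without continuity correction. When an
  expected cell drops below 5 the function warns but does not switch
  method: published zone comparisons report plain χ² p-values, and a
  silent method switch would make values non-comparable.

Colocalization with clustered nuclear pores is scored per cell as
complete overlap / no overlap, so the natural model is binomial. The
expected random-overlap fraction $p_0 = 0.09$ is an empirical constant
for pore-cluster geometry taken from prior work; it is an input, not
something the package derives. `coloc_test()` is the exact binomial test,
two-sided by the point-probability method (outcomes no more probable than
the observed one), as implemented in `stats::binom.test`. An exact test
was chosen because scored cell counts vary widely (tens to hundreds) and
the normal approximation is unnecessary.

## Locus binding calls from tiling arrays

Each array locus — 300 bp, or 100 bp on denser regions — carries 11
probe-level log2 IP/input ratios. The per-locus call asks whether those
ratios are systematically above zero. nucorg uses an **exact one-sided
Wilcoxon signed-rank test**: zeros are dropped, magnitudes are ranked
with midranks for ties, and the null distribution of the positive-rank
sum is obtained by full enumeration of all $2^n$ sign assignments of the
observed rank multiset (up to $n = 14$; beyond that a normal
approximation with tie correction and continuity correction takes over,
though with 11 probes the exact path always runs). Null distributions are
cached by rank multiset, so a full-array run enumerates essentially once.
A rank-based exact test is robust to the heavy-tailed probe noise of
hybridization arrays and needs no variance estimate from 11 values.

A locus is *positive* when the upper-tail p < 0.025 and *negative* when
the lower-tail p < 0.025 (strict inequalities, mirroring the published
threshold). One consequence of exactness worth knowing: with 11 tie-free
probes the p-values are multiples of $1/2048$, and the largest achievable
rejection level below 0.025 is slightly smaller than 0.025 itself, so the
realized false-positive rate under a pure-noise landscape sits a little
below the nominal threshold. The calibration test accounts for this by
checking the rate against its tolerance band rather than against 2.5%
exactly.

Downstream statistics and their conventions:

* **Clusters** are maximal runs of at least 2 *contiguous* positive loci —
  contiguous meaning each locus starts where the previous ends on the same
  chromosome; runs never jump grid gaps or chromosome boundaries.
* **Peaks**: clusters ranked by their maximum member log2 ratio, filtered
  at signal log ratio > 0.8, top 10 kept. The cluster score had to be
  chosen (the convention in the field's figures names "highest clusters"
  without a formula); the member maximum matches the "peak" language and
  is insensitive to cluster length.
* **Coincidence tables** count, per chromosome and pooled, the detectable
  loci, the A-positive loci (as % of detectable) and the A-positive loci
  that are also B-positive (as % of A-positive). Percentages round
  half-up to integers, reproducing the printed-table convention.
  When the two tracks sit on different grids, 100-bp loci are mapped into
  their containing 300-bp bin (a bin is positive if any member is); the
  mapping rule is containment because the coarser grid defines the
  reporting resolution.
* **Coincidence attenuation.** The measured coincidence percentage is a
  property of the *called* A-positive set, which at any finite threshold
  contains a small admixture of false positives. False-positive loci carry
  only the background B rate, so the measured percentage sits slightly
  below the true conditional overlap among genuinely bound loci. The
  planted-recovery tests measure exactly this end-to-end quantity, and
  their tolerance (3 percentage points) absorbs the attenuation; users
  comparing measured coincidence between conditions should remember both
  numbers are attenuated the same way.
* **Subtelomere reports** count positive loci whose interval intersects
  the terminal 10 kb of each chromosome arm (configurable). The package
  takes chromosome sizes as given; masking of repetitive subtelomeric
  sequence is upstream of it.
* **Genomic context** labels each locus against GFF3 gene annotations
  with precedence divergent_promoter → single_promoter → ORF_internal →
  intergenic_other. A divergent promoter is the intergenic interval
  between the 5′ starts of a head-to-head gene pair; a single promoter is
  the 400-bp upstream flank of one gene (400 bp reflecting how close
  observed binding sites sit to start codons). Strandless gene records
  are rejected rather than guessed.

Coordinates are 0-based half-open internally and in BED output; GFF3 is
converted from its 1-based inclusive convention on read.

## Differential expression

Expression is compared per gene between a mutant and wild type on
replicate log2 intensities (at least three replicates each). The test is
the **two-sample Student t-test with pooled variance**. The choice
deserves a note: with only three replicates per group, the
Welch–Satterthwaite approximation is markedly conservative — its true
size at the nominal 5% level falls well short of 5% — while the pooled
test is exact under the equal-variance normal model the simulators (and,
to a good approximation, replicate arrays of a single design) satisfy.
Since the analysis is calibrated against a nominal 5% type-I rate, the
pooled test is the defensible default at this design size.

Raw p-values are thresholded at 0.05 with **no multiple-testing
correction** — deliberately, for fidelity to the published analysis
convention this package reproduces; users wanting FDR control can apply
`p.adjust` to the returned p column. A gene is *changed* at a 1.25-fold
threshold applied on the log2 scale with an inclusive boundary
($|\Delta| \ge \log_2 1.25 \approx 0.322$). The reported log2 ratio is
the difference of replicate means of log2 values (equivalently the log of
the geometric-mean ratio); whether published tables used this or the log
of the ratio of arithmetic means is ambiguous, and the mean-difference
form was chosen as the standard quantity for log-scale data. Degenerate
zero-variance genes are handled explicitly: equal means give p = 1,
unequal means with no within-group scatter give p = 0.

Set overlaps report integer-rounded (half-up) percentages in the
direction "share of A also in B", the form used beside two-set Venn
diagrams. Top tables rank by the first mutant's log2 ratio and print the
second mutant's ratio in parentheses when that gene's own change is not
significant — the published table convention.

## What the simulators emulate — and what they do not

Every analysis stage has a seeded generator so the full pipeline runs
with no external data, and so calibration and recovery can be tested
against known ground truth.

* `simulate_spots()` draws a zone per the configured occupancy
  probabilities and then an **area-uniform position within that zone's
  annulus** ($r = R\sqrt{u}$ sampling); with probabilities (1/3, 1/3,
  1/3) this is exactly the global uniform null. Stage labels (G1/S) and
  pore colocalization are independent Bernoulli draws. The nuclear
  diameter defaults to 2.0 µm — only the ratio matters downstream. Not
  modeled: spatial pore-cluster geometry (the 9% constant is an input),
  chromatin-tether dynamics, any coupling between stage and position, or
  segmentation error beyond what the outside-nucleus guard catches.
* `simulate_tiling()` tiles chromosomes into non-overlapping loci, plants
  factor A Bernoulli-independently per locus and factor B conditionally
  on A (so the conditional coincidence is a direct dial), and draws probe
  values i.i.d. Normal around the planted effect. Bound loci get a
  per-locus strength multiplier (uniform 0.75–1.25) shared between
  factors where co-bound, so paired signal strengths co-vary as on real
  arrays. Defaults — 24% bound, conditional overlap 0.76, probe effect
  1.5 log2 units, probe noise 0.5 — mirror the scale of the
  four-chromosome array study the pipeline is anchored on (8441 loci at
  300 bp). Not modeled: spatially correlated probe noise, sequence or
  GC effects, repetitive-region dropout, fragment-size smoothing across
  neighbouring loci (planted sites are single loci, so simulated
  clusters arise only by chance adjacency).
* `simulate_expression()` gives each gene a Normal baseline (mean 8,
  SD 1.5 log2 units) and adds planted per-mutant log2 effects;
  replicates scatter i.i.d. Normal with SD 0.15, a typical
  replicate-array log2 dispersion for a single lab and design. Planted
  effect magnitudes in the demo span 0.4–2.4 log2 units — from just
  above the 1.25-fold reporting threshold to the strongest changes seen
  in top tables. Not modeled: intensity-dependent variance, correlated
  gene modules, or normalization artifacts; the matrix is taken as
  already normalized, as the analysis stage assumes.

Passing recovery tests therefore show that the *scoring machinery* is
correct and calibrated under the stated stochastic model — they do not
certify performance on real arrays with correlated noise, nor do they
reproduce any published biological value, which would require the
deposited datasets themselves.

## Numerical choices and test scales

All generators restore the caller's RNG state and are bit-reproducible
for a given config and seed. Equal-area geometry is checked to $10^{-9}$,
the df-2 closed form to $10^{-9}$, and exact signed-rank p-values to
$10^{-12}$ against a brute-force enumeration oracle. The calibration and
recovery tests run at the sizes the package treats as its reference
conditions: 100,000 spots for the uniform null, 10,000 panels of 200
cells for zone-test calibration, 10,000 genes at 3+3 replicates for
t-test calibration, 10,000 loci for the binding-call null rate, the
8441-locus four-chromosome grid for coincidence recovery, and planted DE
sets of ≈ 400–500 genes with 17% overlap for overlap recovery. These
sizes keep each suite comfortably within a few minutes on one CPU while
leaving Monte Carlo error well inside the asserted tolerances.

## Known limitations

* The zone null is strictly two-dimensional; studies scoring positions
  from 3-D stacks need a spherical-shell null that this package does not
  provide.
* The binding caller assumes probe values within a locus are exchangeable
  under the null; strong within-locus trends (e.g. a binding site at a
  locus edge shared with its neighbour) are not modeled and blur into
  adjacent-locus clusters.
* Coincidence percentages are attenuated by threshold false positives as
  described above; the package reports the conventional measured
  quantity, not a de-attenuated estimate.
* With three replicates the t-test has limited power near the 1.25-fold
  boundary; planted-set recovery rates in the tests quantify this under
  the simulator's noise model only.
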