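---
title: "Methods: survival-zone triangulation, 5C processing, and ensemble contact analysis"
author: "chromfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival-zone triangulation, 5C processing, and ensemble contact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfold)
```

This vignette documents the models behind each analysis stage, the
assumptions they make, the tunable parameters and their defaults, the
numerical choices taken where the mathematics leaves freedom, and what the
synthetic-data generator does and does not emulate.

## The three-loci survival-zone model

### Model and assumptions

Three loci tagged with distinct fluorophores (R, G, B) are imaged in 3D in
each of n nuclei, yielding one triplet of pairwise distances per nucleus.
The model assumes that, across the population, each locus explores a disk
("survival zone") of radius `Rr`, `Rg` or `Rb` lying in the common plane of
the three loci, with fixed centers, and that each locus samples its disk
uniformly and independently of the others.  Under these assumptions the
population extremes of each pairwise distance are attained when both loci
sit at the ends of the inter-center segment, giving

    d_ab_max − d_ab_min = 2 (Ra + Rb)

for every pair, and the per-pair midrange estimates the center-center
distance.  Three linear relations in three unknowns yield each radius as a
signed quarter-sum of the six extremes (`solve_radii()`), and the law of
cosines applied to the midranges yields the angle at G between the R–G and
G–B axes (`solve_geometry()`).

The key statistical caveat is that sample minima/maxima converge slowly and
are *biased inward*: recovered radii systematically undershoot the truth at
finite n and approach it from below as n grows.  The package therefore
exposes quantile-based ranges (`summarize_ranges(lower_q, upper_q)`) as a
robust alternative for noisy data, while the default `(0, 1)` uses the
exact extremes that the closed forms are derived for.  With the reference
simulation scenario (radii 50/100/150 nm, centers 400/500/600 nm apart)
the maximum relative radius error is roughly 30 % at n = 100, 13 % at
n = 1,000 and under 10 % at n = 10,000, with the angle recovered to well
under a degree of arc at the largest n; these are the problem sizes
exercised by the test suite.

Distances measured in intact nuclei carry localization error whose
magnitude depends on the microscope and registration; since no correction
is universally right, the generator exposes `localization_noise_sd` as a
parameter (default 0) rather than asserting a value, and the solver treats
triangle-inequality violations in measured triplets as flagged-but-kept
data (a `strict` mode drops them).

### Degenerate and infeasible solutions

Nothing forces the quarter-sum formulas to return non-negative radii when
the model is violated or n is small.  Negative raw radii are clamped to 0
and flagged, with the raw values retained in `raw_radii` for diagnostics.
Likewise a midrange triangle violating the triangle inequality produces a
cosine outside `[−1, 1]`, which is clamped to the boundary and flagged.
When the G–B or R–G midrange is zero the angle is undefined and reported as
`NA`.

### Position reconstruction

Per-nucleus positions are found by exhaustive search over polar
discretizations of the three disks.  The grid for a disk of radius r is the
center plus N radial rings at radii `r·i/N` (i = 1..N) times M angles
`2πj/M` (j = 1..M) — the only reading of the ring spacing that keeps every
grid point inside the disk.  The objective is the root-mean-square mismatch
between the three grid-point distances and the observed triplet; in-disk
constraints hold by construction.  Two deliberate choices:

* **Gauge fixing.** The model determines geometry only up to rigid motion,
  so a canonical frame is fixed: G at the origin, R on the positive x-axis
  at distance C, B at angle θ from the G→R axis.
* **Tie-breaking.** Exact cost ties are resolved by the lowest grid-point
  index of R, then G, then B (center first, then increasing radial, then
  angular index), making the search deterministic and equal to a
  brute-force enumeration in the same order — which the test suite runs as
  an independent oracle on N = 2, M = 8 grids.

A residual above `infeasible_tol` (default 1e-6 nm) flags a triplet that no
in-zone configuration can reproduce.

## Pairwise FISH distance statistics

Distances are tabulated into classes with *upper-inclusive* boundaries
(≤100 nm, 100–200 nm as "≤200", >200 nm), matching the convention that
distances up to 200 nm represent contacts detectable by 5C.  Condition
comparisons use Fisher's exact test.  Because the source convention does
not fix the table construction, the default collapses classes at 200 nm
into a 2×2 table (close/far × condition), and a `method = "full"` variant
tests the complete 2×k table.  Two-sided p-values follow the standard
convention of summing the probabilities of all tables, with the observed
margins, at most as probable as the observed one; the test suite verifies
this against a from-scratch hypergeometric enumeration over every 2×2
table with both condition sizes up to 30.  Degenerate margins (all
observations in one class in both conditions) return p = 1 with a flag.

## 5C matrix processing

The processing chain runs in the fixed order **filter → scale → bin →
balance** (`process_fivec()` enforces it and refuses non-raw input).
Choices the convention leaves open, and the defaults taken:

* **Primer filter** (`filter_primers`, thresholds 6 cis / 12 trans):
  per-primer cis and trans interaction totals are log1p-transformed before
  z-scoring, because raw totals are heavy-tailed and "very low or
  excessive" implies a two-sided criterion on a roughly symmetric scale.
  Single-region 5C designs have no trans primer pairs, so the trans filter
  is skipped with a message when only one chromosome is present.  Note an
  arithmetic bound worth knowing: a single outlier among n primers can
  reach |z| at most (n−1)/√n, so a lone extreme primer is only maskable at
  z = 6 when the panel has ≳39 primers.
* **Binning** (`bin_matrix`): fragments are assigned to bins by *midpoint*;
  sliding bins of width 15 kb advanced in 8 steps per width give 1.875-kb
  steps and 13.125-kb overlaps.  Aggregation is by sum (mean available),
  which makes disjoint tiling (`steps_per_bin = 1`) conserve total counts
  exactly.
* **Balancing** (`ice_balance`): the Sinkhorn–Knopp iteration divides every
  row and column by (its sum / mean of valid sums) until the maximum
  relative deviation of row sums is below `tol = 1e-5`, capped at 200
  iterations (non-convergence is flagged, never silently accepted).
  Rows/columns are corrected by identical factors, so symmetry is exact,
  and the accumulated correction vector is returned as the `"ice_bias"`
  attribute.  All-zero rows are masked first.  When assessing bias removal
  on synthetic matrices, the balanced counts must be compared against the
  *balanced* bias-free expectation: ICE equalizes row sums, which the raw
  power-law expectation does not have at matrix edges, so the raw ratio
  conflates bias removal with edge effects.  Against the balanced
  reference, per-row mean ratios on a 40-fragment matrix at ~10⁴ counts per
  row are flat to a CV of ~1.5 %.
* **Expected-by-distance** (`expected_by_distance`): LOWESS (span 0.3) of
  log mean count on log separation over per-distance means of valid pairs.
  On log-log axes a power law is exactly linear, so a noise-free decay
  matrix is recovered to within 5 % at interior distances; at least 10
  distinct separations are required.  Observed/expected is division by the
  interpolated curve.
* **Window quantification** (`window_interaction`): all valid cells whose
  bins intersect the two anchor windows (summit ± half-width, default
  10 kb) are returned individually — the distribution feeds violin plots —
  along with their mean.

## Model-ensemble contact analysis

A *contact arch* links two particles whose distance is below a threshold in
at least a fraction of the ensemble's models (defaults 200 nm and 0.5).
The source convention states the threshold inconsistently in different
places (50 nm in the results narrative, 200 nm in the methods); it is
therefore a parameter, with the methods value as default.  Chain-adjacent
pairs (|i−j| ≤ 1) are excluded from arch calling — consecutive 50-nm beads
are trivially always in contact.  Differential arches compare two
conditions by the *absolute* change in model fraction, labelled increased /
decreased at |Δ| ≥ 0.20; a relative-change reading was considered and
rejected because a 20 % relative change of a near-zero fraction is
meaningless.  The Δ comparison uses a 1e-9 float guard so that a change of
exactly 0.20 formed from small-integer fractions (e.g. 14/20 − 10/20)
counts as reaching the threshold.  Fosmids spanning several particles are
located at the unweighted center of mass of their particles.

## Pausing index

The promoter-proximal window is read as `[TSS − 30, TSS + 300)` and the
body as `[TSS + 300, TES)` — the standard pausing-index convention and the
only reading that makes the two windows complementary at TSS + 300.  Genes
of 300 bp or less are rejected.  Minus-strand genes mirror both windows in
genomic coordinates.  The index is a ratio of mean densities, hence
invariant under any global scaling of the track, so raw and normalized
coverage give identical indices.

## The synthetic-data generator

The generator produces inputs with exactly the structure the analyses
assume — which is what makes it useful for validation and also bounds what
passing tests demonstrate:

* **Triplets**: loci sampled uniformly in coplanar disks (a 3D-ball mode
  exists behind `sampling = "sphere"` for robustness studies), optional
  isotropic Gaussian localization noise.  Real nuclei add chromatic shift,
  segmentation error and possible non-uniform, correlated locus motion,
  none of which are modeled.
* **Contact matrices**: expected counts `depth · |i−j|^(−α)` with
  TAD-block and loop enrichments, log-normal per-primer biases (geometric
  mean 1) and Poisson sampling (negative-binomial behind an
  `overdispersion` flag); the diagonal is zero, since 5C self-ligation is
  uninformative.  Real 5C adds primer-specific efficiencies that are not
  purely multiplicative, and mapping artifacts.
* **Ensembles**: freely jointed chains with fixed 50-nm steps and 5 kb per
  bead; folded pairs are enforced by rigidly repositioning one bead at the
  target distance in the stated fraction of models (entries naming the same
  pair claim disjoint consecutive model subsets, so complementary fractions
  pin a pair's contact fraction exactly).  This tests arch *statistics*,
  not polymer physics: excluded volume, chain stiffness and restraint
  optimization are deliberately absent.
* **Coverage**: piecewise-constant proximal/body densities — sufficient
  for index arithmetic, with none of the read-level noise of ChIP-seq.

All generators are deterministic under a fixed seed, and their defaults
(50-nm beads, 5-kb particles, 15-kb/8-step binning, 200-nm / 0.5 / 0.20
arch parameters, ±10-kb windows, −30/+300 pausing windows) are the
conventional values of the assays they emulate.

## Known limitations

* The closed-form inversion requires pairwise-disjoint zones along each
  inter-center segment; overlapping zones make extremes uninformative about
  the individual radii.  `enforce_separation` guards the generator, and
  clamping flags the solver-side symptom.
* Min/max-based estimation is inherently noise-sensitive; a single
  mislocalized nucleus corrupts a range.  The quantile option trades bias
  for robustness but breaks the exact extremal identities.
* Published radii and angles from the motivating microscopy experiments
  derive from unreleased measurements and cannot be recomputed here; the
  simulation scenarios use parameter scales of the same order instead.
* The exhaustive position search costs O(N²M²·NM) per nucleus and is meant
  for the modest grids (N ≤ 20, M ≤ 36) at which it is used.
* Restraint-based model *building* (the step that produces ensembles from
  5C matrices) is out of scope; ensembles are analyzed, not fitted, so no
  model-to-matrix correlation is computed.
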