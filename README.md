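# chromfold

Tools for analyzing the 3D folding of regulatory chromatin domains — the
kind of question asked of an estrogen-responsive gene domain whose upstream
enhancer cluster folds onto the gene body upon hormone induction.  The
package combines four views of the same biology:

* **Three-loci survival-zone triangulation** — inverting population
  distributions of pairwise 3D DNA FISH distances among three loci into the
  radii of the regions each locus explores, the angle between locus axes,
  and constrained per-nucleus positions.
* **Pairwise FISH distance statistics** — distance-class tables
  (≤100 nm, 100–200 nm, >200 nm), exact-test condition comparisons, ECDFs.
* **5C contact-matrix processing** — primer z-score filtering, read
  scaling, overlapping binning (15-kb bins, 8 steps, 13.125-kb overlaps),
  Sinkhorn–Knopp/ICE balancing, LOWESS expected-by-distance, and
  anchored-window interaction quantification around enhancer summits.
* **Model-ensemble contact analysis** — contact arches and differential
  arches over ensembles of restraint-based 3D bead-chain models, and
  fosmid-level distance distributions.

It also computes the RNA Pol II **pausing index** from coverage tracks, and
ships a **synthetic-data generator** that emulates every input (coplanar
disk-confined loci, power-law decay matrices with TADs/loops/biases,
two-condition bead-chain ensembles, paused-polymerase coverage), so the
entire pipeline is testable without microscopy or sequencing data.

## The survival-zone model

Three loci R, G, B are assumed to move, across a population of n nuclei,
within coplanar disks ("survival zones") of radii `Rr`, `Rg`, `Rb` centered
at fixed points.  For each pair, the population extremes of the measured 3D
distance satisfy

```
d_rg_max = 2 (Rr + Rg) + d_rg_min        (and cyclically)
```

so the three radii follow in closed form from the six observed extremes,
e.g.

```
Rg = (d_rg_max + d_gb_max − d_rb_max − d_rg_min − d_gb_min + d_rb_min) / 4 .
```

The midranges `A = (d_rb_max + d_rb_min)/2`, `B`, `C` estimate the
center-center distances, and the law of cosines gives the angle at G
between the R–G and G–B axes: `cos θ = (C² + B² − A²) / (2CB)`.  Per-nucleus
locus positions are then reconstructed by exhaustive search over polar
discretizations of the three disks for the configuration best matching each
observed distance triplet.

## Worked example

```r
library(chromfold)

# ground truth: radii 50/100/150 nm, centers 400/500 nm apart, 82.82° at G
sc  <- tri_loci_scenario(center_RG_distance = 400, center_GB_distance = 500,
                         center_angle_at_G = 82.82, radius_R = 50,
                         radius_G = 100, radius_B = 150,
                         n_nuclei = 10000, seed = 42)
sol <- solve_survival_zones(generate_triplets(sc))
print(sol)
#> Survival-zone solution
#>   radii (nm):     R = 48.81  G = 92.77  B = 144.41
#>   midranges (nm): A(R-B) = 597.27  B(G-B) = 506.22  C(R-G) = 403.06
#>   angle at G:     81.26 degrees
```

The recovered radii sit slightly below truth (sample min/max estimators are
biased inward) and the angle is within 2° of the 82.82° used to generate
the data.  Reconstruction of one nucleus:

```r
tr    <- generate_triplets(sc)
grids <- build_zone_grids(sol, n_radial = 10, n_angular = 24)
reconstruct_positions(as.numeric(tr[1, c("d_RG", "d_GB", "d_RB")]), grids)
#> first nucleus: R=(361, -24) G=(59, 59) B=(14, 536), residual 0.9 nm
```

A synthetic 5C matrix with a planted enhancer–promoter loop, processed with
the standard chain and quantified at the anchors:

```r
raw  <- generate_contact_matrix(synthetic_matrix_spec(
  60, decay_exponent = 1, depth = 800, bias_log_sd = 0.3,
  loops = list(c(10, 50, 5)), seed = 7))
proc <- process_fivec(raw, config = binning_config(16000, 8))
print(proc)
#> ContactMatrix: 120 x 120 [balanced], 0 masked, total 2.55e+07
window_interaction(proc, anchor_window("ERBS", 38000, 10000),
                         anchor_window("TSS", 198000, 10000))$mean
#> 400.31   # ~5x the background window mean, as planted
```

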