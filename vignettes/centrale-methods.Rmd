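---
title: "Testing centrale fusion versus loss in the archosauromorph ankle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing centrale fusion versus loss in the archosauromorph ankle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrale)
```

## The question and the test

Early archosauromorphs carry a separate tarsal ossification, the centrale,
medial to the astragalus. In Erythrosuchidae + Eucrocopoda the centrale is
gone as an independent element. Two homology hypotheses explain this: the
centrale **fused** into the astragalus (the derived astragalus is the old
astragalus + centrale), or the centrale was **lost** and the astragalus
expanded medially into the vacated space.

`centrale` implements a quantitative test of these alternatives based on
two landmark configurations of the same bones:

* *astragalus + centrale* — the medial outline follows the combined unit in
  taxa that retain a separate centrale, and the astragalus alone where the
  centrale is absent. Under fusion this configuration is homologous across
  the focal branch and should change little there.
* *astragalus only* — the outline excludes the centrale everywhere. Under
  loss this configuration tracks a single bone throughout and should change
  smoothly.

Each configuration is Procrustes-aligned, re-superimposed onto a reference
taxon by the minimum-distance criterion, and optimized on a fixed phylogeny
by landmark parsimony. The decision statistic is the summed displacement of
the five medial-margin points (landmarks 2, 6, 9 and both semilandmarks) on
the stem branch of the focal clade: *the configuration needing fewer steps
where the centrale disappears carries the preferred homology hypothesis*.
Being a parsimony argument, any difference counts; no significance test is
attached, and the package's simulation calibration quantifies the rule's
error rates instead.

## Pipeline stages and their models

### Landmark input

Data are 2D landmark tables (TPS interchange format): 9 fixed landmarks and
2 sliding semilandmarks on the anterior outline of the medial proximal
tarsal, in millimetres, left side (right-side specimens are mirrored
`x -> -x`; the side flag prevents double mirroring). Coordinates follow the
mathematical convention: +y dorsal, and medial is -x after mirroring to the
left. The scheme — semilandmark tangent neighbours and named subsets,
including the 5-point `"medial"` subset — is data (`landmark_scheme()`),
not hard-coded anatomy.

### Generalized Procrustes alignment with sliding

`gpa_align()` iterates centring, scaling (unit centroid size, or none in mm
mode), rotation to the consensus, and semilandmark sliding, to a consensus
root-mean-square change below 1e-12 (cap 100 iterations; non-convergence is
recorded in the provenance, not fatal). Sliding follows the Procrustes
distance criterion: each semilandmark moves along the chord direction of
its two neighbours to the perpendicular foot of the consensus point. Two
numerical choices matter:

* The per-semilandmark slide across all specimens is solved jointly as a
  small linear system. When tangent chords are nearly parallel across
  specimens that system has one near-singular mode — every semilandmark
  sliding in unison, with the consensus following — along which the
  objective is flat to first order. That mode is truncated (eigenvalues
  below 0.05), which pins the gauge and removes an oscillation that
  otherwise slows convergence by orders of magnitude without changing the
  objective.
* The output orientation is canonicalized to the consensus principal axes
  (180-degree ambiguity resolved by the most lateral landmark's sign), so
  alignment output is invariant to the arbitrary orientations of the
  inputs, and re-aligning an aligned dataset is a fixed point.

The morphospace (`shape_pca()`, `sum_of_variances()`) is always computed on
unit-scaled Procrustes coordinates; disparity is the sum of per-coordinate
variances, equal to the PCA eigenvalue sum. The variance divisor is n-1 by
default with n available; reported disparities state the convention.

### Minimum-distance re-alignment and the scale mode

Before parsimony optimization the configurations are re-superimposed onto a
reference taxon (the earliest-branching outgroup member) minimizing the
*unsquared* summed landmark distances — an L1 criterion, solved by
iteratively reweighted least squares (weights 1/distance floored at 1e-9,
objective change below 1e-12, with a transform-space extrapolation step
that is accepted only when it lowers the objective). Rotation and
translation only; no reflection; scaling behind an option.

`run_configuration()`'s `scale_mode` governs this parsimony leg. The
default is `"mm"`: configurations keep their millimetre scale (alignment
without rescaling), matching the stated millimetre scaling of the
optimization step in this study design. This choice is not cosmetic: a
medial expansion of a bone is in large part a *size* signal, and unit
Procrustes scaling absorbs most of it — under identical simulations the
focal-branch signal surviving unit scaling is roughly one tenth of what
survives in mm mode. `"unit"` remains available, and the two can be
compared directly.

### Landmark parsimony

`reconstruct_ancestral()` places a configuration at every internal node to
minimize total Euclidean landmark displacement summed over branches (input
branch lengths are ignored; displacement *is* the branch length). The
objective decomposes into one convex multifacility Weber problem per
landmark. Each is solved by:

1. an epsilon-smoothing schedule (1e-3, 1e-5, 1e-7, 1e-10) so iterations
   cannot stall on coincident points, with, at each level, the better of a
   damped Newton step (quadratic near smooth optima) and an IRLS
   tree-Laplacian step (monotone majorize-minimize, geometric progress
   through the kinks where ancestral nodes sit exactly on neighbours);
2. a contraction polish: edges driven toward zero length are contracted
   (coarse-to-fine thresholds), the reduced problem is re-solved, and the
   result is accepted only if the unsmoothed objective does not increase.
   This finishes vertex-type optima exactly instead of crawling toward
   them, and is what makes the reported lengths root-invariant to ~1e-12.

Non-unique optima at two-neighbour nodes (the root of a rooted binary tree
is optimal anywhere on the segment joining its children) are reported at the
segment midpoint; lengths are unaffected. A squared-change option solves
the unit-weight Laplacian instead, for comparison only.

The consistency index is reported as the summed per-landmark Euclidean
minimum-spanning-tree lengths over the terminals divided by the realized
tree length. This is a declared package convention: because ancestral
(Steiner-type) nodes can realize less length than the MST, values slightly
above 1 are possible for star-like optima, and the column is not promised
to match consistency indices computed under other software's conventions.

### The decision rule

`compare_hypotheses()` prefers the configuration with the strictly smaller
focal-branch medial-subset length (ties are inconclusive), mapping the
combined configuration to "fusion" and the astragalus-only configuration to
"loss". `comparison_report()`/`write_report()` assemble the configuration x
topology table, the per-topology preference, the disparity contrast, and
the per-landmark displacement vectors on the focal branch; reports carry no
timestamps, so a fixed input reproduces byte-identical files.

## The synthetic generator

`simulation_spec()`/`simulate_dataset()` emulate the study's inputs so that
every stage is testable without the original material, and so the decision
rule can be calibrated. Landmark coordinates evolve as independent Brownian
motion down the tree (per-coordinate variance `sigma^2 x` branch duration,
duration 1 per branch for topology-only trees), with Gaussian digitization
noise at the leaves. Brownian motion runs on raw coordinates, not in
Procrustes tangent space — a deliberate simplification; the pipeline's own
alignment removes the nuisance similarity components.

The scenario controls the focal-branch signal. The configuration whose
landmark homology the true scenario *violates* shows an apparent medial
jump of magnitude `delta` (toward -x, inherited by all descendants of the
focal branch): under `loss_expansion` the combined configuration jumps (its
medial margin switches from the centrale's edge to the expanded
astragalus'), under `fusion` the astragalus-only configuration jumps (its
labelled astragalus suddenly includes former centrale territory — the
ventromedial displacement pattern seen in real data). `delta = 0` gives a
no-signal null in either scenario. This assignment is what makes the
decision rule's calibration coherent: simulating a scenario leads the rule
to prefer that scenario's hypothesis.

What the generator does **not** emulate: correlated landmark covariance
(real outlines deform coherently), allometry, missing data, digitization
error structure beyond isotropic noise, and rate variation across branches.
Passing calibration therefore shows the decision rule recovers the injected
signal under idealized evolution — not that the biological conclusion is
insensitive to those factors.

### Default study conditions

Chosen once to mirror the study design at test scale, and used by the
bundled fixture and the calibration:

| Parameter | Default | Why |
|---|---|---|
| tree | 8 taxa: outgroup clade `(o1,(o2,o3))`, then `p1`, focal clade `(f1,(f2,(f3,f4)))` | smallest layout with the study's structure: a 3-taxon rooting clade, an intervening taxon, and a focal clade with a stem branch |
| ancestor shape | 11-point outline ~12 mm wide | the size class of the Triassic astragali sampled |
| `sigma` | 0.1 mm per unit branch | ~1% of shape size per branch: gradual background evolution |
| `noise` | 0.02 mm | a fifth of the per-branch signal: careful digitization |
| `delta` | 0.5 mm (fixture; `delta/sigma = 5`) | a clear but not overwhelming apparent jump |
| reference taxon | `o1` | earliest-branching outgroup member, as in the study design |
| seed | 42 (fixture) | fixed so the shipped files regenerate byte-identically |

Replicate r of a calibration derives its seed as `seed + r`, and the two
configurations of one replicate use seeds `(seed + 1000003 k) mod (2^31-1)`
for k = 1, 2 — every replicate is individually reproducible.

`calibrate_decision_rule()` at these conditions detects the injected
scenario in ~93-96% of replicates at `delta/sigma = 5` and sits near 1/2
under `delta = 0`; the acceptance tests run 200 replicates for power and
150 for the null (the acceptance script, 100 for the null). Problem sizes used by the test-suite: the Brownian
variance/covariance check uses 1,000 replicate simulations of 3-taxon
trees; the power-monotonicity grid uses 3 x 30 replicates; the
solver-versus-grid-search comparison uses 50 random instances of 3-5-leaf
trees (plus 8 in the unit tests).

## Degenerate inputs and edge behaviour

* Coincident semilandmark neighbours (zero tangent): the point is left
  unmoved, with a warning.
* All-coincident configurations: centroid size errors (no shape).
* Identical configurations across taxa: zero-length tree, CI defined as 1,
  zero disparity.
* A clade that is not monophyletic in a given tree (or equals the full leaf
  set) is an error naming the offending leaves — focal clades are inputs,
  never guessed.
* TPS curve extensions (`CURVES=`/`POINTS=`) fail loudly rather than being
  silently dropped.

## Known limitations

* 2D only, by design of the study it implements.
* Sliding uses chord tangents and the Procrustes distance criterion;
  bending energy is out of scope.
* The minimum-distance re-alignment precedes optimization; alignment and
  ancestral reconstruction are not jointly optimized.
* The consistency index convention is package-specific (see above).
* The parsimony solver is exact for its convex objective, so on real data
  its lengths may legitimately fall at or slightly below values published
  from heuristic optimizers.
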