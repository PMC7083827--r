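# centrale

Did the archosaur astragalus swallow the centrale, or was the centrale
simply lost? In early archosauromorphs the centrale is a separate tarsal
ossification medial to the astragalus; in Erythrosuchidae + Eucrocopoda it
disappears as an independent element. `centrale` implements a
geometric-morphometric, phylogeny-based test of the two homology
hypotheses — **fusion** (the centrale is incorporated into the astragalus)
versus **loss** (the centrale vanishes and the astragalus expands
medially) — for palaeontologists and morphometricians working with 2D
landmark data on fixed phylogenies.

## The method

Two landmark configurations describe the same 42 specimens: one samples the
astragalus + centrale as a single unit, the other the astragalus only. For
each configuration and each candidate topology the pipeline runs:

1. **Generalized Procrustes analysis** with semilandmark sliding along
   neighbour-chord tangents under the Procrustes distance criterion
   (`gpa_align()`), plus a PCA morphospace and the Sum of Variances
   disparity (`shape_pca()`, `sum_of_variances()`),
2. **minimum-distance superimposition** onto a reference taxon — each
   configuration rotated and translated to minimize the summed *unsquared*
   landmark distances (`minimum_distance_align()`),
3. **landmark parsimony**: ancestral configurations at every internal node
   minimizing the total Euclidean landmark displacement

   L = Σ_landmarks Σ_branches ‖x_parent − x_child‖,

   a convex multifacility Weber problem per landmark, solved to the global
   optimum by smoothed Newton/IRLS iteration with an exact vertex
   (edge-contraction) polish (`reconstruct_ancestral()`). Branch lengths
   *are* these displacements; input branch lengths are never used.

The decision statistic is the summed displacement of the five
medial-margin points (landmarks 2, 6, 9 and the two semilandmarks) on the
stem branch of the focal clade, where the centrale disappears. The
configuration requiring fewer steps there carries the preferred homology
hypothesis (`compare_hypotheses()`): combined smaller → fusion,
astragalus-only smaller → loss. Because the argument is parsimony, any
difference decides; instead of a significance test, a simulation module
(`simulate_dataset()`, `calibrate_decision_rule()`) generates Brownian
landmark evolution on a tree with a controllable focal-branch medial jump
and measures the rule's power and null behaviour.

## Worked example

The package ships an 8-taxon miniature of the study design (seed 42,
loss-expansion scenario, medial jump of 0.5 mm against a Brownian scale of
0.1 mm per branch):

```r
library(centrale)

cfg <- system.file("extdata", "fixture", "config.yaml", package = "centrale")
report <- run_comparison_from_config(cfg)
report
#> <comparison_report>
#> # A tibble: 2 × 6
#>   configuration    topology tree_length consistency_index focal_branch_medial_…¹
#>   <chr>            <chr>          <dbl>             <dbl>                  <dbl>
#> 1 astragalus_plus… sim             12.1             0.767                 0.458
#> 2 astragalus_only  sim             10.1             0.774                 0.0918
#>
#> preferred per topology:
#> # A tibble: 1 × 3
#>   topology preferred       hypothesis
#>   <chr>    <chr>           <chr>
#> 1 sim      astragalus_only loss
```

Reading this: the combined configuration needs 0.458 mm of medial-margin
displacement on the focal branch, the astragalus-only configuration just
0.092 mm — the astragalus-only homology explains the transition with fewer
steps, so the simulated loss-plus-medial-expansion scenario is correctly
recovered as "loss". (On the real data the inequality runs the other way,
which is the quantitative case for fusion.) Tree lengths (12.1 and
10.1 mm) are the total displacement summed over all branches and landmarks,
and the consistency index compares each landmark's realized length with its
minimum-spanning-tree bound.

The same pipeline is scriptable from a shell via the thin CLI in
`inst/scripts/centrale` (`align`, `optimize`, `compare`, `simulate`), each
subcommand driven by the same YAML run config that `write_fixture()`
emits.

A single configuration can also be run directly:

```r
spec <- default_fixture_spec()
pair <- simulate_dataset(spec)
run_configuration(pair$astragalus_plus_centrale, spec$scheme, spec$tree,
                  spec$reference, spec$focal_clade,
                  configuration_label = "astragalus_plus_centrale",
                  topology_label = "sim")
#> <configuration_result> astragalus_plus_centrale on sim
#>   tree length = 12.05835, CI = 0.7672, focal medial length = 0.4578588, SoV = 0.001385856
```

`tidy()`, `glance()` and `autoplot()` methods cover the fitted objects
(alignments, morphospaces, reconstructions, reports, calibrations).

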