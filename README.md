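# bhctvi — breath-hold CT ventilation imaging by deformable registration

`bhctvi` computes regional lung ventilation surrogates from paired
expiration/inspiration breath-hold CT volumes, for researchers studying how
body position (supine, prone, right/left lateral decubitus) redistributes
ventilation, and for anyone needing a fully synthetic, ground-truthed test
bed for Jacobian-based CT ventilation pipelines.

The chain it implements:

1. **Deformable registration.** The inspiration scan is registered to the
   expiration scan (the fixed reference) with a cubic B-spline free-form
   deformation: exhaustive two-pass block matching for initialisation,
   then L-BFGS-B refinement of an SSD/NCC metric with a bending-energy
   penalty. The result is a displacement field u(x, y, z) in mm mapping each
   expiration voxel to its inspiration position.
2. **Ventilation map.** The Jacobian determinant V = det(I + ∇u) measures
   local volume change: V > 1 expansion, V < 1 contraction, V = 1 none.
3. **Highly functional areas.** V is converted to percentile ranks over all
   voxels of both lungs; voxels at or above the 75th percentile form the
   highly functional mask (the top quartile of ventilation).
4. **Regional reports.** Threshold-based lung segmentation, lung volumes in
   mL, four cranio-caudal sections (apical / middle / basal / diaphragm),
   and per-lung-per-section highly-functional-area percentages.
5. **Displacement orientation.** Per-region gravity-alignment (magnitude-
   weighted mean cosine with the gravity direction) and ground-parallelism
   indices summarise whether breathing motion follows or ignores gravity.
6. **Position statistics.** Paired exact Wilcoxon signed-rank tests compare
   section ratios across positions against the supine reference, with a
   Bonferroni-adjusted threshold (0.05/3, displayed 0.016).

A synthetic thorax phantom with an analytically known deformation field
(`phantom_spec()` / `generate_phantom()`) stands in for patient data and
drives the entire validation suite.

## Worked example

```r
library(bhctvi)

spec <- phantom_spec(grid_shape = c(64, 64, 64), spacing_mm = 3,
                     position = "supine")
pair <- generate_phantom(spec)
pair
#> phantom_pair: supine, 64x64x64 voxels @ 3 mm, mean lung Jacobian 1.300

dvf   <- register_bspline(pair$exhale, pair$inhale)
lungs <- segment_lungs(pair$exhale)
lung_volume(lungs)                      # 385.3 mL at exhale
lung_volume(segment_lungs(pair$inhale)) # 507.6 mL at inhale (ratio ~1.30)

jac <- jacobian_map(dvf)
hf  <- functional_mask(percentile_map(jac, lungs), 75)
functional_ratio(hf, lungs, define_sections(lungs))
#>    lung   section ratio_pct volume_ml n_voxels
#> 1 right    apical      0.00      13.4      495
#> 2 right    middle     21.31      24.7      915
#> 3 right     basal     40.43      24.0      888
#> 4 right diaphragm     37.50      11.2      416
#> 5  left    apical      0.00      13.4      498
#> 6  left    middle     22.48      24.9      921
#> 7  left     basal     42.95      24.1      894
#> 8  left diaphragm      6.46      11.3      418

region_vector_summary(dvf, lungs$data > 0, gravity_vector("supine"))
#>   ... mean_magnitude_mm gravity_alignment ground_parallelism ...
#> 1 ...               7.1            -0.719              0.597 ...
```

Reading the output: the inhale/exhale volume ratio recovers the phantom's
target expansion of 1.30; highly functional areas concentrate in the basal
(gravity- and diaphragm-favoured) sections, rising from 0% apically to
~40% basally — the most caudal slab is the noisiest under registration; and
the negative gravity alignment (−0.72) says the supine displacement vectors
point dorsal-to-ventral, i.e. against gravity, while a prone phantom yields
ground-parallelism above 0.9 (head-to-feet motion parallel to the table).

The end-to-end pipeline, including a seeded multi-subject cohort and the
paired position comparison, is one call:

```r
res <- run_pipeline(run_config(n_subjects = 8, use_truth_dvf = TRUE))
res$comparison   # Wilcoxon p-values per lung x section x position contrast
```

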