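# billmorph

Hermit hummingbirds fight at leks, and in at least some species the males'
bills are weapons: straighter, longer and sharper-tipped than the females',
and apparently better at stabbing rivals. Testing that idea quantitatively
takes two toolkits that rarely live together — landmark-based 3D geometric
morphometrics to establish *that* and *how* bill shape differs between the
sexes, and comparative finite-element analysis to ask whether the male
shape actually performs better as a stabbing tool. `billmorph` implements
both ends of that study as one reproducible R pipeline, exercised
end-to-end on parametric synthetic bill geometries with known ground
truth (the original museum and CT specimens are not publicly deposited).

It is aimed at morphologists and biomechanists who want a transparent,
scriptable version of this workflow: every stage is an exported function
with analytic tests behind it, and the whole study runs from four short
drivers.

## What it computes

**Shape.** Three labeled contour curves per specimen (culmen, left and
right tomium), resampled to 60 points each and merged into a 178-point
configuration (4 fixed landmarks + 174 sliding semilandmarks). Generalized
Procrustes analysis with tangent-line semilandmark sliding, bilateral
(object) symmetry decomposition, PCA of the symmetric component, and
centroid size.

**Bill descriptors.** Curvature as the arc:chord ratio of the culmen
(arc length / chord length, 1 = straight); outer surface area; tip
sharpness as `1 − A1/A2` with `A1`, `A2` the outer areas of the first and
second distal millimeters (exact plane clipping); the dorsal included
angle `2·atan(half-width / 0.5 mm)`.

**Statistics.** Procrustes ANOVA with residual-randomization permutation
(R², pseudo-F, seeded p-values), exact Mann–Whitney U, Spearman
correlations.

**Biomechanics.** Linear-static FE on quadratic tetrahedra (keratin shell
1700 MPa over bone core 7300 MPa, ν = 0.4, bonded interface), stabbing
boundary conditions (base fixed, distal-millimeter tip load, horizontal
and tip-parallel angles), 98th-percentile and mesh-weighted-mean von Mises
stress, strain energy, and eigenvalue buckling. The comparative protocol
scales the target load to an equal force:surface-area ratio
(`F_B = F_A · SA_B / SA_A`) and adjusts strain energy to the common
force:volume regime (`U′_B = U_B (F_A/F_B)² (V_B/V_A)^{1/3}`).

## Worked example

```r
library(billmorph)

p  <- male_bill_params()                 # arc 42 mm, arc:chord 1.035, ...
sp <- generate_surface(p)                # watertight mesh + labeled contours
sp$truth <- p; sp$id <- "demo"; sp$sex <- "M"
bill_metrics(sp)
#>     id sex arc_length chord_length arc_chord_ratio outer_surface_area
#> 1 demo   M   41.99934     40.57971        1.034984           314.9597
#>   area_distal_mm area_second_mm sharpness_ratio included_angle centroid_size
#> 1      0.7199165       1.574626       0.5428015       27.70122      158.3063
```

The measured arc length and arc:chord recover the generating parameters
(42 mm, 1.035) to well under 1%; the sharpness ratio 0.54 and included
angle 27.7° quantify the male's fine tip. The full study —

```r
report <- run_study(study_config())
report
```

— generates 8 + 8 specimens, finds sex a significant predictor of
symmetric bill shape (R² ≈ 0.78, permutation p ≈ 0.002 at seed 1) with
complete separation of the sexes along PC1, and runs the comparative FE on
the PC1-extreme pair: under equal force:surface-area horizontal loading
the straighter male bill stores roughly 79% less strain energy and carries
a 63% lower mesh-weighted mean stress than the curved female bill, while
parallel-to-tip loading costs the curved bill ~60% more energy than
horizontal — the directional pattern expected if straight bills are better
stabbing tools.

The numbered scripts under `analysis/` run the same study in four stages
(simulate → landmarks/shape → metrics/stats → FE comparison) and write
tables under `results/`.

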