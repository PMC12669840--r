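---
title: "Methods: synthetic bill morphometrics and stabbing biomechanics"
author: "billmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic bill morphometrics and stabbing biomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`billmorph` implements, as a tested pipeline over synthetic geometry, a
complete study of bill sexual dimorphism and stabbing biomechanics in a
lekking hermit hummingbird: semilandmark geometric morphometrics of the
maxillary rhamphotheca, the univariate bill descriptors used in that
literature (arc:chord curvature, tip sharpness ratio, included angle,
outer surface area), and a comparative linear-static finite-element (FE)
simulation of stabbing with von Mises stress summaries, strain energy and
eigenvalue buckling. This vignette documents the models, the parameter
choices and their rationale, the numerical decisions, and what the
synthetic-data results do and do not establish about real specimens.

## The synthetic bill family

Museum photogrammetry models and CT scans of the study species are not
publicly deposited, so the pipeline runs end-to-end on a parametric bill
family with known ground truth.

**Centerline.** The culmen (dorsal ridge) is a planar circular arc — the
unique planar curve realizing a prescribed arc:chord ratio — of length $L$
(`arc_length`, mm) in the sagittal $x$–$z$ plane, chord on the $x$ axis,
tip at the origin, bulging dorsally. The subtended angle $\theta$ solves
$\theta / (2\sin(\theta/2)) = \text{arc:chord}$, found by root bracketing;
arc:chord $= 1$ degenerates smoothly to a straight segment.

**Cross-section.** A dorsal half-ellipse over a shallow ventral
half-ellipse (18% of the section height), giving slope discontinuities at
the lateral extremes that make the tomia well-defined edge curves and the
dorsal apex the culmen. The sweep follows the culmen rather than a
mid-section axis, so the generated culmen curve *is* the parametric arc:
ground-truth arc length and arc:chord are exactly the quantities the
metrics module later measures (a mid-axis sweep would displace the culmen
dorsally and inflate its length by several percent, making the stated 1%
recovery unreachable).

**Taper.** Cross-section dimensions scale as $(s/L)^p$ with arc position
$s$ from the tip; the exponent $p$ (`taper_exponent`) controls tip
sharpness. A mechanical constraint pins the admissible range: with section
radius $\propto s^p$, the bending compliance of the tip under a transverse
load has integrand $\propto s^{2}/I(s) \propto s^{2-4p}$, which diverges
as $s \to 0$ whenever $p \ge 3/4$. Sharper tapers therefore make strain
energy under tip loading an ill-posed quantity whose value is set by the
mesh truncation rather than by the biology. The defaults, female
$p = 0.50$ and male $p = 0.65$, keep tip mechanics convergent while
producing realistic tips (half-widths of 0.16–0.32 mm at 1 mm from the
tip; dorsal included angles of roughly 45° and 29°, the male sharper by
both sharpness metrics).

**Default group means.** Females: arc 39 mm, arc:chord 1.100, base
4.0 × 3.0 mm. Males: arc 42 mm, arc:chord 1.035, base 4.5 × 3.4 mm.
These magnitudes are plausible for a large hermit (~40 mm bill) and
reproduce the direction of every reported sexual difference: males
straighter, longer, sharper-tipped, with larger outer surface area. No
cross-sectional or shell-thickness measurements exist for the species;
base dimensions and the 0.15 mm keratin shell are explicit non-biological
calibrations. Individual noise defaults to ~2% coefficients of variation
per parameter plus 0.02 mm isotropic landmark jitter on contour points,
with eight specimens per sex — the study's sample structure.

**Meshing.** The surface is a swept triangulation, closed by an exact apex
fan at the tip and a basal cap; bilateral symmetry is exact to machine
precision by construction, and watertightness is asserted. The apex is
kept on the surface (a cone point triangulates cleanly), so tip metrics do
not depend on `tip_truncation`. The volume mesh is a structured
tetrahedralization of the same solid: a polar cross-section template
(center fan, two core rings, one shell ring) extruded along the sweep,
with prisms split into tetrahedra by an ascending-vertex-index rule that
is provably conforming; here the apex *is* truncated (default 0.05 mm)
because vanishing tetrahedra are numerically singular. The shell/core
interface shares nodes — bonded contact — and shell thickness is measured
radially in the section plane; near the tip, where the section is thinner
than the shell, the core persists as a minimal kernel (25% of the local
radius) so all elements stay valid.

## Landmark protocol and Procrustes machinery

Three contour curves (culmen, left and right tomium), digitized tip-first
and sharing the tip point, are resampled to 60 points each by arc length;
duplicate tip copies are dropped, for $3 \times 60 - 2 = 178$ points. The
four curve endpoints are fixed homologous landmarks; the 174 interior
points are sliding semilandmarks with tangents from central differences of
curve neighbors. The tip is retained once and assigned to the midline;
left and right tomium points are paired by within-curve index.

Generalized Procrustes analysis centers each configuration, scales to unit
centroid size, rotates to the running consensus (proper rotations only),
and interleaves semilandmark sliding: each semilandmark moves along its
tangent line by the projection of its residual to the consensus, capped at
the local inter-neighbor spacing to prevent fold-over, then is re-projected
onto the pre-slide polyline so it stays on its curve. Outer iterations stop
when the consensus moves less than $10^{-8}$ (Frobenius) or after 10
iterations; sliding typically continues improving slowly, so the fit may
report `converged = FALSE` while residual changes are far below any
quantity of interest. The converged fit is put in a canonical frame by the
consensus principal axes, with axis signs fixed by the third moment of the
shape along each axis — a rotation-equivariant convention, so the GPA
output is invariant (to $10^{-8}$) under arbitrary rigid motions and
rescalings of the inputs; the bilaterally symmetric lateral axis (zero
third moment) is completed right-handedly.

Object symmetry: each aligned configuration is mirrored across the
sagittal plane, relabeled by the left/right pairing, Procrustes-aligned
onto the original, and averaged. The average is the symmetric component;
the residual is the asymmetric component; the two reconstruct the aligned
coordinates exactly. PCA of the mean-centered, flattened symmetric
coordinates (SVD; sign fixed by the largest-magnitude loading) gives the
shape space.

## Bill descriptors

All tip measures operate in a standard frame: tip at the origin, chord
(tip to proximal culmen endpoint) along $+x$, sagittal plane mapped to
$x$–$z$. Arc:chord is measured on the 60-point culmen. The outer surface
area sums lateral triangle areas (the morphometric selection — distinct
from the closed-boundary area used by force scaling). The sharpness ratio
is $1 - A_1/A_2$, with $A_1$ and $A_2$ the outer areas of the first and
second distal millimeters, measured as slabs along the aligned $x$ axis
with exact polygon clipping at the slab planes (vertex binning would bias
the few-triangle $A_1$). The included angle is
$2\arctan(w_{1/2}/0.5\,\text{mm})$ from the dorsal-silhouette half-width
at 0.5 mm. Closed-form checks pin these: a right circular cone gives
$A_1/A_2 = 1/3$ (sharpness $2/3$), a cylinder 0, a 15° half-angle cone a
30° included angle.

## Statistics

Procrustes ANOVA regresses the flattened shape coordinates on one
predictor; $R^2$ is the effect share of total squared variation, the
pseudo-$F$ uses the standard degrees of freedom, and the $p$ value comes
from permuting response rows under the intercept-only reduced model
(residual randomization), 999 permutations by default with an explicit
seed and the observed statistic included in the reference set. Note one
discreteness property: with perfectly separated groups the attainable
minimum $p$ is governed by the probability that a row permutation
recreates the grouping ($2\,n_1!\,n_2!/n!$), not $1/(n_\text{perm}+1)$.
Mann–Whitney U and Spearman correlations go through `wilcox.test()` and
rank-based `cor()` — exact enumeration for small untied samples (the
complete-separation two-sided $p$ at $n=m=8$ is $2/12870$), tie-corrected
normal approximation otherwise; fully tied samples return $p = 1$. Both
permutation and rank tests hold their nominal 5% level under the null
generator (asserted at 1000 replicates).

## Finite-element model

Isotropic linear elasticity on straight-sided tetrahedra: quadratic
10-node elements by default (4-point Gauss rule, exact for the affine
map), linear 4-node elements as a fast option. Materials follow published
bird-bill values: keratin shell 1700 MPa, bone core 7300 MPa, Poisson's
ratio 0.4. Units are mm/N/MPa, so energies are mJ. Assembly is compiled
(Rcpp); the reduced system solves by sparse supernodal Cholesky.

Boundary conditions emulate stabbing: all nodes on the proximal cut plane
are fixed (attachment to the head); the total force — 200 mN reference,
125 mN male-unscaled, both converted to N — is distributed over nodes
within the distal millimeter of the tip. The default distribution is
area-weighted (each node carries its tributary boundary-surface area),
approximating a uniform traction over the loaded patch; equal nodal
shares are available but concentrate finite force fractions on the
vanishing apex elements of a tip-graded mesh, where local compliance
dominates the response. Two load angles: *horizontal*, along $+x$ (the
chord, pointing proximally), and *parallel*, along the centerline tangent
at the tip.

Summaries: the 98th percentile of element-centroid von Mises stresses
(type-7 linear order-statistic interpolation; the top 2% is discarded as
numerical singularity), the mesh-weighted arithmetic mean (volume
weights), and the strain energy $u^\top f/2$. Buckling solves
$(K + \lambda K_g(u_0))\,\phi = 0$ with the geometric stiffness assembled
from the static stress state; the smallest positive $\lambda$ is found by
Lanczos iteration (80 vectors, full reorthogonalization) on the
symmetrized pencil $L^{-1}(-K_g)L^{-\top}$, which still finds the positive
branch when a larger-magnitude negative eigenvalue exists (as under
predominantly tensile states, reported as no compressive instability).

Validation is part of the test suite: cantilever tip deflection within 5%
of $FL^3/(3EI)$ at $L/h = 20$, fixed-free column buckling within 10% of
$\pi^2 EI/(4L^2)$, the work-balance identity to $10^{-8}$, exact linearity
in the load, and strain-energy stability (<2%) under one uniform 1:8 tet
octasection — a refinement that preserves the polyhedral geometry exactly
and so isolates discretization error from geometry approximation.

## Comparative protocol

The scaled analysis loads the reference model A (female) with
$F_A = 200$ mN and the target B with $F_B = F_A \cdot SA_B/SA_A$ (equal
force:surface-area; $SA$ is the full closed-model boundary area). Strain
energies are additionally adjusted to the common force:volume regime,
$U_B' = U_B\,(F_A/F_B)^2\,(V_B/V_A)^{1/3}$, which maps geometrically
similar models to identical adjusted energies and is the identity when
forces and volumes agree. The unscaled analysis applies the empirical
puncture forces (200/125 mN). Differences are reported as
$100\,(x_B - x_A)/x_A$. The reference model is configurable; the female is
the default, and the choice is arbitrary in a comparative analysis.

## Problem sizes

Default study sizes, chosen to keep a complete run in well under a minute
on one CPU while leaving all qualitative behavior unchanged: surface
meshes of 120 × 32 sweep/angular stations for metrics; volume meshes of
20 stations × 12 angular sectors × 3 radial layers (≈3,400 quadratic tets,
≈20,000 degrees of freedom) for FE, with grading exponent 2.6
concentrating stations at the loaded tip — the resolution at which the
refinement check above passes on the female reference geometry (the
male's sharper tip converges more slowly, with refinement estimates
fluctuating a few percent; the comparative orderings have margins an
order of magnitude larger). These meshes are deliberately far smaller
than the several-hundred-thousand-element models used on real CT
geometry; all FE conclusions drawn from them are comparative orderings,
not absolute magnitudes.

## What the synthetic results do and do not show

The generator emulates: curved, tapered, bilaterally symmetric bills with
a thin keratin shell over a bone core; dimorphism in curvature, length,
sharpness and area; individual variation and digitization jitter. It does
not emulate: irregular real cross-sections, the mandible and
maxilla–mandible fit, heterogeneous or graded material properties, cranial
kinesis, or contact/impact dynamics. Passing tests therefore establish
that the *pipeline* is correct (its operations match closed forms and
oracles) and that the *qualitative mechanics* hold on this family —
straighter bills transmit horizontal stabbing loads with less strain
energy and lower mean stress, curved bills suffer more under loads
parallel to the tip axis — but they do not reproduce effect sizes measured
on real specimens, whose geometry is not publicly available. The
98th-percentile peak stress is the most fragile summary in this family:
the male's finer tip concentrates stress over more than 2% of elements, so
peak comparisons can run opposite to the volume-weighted mean; the mean
(MWAM) and energy are the robust comparative quantities here.

## Reproducing the study

The numbered drivers under `analysis/` run the four stages (population →
landmarks/shape → metrics/statistics → comparative FE) and write their
tables under `results/`. `scripts/acceptance.R --seed <s> --out <path>`
recomputes the pipeline's published-value check (the 203 mN scaled load)
from scratch. Every stochastic step takes an explicit seed; rerunning any
stage with the same configuration reproduces its outputs bit-for-bit.
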