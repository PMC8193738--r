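---
title: "Methods: image-based finite-element analysis of disc bulge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based finite-element analysis of disc bulge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`osteodisc` implements a combined experimental/computational workflow for
bone--disc--bone ("osteodisc") specimens under stepwise axial compression:

1. **Synthetic specimen generation** — voxel phantoms of a cylindrical
   intervertebral disc between two bone blocks potted in PMMA endcaps,
   carrying 40 glass fiducial markers on the disc surface, imaged on an
   82 µm isotropic CT-like grid and a coarse anisotropic MR-like grid.
2. **Image processing** — greyscale normalisation, rigid registration of
   step volumes to the preloaded scan, automatic marker centroid
   extraction, bulge computation, and recovery of the applied platen
   displacement from the endcap inner surfaces.
3. **Specimen-specific finite elements** — labelled geometry, three
   nucleus model types, tetrahedral meshing, Holzapfel-type
   fibre-reinforced annulus, Mooney–Rivlin nucleus, greyscale-mapped
   linear elastic bone, and a total-Lagrangian Newton solver.
4. **Inverse calibration** — bounded trust-region least squares on tissue
   compressibility against per-step peak loads.
5. **Agreement statistics** — Welch-corrected regional ANOVA, Lin's
   concordance correlation, Bland–Altman-style mean differences, and the
   lower-tenth-percentile exclusion rule.

Viscoelastic/time-dependent behaviour, relaxation, MR physics, and the
fourth compression step (beyond the validated strain range of the annulus
model) are deliberately out of scope.

# The synthetic phantom and what it emulates

The generator is the study's ground-truth engine: every downstream stage
is tested against quantities the phantom knows exactly.

**Geometry.** A disc cylinder (radius $R$, height $h$) sits between two
bone blocks (radius $0.95R$) and PMMA endcaps (radius $1.15R$). Defaults
($R = 13$ mm, $h = 9$ mm, 15 mm bone per side) approximate a bovine
coccygeal specimen; tests and the acceptance runs use a desk-scaled
geometry ($R = 5.5$ mm, 2.5 mm bone, 2 mm endcaps) at the *same* 82 µm
resolution so that voxel-level error mechanisms are preserved while a
volume stays below ten million voxels. The nucleus is a coaxial cylinder
spanning the disc height whose volume fraction is sampled uniformly on
[0.07, 0.17] of the disc volume — the measured range of the study tissue —
which implies nucleus-to-annulus diameter ratios of 26–41%.

**Markers.** Forty ~1 mm glass markers on 8 craniocaudal lines at 45°
intervals, 5 levels per line, rendered as anti-aliased spheres
(partial-volume fractions from the signed distance to the sphere surface)
so sub-voxel centroid recovery is possible, as in the physical data.
PinPoint-style 3 mm reference markers are embedded in both endcaps and
rendered in both modalities.

**Compression protocol.** A 50 N preload defines step 0; four platen
steps are drawn from $N(0.89, 0.14^2)$ mm, the measured per-step
displacement distribution. The top bone/endcap assembly translates
axially; the disc compresses linearly between the rigid blocks.

**Planted bulge field.** The radial surface displacement is
$u_r(\theta, \zeta) = A_s\, g(\theta) \sin(\pi \zeta / h)$ — smooth, zero
at the endplates, anterior-biased through
$g(\theta) = 1 + 0.25\cos(\theta - \theta_A) + \sum_{k=2,3} (a_k \cos k\theta + b_k \sin k\theta)$,
clamped at 0.05. The per-step amplitude $A_s$ is calibrated once so that
the marker-layout average of $g \cdot \sin$ equals the study's cumulative
bulge means (0.24, 0.48, 0.67, 0.84 mm), and the variance is budgeted
across three sources: the deterministic axial profile (CV 0.28 over the
five marker levels), the anterior bias plus random azimuthal modes
($\sigma = 0.189$ per mode coefficient), and a per-specimen amplitude
factor (CV 0.15). Together these reproduce the reported across-marker SDs
(≈0.45 CV) while keeping cohort means estimable from ~20 specimens.
Markers ride the surface exactly, so planted displacements are
recoverable from ground truth with no discretisation error.

**Rigid perturbation.** Each step volume additionally receives a random
whole-specimen rigid motion (≤1°, ≤0.5 mm) so that registration is always
exercised; the caudal bone is rigid under the deformation, which is what
makes the caudal-ROI registration well posed. An intensity texture
(±8% sinusoidal modulation) gives the bone interior registration
contrast.

**What the phantom does not emulate**: beam hardening, scanner noise
correlation, MR physics, petroleum-jelly artefacts around markers,
non-circular disc cross-sections, endplate curvature, and any
time-dependent tissue behaviour. Passing tests therefore demonstrate the
pipeline's correctness and its error floor on idealised data, not its
robustness to every artefact of real scans.

**Load model.** The synthetic load record is a cubic monotone curve
$L(d) = 50 + 200 d + 12 d^3$ (N, mm), chosen to reproduce the stiffening
shape and ~2 kN ceiling of the measured curves without claiming their
values; for calibration-recovery studies the record is instead generated
by the forward FE model with known compressibilities.

# Image-processing choices

* **Marker detection.** Otsu's threshold over the bright intensity tail,
  6-connected components, a size gate of 0.3–3× the nominal marker
  volume, and intensity-weighted (background-subtracted) centroids.
  Components holding 2–6 marker volumes — markers touch along a line once
  the disc is strongly compressed — are split by k-means seeded
  deterministically along the component axis, with the per-marker unit
  volume estimated from the unambiguous single-marker components.
* **Registration.** Step volumes: multi-resolution (4×, 2×, 1×)
  mean-squares minimisation over the caudal-bone region with a
  derivative-free simplex at each level (six pose parameters, rotation
  as a Rodrigues vector about the ROI centroid). MR: closed-form Kabsch
  alignment of the detected PinPoint constellations. On phantoms the
  caudal mode recovers planted motions to well under half a voxel RMS.
* **Applied displacement.** The endcap inner surfaces are located from
  the slice profile of endcap-intensity voxels (interfaces also cross the
  intensity band but are only 1–2 voxels thick), refined per transverse
  column inside a ±5-slice window and combined by a 10%-trimmed mean.
  Quantisation error is below one voxel (82 µm).

# Constitutive models

All hyperelastic responses use the isochoric split
$\bar{F} = J^{-1/3} F$ applied to both deviatoric invariants and fibre
pseudo-invariants, with volumetric energy $U(J) = \tfrac{K}{2}(J-1)^2$
(a log-form alternative is available by configuration).

* **Annulus (GOH, two discrete families, $\kappa = 0$):**
  $W = C_{10}(\bar I_1 - 3) + \sum_f \tfrac{k_1}{2k_2}\left(e^{k_2 \langle \bar I_{4f} - 1\rangle^2} - 1\right) + U(J)$
  with $C_{10} = 0.25$ MPa, $k_1 = 1.43$ MPa, $k_2 = 1.63$, fibres at
  ±20° to the transverse plane in the (circumferential, axial) plane.
  The Macaulay bracket disables compressed fibres.
* **Nucleus (Mooney–Rivlin):** $C_{10} = 0.07$, $C_{01} = 0.02$ MPa.
* **Bone:** linear elastic, $E$ mapped linearly from the 0–255 rescaled
  greyscale after 0.5 mm mean-pooling, clamped to [3.6, 842] MPa,
  $\nu = 0.3$. The published map's coefficients are not restated in the
  source text, so the default slope (842/255 MPa per unit, zero
  intercept) reproduces the range ends and is explicitly overridable.
* **PMMA:** $E = 1035$ MPa, $\nu = 0.3$. The source reports both 1035
  (tabulated) and 2450 MPa (text); the tabulated value is the default and
  the alternative is a configuration choice.

Stresses are exact derivatives of the energies and the tangents are the
consistent analytic second derivatives; the test suite checks both
against central finite differences to 1e-6/1e-5 relative on random
deformation states, plus objectivity under random rotations.

**Equivalent Poisson's ratio.** Calibrated bulk moduli are reported as
$\nu = (3K - 4C_{10})/(6K + 4C_{10})$, using $C_{10} = 0.07$ MPa for the
nucleus and a linearised annulus reference. Our linearisation (uniaxial
circumferential tension, traction-free lateral faces, strains ≤2%, slope
fit through the origin, $C_{10} = E_{\text{eff}}/6$) gives ≈1.51 MPa for
the tabulated annulus parameters versus the reference value 1.92 MPa;
since the original fit's strain mode and range are unstated, the function
reports its own fit metadata rather than asserting agreement, and the
conversion uses 1.92 by default for comparability.

# Meshing and the finite-element solver

**Meshing.** No tetrahedralisation library is assumed: the mesher samples
the label volume on a uniform grid and splits each occupied cell into six
tetrahedra around the cell diagonal (Kuhn subdivision, uniform
orientation, conforming by construction) — the same structured
image-based meshing family used by commercial segmentation pipelines.
Grid spacing 0.55 mm keeps every element edge inside the study's
0.5–1.0 mm band; desk-scale work uses 1.5–2.5 mm. Region labels,
per-element bone moduli (element centroid lookup in the pooled CT), and
fibre pairs (local circumferential frame about the disc axis) ride on the
elements.

**Nucleus model types.** `std_cyl`: coaxial cylinder at half the annulus
diameter; `fit_cyl`: coaxial full-height cylinder with the MR-measured
nucleus volume ($r = \sqrt{V/\pi h}$ — the height convention is ours, the
source fixes only the volume); `mr`: the segmented MR mask mapped through
the pinpoint registration into element labels.

**Solver.** Total-Lagrangian linear tetrahedra, one-point quadrature,
Newton–Raphson with a consistent tangent, direct sparse solves, and load
substepping (5 equal substeps per step, adaptive halving on divergence,
up to 8 halvings). Convergence: free-residual norm below 1e-6 of the
constraint-force norm, or a 1e-8 incremental-energy criterion. Boundary
conditions clamp the lower endcap face and drive the upper face axially
with transverse translations fixed. Reactions are the axial constraint
forces summed over the top face.

**Volumetric locking.** Near-incompressible tissue with displacement-only
linear tetrahedra locks; the mesh-refinement test demonstrates Cauchy
convergence, not convergence to the exact continuum limit at desk
resolutions. This bias is absorbed by the calibrated compressibility —
the same logic by which the physical study calibrated compressibility
against measured loads rather than asserting literature values. For that
reason parameter-recovery tests (same forward model both sides) are exact
while absolute load levels at coarse meshes should not be
over-interpreted.

# Calibration

The optimisation variable is compressibility $1/K$ of each tissue
(bounded so $K \in [1, 10^5]$ MPa), starting from water
($K = 2200$ MPa); the cost is the RMS difference between experimental
and computational peak loads over the first three steps. A compact
bounded trust-region Gauss–Newton (Levenberg damping, steps clipped to
the box, forward-difference Jacobian with 1% relative steps) minimises
it; no bounded trust-region least-squares routine was available among
the package's dependencies, so it is authored here and exercised by the
recovery tests. Success is declared below 10% of the maximum
experimental load; terminations by cost, parameter convergence, and
evaluation budget are reported distinctly. Averaging across specimens is
done on compressibility (mean of $1/K$, then inverted) because
compressibility is the calibrated quantity; averaging $K$ directly is a
configuration switch.

# Statistics

Normalised bulge (per-marker bulge divided by the step's applied
displacement) is compared across the eight zones with Shapiro–Wilk
per-zone normality, Levene's test, and a Welch-corrected one-way ANOVA
(diagnostics reported, never gating), with pooled-SD pairwise t tests
under Bonferroni correction when the ANOVA is significant at 0.05.
Lin's concordance correlation uses population (1/n) moments and the
Fisher-z normal-approximation CI; pairs whose experimental bulge falls in
the pooled lower tenth percentile (type-7 quantile) are excluded before
bulge concordance, and the fraction of surviving pairs within the 82 µm
resolution band is reported alongside.

# Numerical and design choices, in brief

* World coordinates: right-handed mm, z cranial, +y anterior, 0-based
  voxel indices; units mm/N/MPa throughout.
* Tenth-percentile filter pooled over the comparison set (not
  per-specimen), matching the pooled wording of the agreement analysis.
* Bonferroni family: all 28 zone pairs at a given step.
* Marker/blob threshold, size gates, endcap intensity band, and
  registration effort are all explicit arguments with the defaults above.
* Degenerate inputs fail loudly: constant volumes cannot be rescaled,
  single-zone tables cannot be tested regionally, zero-variance pairs
  have no concordance, non-positive-definite deformations abort the
  solver with the offending element.
* Problem sizes used by the test-suite and acceptance runs: 20 phantoms
  at 82 µm for the marker arm, 8 of them through the full deformation
  pipeline; FE meshes of 2–7k elements with three refinement levels for
  convergence checks; 50 sampled specimens for the nucleus-fraction
  bound. These sizes were chosen so a complete run stays desk-tractable
  while every mechanism (partial volume, sub-voxel registration,
  locking, identifiability) is still exercised.

# Known limitations

* The image arm's accuracy statements hold for idealised phantoms;
  real scans add artefacts the generator deliberately omits.
* Displacement-formulation tetrahedra overestimate stiffness near
  incompressibility; calibrated compressibilities are therefore
  mesh-conditional, exactly as the physical study's were
  solver-conditional.
* The MR nucleus pathway assumes the nucleus is the largest
  hyperintense component; pathology or field inhomogeneity would break
  that assumption.
* `fit_cyl` fixes the cylinder height to the disc height; only the
  volume is constrained by measurement.
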