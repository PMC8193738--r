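# osteodisc

Image-based finite-element analysis of intervertebral disc bulge under
axial compression.

## The problem

When a bone–disc–bone specimen (an *osteodisc*) is compressed axially,
the intervertebral disc bulges radially outward. Quantifying that bulge
*in vitro* — by tracking ~1 mm glass fiducial markers glued to the disc
surface across micro-CT scans at successive compression steps — and
reproducing it *in silico* with specimen-specific finite-element models
is a complete validation loop for disc modelling: the same specimen
yields the measured loads and bulge that its own image-based model must
match. `osteodisc` implements both arms of that loop for synthetic
phantom specimens, so every stage is testable against exact ground truth
without any imaging data.

The package is aimed at researchers in musculoskeletal biomechanics and
biological image analysis who want a fully scripted, reproducible
version of this workflow: phantom generation, marker tracking, bulge
statistics, nonlinear FE with fibre-reinforced hyperelasticity, inverse
material calibration, and agreement scoring.

## The models at the core

* **Annulus fibrosus** — Gasser–Ogden–Holzapfel hyperelasticity with two
  discrete fibre families at ±20° to the transverse plane:
  `W = C10 (Ī₁ − 3) + Σ_f k1/(2 k2) [exp(k2 ⟨Ī₄f − 1⟩²) − 1] + (K/2)(J − 1)²`,
  with C10 = 0.25 MPa, k1 = 1.43 MPa, k2 = 1.63; compressed fibres carry
  no load (Macaulay bracket).
* **Nucleus pulposus** — Mooney–Rivlin, C10 = 0.07 MPa, C01 = 0.02 MPa.
* **Bone** — linear elastic with the modulus mapped element-by-element
  from the 0–255 normalised CT greyscale (3.6–842 MPa); PMMA endcaps at
  1035 MPa.
* **Calibration** — the bulk moduli K of annulus and nucleus are the
  unknowns; a bounded trust-region least-squares fit matches the FE
  reaction force to the measured peak load at each of the first three
  displacement steps, starting from the compressibility of water
  (1/2200 MPa⁻¹). Calibrated K values are reported as equivalent
  Poisson's ratios `ν = (3K − 4 C10)/(6K + 4 C10)`.
* **Agreement** — Lin's concordance correlation coefficient (population
  moments, Fisher-z CI) on loads and on per-marker bulge, after
  excluding markers in the lower tenth percentile of experimental bulge.

## Worked example

```r
library(osteodisc)

# a synthetic specimen at 82 um CT resolution (desk-scaled geometry)
cfg <- phantom_config(disc_radius = 5.5, disc_height = 9,
                      bone_height = 2.5, endcap_height = 2,
                      margin = 1, seed = 7)
ph  <- generate_phantom(cfg, render_mr = FALSE)

# in vitro arm: compress one step, register, track markers, measure bulge
def <- deform_phantom(ph, step = 1)
tf  <- register_rigid(def$ct, ph$ct, mode = "caudal")
mk0 <- detect_markers(ph$ct, 40)
mk1 <- detect_markers(def$ct, 40)
reg <- transform_points(invert_transform(tf),
                        as.matrix(mk1[, c("x", "y", "z")]))
mk1$x <- reg[, 1]; mk1$y <- reg[, 2]; mk1$z <- reg[, 3]
bulge <- compute_bulge(mk0, mk1, step = 1)
mean(bulge$bulge_mm)
#> [1] 0.2372542          # planted ground-truth mean: 0.2363031 mm

measure_applied_displacement(ph$ct, def$ct, transform = tf)
#> [1] 0.8377411          # planted platen displacement: 0.8537138 mm

# in silico arm: specimen-specific model and compressibility calibration
fe_cfg <- phantom_config(disc_radius = 5, disc_height = 6,
                         bone_height = 2.5, endcap_height = 2,
                         markers_per_line = 0,
                         step_displacements = rep(0.5, 4), seed = 3)
fe_ph  <- generate_phantom(fe_cfg, render = FALSE)
model  <- build_specimen_model(fe_ph, "std_cyl", target_edge = 2)

truth  <- material_params(K_af = 800, K_np = 1500)
loads  <- forward_load_curve(model, truth, c(0.5, 1.0, 1.5))
rec    <- tibble::tibble(displacement_mm = loads$displacement_mm,
                         peak_load_N = loads$load_N)
cal    <- calibrate(model, rec)
cal
#> <calibration_result> K_af = 801.8 MPa, K_np = 1496.5 MPa
#>   cost 0.046 N (0.01% of max load 850.5 N) -> success
#>   equivalent nu: AF 0.49761, NP 0.49995; termination: cost tolerance (10 evals)
```

The numbers mean: the measured mean step-1 bulge (0.237 mm) reproduces
the planted surface field (0.236 mm) to well under the 82 µm image
resolution; the endcap-based displacement recovers the planted platen
motion within one voxel; and the calibration, started from water
compressibility, recovers the generating bulk moduli with an RMS load
error around 0.01% of the maximum load — far inside the 10% success
criterion. (The two bulk moduli trade off against each other in a
three-load record, so individual K values are recovered only up to that
identifiability; the load curve itself is matched almost exactly.)

`run_study()` chains both arms over a cohort (six specimens × three
nucleus model types by default) and pools calibrations, regional bulge
statistics and concordance tables into one report; see
`vignettes/osteodisc-methods.Rmd` for the modelling assumptions, the
generator's calibration, and known limitations.

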