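#' Material parameter set for the osteodisc model
#'
#' Bundles the constitutive parameters of all tissues: the annulus fibrosus
#' (Gasser-Ogden-Holzapfel fibre-reinforced hyperelastic model with two
#' discrete fibre families at +/- `fibre_angle` to the transverse plane),
#' the nucleus pulposus (Mooney-Rivlin), greyscale-mapped linear elastic
#' bone, and the PMMA endcaps. The bulk moduli `K_af` and `K_np` are the
#' calibration targets; their default, 2200 MPa, is the bulk modulus of
#' water used as the calibration starting point. `af_c10_lin` is the
#' linearised small-strain shear reference of the annulus used only when
#' converting bulk moduli to equivalent Poisson's ratios.
#'
#' @param af_c10,af_k1,af_k2 annulus matrix stiffness (MPa), fibre stiffness
#'   (MPa) and fibre nonlinearity (dimensionless).
#' @param K_af,K_np annulus and nucleus bulk moduli (MPa).
#' @param fibre_angle_deg fibre inclination to the transverse plane (deg).
#' @param np_c10,np_c01 nucleus Mooney-Rivlin coefficients (MPa).
#' @param bone_slope,bone_intercept linear greyscale (0--255) to bone
#'   modulus map (MPa per greyscale unit, MPa).
#' @param bone_E_min,bone_E_max clamping bounds of the bone modulus (MPa).
#' @param bone_nu,pmma_nu Poisson's ratios.
#' @param pmma_E PMMA endcap modulus (MPa). 1035 MPa by default; 2450 is a
#'   documented alternative.
#' @param af_c10_lin linearised annulus shear reference (MPa) for
#'   equivalent-Poisson reporting.
#' @param volumetric_form `"quadratic"` for U(J) = K/2 (J-1)^2 or
#'   `"log"` for U(J) = K/4 (J^2-1) - K/2 ln J.
#' @return A `material_params` list.
#' @export
material_params <- function(af_c10 = 0.25, af_k1 = 1.43, af_k2 = 1.63,
                            K_af = 2200, fibre_angle_deg = 20,
                            np_c10 = 0.07, np_c01 = 0.02, K_np = 2200,
                            bone_slope = 842 / 255, bone_intercept = 0,
                            bone_E_min = 3.6, bone_E_max = 842,
                            bone_nu = 0.3, pmma_E = 1035, pmma_nu = 0.3,
                            af_c10_lin = 1.92,
                            volumetric_form = c("quadratic", "log")) {
  volumetric_form <- match.arg(volumetric_form)
  p <- list(af_c10 = af_c10, af_k1 = af_k1, af_k2 = af_k2, K_af = K_af,
            fibre_angle_deg = fibre_angle_deg, np_c10 = np_c10,
            np_c01 = np_c01, K_np = K_np, bone_slope = bone_slope,
            bone_intercept = bone_intercept, bone_E_min = bone_E_min,
            bone_E_max = bone_E_max, bone_nu = bone_nu, pmma_E = pmma_E,
            pmma_nu = pmma_nu, af_c10_lin = af_c10_lin,
            volumetric_form = volumetric_form)
  stopifnot(af_c10 > 0, af_k1 >= 0, af_k2 > 0, K_af > 0, np_c10 > 0,
            K_np > 0, fibre_angle_deg > 0, fibre_angle_deg < 90)
  structure(p, class = "material_params")
}

volform_code <- function(x) if (identical(x, "log")) 1L else 0L

check_F <- function(F) {
  F <- matrix(as.numeric(F), 3, 3)
  if (det(F) <= 0) stop("deformation gradient must have positive det(F)")
  F
}

#' Mooney-Rivlin point response
#'
#' Strain energy W = C10 (I1bar - 3) + C01 (I2bar - 3) + U(J), with the
#' isochoric invariants of `Fbar = J^(-1/3) F` and volumetric energy U(J).
#' The stress is the exact derivative of W and the tangent is consistent.
#'
#' @param F 3x3 deformation gradient (det > 0).
#' @param C10,C01 Mooney-Rivlin coefficients (MPa).
#' @param K bulk modulus (MPa).
#' @param volumetric_form volumetric energy form, see [material_params()].
#' @return List: `energy` (MPa), `S` (second Piola-Kirchhoff, 3x3), `P`
#'   (first Piola-Kirchhoff), `cauchy` (3x3), `tangent` (9x9 matrix
#'   `dP/dF`, column-major blocks).
#' @export
mooney_rivlin_energy_stress <- function(F, C10 = 0.07, C01 = 0.02, K = 2200,
                                        volumetric_form = "quadratic") {
  F <- check_F(F)
  ev <- cpp_material_eval(F, 1L, c(C10, C01, K, 0), matrix(0, 3, 2),
                          volform_code(volumetric_form))
  list(energy = ev$W, S = ev$S, P = ev$P, cauchy = ev$cauchy,
       tangent = ev$A)
}

#' Gasser-Ogden-Holzapfel point response
#'
#' Neo-Hookean matrix plus two tension-only exponential fibre families:
#' W = C10 (I1bar - 3) + sum_f k1/(2 k2) (exp(k2 <I4bar,f - 1>^2) - 1)
#' + U(J). The Macaulay bracket disables fibres whose pseudo-invariant is
#' compressive. Fibre directions are isochorically mapped (dispersion
#' parameter zero: two discrete families).
#'
#' @inheritParams mooney_rivlin_energy_stress
#' @param k1,k2 fibre stiffness (MPa) and dimensionless nonlinearity.
#' @param fibre_dirs 3x2 matrix of reference fibre directions (columns);
#'   non-unit columns are normalised with a warning.
#' @return As [mooney_rivlin_energy_stress()].
#' @export
goh_energy_stress <- function(F, C10 = 0.25, k1 = 1.43, k2 = 1.63, K = 2200,
                              fibre_dirs, volumetric_form = "quadratic") {
  F <- check_F(F)
  fibre_dirs <- matrix(as.numeric(fibre_dirs), 3)
  lens <- sqrt(colSums(fibre_dirs^2))
  if (any(abs(lens - 1) > 1e-8)) {
    warning("normalising non-unit fibre direction(s)")
    fibre_dirs <- sweep(fibre_dirs, 2, lens, "/")
  }
  ev <- cpp_material_eval(F, 2L, c(C10, k1, k2, K), fibre_dirs,
                          volform_code(volumetric_form))
  list(energy = ev$W, S = ev$S, P = ev$P, cauchy = ev$cauchy,
       tangent = ev$A)
}

#' Bone elastic modulus from CT greyscale
#'
#' Linear map E = slope * GS + intercept on the 0--255 normalised
#' greyscale, clamped to `[E_min, E_max]`. The default slope is chosen so
#' that GS = 255 maps to about 842 MPa with E_min = 3.6 MPa, reproducing
#' the range of the calibrated bovine relationship; the exact published
#' coefficients are not restated here, so treat the default as a
#' plausible stand-in and override from configuration where a calibrated
#' map is available.
#'
#' @param greyscale numeric in \[0, 255\].
#' @param slope,intercept map coefficients (MPa/unit, MPa).
#' @param E_min,E_max clamp bounds (MPa).
#' @return Modulus in MPa.
#' @export
bone_modulus_from_greyscale <- function(greyscale, slope = 842 / 255,
                                        intercept = 0, E_min = 3.6,
                                        E_max = 842) {
  if (any(greyscale < 0 | greyscale > 255))
    stop("greyscale values must lie in [0, 255]")
  pmin(pmax(slope * greyscale + intercept, E_min), E_max)
}

#' Equivalent Poisson's ratio of a nearly incompressible tissue
#'
#' Converts a calibrated bulk modulus K and small-strain shear reference
#' C10 (shear modulus G = 2 C10) into the Poisson's ratio of the
#' linear-equivalent material, nu = (3K - 4 C10) / (6K + 4 C10). A
#' reporting convenience, not a model input; strictly increasing in K and
#' bounded above by 0.5.
#'
#' @param K bulk modulus (MPa).
#' @param C10 shear reference (MPa): 0.07 for the nucleus, the linearised
#'   1.92 for the annulus.
#' @return Equivalent Poisson's ratio.
#' @export
equivalent_poisson <- function(K, C10) {
  stopifnot(all(K > 0), all(C10 > 0))
  (3 * K - 4 * C10) / (6 * K + 4 * C10)
}

#' Linearised small-strain shear reference of the annulus
#'
#' Simulates uniaxial tension of the annulus constitutive model along a
#' direction in the fibre plane (the circumferential axis) at strains up to
#' `strain_max`, with traction-free lateral faces and near-incompressible
#' volumetric response, fits the small-strain slope E_eff through the
#' origin, and converts it to an equivalent C10 via the incompressible
#' linear relations E = 3 G and G = 2 C10, i.e. C10_lin = E_eff / 6.
#'
#' @param params a [material_params()] (annulus entries used).
#' @param strain_max largest strain in the fit (default 0.02).
#' @param n number of strain samples.
#' @return `C10_lin` in MPa, with attributes `slope` (E_eff), `mode` and
#'   `strains`.
#' @export
linearize_af_shear <- function(params = material_params(),
                               strain_max = 0.02, n = 8) {
  ang <- params$fibre_angle_deg * pi / 180
  fib <- cbind(c(cos(ang), 0, sin(ang)), c(cos(ang), 0, -sin(ang)))
  K <- 2000 * max(params$af_c10, 1e-6)  # near-incompressible for the fit
  lat <- c(1, 1)
  sigma11 <- function(lambda) {
    # lateral stretches from zero transverse Cauchy stress
    f <- function(l) {
      Fm <- diag(c(lambda, l[1], l[2]))
      s <- goh_energy_stress(Fm, params$af_c10, params$af_k1, params$af_k2,
                             K, fib, params$volumetric_form)$cauchy
      c(s[2, 2], s[3, 3])
    }
    for (it in 1:60) {
      r <- f(lat)
      if (max(abs(r)) < 1e-10) break
      h <- 1e-7
      Jm <- cbind((f(lat + c(h, 0)) - r) / h, (f(lat + c(0, h)) - r) / h)
      lat <- lat - solve(Jm, r)
    }
    Fm <- diag(c(lambda, lat[1], lat[2]))
    goh_energy_stress(Fm, params$af_c10, params$af_k1, params$af_k2, K,
                      fib, params$volumetric_form)$cauchy[1, 1]
  }
  strains <- seq(strain_max / n, strain_max, length.out = n)
  stress <- vapply(1 + strains, sigma11, numeric(1))
  slope <- sum(stress * strains) / sum(strains^2)  # fit through origin
  out <- slope / 6
  attr(out, "slope") <- slope
  attr(out, "mode") <- "uniaxial, circumferential, traction-free lateral"
  attr(out, "strains") <- strains
  out
}
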