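#' Phantom specimen configuration
#'
#' Describes a synthetic osteodisc: a cylindrical intervertebral disc between
#' two bone blocks potted in PMMA endcaps, carrying 40 surface fiducial
#' markers (8 craniocaudal lines at 45 degree intervals, 5 markers per line)
#' and PinPoint-style multi-modality reference markers in the endcaps. The
#' generator emulates the imaging and loading protocol of the physical rig:
#' an 82 um isotropic CT grid, a coarse anisotropic MR-like grid, a 50 N
#' preload, and four axial compression steps of about 0.89 +/- 0.14 mm each,
#' with an anterior-biased radial bulge field planted on the disc surface.
#'
#' Distribution-valued entries (`np_volume_fraction`, `step_displacements`)
#' may be left `NULL`, in which case [generate_phantom()] samples them:
#' the nucleus volume fraction uniformly on \[0.07, 0.17\] of disc volume and
#' the four platen steps from N(0.89, 0.14^2) mm. The per-step planted bulge
#' distribution defaults to the cumulative means/SDs 0.24/0.48/0.67/0.84 mm
#' and 0.11/0.22/0.30/0.36 mm across markers and specimens.
#'
#' @param voxel_spacing CT voxel size, mm (isotropic; default 0.082).
#' @param disc_radius,disc_height disc cylinder dimensions, mm.
#' @param bone_height bone stock per side, mm (about 15 in the physical prep).
#' @param endcap_height PMMA endcap thickness per side, mm.
#' @param bone_radius_frac,endcap_radius_frac bone/endcap radii as fractions
#'   of the disc radius.
#' @param np_volume_fraction nucleus-to-disc volume fraction in (0, 1), or
#'   `NULL` to sample per specimen.
#' @param np_center_offset transverse (x, y) offset of the nucleus axis, mm
#'   (+y anterior).
#' @param n_marker_lines,markers_per_line marker layout (8 x 5 = 40 default).
#' @param marker_diameter glass marker diameter, mm.
#' @param pinpoint_diameter endcap reference marker diameter, mm.
#' @param step_displacements length-4 numeric of per-step platen
#'   displacements, mm, or `NULL` to sample.
#' @param bulge_profile list with `mean` and `sd`, the cumulative planted
#'   marker-bulge distribution per step (mm).
#' @param anterior_bias relative amplitude of the anterior-minus-posterior
#'   cosine modulation of the bulge field.
#' @param specimen_cv coefficient of variation of the per-specimen bulge
#'   amplitude factor.
#' @param azimuthal_mode_sd SD of the random azimuthal Fourier-mode
#'   coefficients (orders 2 and 3) of the bulge field.
#' @param load_curve_params named numeric `(preload, linear, cubic)`: the
#'   synthetic stiffening load model L(d) = preload + linear d + cubic d^3
#'   (N, N/mm, N/mm^3).
#' @param greyscale_levels named list of CT tissue intensities plus
#'   `bone_texture` (relative amplitude of the intra-bone intensity
#'   modulation) and `noise_sd` (additive Gaussian noise SD; default 5% of
#'   the bone level).
#' @param mr list describing the MR-like acquisition: `spacing` (mm),
#'   `levels` (tissue intensities; NP brighter than AF), `noise_sd`,
#'   `max_angle_deg` and `max_translation` of the random pose offset
#'   relative to the CT frame.
#' @param rigid_perturbation list with `max_angle_deg` and `max_translation`
#'   (mm): bounds of the random whole-specimen rigid motion applied at each
#'   compression step to exercise registration.
#' @param margin padding of the image field of view around the specimen, mm.
#' @param seed integer seed; the same seed reproduces bit-identical volumes.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(voxel_spacing = 0.082,
                           disc_radius = 13, disc_height = 9,
                           bone_height = 15, endcap_height = 4,
                           bone_radius_frac = 0.95, endcap_radius_frac = 1.15,
                           np_volume_fraction = NULL,
                           np_center_offset = c(0, 1),
                           n_marker_lines = 8L, markers_per_line = 5L,
                           marker_diameter = 1.0,
                           pinpoint_diameter = 3.0,
                           step_displacements = NULL,
                           bulge_profile = list(
                             mean = c(0.24, 0.48, 0.67, 0.84),
                             sd   = c(0.11, 0.22, 0.30, 0.36)),
                           anterior_bias = 0.25,
                           specimen_cv = 0.15,
                           azimuthal_mode_sd = 0.189,
                           load_curve_params = c(preload = 50, linear = 200,
                                                 cubic = 12),
                           greyscale_levels = list(
                             background = 5, disc = 60, np = 62, bone = 200,
                             endcap = 120, marker = 255, pinpoint = 255,
                             bone_texture = 0.08, noise_sd = 10),
                           mr = list(
                             spacing = c(0.3, 0.3, 1.0),
                             levels = list(background = 5, disc = 80,
                                           np = 200, bone = 30, endcap = 50,
                                           pinpoint = 255, noise_sd = 4),
                             max_angle_deg = 2, max_translation = 1),
                           rigid_perturbation = list(max_angle_deg = 1,
                                                     max_translation = 0.5),
                           margin = 1.5,
                           seed = 1L) {
  cfg <- list(voxel_spacing = voxel_spacing, disc_radius = disc_radius,
              disc_height = disc_height, bone_height = bone_height,
              endcap_height = endcap_height,
              bone_radius_frac = bone_radius_frac,
              endcap_radius_frac = endcap_radius_frac,
              np_volume_fraction = np_volume_fraction,
              np_center_offset = np_center_offset,
              n_marker_lines = as.integer(n_marker_lines),
              markers_per_line = as.integer(markers_per_line),
              marker_diameter = marker_diameter,
              pinpoint_diameter = pinpoint_diameter,
              step_displacements = step_displacements,
              bulge_profile = bulge_profile,
              anterior_bias = anterior_bias, specimen_cv = specimen_cv,
              azimuthal_mode_sd = azimuthal_mode_sd,
              load_curve_params = load_curve_params,
              greyscale_levels = greyscale_levels, mr = mr,
              rigid_perturbation = rigid_perturbation,
              margin = margin, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  lens <- c(cfg$voxel_spacing, cfg$disc_radius, cfg$disc_height,
            cfg$bone_height, cfg$endcap_height, cfg$marker_diameter)
  if (any(lens <= 0)) stop("all phantom lengths must be positive")
  if (!is.null(cfg$np_volume_fraction) &&
      (cfg$np_volume_fraction <= 0 || cfg$np_volume_fraction >= 1))
    stop("np_volume_fraction must lie in (0, 1)")
  if (cfg$n_marker_lines < 0 || cfg$markers_per_line < 0)
    stop("marker counts must be non-negative")
  if (cfg$n_marker_lines > 0 && cfg$markers_per_line > 0) {
    if (cfg$marker_diameter < 3 * cfg$voxel_spacing)
      stop("marker diameter below 3 voxels: markers would be undetectable")
    axial_gap <- cfg$disc_height / (cfg$markers_per_line + 1)
    if (axial_gap < cfg$marker_diameter)
      stop("markers on a line overlap: axial spacing ",
           signif(axial_gap, 3), " mm < marker diameter")
    if (cfg$n_marker_lines > 1) {
      arc <- 2 * pi * cfg$disc_radius / cfg$n_marker_lines
      if (arc < cfg$marker_diameter)
        stop("markers on adjacent lines overlap")
    }
  }
  invisible(cfg)
}

# zone labels in counter-clockwise order starting anterior (+y);
# line j sits at azimuth 90 + 45 j degrees
zone_names <- c("A", "AL", "L", "PL", "P", "PR", "R", "AR")

#' Map transverse azimuth to disc zone
#'
#' Zones divide the disc into 8 equal 45 degree sectors about the disc axis
#' with `A` (anterior) centred on +y: `A, AL, L, PL, P, PR, R, AR`
#' counter-clockwise.
#'
#' @param theta azimuth in radians (`atan2(y, x)` about the disc axis).
#' @return Character vector of zone labels.
#' @export
zone_from_azimuth <- function(theta) {
  sector <- round((theta - pi / 2) / (pi / 4)) %% 8
  zone_names[sector + 1]
}
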