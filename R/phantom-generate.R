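#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# derived geometry of the specimen stack (specimen frame: z = 0 at the
# outer face of the bottom endcap, +z cranial, +y anterior)
phantom_geometry <- function(cfg) {
  e <- cfg$endcap_height; b <- cfg$bone_height; h <- cfg$disc_height
  R <- cfg$disc_radius
  L <- 2 * e + 2 * b + h
  list(e = e, b = b, h = h, R = R,
       Rb = cfg$bone_radius_frac * R, Re = cfg$endcap_radius_frac * R,
       z_d0 = e + b, z_d1 = e + b + h, L = L,
       center = c(0, 0, L / 2))
}

rot_rodrigues <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# azimuthal modulation of the planted bulge field
bulge_modulation <- function(theta, bias, modes) {
  g <- 1 + bias * cos(theta - pi / 2) +
    modes[1] * cos(2 * theta) + modes[2] * sin(2 * theta) +
    modes[3] * cos(3 * theta) + modes[4] * sin(3 * theta)
  pmax(g, 0.05)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  expr
}

#' Generate a synthetic osteodisc phantom
#'
#' Builds the full ground truth for one synthetic specimen (marker
#' trajectories over the preload state and four compression steps, planted
#' bulge field, platen displacements, load record, rigid per-step
#' perturbations, nucleus geometry) and renders the preloaded CT volume and
#' the coarse MR-like volume. Deformed step volumes are rendered on demand
#' by [deform_phantom()]. All randomness derives from `config$seed`; the
#' same seed yields bit-identical volumes.
#'
#' @param config a [phantom_config()].
#' @param render if `FALSE`, skip volume rendering and return ground truth
#'   only (used for fast cohort statistics).
#' @param render_mr if `FALSE`, skip the MR-like volume (CT-only studies).
#' @return An `osteodisc_phantom` list with elements `config`, `ct`
#'   (preloaded CT [voxel_volume()]), `mr` (MR-like [voxel_volume()]) and
#'   `truth` (ground-truth list; see Details).
#' @details `truth` carries: `markers`, a tibble of exact marker centroids
#' per step in the specimen (preloaded CT) frame; `applied`, per-step and
#' cumulative platen displacements (mm); `loads`, the synthetic
#' load--displacement record (N); `perturbations`, the per-step rigid motion
#' applied to the scanned specimen; `pinpoints`, endcap reference marker
#' positions; `np_fraction`, `np_radius` and `np_center`; the bulge-field
#' parameters; and `endcap_distance`, the inner-surface distance per step.
#' @export
generate_phantom <- function(config, render = TRUE, render_mr = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  g <- phantom_geometry(cfg)
  with_preserved_rng({
    set.seed(cfg$seed)
    f_np <- cfg$np_volume_fraction %||% runif(1, 0.07, 0.17)
    steps <- cfg$step_displacements %||% pmax(rnorm(4, 0.89, 0.14), 0.4)
    eps_s <- pmax(rnorm(4, 1, cfg$specimen_cv), 0.3)
    modes <- rnorm(4, 0, cfg$azimuthal_mode_sd)
    perturbations <- lapply(1:4, function(s) {
      ang <- runif(1, 0.1, cfg$rigid_perturbation$max_angle_deg) * pi / 180
      axis <- rnorm(3)
      tr <- runif(3, -cfg$rigid_perturbation$max_translation,
                  cfg$rigid_perturbation$max_translation)
      list(R = rot_rodrigues(axis, ang), t = tr)
    })
    mr_ang <- runif(1, 0.1, cfg$mr$max_angle_deg) * pi / 180
    mr_pose <- list(R = rot_rodrigues(rnorm(3), mr_ang),
                    t = runif(3, -cfg$mr$max_translation,
                              cfg$mr$max_translation))
    bone_phases <- runif(3, 0, 2 * pi)
    noise_seeds <- sample.int(2^30, 6)

    cum <- cumsum(steps)
    m <- cfg$markers_per_line
    nl <- cfg$n_marker_lines
    zmean <- if (m > 0) mean(sin(pi * (1:m) / (m + 1))) else 1
    A_s <- cfg$bulge_profile$mean / zmean * eps_s  # cumulative amplitudes

    r_mark <- cfg$marker_diameter / 2
    markers <- NULL
    if (m > 0 && nl > 0) {
      lay <- expand.grid(line = 0:(nl - 1), level = 0:(m - 1))
      theta <- pi / 2 + 2 * pi * lay$line / nl
      zeta <- g$h * (lay$level + 1) / (m + 1)
      r0 <- g$R + 0.35 * r_mark
      gmod <- bulge_modulation(theta, cfg$anterior_bias, modes)
      rows <- lapply(0:4, function(s) {
        if (s == 0) {
          rr <- r0; zz <- g$z_d0 + zeta
        } else {
          rr <- r0 + A_s[s] * gmod * sin(pi * zeta / g$h)
          zz <- g$z_d0 + zeta * (g$h - cum[s]) / g$h
        }
        tibble::tibble(
          marker_id = lay$line * m + lay$level + 1L,
          line = as.integer(lay$line), level = as.integer(lay$level),
          zone = zone_from_azimuth(theta), step = s,
          x = rr * cos(theta), y = rr * sin(theta), z = zz)
      })
      markers <- dplyr::arrange(dplyr::bind_rows(rows), .data$step,
                                .data$marker_id)
    } else {
      markers <- tibble::tibble(marker_id = integer(), line = integer(),
                                level = integer(), zone = character(),
                                step = integer(), x = numeric(),
                                y = numeric(), z = numeric())
    }

    pin_r <- 0.55 * g$Re
    pin_az_bot <- c(10, 95, 200, 290) * pi / 180
    pin_az_top <- c(35, 120, 215, 300) * pi / 180
    pinpoints <- tibble::tibble(
      pin_id = 1:8,
      endcap = rep(c("bottom", "top"), each = 4),
      x = pin_r * cos(c(pin_az_bot, pin_az_top)),
      y = pin_r * sin(c(pin_az_bot, pin_az_top)),
      z = rep(c(g$e / 2, g$L - g$e / 2), each = 4))

    lc <- cfg$load_curve_params
    loads <- tibble::tibble(
      step = 0:4, displacement_mm = c(0, cum),
      peak_load_N = lc[["preload"]] + lc[["linear"]] * c(0, cum) +
        lc[["cubic"]] * c(0, cum)^3)

    truth <- list(
      markers = markers, pinpoints = pinpoints,
      applied = tibble::tibble(step = 1:4, displacement_mm = steps,
                               cumulative_mm = cum),
      loads = loads,
      perturbations = perturbations, mr_pose = mr_pose,
      np_fraction = f_np, np_radius = g$R * sqrt(f_np),
      np_center = cfg$np_center_offset,
      bulge = list(A = A_s, modes = modes, bias = cfg$anterior_bias,
                   specimen_factor = eps_s),
      bone_phases = bone_phases, noise_seeds = noise_seeds,
      endcap_distance = 2 * g$b + g$h - c(0, cum),
      geometry = g)

    ph <- structure(list(config = cfg, truth = truth, ct = NULL, mr = NULL),
                    class = "osteodisc_phantom")
    if (render) {
      ph$ct <- render_phantom_volume(ph, step = 0, modality = "CT")
      if (render_mr)
        ph$mr <- render_phantom_volume(ph, step = 0, modality = "MR")
    }
    ph
  })
}

#' @export
print.osteodisc_phantom <- function(x, ...) {
  g <- x$truth$geometry
  cat(sprintf(
    "<osteodisc_phantom> disc R %.1f mm, h %.1f mm, NP %.1f%% of disc volume\n",
    g$R, g$h, 100 * x$truth$np_fraction))
  cat(sprintf("  %d markers, steps %s mm (cumulative)\n",
              nrow(dplyr::filter(x$truth$markers, .data$step == 0)),
              paste(signif(x$truth$applied$cumulative_mm, 3), collapse = ", ")))
  if (!is.null(x$ct)) print(x$ct)
  invisible(x)
}

# Render one volume of the phantom. step 0 = preloaded (identity pose for
# CT; MR has its own pose offset); steps 1..4 apply the cumulative
# compression, the planted bulge field, and the per-step rigid perturbation.
render_phantom_volume <- function(phantom, step = 0,
                                  modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  cfg <- phantom$config
  tr <- phantom$truth
  g <- tr$geometry
  delta <- if (step == 0) 0 else tr$applied$cumulative_mm[step]
  A <- if (step == 0) 0 else tr$bulge$A[step]

  if (modality == "CT") {
    sp <- rep(cfg$voxel_spacing, 3)
    lv <- cfg$greyscale_levels
    pose <- if (step == 0) list(R = diag(3), t = c(0, 0, 0))
            else tr$perturbations[[step]]
    noise_seed <- tr$noise_seeds[step + 1]
  } else {
    sp <- cfg$mr$spacing
    lv <- cfg$mr$levels
    lv$bone_texture <- 0
    lv$noise_sd <- cfg$mr$levels$noise_sd
    pose <- tr$mr_pose
    noise_seed <- tr$noise_seeds[6]
  }

  m <- cfg$margin
  half <- g$Re + m
  nx <- as.integer(floor(2 * half / sp[1])) + 1L
  ny <- as.integer(floor(2 * half / sp[2])) + 1L
  nz <- as.integer(floor((g$L + 2 * m) / sp[3])) + 1L
  org <- c(-half, -half, -m)
  vol <- array(lv$background, dim = c(nx, ny, nz))

  c0 <- g$center
  RT <- t(pose$R)
  xs <- org[1] + (0:(nx - 1)) * sp[1]
  ys <- org[2] + (0:(ny - 1)) * sp[2]
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  spr <- mean(sp[1:2])
  frac1 <- function(d, s) pmin(pmax(0.5 + d / s, 0), 1)
  gmod_of <- function(theta) bulge_modulation(theta, tr$bulge$bias,
                                              tr$bulge$modes)
  ph <- tr$bone_phases
  tex <- function(px, py, pz_mat) {
    1 + lv$bone_texture * sin(2 * pi * px / 3.1 + ph[1]) *
      sin(2 * pi * py / 2.7 + ph[2]) * sin(2 * pi * pz_mat / 3.9 + ph[3])
  }

  identity_pose <- all(pose$R == diag(3)) && all(pose$t == 0)
  for (k in seq_len(nz)) {
    zw <- org[3] + (k - 1) * sp[3]
    if (identity_pose) {
      px <- X; py <- Y; pz <- zw
      pzm <- matrix(zw, nx, ny)
    } else {
      dx <- X - c0[1] - pose$t[1]
      dy <- Y - c0[2] - pose$t[2]
      dz <- zw - c0[3] - pose$t[3]
      px <- RT[1, 1] * dx + RT[1, 2] * dy + RT[1, 3] * dz + c0[1]
      py <- RT[2, 1] * dx + RT[2, 2] * dy + RT[2, 3] * dz + c0[2]
      pzm <- RT[3, 1] * dx + RT[3, 2] * dy + RT[3, 3] * dz + c0[3]
      pz <- pzm
    }
    r <- sqrt(px^2 + py^2)
    v <- vol[, , k]

    paint_cyl <- function(v, Rc, z0, z1, I, zmat_off = 0, textured = FALSE) {
      fz <- frac1(pmin(pz - z0, z1 - pz), sp[3])
      frad <- frac1(Rc - r, spr)
      f <- frad * fz
      I_eff <- if (textured) I * tex(px, py, pzm + zmat_off) else I
      v * (1 - f) + I_eff * f
    }
    # bottom endcap and bone (static)
    v <- paint_cyl(v, g$Re, 0, g$e, lv$endcap)
    v <- paint_cyl(v, g$Rb, g$e, g$z_d0, lv$bone,
                   textured = lv$bone_texture > 0)
    # top bone and endcap (shifted down by the cumulative displacement)
    v <- paint_cyl(v, g$Rb, g$z_d1 - delta, g$z_d1 - delta + g$b, lv$bone,
                   zmat_off = delta, textured = lv$bone_texture > 0)
    v <- paint_cyl(v, g$Re, g$z_d1 - delta + g$b, g$L - delta, lv$endcap,
                   zmat_off = delta)
    # disc with bulged lateral surface
    hdef <- g$h - delta
    zeta <- pmin(pmax((pz - g$z_d0) * g$h / hdef, 0), g$h)
    theta <- atan2(py, px)
    sinprof <- sin(pi * zeta / g$h)
    Rdef <- g$R + A * gmod_of(theta) * sinprof
    fz <- frac1(pmin(pz - g$z_d0, (g$z_d1 - delta) - pz), sp[3])
    f <- frac1(Rdef - r, spr) * fz
    v <- v * (1 - f) + lv$disc * f
    # nucleus (slight CT contrast; bright on MR)
    rnp_loc <- sqrt((px - tr$np_center[1])^2 + (py - tr$np_center[2])^2)
    Rnp <- tr$np_radius * (1 + A * gmod_of(theta) * sinprof / g$R)
    f <- frac1(Rnp - rnp_loc, spr) * fz
    v <- v * (1 - f) + lv$np * f
    vol[, , k] <- v
  }

  out <- voxel_volume(vol, sp, org, modality)
  # spheres: glass markers (CT only) and PinPoint markers (both modalities)
  blend_sphere <- function(out, centre_spec, radius, I) {
    cw <- as.vector(pose$R %*% (centre_spec - c0)) + c0 + pose$t
    blend_sphere_world(out, cw, radius, I)
  }
  if (modality == "CT" && nrow(tr$markers) > 0) {
    mk <- dplyr::filter(tr$markers, .data$step == !!step)
    for (i in seq_len(nrow(mk)))
      out <- blend_sphere(out, c(mk$x[i], mk$y[i], mk$z[i]),
                          cfg$marker_diameter / 2, lv$marker)
  }
  pp <- tr$pinpoints
  for (i in seq_len(nrow(pp))) {
    ctr <- c(pp$x[i], pp$y[i], pp$z[i])
    if (pp$endcap[i] == "top") ctr[3] <- ctr[3] - delta
    out <- blend_sphere(out, ctr, cfg$pinpoint_diameter / 2, lv$pinpoint)
  }
  if (lv$noise_sd > 0) {
    out$values <- with_preserved_rng({
      set.seed(noise_seed)
      out$values + rnorm(length(out$values), 0, lv$noise_sd)
    })
  }
  out
}

# anti-aliased sphere blended into a volume at a world-frame centre
blend_sphere_world <- function(vol, centre, radius, I) {
  sp <- vol$spacing
  lo <- pmax(1L, as.integer(floor((centre - radius - vol$origin) / sp)) - 1L)
  hi <- pmin(dim(vol$values),
             as.integer(ceiling((centre + radius - vol$origin) / sp)) + 2L)
  if (any(lo > hi)) return(vol)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  xs <- vol$origin[1] + (ix - 1) * sp[1] - centre[1]
  ys <- vol$origin[2] + (iy - 1) * sp[2] - centre[2]
  zs <- vol$origin[3] + (iz - 1) * sp[3] - centre[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  f <- pmin(pmax(0.5 + (radius - sqrt(d2)) / mean(sp), 0), 1)
  blk <- vol$values[ix, iy, iz]
  vol$values[ix, iy, iz] <- blk * (1 - f) + I * f
  vol
}

#' Render a deformed compression-step volume
#'
#' Applies the analytic deformation of step `step` (axial compression of the
#' disc between rigid bone blocks plus the planted anterior-biased radial
#' bulge), moves the markers with the disc surface, applies the step's
#' random whole-specimen rigid perturbation, and re-voxelizes at CT
#' resolution.
#'
#' @param phantom an `osteodisc_phantom` from [generate_phantom()].
#' @param step compression step, 1 to 4.
#' @return A list with `ct` (the deformed CT [voxel_volume()]), `step`,
#'   `markers` (exact post-deformation centroids, specimen frame),
#'   `perturbation` (the planted rigid motion) and `applied_mm` (cumulative
#'   platen displacement).
#' @export
deform_phantom <- function(phantom, step) {
  stopifnot(inherits(phantom, "osteodisc_phantom"))
  if (!step %in% 1:4) stop("step must be in 1..4")
  vol <- render_phantom_volume(phantom, step = step, modality = "CT")
  list(ct = vol, step = step,
       markers = dplyr::filter(phantom$truth$markers, .data$step == !!step),
       perturbation = phantom$truth$perturbations[[step]],
       applied_mm = phantom$truth$applied$cumulative_mm[step])
}

#' Synthetic load--displacement record
#'
#' Returns the specimen's load record: monotone, convex peak load versus
#' cumulative applied displacement through the four compression steps, with
#' a 50 N preload at step 0. In `"fe"` mode the loads are instead computed
#' by the forward finite-element model (used for calibration-recovery
#' studies).
#'
#' @param phantom an `osteodisc_phantom`.
#' @param noise_sd additive load noise SD (N).
#' @param mode `"analytic"` (default cubic-monotone model) or `"fe"`.
#' @param model,materials required in `"fe"` mode: a specimen model and
#'   [material_params()] passed to [forward_load_curve()].
#' @return A tibble `(step, displacement_mm, peak_load_N)`.
#' @export
generate_load_record <- function(phantom, noise_sd = 0,
                                 mode = c("analytic", "fe"),
                                 model = NULL, materials = NULL) {
  mode <- match.arg(mode)
  rec <- phantom$truth$loads
  if (mode == "fe") {
    if (is.null(model) || is.null(materials))
      stop("fe mode requires `model` and `materials`")
    fl <- forward_load_curve(model, materials,
                             phantom$truth$applied$cumulative_mm[1:3])
    rec <- tibble::tibble(step = c(0L, fl$step),
                          displacement_mm = c(0, fl$displacement_mm),
                          peak_load_N = c(
                            phantom$config$load_curve_params[["preload"]],
                            fl$load_N))
  }
  if (noise_sd > 0)
    rec$peak_load_N <- rec$peak_load_N + rnorm(nrow(rec), 0, noise_sd)
  rec
}

#' Label volume of the phantom geometry
#'
#' Renders the preloaded specimen as an integer label volume in the
#' specimen frame (no markers, no pose perturbation): 0 background,
#' 1 bottom endcap, 2 caudal bone, 3 annulus fibrosus, 4 nucleus pulposus,
#' 5 cranial bone, 6 top endcap. Used to build the finite-element mesh.
#'
#' @param phantom an `osteodisc_phantom`.
#' @param spacing label grid spacing in mm (default 0.5).
#' @return A [voxel_volume()] of integer labels.
#' @export
phantom_labels <- function(phantom, spacing = 0.5) {
  cfg <- phantom$config
  g <- phantom$truth$geometry
  m <- cfg$margin
  half <- g$Re + m
  sp <- rep_len(spacing, 3)
  nx <- as.integer(floor(2 * half / sp[1])) + 1L
  ny <- as.integer(floor(2 * half / sp[2])) + 1L
  nz <- as.integer(floor((g$L + 2 * m) / sp[3])) + 1L
  org <- c(-half, -half, -m)
  xs <- org[1] + (0:(nx - 1)) * sp[1]
  ys <- org[2] + (0:(ny - 1)) * sp[2]
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  rnp <- sqrt((X - phantom$truth$np_center[1])^2 +
              (Y - phantom$truth$np_center[2])^2)
  lab <- array(0L, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    z <- org[3] + (k - 1) * sp[3]
    sl <- matrix(0L, nx, ny)
    if (z >= 0 && z < g$e) sl[r <= g$Re] <- 1L
    else if (z >= g$e && z < g$z_d0) sl[r <= g$Rb] <- 2L
    else if (z >= g$z_d0 && z < g$z_d1) {
      sl[r <= g$R] <- 3L
      sl[sl == 3L & rnp <= phantom$truth$np_radius] <- 4L
    } else if (z >= g$z_d1 && z < g$z_d1 + g$b) sl[r <= g$Rb] <- 5L
    else if (z >= g$z_d1 + g$b && z <= g$L) sl[r <= g$Re] <- 6L
    lab[, , k] <- sl
  }
  voxel_volume(lab, sp, org, "CT")
}

#' Nucleus-to-disc volume fraction measured on voxel masks
#'
#' Renders partial-volume coverage masks of the whole disc and of the
#' nucleus at the given grid spacing (restricted to the disc bounding box)
#' and returns the ratio of their volumes.
#'
#' @param phantom an `osteodisc_phantom`.
#' @param spacing mask grid spacing in mm; defaults to the CT voxel size.
#' @return The measured nucleus volume fraction (dimensionless).
#' @export
np_volume_fraction <- function(phantom, spacing = NULL) {
  cfg <- phantom$config
  g <- phantom$truth$geometry
  sp <- spacing %||% cfg$voxel_spacing
  half <- g$R + 2 * sp
  nx <- as.integer(floor(2 * half / sp)) + 1L
  xs <- -half + (0:(nx - 1)) * sp
  X <- matrix(xs, nx, nx)
  Y <- matrix(xs, nx, nx, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  rnp <- sqrt((X - phantom$truth$np_center[1])^2 +
              (Y - phantom$truth$np_center[2])^2)
  frac1 <- function(d, s) pmin(pmax(0.5 + d / s, 0), 1)
  disc_area <- sum(frac1(g$R - r, sp))
  np_area <- sum(frac1(phantom$truth$np_radius - rnp, sp))
  # both cylinders span the full disc height, so the height factor cancels
  # up to the identical axial partial-volume profile
  np_area / disc_area
}
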