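#' Rigid transforms
#'
#' A rigid (rotation + translation) map of world coordinates,
#' `y -> R (y - center) + center + t`. [register_rigid()] returns the
#' transform taking points from the fixed frame into the moving scan;
#' its inverse maps detected coordinates in the moving scan back into the
#' fixed (preloaded) frame.
#'
#' @param R 3x3 rotation matrix (det = +1).
#' @param t translation, mm.
#' @param center rotation centre, mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  if (abs(det(R) - 1) > 1e-6 || max(abs(t(R) %*% R - diag(3))) > 1e-6)
    stop("R must be a proper rotation matrix")
  structure(list(R = R, t = as.numeric(t), center = as.numeric(center)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param tf a `rigid_transform`.
#' @param pts n x 3 matrix of points (mm).
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, tf$center, "-") %*% t(tf$R), 2, tf$center + tf$t, "+")
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), -as.vector(t(tf$R) %*% tf$t), tf$center)
}

#' @rdname rigid_transform
#' @param tf2 transform applied first (composition `tf` after `tf2`).
#' @export
compose_transforms <- function(tf, tf2) {
  # x -> tf(tf2(x)); fold into a single transform about tf2's centre
  Rn <- tf$R %*% tf2$R
  c2 <- tf2$center
  # tf2: R2 (x - c2) + c2 + t2 ; then tf: R1 (y - c1) + c1 + t1
  y0 <- transform_points(tf, matrix(c2 + tf2$t, 1))
  rigid_transform(Rn, as.vector(y0) - c2, c2)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$R)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%s) mm\n",
              ang, paste(signif(x$t, 4), collapse = ", ")))
  invisible(x)
}

rotvec_to_matrix <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(diag(3))
  rot_rodrigues(v / ang, ang)
}

#' Rigidly register a moving volume to a fixed volume
#'
#' Two modes mirror the study protocol. `"caudal"` minimises the
#' mean-squared intensity difference over a region of interest covering the
#' most caudal (lowest-z) bone, in a multi-resolution scheme (4x, 2x, 1x
#' pooling) with derivative-free simplex refinement at each level; it is
#' used to register compression-step CT volumes to the preloaded CT.
#' `"pinpoint"` detects the bright endcap reference markers in both volumes
#' and solves the closed-form least-squares (Kabsch) alignment of the two
#' point constellations; it is used for the MR to CT registration.
#'
#' @param moving,fixed [voxel_volume()] objects with overlapping anatomy.
#' @param mode `"caudal"` or `"pinpoint"`.
#' @param roi_fraction caudal mode: fraction of the occupied z-extent
#'   (from the bottom) used as the registration region.
#' @param bone_threshold caudal mode: intensity threshold selecting bone in
#'   the fixed volume, or `NULL` for `0.6 * max`.
#' @param max_points caudal mode: maximum ROI sample points per level.
#' @param maxit caudal mode: simplex iterations per resolution level.
#' @param max_residual registration is flagged failed when the final
#'   residual (RMS intensity difference, or RMS point mismatch in mm)
#'   exceeds this.
#' @param pinpoint_diameter pinpoint mode: reference marker diameter, mm.
#' @return A [rigid_transform()] mapping fixed-frame points into the moving
#'   scan, with attributes `residual` (RMS metric at the optimum) and
#'   `success`.
#' @export
register_rigid <- function(moving, fixed, mode = c("caudal", "pinpoint"),
                           roi_fraction = 0.4, bone_threshold = NULL,
                           max_points = 40000, max_residual = Inf,
                           maxit = 300, pinpoint_diameter = 3.0) {
  mode <- match.arg(mode)
  if (mode == "pinpoint") {
    pf <- detect_bright_blobs(fixed, diameter = pinpoint_diameter)
    pm <- detect_bright_blobs(moving, diameter = pinpoint_diameter)
    if (nrow(pf) < 3 || nrow(pm) < 3)
      stop("need at least 3 reference markers in each volume (found ",
           nrow(pf), " fixed, ", nrow(pm), " moving)")
    tf <- kabsch_align(as.matrix(pf[, c("x", "y", "z")]),
                       as.matrix(pm[, c("x", "y", "z")]))
    res <- attr(tf, "residual")
  } else {
    thr <- bone_threshold %||% (0.6 * max(fixed$values))
    tf <- register_intensity(moving, fixed, thr, roi_fraction, max_points, maxit)
    res <- attr(tf, "residual")
  }
  attr(tf, "success") <- res <= max_residual
  if (res > max_residual)
    warning("registration residual ", signif(res, 4),
            " exceeds threshold ", signif(max_residual, 4))
  tf
}

# least-squares rigid alignment of matched point sets (Kabsch/SVD);
# correspondence by greedy nearest neighbours on centroid-centred
# constellations (translation-invariant; assumes a small relative rotation,
# which holds for the scanner pose offsets this is used for)
kabsch_align <- function(pts_fixed, pts_moving) {
  cf0 <- sweep(pts_fixed, 2, colMeans(pts_fixed))
  cm0 <- sweep(pts_moving, 2, colMeans(pts_moving))
  used <- rep(FALSE, nrow(pts_moving))
  match_idx <- integer(nrow(pts_fixed))
  for (i in seq_len(nrow(pts_fixed))) {
    d <- colSums((t(cm0) - cf0[i, ])^2)
    d[used] <- Inf
    j <- which.min(d)
    match_idx[i] <- j
    used[j] <- TRUE
  }
  Pm <- pts_moving[match_idx, , drop = FALSE]
  cf <- colMeans(pts_fixed)
  cm <- colMeans(Pm)
  H <- t(sweep(pts_fixed, 2, cf)) %*% sweep(Pm, 2, cm)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tf <- rigid_transform(R, cm - cf, cf)
  pred <- transform_points(tf, pts_fixed)
  attr(tf, "residual") <- sqrt(mean(rowSums((pred - Pm)^2)))
  tf
}

register_intensity <- function(moving, fixed, bone_threshold, roi_fraction,
                               max_points, maxit = 300) {
  # ROI: bone-bright voxels in the caudal part of the fixed volume
  occ_z <- which(apply(fixed$values > bone_threshold, 3, any))
  if (length(occ_z) == 0) stop("no bone-intensity voxels found for the ROI")
  zcut <- occ_z[1] + roi_fraction * (tail(occ_z, 1) - occ_z[1])
  bg <- min(fixed$values)

  levels <- c(4L, 2L, 1L)
  par <- rep(0, 6)
  centre <- NULL
  for (f in levels) {
    fv <- if (f > 1) downsample_volume(fixed, fixed$spacing * f) else fixed
    zcut_w <- fixed$origin[3] + (zcut - 1) * fixed$spacing[3]
    mask <- fv$values > bone_threshold
    idx <- which(mask, arr.ind = TRUE)
    wz <- fv$origin[3] + (idx[, 3] - 1) * fv$spacing[3]
    idx <- idx[wz <= zcut_w, , drop = FALSE]
    if (nrow(idx) > max_points)
      idx <- idx[seq(1, nrow(idx), length.out = max_points), , drop = FALSE]
    pts <- index_to_world(fv, idx - 1)
    vals <- fv$values[idx]
    if (is.null(centre)) centre <- colMeans(pts)
    obj <- function(p) {
      R <- rotvec_to_matrix(p[1:3])
      sm <- cpp_sample_points(moving$values, dim(moving$values),
                              moving$spacing, moving$origin,
                              sweep(sweep(pts, 2, centre) %*% t(R), 2,
                                    centre + p[4:6], "+"), bg)
      mean((sm - vals)^2)
    }
    sc <- c(rep(2e-3, 3), rep(0.05, 3)) * f
    opt <- optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10,
                                parscale = sc))
    par <- opt$par
  }
  tf <- rigid_transform(rotvec_to_matrix(par[1:3]), par[4:6], centre)
  attr(tf, "residual") <- sqrt(opt$value)
  tf
}

#' Resample a volume onto a reference grid
#'
#' Trilinear resampling of `volume` onto the voxel grid of `reference`
#' through a rigid transform (fixed frame to moving scan); voxels mapping
#' outside the field of view receive the background value.
#'
#' @param volume the moving [voxel_volume()].
#' @param reference the [voxel_volume()] whose grid defines the output.
#' @param transform a [rigid_transform()] as returned by [register_rigid()];
#'   identity by default.
#' @param background fill value outside the field of view.
#' @return A [voxel_volume()] on the reference grid.
#' @export
resample_to <- function(volume, reference, transform = rigid_transform(),
                        background = min(volume$values)) {
  vals <- cpp_resample_affine(
    volume$values, dim(volume$values), volume$spacing, volume$origin,
    dim(reference$values), reference$spacing, reference$origin,
    transform$R, transform$t, transform$center, background)
  voxel_volume(vals, reference$spacing, reference$origin, volume$modality)
}
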