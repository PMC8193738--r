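#' Voxel volume container
#'
#' A minimal carrier for 3D scalar image volumes with physical geometry:
#' a numeric array plus per-axis voxel spacing (mm), a world-space origin
#' (mm, the centre of voxel `[1, 1, 1]`), and a modality tag. World
#' coordinates follow `world = origin + index * spacing` with 0-based
#' indices; axes are ordered (x, y, z) with z the cranio-caudal (loading)
#' axis and +y anterior.
#'
#' @param values numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world coordinate of the first voxel centre.
#' @param modality `"CT"` or `"MR"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0),
                         modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  structure(
    list(values = values, spacing = spacing,
         origin = rep_len(as.numeric(origin), 3L), modality = modality),
    class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume [%s]> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              x$modality, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

# world <-> continuous 0-based index helpers
index_to_world <- function(vol, idx) {
  sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
}
world_to_index <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' Rescale volume greyscale to the 0--255 range
#'
#' Linear, order-preserving map of the intensity range onto `[0, 255]`,
#' the normalisation required before applying a calibrated greyscale-to-bone
#' modulus relationship.
#'
#' @param vol a [voxel_volume()].
#' @return The rescaled [voxel_volume()].
#' @export
rescale_greyscale <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  rng <- range(vol$values)
  if (diff(rng) == 0)
    stop("constant volume: greyscale rescaling is undefined")
  vol$values <- (vol$values - rng[1]) * (255 / diff(rng))
  vol
}

#' Mean-pool a volume to a coarser grid
#'
#' Downsamples by the integer factor closest to `target_spacing / spacing`
#' per axis (block mean pooling). Used to bring the high-resolution CT to
#' the 0.5 mm grid on which the greyscale-to-modulus map is applied.
#'
#' @param vol a [voxel_volume()].
#' @param target_spacing numeric, desired spacing in mm (scalar or length 3).
#' @return A coarser [voxel_volume()].
#' @export
downsample_volume <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "voxel_volume"))
  target_spacing <- rep_len(target_spacing, 3L)
  f <- pmax(1L, as.integer(round(target_spacing / vol$spacing)))
  vals <- cpp_downsample_mean(vol$values, dim(vol$values), f)
  sp <- vol$spacing * f
  # origin moves to the centre of the first pooled block
  org <- vol$origin + (f - 1) / 2 * vol$spacing
  voxel_volume(vals, sp, org, vol$modality)
}

#' Sample a volume at world points (trilinear)
#'
#' @param vol a [voxel_volume()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param background value returned outside the field of view.
#' @return Numeric vector of sampled intensities.
#' @export
sample_volume <- function(vol, pts, background = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_sample_points(vol$values, dim(vol$values), vol$spacing, vol$origin,
                    pts, background)
}

#' Write / read volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} preserving spacing; the world origin is
#' stored in the qform translation.
#'
#' @param vol a [voxel_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [voxel_volume()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path)
  meta <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(origin = vol$origin, modality = vol$modality),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @param modality modality tag used when no side-car metadata is present.
#' @export
read_volume <- function(path, modality = "CT") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  meta <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(meta)) {
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    origin <- m$origin
    modality <- m$modality
  }
  voxel_volume(array(as.numeric(img), dim = dim(img)), sp, origin, modality)
}
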