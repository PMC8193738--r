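#' Measure applied platen displacement from endcap inner surfaces
#'
#' The applied compression at each step is recovered from the images as the
#' change in axial distance between the inner surfaces of the two PMMA
#' endcaps. For each transverse column the inner surface is the innermost
#' endcap-intensity voxel (top of the bottom endcap, bottom of the top
#' endcap); the per-volume distance is the 10%-trimmed mean over columns,
#' which is robust to marker bleed and edge voxels. Quantisation error is
#' at most one voxel along z.
#'
#' @param preloaded preloaded [voxel_volume()].
#' @param deformed deformed [voxel_volume()] in the same frame (register
#'   and [resample_to()] first, or pass `transform`).
#' @param transform optional [rigid_transform()] (fixed to moving) used to
#'   resample `deformed` onto the preloaded grid before measuring.
#' @param endcap_range intensity band selecting PMMA endcap voxels.
#' @param trim trimming fraction of the per-column surface heights.
#' @return Measured displacement in mm (positive = compression), with
#'   attribute `distances` giving the two endcap inner-surface distances.
#' @export
measure_applied_displacement <- function(preloaded, deformed,
                                         transform = NULL,
                                         endcap_range = c(90, 160),
                                         trim = 0.1) {
  if (!is.null(transform))
    deformed <- resample_to(deformed, preloaded, transform)
  d0 <- endcap_inner_distance(preloaded, endcap_range, trim)
  d1 <- endcap_inner_distance(deformed, endcap_range, trim)
  out <- d0 - d1
  attr(out, "distances") <- c(preloaded = d0, deformed = d1)
  out
}

endcap_inner_distance <- function(vol, endcap_range, trim) {
  v <- vol$values
  nz <- dim(v)[3]
  mask <- v >= endcap_range[1] & v <= endcap_range[2]
  # slice profile of endcap-intensity voxels locates the two slabs;
  # tissue interfaces also pass through the band but only 1-2 voxels thick
  prof <- apply(mask, 3, sum)
  slab <- prof > 0.5 * max(prof)
  runs <- rle(slab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  on <- which(runs$values)
  if (length(on) < 2)
    stop("endcap mask not found in the intensity band [",
         endcap_range[1], ", ", endcap_range[2], "]")
  bot_inner0 <- ends[on[1]]            # top slice of the bottom slab
  top_inner0 <- starts[on[length(on)]] # bottom slice of the top slab
  # per-column sub-voxel refinement inside a window around each interface
  refine <- function(k0, inner_is_max) {
    win <- max(1, k0 - 5):min(nz, k0 + 5)
    sub <- mask[, , win, drop = FALSE]
    zcol <- matrix(NA_real_, dim(v)[1], dim(v)[2])
    for (i in seq_along(win)) {
      mk <- sub[, , i]
      if (inner_is_max) zcol[mk] <- win[i]
      else zcol[mk & is.na(zcol)] <- win[i]
    }
    zcol
  }
  bot <- refine(bot_inner0, inner_is_max = TRUE)
  top <- refine(top_inner0, inner_is_max = FALSE)
  ok <- !is.na(bot) & !is.na(top)
  if (!any(ok)) stop("no columns intersect both endcap inner surfaces")
  zb <- mean(bot[ok], trim = trim)
  zt <- mean(top[ok], trim = trim)
  (zt - zb) * vol$spacing[3]
}
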