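#' Otsu threshold of a numeric vector
#'
#' Histogram-based two-class threshold maximising between-class variance.
#' @param v numeric values.
#' @param nbins number of histogram bins.
#' @return The threshold value.
#' @keywords internal
otsu_threshold <- function(v, nbins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + as.integer((v - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

# bright spherical blobs: threshold + 6-connected components + size gate,
# intensity-weighted (background-subtracted) centroids in world mm.
# Components holding k ~ 2..4 nominal marker volumes (markers touching
# after compression) are split into k clusters seeded along the component's
# long axis before centroiding.
detect_bright_blobs <- function(volume, diameter, threshold = NULL,
                                size_gate = c(0.3, 3.0)) {
  v <- volume$values
  thr <- threshold %||% {
    hi <- v[v > 0.55 * max(v)]
    otsu_threshold(hi)
  }
  mask <- v >= thr
  lab <- cpp_label_components(mask, dim(v))
  ncomp <- attr(lab, "ncomp")
  empty <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          n_voxels = integer())
  if (ncomp == 0) return(empty)
  w <- pmax(v - thr, 0)
  st <- cpp_component_centroids(lab, dim(v), w, ncomp)
  vox_vol <- prod(volume$spacing)
  nominal <- (4 / 3) * pi * (diameter / 2)^3 / vox_vol
  # thresholding clips the partial-volume shell, so the observed size of a
  # single marker runs below nominal; estimate it from the data when
  # enough unambiguous singles exist
  prov <- st[st[, 1] >= size_gate[1] * nominal & st[, 1] < 1.2 * nominal, 1]
  unit <- if (length(prov) >= 3) median(prov) else 0.8 * nominal
  single <- which(st[, 1] >= size_gate[1] * nominal &
                    st[, 1] < 1.6 * unit)
  merged <- which(st[, 1] >= 1.6 * unit & st[, 1] <= 6.5 * unit)

  rows <- list()
  if (length(single) > 0) {
    ctr <- st[single, 3:5, drop = FALSE] / st[single, 2]
    wpts <- index_to_world(volume, ctr)
    rows[[1]] <- tibble::tibble(x = wpts[, 1], y = wpts[, 2], z = wpts[, 3],
                                n_voxels = as.integer(st[single, 1]))
  }
  if (length(merged) > 0) {
    sel <- which(array(lab %in% merged, dim(v)))
    coords <- arrayInd(sel, dim(v)) - 1L
    labs_v <- lab[sel]
    wv <- w[sel]
    for (l in merged) {
      pick <- labs_v == l
      pc <- coords[pick, , drop = FALSE]
      pw <- wv[pick]
      k <- max(2L, min(6L, as.integer(round(nrow(pc) / unit))))
      # deterministic seeds along the long (z) axis of the blob chain
      ord <- order(pc[, 3])
      seeds <- pc[ord[round((seq_len(k) - 0.5) / k * nrow(pc))], ,
                  drop = FALSE]
      km <- suppressWarnings(stats::kmeans(pc, centers = seeds,
                                           iter.max = 50))
      for (cl in seq_len(k)) {
        cm <- km$cluster == cl
        if (sum(cm) < size_gate[1] * nominal) next
        cw <- pw[cm]
        ctr <- colSums(pc[cm, , drop = FALSE] * cw) / sum(cw)
        wp <- index_to_world(volume, matrix(ctr, 1))
        rows[[length(rows) + 1]] <- tibble::tibble(
          x = wp[1], y = wp[2], z = wp[3], n_voxels = sum(cm))
      }
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

#' Detect disc-surface fiducial markers
#'
#' Segments bright marker blobs (threshold from Otsu's method over the
#' high-intensity tail unless given), takes intensity-weighted centroids of
#' the 6-connected components, applies a size gate of 0.3--3 times the
#' nominal marker volume, and matches the surviving blobs to the
#' craniocaudal line layout: line index from the transverse azimuth about
#' the marker-cloud axis, level index from the axial rank within each line.
#' Zone labels follow the 8-sector convention of [zone_from_azimuth()].
#'
#' @param volume a [voxel_volume()] (rescaled, in the registered frame or
#'   close to it; sector assignment tolerates small rigid offsets).
#' @param expected_n expected marker count; detection errors out if the
#'   count after gating differs, listing affected zones.
#' @param n_lines,markers_per_line layout to match (8 x 5 default).
#' @param marker_diameter nominal marker diameter, mm.
#' @param threshold optional explicit intensity threshold.
#' @return A tibble `(marker_id, line, level, zone, x, y, z, n_voxels)`
#'   with centroids in world mm.
#' @export
detect_markers <- function(volume, expected_n = 40L, n_lines = 8L,
                           markers_per_line = 5L, marker_diameter = 1.0,
                           threshold = NULL) {
  blobs <- detect_bright_blobs(volume, marker_diameter, threshold)
  if (nrow(blobs) != expected_n) {
    zb <- if (nrow(blobs)) {
      cxy <- c(mean(blobs$x), mean(blobs$y))
      table(zone_from_azimuth(atan2(blobs$y - cxy[2], blobs$x - cxy[1])))
    } else "none"
    stop("detected ", nrow(blobs), " markers, expected ", expected_n,
         "; blobs per zone: ", paste(names(zb), zb, collapse = " "))
  }
  if (expected_n == 0L)
    return(tibble::tibble(marker_id = integer(), line = integer(),
                          level = integer(), zone = character(),
                          x = numeric(), y = numeric(), z = numeric(),
                          n_voxels = integer()))
  cxy <- c(mean(blobs$x), mean(blobs$y))
  theta <- atan2(blobs$y - cxy[2], blobs$x - cxy[1])
  line <- as.integer(round((theta - pi / 2) / (2 * pi / n_lines)) %% n_lines)
  out <- blobs
  out$line <- line
  out$zone <- zone_from_azimuth(theta)
  out <- out %>%
    dplyr::group_by(.data$line) %>%
    dplyr::mutate(level = as.integer(rank(.data$z) - 1)) %>%
    dplyr::ungroup()
  bad <- out %>% dplyr::count(.data$line) %>%
    dplyr::filter(.data$n != markers_per_line)
  if (nrow(bad) > 0)
    stop("marker layout mismatch on line(s) ",
         paste(bad$line, collapse = ", "))
  out %>%
    dplyr::mutate(marker_id = .data$line * markers_per_line +
                    .data$level + 1L) %>%
    dplyr::arrange(.data$marker_id) %>%
    dplyr::select("marker_id", "line", "level", "zone", "x", "y", "z",
                  "n_voxels")
}

#' Detect PinPoint-style endcap reference markers
#'
#' Same blob detection as [detect_markers()] but gated at the larger
#' reference-marker size; no layout matching.
#'
#' @inheritParams detect_markers
#' @param diameter reference marker diameter, mm.
#' @return A tibble `(x, y, z, n_voxels)`.
#' @export
detect_pinpoints <- function(volume, diameter = 3.0, threshold = NULL) {
  detect_bright_blobs(volume, diameter, threshold)
}
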