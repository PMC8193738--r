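# region codes shared with phantom_labels()
REGION <- c(endcap_bottom = 1L, bone_caudal = 2L, af = 3L, np = 4L,
            bone_cranial = 5L, endcap_top = 6L)

#' Nucleus geometry for the three model types
#'
#' The CT cannot separate nucleus from annulus, so the nucleus region is
#' constructed in one of three ways: `std_cyl`, a coaxial cylinder with
#' NP:AF diameter ratio 0.5 spanning the full disc height; `fit_cyl`, a
#' coaxial full-height cylinder whose volume matches the MR-segmented
#' nucleus volume (radius from V = pi r^2 h); or `mr`, the segmented MR
#' mask mapped directly into the mesh.
#'
#' @param model_type `"std_cyl"`, `"fit_cyl"` or `"mr"`.
#' @param disc_radius,disc_height disc dimensions, mm.
#' @param np_mask_volume MR nucleus volume in mm^3 (required for
#'   `fit_cyl`).
#' @param np_mask a [voxel_volume()] binary mask (required for `mr`).
#' @param mask_transform optional [rigid_transform()] taking specimen-frame
#'   points into the mask volume's frame (from pinpoint registration).
#' @param center transverse (x, y) nucleus axis position, mm.
#' @return A `nucleus_geometry` list.
#' @export
build_nucleus <- function(model_type = c("std_cyl", "fit_cyl", "mr"),
                          disc_radius, disc_height, np_mask_volume = NULL,
                          np_mask = NULL, mask_transform = NULL,
                          center = c(0, 0)) {
  model_type <- match.arg(model_type)
  out <- list(type = model_type, center = center)
  if (model_type == "std_cyl") {
    out$radius <- disc_radius / 2
  } else if (model_type == "fit_cyl") {
    if (is.null(np_mask_volume)) {
      if (is.null(np_mask)) stop("fit_cyl requires np_mask_volume or np_mask")
      np_mask_volume <- sum(np_mask$values > 0.5) * prod(np_mask$spacing)
    }
    r <- sqrt(np_mask_volume / (pi * disc_height))
    if (r >= disc_radius)
      stop("fitted nucleus radius exceeds the annulus outer bound")
    out$radius <- r
    out$volume <- np_mask_volume
  } else {
    if (is.null(np_mask)) stop("mr nucleus requires np_mask")
    out$mask <- np_mask
    out$mask_transform <- mask_transform %||% rigid_transform()
  }
  structure(out, class = "nucleus_geometry")
}

#' Segment the nucleus from the MR-like volume
#'
#' Thresholds the bright nucleus signal (Otsu over the upper intensity
#' tail unless given) and keeps the largest connected component.
#'
#' @param mr an MR-like [voxel_volume()] (nucleus hyperintense).
#' @param threshold optional explicit threshold.
#' @return A binary-mask [voxel_volume()] with attribute `volume_mm3`.
#' @export
segment_np_mr <- function(mr, threshold = NULL) {
  thr <- threshold %||% otsu_threshold(mr$values[mr$values >
                                                   0.3 * max(mr$values)])
  mask <- mr$values >= thr
  lab <- cpp_label_components(mask, dim(mr$values))
  nc <- attr(lab, "ncomp")
  if (nc == 0) stop("no nucleus signal above threshold")
  sizes <- tabulate(lab[lab > 0], nc)
  big <- which.max(sizes)
  out <- voxel_volume(array(as.numeric(lab == big), dim(mr$values)),
                      mr$spacing, mr$origin, "MR")
  attr(out, "volume_mm3") <- sizes[big] * prod(mr$spacing)
  out
}

element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
     mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
}

#' Assign the nucleus region inside the disc
#'
#' Resets all disc elements to annulus, then relabels as nucleus those
#' whose centroid falls inside the [build_nucleus()] geometry.
#'
#' @param mesh a `tet_mesh` with disc elements labelled 3/4.
#' @param nucleus a `nucleus_geometry`.
#' @return The mesh with updated `region`.
#' @export
assign_nucleus <- function(mesh, nucleus) {
  disc <- mesh$region %in% c(REGION[["af"]], REGION[["np"]])
  mesh$region[disc] <- REGION[["af"]]
  ctr <- element_centroids(mesh)
  if (nucleus$type %in% c("std_cyl", "fit_cyl")) {
    r <- sqrt((ctr[, 1] - nucleus$center[1])^2 +
                (ctr[, 2] - nucleus$center[2])^2)
    inside <- disc & r <= nucleus$radius
  } else {
    pts <- transform_points(nucleus$mask_transform, ctr)
    val <- sample_volume(nucleus$mask, pts, background = 0)
    inside <- disc & val > 0.5
  }
  mesh$region[inside] <- REGION[["np"]]
  mesh
}

#' Assign per-element bone moduli from the CT greyscale
#'
#' Downsamples the rescaled (0--255) CT to 0.5 mm isotropic by mean pooling
#' and maps the greyscale at each bone element centroid through
#' [bone_modulus_from_greyscale()]. Centroids outside the downsampled field
#' of view fall back to the nearest voxel with a warning.
#'
#' @param mesh a `tet_mesh`.
#' @param ct rescaled CT [voxel_volume()] (or already-downsampled volume).
#' @param pool_spacing pooling resolution, mm (default 0.5).
#' @param ... passed to [bone_modulus_from_greyscale()].
#' @return The mesh with a `bone_E` vector (NA for non-bone elements).
#' @export
assign_bone_moduli <- function(mesh, ct, pool_spacing = 0.5, ...) {
  if (max(ct$spacing) < pool_spacing)
    ct <- downsample_volume(ct, rep(pool_spacing, 3))
  ctr <- element_centroids(mesh)
  bone <- mesh$region %in% c(REGION[["bone_caudal"]], REGION[["bone_cranial"]])
  gs <- rep(NA_real_, nrow(ctr))
  if (any(bone)) {
    v <- sample_volume(ct, ctr[bone, , drop = FALSE], background = -1)
    if (any(v < 0)) {
      warning(sum(v < 0), " bone element centroid(s) outside the volume; ",
              "using nearest voxel")
      idx <- world_to_index(ct, ctr[bone, , drop = FALSE][v < 0, ,
                                                          drop = FALSE])
      idx <- pmin(pmax(round(idx), 0), matrix(dim(ct$values) - 1,
                                              sum(v < 0), 3, byrow = TRUE))
      v[v < 0] <- ct$values[idx + 1]
    }
    gs[bone] <- pmin(pmax(v, 0), 255)
  }
  mesh$bone_E <- ifelse(is.na(gs), NA_real_,
                        bone_modulus_from_greyscale(
                          ifelse(is.na(gs), 0, gs), ...))
  mesh
}

#' Assign annulus fibre directions
#'
#' At each annulus element centroid the local circumferential direction is
#' computed about the disc axis and the two fibre vectors are placed at
#' +/- `angle_deg` from the transverse plane within the (circumferential,
#' axial) plane: the oblique/counter-oblique lamellar architecture.
#'
#' @param mesh a `tet_mesh`.
#' @param angle_deg fibre angle to the transverse plane (default 20).
#' @param axis_center (x, y) of the disc axis.
#' @return The mesh with `fibres`, an E x 6 matrix (two unit vectors per
#'   row; zero rows for non-annulus elements).
#' @export
assign_fibres <- function(mesh, angle_deg = 20, axis_center = c(0, 0)) {
  ctr <- element_centroids(mesh)
  af <- mesh$region == REGION[["af"]]
  fib <- matrix(0, nrow(ctr), 6)
  if (any(af)) {
    dx <- ctr[af, 1] - axis_center[1]
    dy <- ctr[af, 2] - axis_center[2]
    r <- sqrt(dx^2 + dy^2)
    if (any(r < 1e-9))
      stop("annulus element centroid on the disc axis: circumferential ",
           "direction undefined")
    a <- angle_deg * pi / 180
    # circumferential unit vector, then tilt by +/- a out of plane
    ex <- -dy / r; ey <- dx / r
    fib[af, 1] <- cos(a) * ex
    fib[af, 2] <- cos(a) * ey
    fib[af, 3] <- sin(a)
    fib[af, 4] <- cos(a) * ex
    fib[af, 5] <- cos(a) * ey
    fib[af, 6] <- -sin(a)
  }
  mesh$fibres <- fib
  mesh
}

#' Boundary conditions for axial compression
#'
#' Clamps every node of the inferior endcap face and constrains the
#' superior face in transverse translation (which also removes transverse
#' rotation) while prescribing the axial compressive displacement.
#'
#' @param mesh a `tet_mesh`.
#' @param applied_displacement platen displacement, mm (positive =
#'   compression; the top face moves by -z).
#' @param tol node-capture tolerance as a fraction of grid spacing.
#' @return A list: `fixed_dofs` (1-based global dofs `3 (node-1) + comp`),
#'   `values` (prescribed displacement per fixed dof), `top_nodes`,
#'   `bottom_nodes`.
#' @export
build_bcs <- function(mesh, applied_displacement, tol = 0.5) {
  z <- mesh$nodes[, 3]
  eps <- tol * mesh$h
  bottom <- which(z <= min(z) + eps)
  top <- which(z >= max(z) - eps)
  if (length(bottom) == 0 || length(top) == 0)
    stop("empty endcap face node set")
  fixed <- c(rbind(3 * (bottom - 1) + 1, 3 * (bottom - 1) + 2,
                   3 * (bottom - 1) + 3))
  vals <- rep(0, length(fixed))
  ftop <- c(rbind(3 * (top - 1) + 1, 3 * (top - 1) + 2, 3 * (top - 1) + 3))
  vtop <- rep(c(0, 0, -abs(applied_displacement)), times = length(top))
  list(fixed_dofs = c(fixed, ftop), values = c(vals, vtop),
       top_nodes = top, bottom_nodes = bottom)
}

#' Build a specimen-specific finite-element model
#'
#' Assembles the complete model from a phantom: meshes the labelled
#' geometry, installs the requested nucleus model type, assigns bone moduli
#' (uniform median modulus when no CT is supplied), annulus fibre
#' directions, and the marker-to-surface-node map (markers were excluded
#' from the physical segmentation and are represented by their closest
#' annulus surface node).
#'
#' @param phantom an `osteodisc_phantom`.
#' @param nucleus_type `"std_cyl"`, `"fit_cyl"` or `"mr"`.
#' @param target_edge mesh grid spacing, mm.
#' @param ct optional rescaled CT [voxel_volume()] for greyscale bone
#'   mapping; when `NULL` all bone elements get `uniform_bone_E`.
#' @param np_mask optional MR nucleus mask (else segmented from
#'   `phantom$mr` for the fit_cyl / mr types, using ground-truth geometry
#'   when no MR volume was rendered).
#' @param uniform_bone_E fallback bone modulus, MPa (study median).
#' @param markers marker positions used for the surface map (default:
#'   ground-truth step-0 centroids).
#' @return A `specimen_model`: `mesh`, `bcs` template (`top_nodes`,
#'   `bottom_nodes`), `marker_map` tibble, `nucleus`, `geometry`.
#' @export
build_specimen_model <- function(phantom,
                                 nucleus_type = c("std_cyl", "fit_cyl", "mr"),
                                 target_edge = 2, ct = NULL, np_mask = NULL,
                                 uniform_bone_E = 386.8, markers = NULL) {
  nucleus_type <- match.arg(nucleus_type)
  g <- phantom$truth$geometry
  labels <- phantom_labels(phantom, spacing = target_edge / 2)
  mesh <- mesh_specimen(labels, target_edge)

  if (nucleus_type == "std_cyl") {
    nuc <- build_nucleus("std_cyl", g$R, g$h)
  } else {
    if (is.null(np_mask)) {
      if (!is.null(phantom$mr)) {
        np_mask <- segment_np_mr(phantom$mr)
        # MR scan frame -> specimen frame via the planted pose (tests may
        # instead pass a pinpoint-registered mask)
        tfm <- rigid_transform(phantom$truth$mr_pose$R,
                               phantom$truth$mr_pose$t, g$center)
      } else {
        np_mask <- NULL
        tfm <- rigid_transform()
      }
    } else tfm <- attr(np_mask, "transform") %||% rigid_transform()
    if (nucleus_type == "fit_cyl") {
      vol <- if (!is.null(np_mask)) attr(np_mask, "volume_mm3")
             else phantom$truth$np_fraction * pi * g$R^2 * g$h
      nuc <- build_nucleus("fit_cyl", g$R, g$h, np_mask_volume = vol,
                           center = phantom$truth$np_center)
    } else {
      if (is.null(np_mask)) stop("mr nucleus type requires an MR volume")
      nuc <- build_nucleus("mr", g$R, g$h, np_mask = np_mask,
                           mask_transform = tfm)
    }
  }
  mesh <- assign_nucleus(mesh, nuc)
  if (!is.null(ct)) {
    mesh <- assign_bone_moduli(mesh, ct)
    mesh$bone_E[is.na(mesh$bone_E)] <- uniform_bone_E
  } else {
    mesh$bone_E <- rep(uniform_bone_E, nrow(mesh$elems))
  }
  mesh <- assign_fibres(mesh)

  bcs0 <- build_bcs(mesh, 0)
  markers <- markers %||% dplyr::filter(phantom$truth$markers, .data$step == 0)
  mm <- marker_node_map(mesh, markers)
  structure(list(mesh = mesh, top_nodes = bcs0$top_nodes,
                 bottom_nodes = bcs0$bottom_nodes, marker_map = mm,
                 nucleus = nuc, geometry = g,
                 nucleus_type = nucleus_type),
            class = "specimen_model")
}

#' @export
print.specimen_model <- function(x, ...) {
  cat(sprintf("<specimen_model> nucleus type %s\n", x$nucleus_type))
  print(x$mesh)
  cat(sprintf("  %d mapped markers\n", nrow(x$marker_map)))
  invisible(x)
}

# nearest annulus-surface node for each marker
marker_node_map <- function(mesh, markers) {
  if (nrow(markers) == 0)
    return(tibble::tibble(marker_id = integer(), zone = character(),
                          node = integer(), dist_mm = numeric()))
  bf <- mesh_boundary_faces(mesh)
  af_faces <- bf$faces[mesh$region[bf$elem] == REGION[["af"]], ,
                       drop = FALSE]
  surf <- sort(unique(as.vector(af_faces)))
  if (length(surf) == 0) stop("no annulus surface nodes")
  sn <- mesh$nodes[surf, , drop = FALSE]
  node <- integer(nrow(markers))
  dist <- numeric(nrow(markers))
  for (i in seq_len(nrow(markers))) {
    d2 <- (sn[, 1] - markers$x[i])^2 + (sn[, 2] - markers$y[i])^2 +
      (sn[, 3] - markers$z[i])^2
    j <- which.min(d2)
    node[i] <- surf[j]
    dist[i] <- sqrt(d2[j])
  }
  tibble::tibble(marker_id = markers$marker_id, zone = markers$zone,
                 node = node, dist_mm = dist)
}

#' Export a mesh as legacy VTK (text)
#'
#' Writes nodes, tetrahedra and per-element region / bone modulus data as
#' an ASCII legacy `.vtk` unstructured grid.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @param point_data optional named list of per-node vectors (e.g.
#'   displacement magnitude).
#' @return `path` invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  write(t(mesh$nodes), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  write(t(cbind(4L, mesh$elems - 1L)), con, ncolumns = 5)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  write(rep(10L, ne), con, ncolumns = 20)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  write(mesh$region, con, ncolumns = 20)
  if (!is.null(mesh$bone_E)) {
    writeLines(c("SCALARS bone_E double 1", "LOOKUP_TABLE default"), con)
    be <- mesh$bone_E; be[is.na(be)] <- 0
    write(be, con, ncolumns = 10)
  }
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      write(point_data[[nm]], con, ncolumns = 10)
    }
  }
  invisible(path)
}

#' Export a model as an Abaqus input deck
#'
#' Nodes, C3D4 elements, per-region element sets and the axial-compression
#' boundary cards, for cross-validation against commercial solvers.
#'
#' @param model a `specimen_model`.
#' @param path output `.inp` file.
#' @param displacement prescribed axial displacement, mm.
#' @return `path` invisibly.
#' @export
write_model_inp <- function(model, path, displacement = 1) {
  mesh <- model$mesh
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.6f, %.6f, %.6f", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  for (rg in sort(unique(mesh$region))) {
    nm <- names(REGION)[match(rg, REGION)]
    writeLines(sprintf("*ELEMENT, TYPE=C3D4, ELSET=%s", toupper(nm)), con)
    idx <- which(mesh$region == rg)
    writeLines(sprintf("%d, %d, %d, %d, %d", idx, mesh$elems[idx, 1],
                       mesh$elems[idx, 2], mesh$elems[idx, 3],
                       mesh$elems[idx, 4]), con)
  }
  writeLines("*NSET, NSET=BOTTOM", con)
  writeLines(paste(model$bottom_nodes, collapse = ", "), con)
  writeLines("*NSET, NSET=TOP", con)
  writeLines(paste(model$top_nodes, collapse = ", "), con)
  writeLines(c("*BOUNDARY", "BOTTOM, 1, 3, 0.", "TOP, 1, 2, 0.",
               sprintf("TOP, 3, 3, %.6f", -abs(displacement))), con)
  invisible(path)
}
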