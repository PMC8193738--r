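test_that("meshing a cube gives positive conforming tetrahedra", {
  lab <- voxel_volume(array(1L, dim = c(8, 8, 8)), spacing = 0.125,
                      origin = rep(0.0625, 3))
  mesh <- mesh_specimen(lab, target_edge = 0.25)
  q <- mesh_quality(mesh)
  expect_true(all(q$volumes > 0))
  expect_gt(q$min_scaled_jacobian, 0.05)
  # each interior face shared by exactly two elements (conforming)
  bf <- osteodisc:::mesh_boundary_faces(mesh)
  expect_equal(nrow(bf$faces), 2L * 6L * (4L)^2)  # 2 triangles per cell face
})

test_that("coarse phantom mesh stays at desk scale", {
  model <- fx_fe_model()
  expect_lt(nrow(model$mesh$elems), 1e4)
  expect_true(all(sort(unique(model$mesh$region)) %in% 1:6))
})

test_that("study-scale grid keeps every element edge in 0.5-1.0 mm", {
  lab <- voxel_volume(array(1L, dim = c(20, 20, 20)), spacing = 0.25,
                      origin = rep(0.125, 3))
  mesh <- mesh_specimen(lab, target_edge = 0.55)
  q <- mesh_quality(mesh)
  expect_gte(min(q$edge_lengths), 0.5)
  expect_lte(max(q$edge_lengths), 1.0)
  expect_gte(median(q$edge_lengths), 0.5)
  expect_lte(median(q$edge_lengths), 1.0)
})

test_that("mesh region volumes match the label geometry", {
  ph <- generate_phantom(fe_config(), render = FALSE)
  model <- build_specimen_model(ph, "std_cyl", target_edge = 1.2)
  g <- ph$truth$geometry
  vols <- tapply(mesh_quality(model$mesh)$volumes, model$mesh$region, sum)
  disc_vol <- pi * g$R^2 * g$h
  expect_equal(unname(vols[["3"]] + vols[["4"]]), disc_vol,
               tolerance = 0.06)
  bone_vol <- pi * g$Rb^2 * g$b
  expect_equal(unname(vols[["2"]]), bone_vol, tolerance = 0.08)
})

test_that("std_cyl nucleus has exactly half the annulus diameter", {
  nuc <- build_nucleus("std_cyl", disc_radius = 15, disc_height = 9)
  expect_equal(nuc$radius, 7.5)
})

test_that("fit_cyl nucleus volume matches the mask volume within 1%", {
  V <- 300
  nuc <- build_nucleus("fit_cyl", disc_radius = 15, disc_height = 9,
                       np_mask_volume = V)
  expect_equal(pi * nuc$radius^2 * 9, V, tolerance = 0.01)
  expect_error(build_nucleus("fit_cyl", disc_radius = 3, disc_height = 1,
                             np_mask_volume = 1000), "exceeds")
})

test_that("mr nucleus mapped from a spherical mask preserves its volume", {
  # spherical mask centred in the disc of the FE phantom
  ph <- generate_phantom(fe_config(seed = 8), render = FALSE)
  g <- ph$truth$geometry
  sp <- 0.25
  n <- as.integer(2 * 4 / sp)
  xs <- seq(-4 + sp / 2, 4 - sp / 2, length.out = n)
  ctr_z <- g$z_d0 + g$h / 2
  arr <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) {
    r2 <- outer(xs^2, xs^2, "+") + xs[k]^2
    arr[, , k] <- as.numeric(r2 <= 2^2)
  }
  mask <- voxel_volume(arr, spacing = sp,
                       origin = c(-4 + sp / 2, -4 + sp / 2,
                                  ctr_z - 4 + sp / 2))
  nuc <- build_nucleus("mr", g$R, g$h, np_mask = mask)
  mesh <- assign_nucleus(
    assign_fibres(mesh_specimen(phantom_labels(ph, 0.4), 0.8)), nuc)
  np_vol <- sum(mesh_quality(mesh)$volumes[mesh$region == 4])
  true_vol <- (4 / 3) * pi * 2^3
  expect_equal(np_vol, true_vol, tolerance = 0.1)
})

test_that("std_cyl nucleus is larger than fit_cyl whenever the measured NP is small", {
  for (f in c(0.07, 0.12, 0.17)) {
    std <- build_nucleus("std_cyl", 14, 9)
    fit <- build_nucleus("fit_cyl", 14, 9,
                         np_mask_volume = f * pi * 14^2 * 9)
    expect_gt(std$radius, fit$radius)  # f < 0.25 always in study range
  }
})

test_that("fibre pairs sit at 20 degrees to the transverse plane", {
  model <- fx_fe_model()
  mesh <- model$mesh
  af <- mesh$region == 3
  expect_true(any(af))
  for (cols in list(1:3, 4:6)) {
    v <- mesh$fibres[af, cols, drop = FALSE]
    lens <- sqrt(rowSums(v^2))
    expect_equal(lens, rep(1, sum(af)), tolerance = 1e-10)
    ang <- asin(abs(v[, 3]) / lens) * 180 / pi
    expect_true(all(abs(ang - 20) < 0.1))
  }
  # mirror symmetry about the transverse plane
  expect_equal(mesh$fibres[af, 1:2], mesh$fibres[af, 4:5])
  expect_equal(mesh$fibres[af, 3], -mesh$fibres[af, 6])
  # orthogonal to the radial direction
  ctr <- osteodisc:::element_centroids(mesh)[af, , drop = FALSE]
  rad <- cbind(ctr[, 1], ctr[, 2], 0)
  rad <- rad / sqrt(rowSums(rad^2))
  expect_lt(max(abs(rowSums(rad * mesh$fibres[af, 1:3]))), 1e-10)
})

test_that("greyscale bone assignment: uniform and two-valued phantoms", {
  model <- fx_fe_model()
  mesh <- model$mesh
  bone <- mesh$region %in% c(2, 5)
  # uniform fallback modulus
  expect_true(all(mesh$bone_E[bone] == 386.8))
  # two-valued synthetic CT: bimodal bone moduli at the mapped levels
  nx <- 40
  arr <- array(80, dim = c(nx, nx, nx))
  arr[, , 1:20] <- 200
  ct <- voxel_volume(arr, spacing = 0.5, origin = rep(-9.75, 3))
  lab <- voxel_volume(array(2L, dim = c(10, 10, 10)), spacing = 2,
                      origin = rep(-9, 3))
  m2 <- assign_bone_moduli(assign_fibres(mesh_specimen(lab, 2)), ct)
  E <- m2$bone_E[!is.na(m2$bone_E)]
  lv <- sort(unique(round(E, 6)))
  expect_equal(lv, bone_modulus_from_greyscale(c(80, 200)), tolerance = 1e-6)
  expect_true(all(E >= 3.6 & E <= 842))
})

test_that("boundary conditions prescribe the top face and clamp the bottom", {
  model <- fx_fe_model()
  bc <- build_bcs(model$mesh, 0.7)
  z <- model$mesh$nodes[, 3]
  expect_true(all(abs(z[bc$top_nodes] - max(z)) < model$mesh$h))
  expect_true(all(abs(z[bc$bottom_nodes] - min(z)) < model$mesh$h))
  vals <- matrix(bc$values, nrow = 3)
  fixed_nodes <- (matrix(bc$fixed_dofs, nrow = 3)[1, ] - 1) %/% 3 + 1
  top_cols <- fixed_nodes %in% bc$top_nodes
  expect_true(all(vals[3, top_cols] == -0.7))
  expect_true(all(vals[1:2, ] == 0))
})

test_that("marker-to-surface-node map distances stay within a grid cell", {
  ph <- generate_phantom(fe_config(markers_per_line = 3L), render = FALSE)
  model <- build_specimen_model(ph, "std_cyl", target_edge = 1.5)
  expect_equal(nrow(model$marker_map), 24L)
  expect_lt(max(model$marker_map$dist_mm), 1.5 * sqrt(3))
})

test_that("mesh and model exports write readable text artefacts", {
  model <- fx_fe_model()
  vtk <- tempfile(fileext = ".vtk")
  write_mesh_vtk(model$mesh, vtk)
  lines <- readLines(vtk, n = 6)
  expect_match(lines[4], "UNSTRUCTURED_GRID")
  inp <- tempfile(fileext = ".inp")
  write_model_inp(model, inp, displacement = 0.5)
  txt <- readLines(inp)
  expect_true(any(grepl("C3D4", txt)))
  expect_true(any(grepl("TOP, 3, 3, -0.5", txt)))
  unlink(c(vtk, inp))
})
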