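test_that("rigid transforms compose, invert and apply correctly", {
  R1 <- osteodisc:::rot_rodrigues(c(0, 0, 1), 0.3)
  tf <- rigid_transform(R1, c(1, -2, 0.5), center = c(3, 3, 3))
  pts <- matrix(rnorm(30), ncol = 3)
  back <- transform_points(invert_transform(tf), transform_points(tf, pts))
  expect_equal(back, pts, tolerance = 1e-12)
  tf2 <- rigid_transform(osteodisc:::rot_rodrigues(c(1, 1, 0), -0.2),
                         c(0, 1, 0))
  comp <- compose_transforms(tf, tf2)
  expect_equal(transform_points(comp, pts),
               transform_points(tf, transform_points(tf2, pts)),
               tolerance = 1e-10)
  expect_error(rigid_transform(matrix(1, 3, 3)), "rotation")
})

test_that("Kabsch alignment of point constellations is exact", {
  set.seed(4)
  pts <- matrix(runif(15, -5, 5), ncol = 3)
  # small relative rotation (scanner pose offset), arbitrary translation
  R <- osteodisc:::rot_rodrigues(c(1, 2, -1), 0.05)
  t <- c(10.3, -20.8, 5.2)
  moved <- t(R %*% t(pts)) + matrix(t, 5, 3, byrow = TRUE)
  tf <- osteodisc:::kabsch_align(pts, moved)
  expect_lt(attr(tf, "residual"), 1e-10)
  expect_equal(transform_points(tf, pts), moved, tolerance = 1e-10)
  # minimal case: 3 non-collinear markers
  tf3 <- osteodisc:::kabsch_align(pts[1:3, ], moved[1:3, ])
  expect_lt(attr(tf3, "residual"), 1e-10)
})

test_that("registering a volume to itself returns the identity", {
  ph <- fx_coarse_phantom()
  tf <- register_rigid(ph$ct, ph$ct, mode = "caudal", maxit = 150)
  ang <- acos(pmin(1, (sum(diag(tf$R)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.05)
  expect_lt(max(abs(tf$t)), 0.02)
})

test_that("caudal registration recovers a planted rigid perturbation", {
  d <- fx_coarse_deformed()
  planted <- d$phantom$truth$perturbations[[1]]
  c0 <- d$phantom$truth$geometry$center
  gt1 <- d$def$markers
  world <- t(planted$R %*% (t(as.matrix(gt1[, c("x", "y", "z")])) - c0) +
               c0 + planted$t)
  back <- transform_points(invert_transform(d$tf), world)
  rms <- sqrt(mean(rowSums((back - as.matrix(gt1[, c("x", "y", "z")]))^2)))
  expect_lt(rms, 0.5 * d$phantom$config$voxel_spacing)
})

test_that("pinpoint registration recovers the MR pose", {
  ph <- fx_coarse_phantom()
  tf <- register_rigid(ph$mr, ph$ct, mode = "pinpoint")
  pl <- ph$truth$mr_pose
  c0 <- ph$truth$geometry$center
  pts <- as.matrix(expand.grid(x = c(-4, 4), y = c(-4, 4), z = c(4, 10)))
  wpl <- t(pl$R %*% (t(pts) - c0) + c0 + pl$t)
  west <- transform_points(tf, pts)
  # limited by the coarse anisotropic MR grid (1 mm slices)
  expect_lt(sqrt(mean(rowSums((wpl - west)^2))), 0.5)
})

test_that("resampling: identity on the same grid, exact one-voxel shift", {
  set.seed(5)
  v <- voxel_volume(array(rnorm(6^3), dim = c(6, 6, 6)), spacing = 1)
  same <- resample_to(v, v)
  expect_equal(same$values, v$values, tolerance = 1e-12)
  # translation by exactly one voxel in +x
  tf <- rigid_transform(diag(3), t = c(1, 0, 0))
  sh <- resample_to(v, v, tf, background = 0)
  expect_equal(sh$values[1:5, , ], v$values[2:6, , ], tolerance = 1e-12)
  # MR-grid volume resampled onto a CT grid inherits the CT spacing
  mr <- voxel_volume(array(rnorm(4 * 4 * 2), dim = c(4, 4, 2)),
                     spacing = c(0.3, 0.3, 1), modality = "MR")
  ct <- voxel_volume(array(0, dim = c(10, 10, 10)), spacing = 0.082)
  out <- resample_to(mr, ct)
  expect_equal(out$spacing, rep(0.082, 3))
  expect_equal(dim(out$values), dim(ct$values))
})

test_that("rigid motion alone produces near-zero measured bulge", {
  cfg <- coarse_config(seed = 21,
                       bulge_profile = list(mean = rep(0, 4),
                                            sd = rep(0, 4)),
                       step_displacements = rep(1e-6, 4))
  ph <- generate_phantom(cfg)
  def <- deform_phantom(ph, 1)
  tf <- register_rigid(def$ct, ph$ct, mode = "caudal")
  mk0 <- detect_markers(ph$ct, 40)
  mk1 <- detect_markers(def$ct, 40)
  reg <- transform_points(invert_transform(tf),
                          as.matrix(mk1[, c("x", "y", "z")]))
  mk1$x <- reg[, 1]; mk1$y <- reg[, 2]; mk1$z <- reg[, 3]
  b <- compute_bulge(mk0, mk1)
  expect_lt(mean(b$bulge_mm), 0.5 * cfg$voxel_spacing)
})
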