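test_that("marker count follows the configured layout", {
  ph <- generate_phantom(coarse_config(), render = FALSE)
  expect_equal(nrow(dplyr::filter(ph$truth$markers, step == 0)), 40L)
  expect_equal(sort(unique(ph$truth$markers$zone)), sort(zone_names))

  cfg0 <- coarse_config(markers_per_line = 0L)
  ph0 <- generate_phantom(cfg0, render = FALSE)
  expect_equal(nrow(ph0$truth$markers), 0L)

  cfg23 <- coarse_config(n_marker_lines = 2L, markers_per_line = 3L)
  ph23 <- generate_phantom(cfg23, render = FALSE)
  expect_equal(nrow(dplyr::filter(ph23$truth$markers, step == 0)), 6L)
})

test_that("phantom config rejects undetectable or overlapping markers", {
  expect_error(phantom_config(marker_diameter = 0.1),
               "undetectable")
  expect_error(phantom_config(disc_height = 4), "overlap")
  expect_error(phantom_config(np_volume_fraction = 1.2), "np_volume_fraction")
})

test_that("nucleus volume fraction is sampled within 7-17% of disc volume", {
  fr <- vapply(1:15, function(i) {
    generate_phantom(coarse_config(seed = 100 + i),
                     render = FALSE)$truth$np_fraction
  }, numeric(1))
  expect_true(all(fr >= 0.07 & fr <= 0.17))
  # mask-measured fraction agrees with the planted fraction
  ph <- fx_coarse_phantom()
  expect_equal(np_volume_fraction(ph, spacing = 0.05),
               ph$truth$np_fraction, tolerance = 1e-3)
})

test_that("same seed gives bit-identical volumes and ground truth", {
  cfg <- coarse_config(seed = 77)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$mr$values, b$mr$values)
  expect_identical(a$truth$markers, b$truth$markers)
})

test_that("load record is monotone, convex, preloaded at 50 N and <= 2 kN", {
  ph <- generate_phantom(phantom_config(seed = 1), render = FALSE)
  rec <- generate_load_record(ph)
  expect_equal(rec$peak_load_N[1], 50)
  expect_true(all(diff(rec$peak_load_N) > 0))
  # convexity of the stiffening curve in displacement
  sl <- diff(rec$peak_load_N) / diff(rec$displacement_mm)
  expect_true(all(diff(sl) > 0))
  expect_lte(rec$peak_load_N[5], 2000)
})

test_that("planted displacement fields are exactly recoverable from truth", {
  ph <- generate_phantom(coarse_config(seed = 9), render = FALSE)
  tr <- ph$truth
  g <- tr$geometry
  mk0 <- dplyr::filter(tr$markers, step == 0)
  for (s in c(1, 3)) {
    mks <- dplyr::filter(tr$markers, step == !!s)
    theta <- atan2(mk0$y, mk0$x)
    zeta <- mk0$z - g$z_d0
    gmod <- osteodisc:::bulge_modulation(theta, tr$bulge$bias, tr$bulge$modes)
    expected_dr <- tr$bulge$A[s] * gmod * sin(pi * zeta / g$h)
    r0 <- sqrt(mk0$x^2 + mk0$y^2)
    rs <- sqrt(mks$x^2 + mks$y^2)
    expect_equal(rs - r0, expected_dr, tolerance = 1e-12)
    expect_equal(mks$z - g$z_d0,
                 zeta * (g$h - tr$applied$cumulative_mm[s]) / g$h,
                 tolerance = 1e-12)
  }
})

test_that("pure axial compression moves markers only axially", {
  cfg <- coarse_config(seed = 3,
                       bulge_profile = list(mean = rep(0, 4),
                                            sd = rep(0, 4)))
  ph <- generate_phantom(cfg, render = FALSE)
  mk0 <- dplyr::filter(ph$truth$markers, step == 0)
  mk1 <- dplyr::filter(ph$truth$markers, step == 1)
  b <- compute_bulge(mk0, mk1)
  expect_equal(b$bulge_mm, rep(0, 40))
  expect_true(all(mk1$z < mk0$z))
})

test_that("re-voxelized marker centroids deviate from truth by < 1 voxel", {
  ph <- fx_coarse_phantom()
  mk <- detect_markers(ph$ct, 40)
  gt <- dplyr::filter(ph$truth$markers, step == 0)
  j <- dplyr::inner_join(mk, gt, by = "marker_id", suffix = c("", ".gt"))
  err <- sqrt((j$x - j$x.gt)^2 + (j$y - j$y.gt)^2 + (j$z - j$z.gt)^2)
  expect_lt(max(err), ph$config$voxel_spacing)
})

test_that("applied displacements accumulate strictly and bound the truth", {
  ph <- generate_phantom(phantom_config(seed = 2), render = FALSE)
  ap <- ph$truth$applied
  expect_true(all(diff(ap$cumulative_mm) > 0))
  expect_equal(cumsum(ap$displacement_mm), ap$cumulative_mm)
  expect_equal(ph$truth$endcap_distance,
               2 * ph$truth$geometry$b + ph$truth$geometry$h -
                 c(0, ap$cumulative_mm))
})
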