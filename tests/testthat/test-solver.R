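test_that("zero displacement yields the zero solution", {
  model <- fx_bar_model()
  res <- solve_step(model, material_params(), 0)
  expect_equal(res$reaction_N, 0)
  expect_equal(max(abs(res$u)), 0)
})

test_that("uniaxial bar matches the linear closed form within 1%", {
  model <- fx_bar_model(E = 100)
  mats <- material_params(bone_nu = 0)  # uniaxial-stress closed form
  d <- 0.02  # 0.1% strain over 20 mm
  res <- solve_step(model, mats, d)
  closed <- 100 * 100 * d / 20  # E A eps
  expect_equal(res$reaction_N, closed, tolerance = 0.01)
})

test_that("a single element under homogeneous deformation reproduces the constitutive stress", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  elems <- matrix(1:4, 1)
  F <- random_F(1, scale = 0.05, seed = 77)[[1]]
  u <- t(F %*% t(nodes)) - nodes
  fib <- af_fibres()
  asm <- osteodisc:::cpp_assemble(nodes, elems - 1L, u, 2L,
                                  matrix(c(0.25, 1.43, 1.63, 50), 1),
                                  matrix(as.vector(fib), 1), 0L, FALSE)
  ev <- goh_energy_stress(F, 0.25, 1.43, 1.63, 50, fib)
  V0 <- 1 / 6
  expect_equal(asm$energy, V0 * ev$energy, tolerance = 1e-12)
  # nodal forces from the exact first Piola-Kirchhoff stress
  G <- rbind(c(-1, -1, -1), diag(3))
  f_exact <- V0 * G %*% t(ev$P)
  expect_equal(matrix(as.numeric(asm$fint), 4, 3, byrow = TRUE), f_exact,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rigid translation produces no internal force", {
  model <- fx_bar_model()
  mesh <- model$mesh
  mats <- osteodisc:::build_material_arrays(mesh, material_params())
  u <- matrix(rep(c(0.3, -0.2, 0.5), each = nrow(mesh$nodes)),
              ncol = 3)
  asm <- osteodisc:::cpp_assemble(mesh$nodes, mesh$elems - 1L, u,
                                  mats$mtype, mats$mpar, mats$mfib, 0L,
                                  FALSE)
  expect_lt(max(abs(asm$fint)), 1e-9)
})

test_that("global equilibrium: constraint forces sum to zero", {
  model <- fx_fe_model()
  res <- solve_step(model, material_params(K_af = 500, K_np = 500), 0.5)
  asm <- attr(res$u, "displacement")  # solved state retained
  mesh <- model$mesh
  mats <- osteodisc:::build_material_arrays(mesh,
                                            material_params(K_af = 500,
                                                            K_np = 500))
  a <- osteodisc:::cpp_assemble(mesh$nodes, mesh$elems - 1L, res$u,
                                mats$mtype, mats$mpar, mats$mfib, 0L, FALSE)
  f <- matrix(as.numeric(a$fint), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colSums(f))), 1e-8 * res$reaction_N)
  expect_gt(res$reaction_N, 0)
})

test_that("solution is invariant under node renumbering", {
  model <- fx_bar_model(E = 50)
  mesh <- model$mesh
  set.seed(9)
  perm <- sample(nrow(mesh$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes[perm, ]
  mesh2$elems <- matrix(inv[mesh$elems], ncol = 4)
  bc <- build_bcs(mesh2, 0)
  model2 <- model
  model2$mesh <- mesh2
  model2$top_nodes <- bc$top_nodes
  model2$bottom_nodes <- bc$bottom_nodes
  r1 <- solve_step(model, material_params(), 0.05)
  r2 <- solve_step(model2, material_params(), 0.05)
  expect_equal(r2$reaction_N, r1$reaction_N, tolerance = 1e-9)
})

test_that("reaction force Cauchy-converges under mesh refinement", {
  ph <- generate_phantom(fe_config(seed = 13), render = FALSE)
  edges <- c(3.2, 2.2, 1.55)
  loads <- vapply(edges, function(h) {
    m <- build_specimen_model(ph, "std_cyl", target_edge = h)
    solve_step(m, material_params(K_af = 300, K_np = 300), 0.5)$reaction_N
  }, numeric(1))
  d <- abs(diff(loads))
  expect_lt(d[2], d[1])
})

test_that("doubling the displacement doubles the load for a linear material", {
  model <- fx_bar_model(E = 200)
  mats <- material_params(bone_nu = 0.3)
  r1 <- solve_step(model, mats, 0.005)
  r2 <- solve_step(model, mats, 0.010)
  expect_equal(r2$reaction_N / r1$reaction_N, 2, tolerance = 0.01)
})

test_that("predicted bulge is zero for the zero solution and positive under compression", {
  ph <- generate_phantom(fe_config(markers_per_line = 3L), render = FALSE)
  model <- build_specimen_model(ph, "std_cyl", target_edge = 2.2)
  r0 <- solve_step(model, material_params(), 0)
  expect_equal(predict_bulge(r0, model)$bulge_mm,
               rep(0, nrow(model$marker_map)))
  r <- solve_step(model, material_params(K_af = 2200, K_np = 2200), 0.6)
  b <- predict_bulge(r, model)
  # near-incompressible tissue must bulge radially under axial compression
  expect_gt(mean(b$bulge_mm), 0)
})

test_that("forward load curves stiffen and respond to compressibility", {
  fr <- fx_fe_record()
  expect_true(all(diff(fr$record$peak_load_N) > 0))
  sl <- diff(fr$record$peak_load_N) / diff(fr$record$displacement_mm)
  expect_true(all(diff(sl) > 0))  # convex stiffening
  # lower bulk modulus -> softer response at the same displacement
  soft <- forward_load_curve(fr$model,
                             material_params(K_af = 800, K_np = 150),
                             c(0.5, 1.0, 1.5))
  expect_true(all(soft$load_N < fr$record$peak_load_N))
})
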