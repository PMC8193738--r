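fd_stress <- function(fun, F, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (fun(Fp)$energy - fun(Fm)$energy) / (2 * h)
  }
  P
}

fd_tangent <- function(fun, F, h = 1e-6) {
  A <- matrix(0, 9, 9)
  for (j in 1:3) for (J in 1:3) {
    Fp <- F; Fp[j, J] <- Fp[j, J] + h
    Fm <- F; Fm[j, J] <- Fm[j, J] - h
    A[, j + 3 * (J - 1)] <- as.vector((fun(Fp)$P - fun(Fm)$P) / (2 * h))
  }
  A
}

test_that("Mooney-Rivlin stress and tangent are exact derivatives", {
  fun <- function(F) mooney_rivlin_energy_stress(F, 0.07, 0.02, 50)
  for (F in random_F(12, seed = 21)) {
    ev <- fun(F)
    expect_equal(ev$P, fd_stress(fun, F), tolerance = 1e-6)
    expect_equal(ev$tangent, fd_tangent(fun, F), tolerance = 1e-5)
  }
  evI <- fun(diag(3))
  expect_equal(evI$energy, 0)
  expect_equal(evI$cauchy, matrix(0, 3, 3))
})

test_that("GOH stress and tangent are exact derivatives", {
  fib <- af_fibres()
  fun <- function(F) goh_energy_stress(F, 0.25, 1.43, 1.63, 50, fib)
  for (F in random_F(12, seed = 22)) {
    ev <- fun(F)
    expect_equal(ev$P, fd_stress(fun, F), tolerance = 1e-6)
    expect_equal(ev$tangent, fd_tangent(fun, F), tolerance = 1e-5)
  }
  expect_equal(fun(diag(3))$energy, 0)
})

test_that("stress is objective under superposed rotations", {
  fib <- af_fibres()
  for (s in 1:5) {
    F <- random_F(1, seed = 30 + s)[[1]]
    Q <- random_rotation(40 + s)
    for (fun in list(
      function(F) mooney_rivlin_energy_stress(F, 0.07, 0.02, 80),
      function(F) goh_energy_stress(F, 0.25, 1.43, 1.63, 80, fib))) {
      s1 <- fun(F)
      s2 <- fun(Q %*% F)
      expect_equal(Q %*% s1$cauchy %*% t(Q), s2$cauchy, tolerance = 1e-9)
      expect_equal(s1$energy, s2$energy, tolerance = 1e-9)
    }
  }
})

test_that("compressed fibres carry no load (Macaulay bracket)", {
  fib <- af_fibres()
  # uniaxial transverse compression shortens both fibres
  F <- diag(c(0.95, 1.0, 0.98))
  g <- goh_energy_stress(F, 0.25, 1.43, 1.63, 60, fib)
  nh <- goh_energy_stress(F, 0.25, 0, 1.63, 60, fib)
  expect_equal(g$S, nh$S, tolerance = 1e-12)
  expect_equal(g$energy, nh$energy, tolerance = 1e-12)
})

test_that("non-unit fibre directions are normalised with a warning", {
  F <- random_F(1, seed = 51)[[1]]
  expect_warning(
    a <- goh_energy_stress(F, 0.25, 1.43, 1.63, 60, 2 * af_fibres()),
    "normalising")
  b <- goh_energy_stress(F, 0.25, 1.43, 1.63, 60, af_fibres())
  expect_equal(a$S, b$S)
})

test_that("large bulk modulus drives J to 1 in a traction-free state", {
  # uniaxial stretch with lateral contraction solved for zero lateral stress
  lateral_solve <- function(K) {
    lat <- 0.97
    for (i in 1:80) {
      f <- function(l) mooney_rivlin_energy_stress(
        diag(c(1.1, l, l)), 0.07, 0.02, K)$cauchy[2, 2]
      r <- f(lat)
      dr <- (f(lat + 1e-7) - r) / 1e-7
      lat <- lat - r / dr
      if (abs(r) < 1e-12) break
    }
    det(diag(c(1.1, lat, lat)))
  }
  expect_lt(abs(lateral_solve(5000) - 1), abs(lateral_solve(5) - 1))
  expect_equal(lateral_solve(5000), 1, tolerance = 1e-3)
})

test_that("bone modulus map hits the published range ends and clamps", {
  expect_equal(bone_modulus_from_greyscale(0), 3.6)
  expect_equal(bone_modulus_from_greyscale(255), 842, tolerance = 1e-6)
  expect_equal(bone_modulus_from_greyscale(c(100, 200), slope = 0,
                                           intercept = 50), c(50, 50))
  expect_error(bone_modulus_from_greyscale(300), "0, 255")
  gs <- seq(0, 255, by = 5)
  E <- bone_modulus_from_greyscale(gs)
  expect_true(all(E >= 3.6 & E <= 842))
  expect_true(all(diff(E) >= 0))
})

test_that("equivalent Poisson's ratio limits, monotonicity and values", {
  expect_equal(equivalent_poisson(4 * 0.07 / 3, 0.07), 0)
  expect_equal(equivalent_poisson(1e12, 0.07), 0.5, tolerance = 1e-10)
  expect_equal(equivalent_poisson(2200, 0.07),
               (3 * 2200 - 4 * 0.07) / (6 * 2200 + 4 * 0.07))
  Ks <- c(10, 100, 1000, 10000)
  nus <- equivalent_poisson(Ks, 1.92)
  expect_true(all(diff(nus) > 0))
  expect_true(all(nus < 0.5))
})

test_that("annulus linearisation: matrix-only limit and fibre monotonicity", {
  c0 <- linearize_af_shear(material_params(af_k1 = 1e-10))
  expect_equal(as.numeric(c0), 0.25, tolerance = 0.01)
  cl <- vapply(c(0.7, 1.43, 2.86), function(k1)
    as.numeric(linearize_af_shear(material_params(af_k1 = k1))), numeric(1))
  expect_true(all(diff(cl) > 0))
  # Table-value parameters: reported, with fit metadata attached
  full <- linearize_af_shear(material_params())
  expect_gt(as.numeric(full), 0.25)
  expect_true(!is.null(attr(full, "mode")))
})
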