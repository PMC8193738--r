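ccc_oracle <- function(x, y) {
  # explicit-sum evaluation, independent of the implementation path
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  2 * sxy / (sxx + syy + n * (mx - my)^2)
}

test_that("concordance equals the explicit formula to 1e-10", {
  set.seed(15)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), 2, 1)
    y <- 0.8 * x + rnorm(length(x), 0.3, 0.4)
    expect_equal(concordance(x, y)$ccc, ccc_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("concordance is symmetric and penalises pure shifts", {
  set.seed(16)
  x <- rnorm(30)
  y <- x + rnorm(30, 0, 0.3)
  expect_equal(concordance(x, y)$ccc, concordance(y, x)$ccc,
               tolerance = 1e-12)
  sh <- concordance(x, x + 1)
  expect_lt(sh$ccc, 1)
  expect_equal(sh$pearson, 1)
  expect_equal(concordance(x, x)$ccc, 1)
})

test_that("ccc magnitude never exceeds the Pearson correlation", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(25, 0.2 * x, 1)
    cc <- concordance(x, y)
    expect_lte(abs(cc$ccc), abs(cc$pearson) + 1e-12)
  }
})

test_that("confidence interval brackets the ccc and degenerates sensibly", {
  set.seed(18)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.2)
  cc <- concordance(x, y)
  expect_lte(cc$ci95[1], cc$ccc)
  expect_gte(cc$ci95[2], cc$ccc)
  expect_equal(concordance(x, x)$ci95, c(1, 1))
  expect_error(concordance(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(concordance(1:2, 1:2), "at least 3")
})

test_that("added noise strictly degrades expected concordance", {
  set.seed(19)
  x <- rnorm(200, 1, 0.5)
  c0 <- mean(replicate(30, concordance(x, x + rnorm(200, 0, 0.1))$ccc))
  c1 <- mean(replicate(30, concordance(x, x + rnorm(200, 0, 0.5))$ccc))
  expect_gt(c0, c1)
})

test_that("bulge agreement filters the lower tenth percentile and bands by resolution", {
  set.seed(20)
  iv <- tibble::tibble(specimen_id = "s1", marker_id = 1:40, step = 1L,
                       bulge_mm = seq(0.05, 2, length.out = 40))
  # perfect prediction: ccc 1, full resolution band
  ag <- bulge_agreement(iv, iv)
  expect_equal(ag$ccc, 1)
  expect_equal(ag$resolution_band_fraction, 1)
  expect_equal(ag$n_pairs, 36L)  # 4 of 40 excluded
  # degenerate zero prediction: non-positive concordance
  is0 <- dplyr::mutate(iv, bulge_mm = 0)
  ag0 <- bulge_agreement(iv, is0)
  expect_lte(ag0$ccc, 0)
  expect_true(all(ag0$mean_difference$difference <= 0))
  # Gaussian prediction noise at the resolution scale: ~68% inside the band
  iv2 <- tibble::tibble(specimen_id = "s1", marker_id = 1:4000, step = 1L,
                        bulge_mm = runif(4000, 0.3, 1.5))
  is2 <- dplyr::mutate(iv2, bulge_mm = bulge_mm + rnorm(4000, 0, 0.082))
  ag2 <- bulge_agreement(iv2, is2)
  expect_equal(ag2$resolution_band_fraction, 2 * pnorm(1) - 1,
               tolerance = 0.04)
})

test_that("load agreement pools cells in the model-type by mode layout", {
  set.seed(22)
  iv <- tidyr::expand_grid(specimen_id = sprintf("s%d", 1:4), step = 1:3)
  iv$load_N <- 300 * iv$step + rnorm(nrow(iv), 0, 20)
  cells <- tidyr::expand_grid(model_type = c("std_cyl", "fit_cyl", "mr"),
                              calibration_mode = c("one_to_one", "average"))
  is <- tidyr::expand_grid(cells, iv[, c("specimen_id", "step")])
  is <- dplyr::left_join(is, iv, by = c("specimen_id", "step"))
  is$load_N <- is$load_N + ifelse(is$calibration_mode == "average",
                                  rnorm(nrow(is), 0, 80),
                                  rnorm(nrow(is), 0, 5))
  out <- load_agreement(iv, is)
  expect_equal(nrow(out), 6L)
  expect_true(all(out$ccc <= 1 & out$ccc >= -1))
  one <- out$ccc[out$calibration_mode == "one_to_one"]
  avg <- out$ccc[out$calibration_mode == "average"]
  expect_gt(mean(one), mean(avg))
})
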