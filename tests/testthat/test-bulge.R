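mk_set <- function(xyz, ids = seq_len(nrow(xyz)), zone = "A") {
  tibble::tibble(marker_id = ids, zone = zone, x = xyz[, 1], y = xyz[, 2],
                 z = xyz[, 3])
}

test_that("bulge is the transverse-plane displacement norm", {
  m0 <- mk_set(matrix(c(1, 0, 5), 1))
  # purely axial motion: zero bulge
  m_ax <- mk_set(matrix(c(1, 0, 5.9), 1))
  expect_equal(compute_bulge(m0, m_ax)$bulge_mm, 0)
  # 3-4-5 in-plane displacement with an axial component: 0.5 mm
  m_345 <- mk_set(matrix(c(1.3, 0.4, 5.5), 1))
  expect_equal(compute_bulge(m0, m_345)$bulge_mm, 0.5)
})

test_that("unmatched marker ids are dropped with a warning", {
  m0 <- mk_set(matrix(rnorm(9), 3), ids = 1:3)
  m1 <- mk_set(matrix(rnorm(9), 3), ids = c(1, 2, 9))
  expect_warning(b <- compute_bulge(m0, m1), "unmatched")
  expect_equal(nrow(b), 2L)
})

test_that("bulge is invariant under in-plane rigid motion but not tilt", {
  set.seed(6)
  xyz0 <- cbind(rnorm(10), rnorm(10), rnorm(10) + 5)
  xyz1 <- xyz0 + cbind(rnorm(10, 0, 0.2), rnorm(10, 0, 0.2), rnorm(10, 0.5))
  b0 <- compute_bulge(mk_set(xyz0), mk_set(xyz1))$bulge_mm
  # common rotation about the axial axis + in-plane translation
  th <- 0.4
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(2, -1, 0)
  ap <- function(m) t(Rz %*% t(m)) + matrix(shift, nrow(m), 3, byrow = TRUE)
  b1 <- compute_bulge(mk_set(ap(xyz0)), mk_set(ap(xyz1)))$bulge_mm
  expect_equal(b1, b0, tolerance = 1e-12)
  # a tilt about x mixes axial into transverse: not invariant
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  apx <- function(m) t(Rx %*% t(m))
  b2 <- compute_bulge(mk_set(apx(xyz0)), mk_set(apx(xyz1)))$bulge_mm
  expect_gt(max(abs(b2 - b0)), 1e-3)
})

test_that("normalisation divides by the applied displacement", {
  tab <- tibble::tibble(specimen_id = "s1", marker_id = 1:2, zone = "A",
                        step = 1L, bulge_mm = c(0.24, 0))
  out <- normalize_bulge(tab, c("1" = 0.89))
  expect_equal(out$normalized_bulge, c(0.24 / 0.89, 0))
  # scale invariance: scaling bulge and displacement together
  tab2 <- dplyr::mutate(tab, bulge_mm = bulge_mm * 3)
  out2 <- normalize_bulge(tab2, c("1" = 0.89 * 3))
  expect_equal(out2$normalized_bulge, out$normalized_bulge)
  expect_error(normalize_bulge(tab, c("1" = 0)), "positive")
})

test_that("tenth-percentile filter retains 36 of 40 distinct values", {
  tab <- tibble::tibble(specimen_id = "s", marker_id = 1:40, zone = "A",
                        step = 1L, bulge_mm = sample(seq(0.1, 4, 0.1)))
  out <- percentile_filter(tab)
  expect_equal(nrow(out), 36L)
  expect_gte(min(out$bulge_mm),
             quantile(tab$bulge_mm, 0.1, type = 7, names = FALSE))
  # all-equal values: nothing strictly below the percentile
  same <- dplyr::mutate(tab, bulge_mm = 1)
  expect_equal(nrow(percentile_filter(same)), 40L)
})

test_that("Welch ANOVA matches a first-principles oracle to 1e-8", {
  set.seed(10)
  tab <- tibble::tibble(
    specimen_id = "s", marker_id = 1:40,
    zone = rep(zone_names, each = 5), step = 1L,
    normalized_bulge = rnorm(40, rep(c(0.2, 0.25, 0.3, 0.22, 0.28, 0.24,
                                       0.26, 0.21), each = 5), 0.03))
  rc <- regional_comparison(tab, 1)
  # Welch (1951) statistic computed directly from group summaries
  g <- split(tab$normalized_bulge, tab$zone)
  ni <- lengths(g); mi <- vapply(g, mean, 0); vi <- vapply(g, var, 0)
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  k <- length(g)
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  B <- sum((1 - wi / sum(wi))^2 / (ni - 1))
  Fw <- A / (1 + 2 * (k - 2) / (k^2 - 1) * B)
  df2 <- (k^2 - 1) / (3 * B)
  expect_equal(rc$welch$statistic, Fw, tolerance = 1e-8)
  expect_equal(rc$welch$df2, df2, tolerance = 1e-8)
  expect_equal(rc$welch$p_value, pf(Fw, k - 1, df2, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(nrow(rc$shapiro), 8L)
  expect_true(is.finite(rc$levene_p))
})

test_that("null simulation keeps the Welch type-I rate near 0.05", {
  set.seed(123)
  rej <- vapply(1:200, function(i) {
    tab <- tibble::tibble(zone = rep(zone_names, each = 5), step = 1L,
                          normalized_bulge = rnorm(40, 0.25, 0.05))
    regional_comparison(tab, 1)$welch$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("a planted anterior shift is detected with Bonferroni post-hoc", {
  set.seed(11)
  mu <- ifelse(rep(zone_names, each = 6) %in% c("A", "AL", "AR"),
               0.25 + 3 * 0.03, 0.25)
  tab <- tibble::tibble(zone = rep(zone_names, each = 6), step = 1L,
                        normalized_bulge = rnorm(48, mu, 0.03))
  rc <- regional_comparison(tab, 1)
  expect_lt(rc$welch$p_value, 0.05)
  expect_false(is.null(rc$posthoc))
  # anterior vs posterior pair significant after correction
  p_ap <- rc$posthoc["P", "A"]
  if (is.na(p_ap)) p_ap <- rc$posthoc["A", "P"]
  expect_lt(p_ap, 0.05)
})

test_that("degenerate zone structures are rejected", {
  tab <- tibble::tibble(zone = rep("A", 10), step = 1L,
                        normalized_bulge = rnorm(10))
  expect_error(regional_comparison(tab, 1), "at least 2 zones")
  tab2 <- tibble::tibble(zone = c("A", "A", "A", "P", "P"), step = 1L,
                         normalized_bulge = rnorm(5))
  expect_error(regional_comparison(tab2, 1), "at least")
})
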