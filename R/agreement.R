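#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurement methods:
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, combining precision (Pearson correlation) and accuracy
#' (location/scale bias). The 95% confidence interval uses Lin's
#' Fisher z-transform normal approximation.
#'
#' @param x,y equal-length paired samples (n >= 3).
#' @param conf confidence level (default 0.95).
#' @param moment `"population"` (1/n, Lin's original) or `"sample"`
#'   (1/(n-1)) denominators.
#' @return An `agreement_result`: `ccc`, `ci95`, `n_pairs`, `pearson`,
#'   `mean_difference` tibble (pair means and differences, Bland-Altman
#'   style), and the input pairs.
#' @export
concordance <- function(x, y, conf = 0.95,
                        moment = c("population", "sample")) {
  moment <- match.arg(moment)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  mx <- mean(x); my <- mean(y)
  denomf <- if (moment == "population") n else n - 1
  sx2 <- sum((x - mx)^2) / denomf
  sy2 <- sum((y - my)^2) / denomf
  sxy <- sum((x - mx) * (y - my)) / denomf
  if (sx2 == 0 && sy2 == 0 && mx == my)
    stop("zero variance in both inputs: concordance undefined")
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (is.finite(r) && abs(ccc) < 1 && abs(r) > 0 && n > 2) {
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)
    se2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(se2) && se2 >= 0) {
      z <- atanh(ccc)
      zc <- qnorm(1 - (1 - conf) / 2)
      ci <- tanh(z + c(-1, 1) * zc * sqrt(se2))
    }
  } else if (abs(ccc) >= 1) {
    ci <- c(ccc, ccc)
  }
  out <- list(ccc = ccc, ci95 = ci, n_pairs = n, pearson = r,
              mean_difference = tibble::tibble(mean = (x + y) / 2,
                                               difference = y - x),
              x = x, y = y)
  class(out) <- "agreement_result"
  out
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> CCC = %.4f (95%% CI %.4f, %.4f), n = %d\n",
              x$ccc, x$ci95[1], x$ci95[2], x$n_pairs))
  cat(sprintf("  Pearson r = %.4f; mean difference %.4g\n", x$pearson,
              mean(x$mean_difference$difference)))
  if (!is.null(x$resolution_band_fraction))
    cat(sprintf("  fraction within resolution band (%.0f um): %.3f\n",
                1000 * x$resolution_mm, x$resolution_band_fraction))
  invisible(x)
}

#' In-vitro versus in-silico bulge agreement
#'
#' Pairs measured and predicted bulge by specimen, marker and step,
#' excludes pairs whose experimental bulge falls in the lower tenth
#' percentile (pooled; see [percentile_filter()]), and scores concordance.
#' Also reports the fraction of surviving pairs whose absolute difference
#' is below the imaging resolution band (82 um by default).
#'
#' @param invitro,insilico bulge tibbles (from [compute_bulge()] /
#'   [predict_bulge()]).
#' @param resolution_mm the imaging resolution band, mm.
#' @param prob exclusion percentile on the experimental bulge.
#' @return An `agreement_result` with `resolution_band_fraction`.
#' @export
bulge_agreement <- function(invitro, insilico, resolution_mm = 0.082,
                            prob = 0.1) {
  keyed <- intersect(c("specimen_id", "marker_id", "step"),
                     intersect(names(invitro), names(insilico)))
  j <- dplyr::inner_join(
    dplyr::select(invitro, dplyr::all_of(keyed), invitro = "bulge_mm"),
    dplyr::select(insilico, dplyr::all_of(keyed), insilico = "bulge_mm"),
    by = keyed)
  if (nrow(j) == 0) stop("no matched marker/step pairs")
  cutoff <- quantile(j$invitro, prob, type = 7, names = FALSE)
  j <- j[j$invitro >= cutoff, , drop = FALSE]
  if (nrow(j) == 0) stop("no pairs survive the percentile filter")
  out <- concordance(j$invitro, j$insilico)
  out$resolution_mm <- resolution_mm
  out$resolution_band_fraction <-
    mean(abs(j$insilico - j$invitro) < resolution_mm)
  out$percentile_cutoff <- cutoff
  out
}

#' Pooled load agreement per model type and calibration mode
#'
#' Replicates the structure of the load-agreement summary: one concordance
#' per (nucleus model type, calibration mode) cell, pooling all specimens
#' and displacement steps in the cell.
#'
#' @param records_invitro tibble `(specimen_id, step, load_N)`.
#' @param records_insilico tibble `(specimen_id, step, load_N)` plus the
#'   grouping columns.
#' @param grouping character vector of grouping columns in
#'   `records_insilico`.
#' @return Tibble with one row per cell: grouping columns, `ccc`, `ci_lo`,
#'   `ci_hi`, `n_pairs`. Cells with too few pairs are skipped with a
#'   warning.
#' @export
load_agreement <- function(records_invitro, records_insilico,
                           grouping = c("model_type", "calibration_mode")) {
  grouping <- intersect(grouping, names(records_insilico))
  cells <- dplyr::distinct(records_insilico[, grouping, drop = FALSE])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(records_insilico))
    for (g in grouping)
      sel <- sel & records_insilico[[g]] == cells[[g]][i]
    sub <- records_insilico[sel, , drop = FALSE]
    j <- dplyr::inner_join(
      dplyr::select(records_invitro, "specimen_id", "step",
                    invitro = "load_N"),
      dplyr::select(sub, "specimen_id", "step", insilico = "load_N"),
      by = c("specimen_id", "step"))
    if (nrow(j) < 3) {
      warning("skipping cell ", paste(unlist(cells[i, ]), collapse = "/"),
              ": fewer than 3 pairs")
      next
    }
    cc <- concordance(j$invitro, j$insilico)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      cells[i, , drop = FALSE],
      tibble::tibble(ccc = cc$ccc, ci_lo = cc$ci95[1], ci_hi = cc$ci95[2],
                     n_pairs = cc$n_pairs))
  }
  dplyr::bind_rows(rows)
}

#' @export
tidy.agreement_result <- function(x, ...) {
  tibble::tibble(ccc = x$ccc, ci_lo = x$ci95[1], ci_hi = x$ci95[2],
                 pearson = x$pearson, n_pairs = x$n_pairs,
                 mean_difference = mean(x$mean_difference$difference),
                 resolution_band_fraction =
                   x$resolution_band_fraction %||% NA_real_)
}

#' @export
glance.agreement_result <- function(x, ...) tidy.agreement_result(x)
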