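#' Compute per-marker disc bulge between two compression states
#'
#' Bulge at a marker is the displacement of its centroid in the transverse
#' plane between the deformed and the initial (preloaded) stage: the
#' Euclidean norm of the (x, y) centroid difference. The axial component is
#' ignored. Both marker sets must be expressed in the registered
#' (preloaded) frame and share marker ids; unmatched ids are dropped with a
#' warning.
#'
#' @param markers_step0 marker tibble at the preloaded state (from
#'   [detect_markers()] or ground truth).
#' @param markers_stepk marker tibble at the deformed step.
#' @param specimen_id specimen identifier recorded in the output.
#' @param step step index recorded in the output.
#' @return A tibble `(specimen_id, marker_id, zone, step, bulge_mm)`.
#' @export
compute_bulge <- function(markers_step0, markers_stepk,
                          specimen_id = "s1", step = 1L) {
  j <- dplyr::inner_join(
    dplyr::select(markers_step0, "marker_id", "zone", x0 = "x", y0 = "y"),
    dplyr::select(markers_stepk, "marker_id", xk = "x", yk = "y"),
    by = "marker_id")
  dropped <- setdiff(union(markers_step0$marker_id, markers_stepk$marker_id),
                     j$marker_id)
  if (length(dropped) > 0)
    warning("dropping unmatched marker id(s): ",
            paste(dropped, collapse = ", "))
  tibble::tibble(
    specimen_id = specimen_id,
    marker_id = j$marker_id,
    zone = j$zone,
    step = as.integer(step),
    bulge_mm = sqrt((j$xk - j$x0)^2 + (j$yk - j$y0)^2))
}

#' Normalise bulge by the applied displacement
#'
#' Adds `normalized_bulge = bulge_mm / applied displacement at that step`,
#' the dimensionless quantity compared across specimens with slightly
#' different platen displacements.
#'
#' @param table a bulge tibble from [compute_bulge()].
#' @param applied_displacements tibble `(step, displacement_mm)` (extra
#'   columns such as `specimen_id` join if present) or a named numeric
#'   vector keyed by step.
#' @return The input tibble with a `normalized_bulge` column.
#' @export
normalize_bulge <- function(table, applied_displacements) {
  if (!is.data.frame(applied_displacements)) {
    applied_displacements <- tibble::tibble(
      step = as.integer(names(applied_displacements)),
      displacement_mm = as.numeric(applied_displacements))
  }
  by <- intersect(c("specimen_id", "step"), names(applied_displacements))
  if (any(applied_displacements$displacement_mm <= 0))
    stop("applied displacement must be positive for every step")
  out <- dplyr::left_join(table, applied_displacements, by = by)
  if (anyNA(out$displacement_mm))
    stop("missing applied displacement for some step(s)")
  out$normalized_bulge <- out$bulge_mm / out$displacement_mm
  dplyr::select(out, -"displacement_mm")
}

#' Lower-tenth-percentile exclusion filter
#'
#' Removes rows whose value falls strictly below the 10th percentile of the
#' comparison set (pooled over the supplied table), the exclusion applied
#' before concordance analysis so that the smallest, most error-prone
#' experimental displacements do not enter the comparison.
#'
#' @param table a bulge tibble.
#' @param value column to filter on (default `bulge_mm`).
#' @param prob percentile (default 0.1).
#' @param type quantile definition passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return The filtered tibble; attribute `cutoff` holds the percentile.
#' @export
percentile_filter <- function(table, value = "bulge_mm", prob = 0.1,
                              type = 7) {
  if (nrow(table) == 0) stop("empty table")
  cutoff <- quantile(table[[value]], prob, type = type, names = FALSE)
  out <- table[table[[value]] >= cutoff, , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  out
}

#' Regional comparison of normalised bulge across disc zones
#'
#' Runs the per-step regional analysis: Shapiro-Wilk normality per zone,
#' Levene's test for heteroscedasticity, a Welch-corrected one-way ANOVA of
#' normalised bulge across the marker zones, and -- when the ANOVA is
#' significant at 0.05 -- a post-hoc pairwise t-test with pooled SD and
#' Bonferroni correction. Normality and variance diagnostics are reported
#' but do not gate the Welch test.
#'
#' @param table bulge tibble with `zone` and the value column.
#' @param step step to analyse (filters `table$step`).
#' @param value column analysed (default `normalized_bulge`).
#' @param alpha significance threshold (default 0.05).
#' @return A `regional_comparison` list: `shapiro` (per-zone p), `levene_p`,
#'   `welch` (F, df, p), `posthoc` (Bonferroni-adjusted pairwise p matrix or
#'   `NULL`), `n_per_zone`, `step`, `alpha`.
#' @export
regional_comparison <- function(table, step, value = "normalized_bulge",
                                alpha = 0.05) {
  d <- table[table$step == step, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows at step ", step)
  d$zone <- factor(d$zone)
  counts <- table(d$zone)
  counts <- counts[counts > 0]
  if (length(counts) < 2 || any(counts < 3))
    stop("need at least 2 zones with at least 3 markers each")
  d$zone <- droplevels(d$zone)
  v <- d[[value]]
  shap <- vapply(split(v, d$zone), function(x) {
    if (length(unique(x)) < 3) NA_real_ else shapiro.test(x)$p.value
  }, numeric(1))
  lev <- car::leveneTest(v ~ d$zone)
  welch <- oneway.test(v ~ d$zone, var.equal = FALSE)
  posthoc <- NULL
  if (is.finite(welch$p.value) && welch$p.value < alpha) {
    posthoc <- pairwise.t.test(v, d$zone, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)$p.value
  }
  structure(list(
    step = step,
    shapiro = tibble::tibble(zone = names(shap), p_normality = unname(shap)),
    levene_p = lev[["Pr(>F)"]][1],
    welch = tibble::tibble(statistic = unname(welch$statistic),
                           df1 = unname(welch$parameter[1]),
                           df2 = unname(welch$parameter[2]),
                           p_value = welch$p.value),
    posthoc = posthoc,
    n_per_zone = tibble::tibble(zone = names(counts), n = as.integer(counts)),
    alpha = alpha), class = "regional_comparison")
}

#' @export
print.regional_comparison <- function(x, ...) {
  cat(sprintf("Regional bulge comparison, step %s\n", x$step))
  cat(sprintf("  Welch ANOVA: F = %.3f (df %.1f, %.1f), p = %.4g\n",
              x$welch$statistic, x$welch$df1, x$welch$df2, x$welch$p_value))
  cat(sprintf("  Levene p = %.4g; Shapiro p range [%.3g, %.3g]\n",
              x$levene_p, min(x$shapiro$p_normality, na.rm = TRUE),
              max(x$shapiro$p_normality, na.rm = TRUE)))
  if (!is.null(x$posthoc))
    cat("  Post-hoc pairwise t (pooled SD, Bonferroni) computed:",
        sum(!is.na(x$posthoc)), "pairs\n")
  else
    cat(sprintf("  ANOVA not significant at %.2f: no post-hoc\n", x$alpha))
  invisible(x)
}

#' @export
tidy.regional_comparison <- function(x, ...) {
  out <- tibble::tibble(
    step = x$step, term = "zone",
    statistic = x$welch$statistic, df1 = x$welch$df1, df2 = x$welch$df2,
    p_value = x$welch$p_value, levene_p = x$levene_p)
  out
}
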