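#' Study configuration
#'
#' Describes a full synthetic cohort study with both arms: the experimental
#' emulation (phantom generation, bulge measurement, load records) and the
#' computational arm (specimen-specific FE models per nucleus type,
#' compressibility calibration, agreement scoring).
#'
#' @param n_specimens cohort size (6 in the physical study).
#' @param nucleus_types subset of `c("std_cyl", "fit_cyl", "mr")`.
#' @param calibration_modes subset of `c("one_to_one", "average")`.
#' @param phantom a [phantom_config()] template; each specimen gets
#'   `seed + specimen index`.
#' @param target_edge FE mesh grid spacing, mm.
#' @param steps number of compression steps analysed (default 3).
#' @param use_images if `TRUE`, the in-vitro arm renders volumes and runs
#'   registration + marker detection; if `FALSE` (default) it reads the
#'   ground-truth marker trajectories directly, which exercises the same
#'   downstream statistics at a fraction of the cost.
#' @param max_nfev forward-evaluation budget per calibration.
#' @param seed root seed; all stage seeds derive from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_specimens = 6,
                         nucleus_types = c("std_cyl", "fit_cyl", "mr"),
                         calibration_modes = c("one_to_one", "average"),
                         phantom = phantom_config(),
                         target_edge = 2, steps = 3, use_images = FALSE,
                         max_nfev = 20, seed = 1L) {
  stopifnot(n_specimens >= 1, steps >= 1, steps <= 4)
  nucleus_types <- match.arg(nucleus_types, several.ok = TRUE)
  calibration_modes <- match.arg(calibration_modes, several.ok = TRUE)
  structure(list(n_specimens = n_specimens, nucleus_types = nucleus_types,
                 calibration_modes = calibration_modes, phantom = phantom,
                 target_edge = target_edge, steps = steps,
                 use_images = use_images, max_nfev = max_nfev,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full two-arm study on a synthetic cohort
#'
#' For each specimen: generate the phantom, measure (or read) per-marker
#' bulge and the load record; build one FE model per nucleus type,
#' calibrate tissue compressibility one-to-one, and predict loads and
#' bulge. If the average-compressibility mode is requested, tissue
#' compressibilities are averaged across specimens within each nucleus
#' type and all specimens re-solved. The report pools regional bulge
#' statistics, per-cell load and bulge concordance, and all calibration
#' results.
#'
#' @param config a [study_config()].
#' @return A `study_report` list: `bulge_invitro`, `load_records`,
#'   `calibrations`, `load_ccc`, `bulge_ccc`, `regional`, `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  specs <- vector("list", config$n_specimens)
  bulge_iv <- list()
  loads_iv <- list()
  models <- list()

  for (i in seq_len(config$n_specimens)) {
    pc <- config$phantom
    pc$seed <- config$seed + i
    sid <- sprintf("s%02d", i)
    ph <- generate_phantom(pc, render = config$use_images)
    specs[[i]] <- ph

    # --- in vitro arm ---
    if (config$use_images) {
      mk0 <- detect_markers(ph$ct, expected_n = pc$n_marker_lines *
                              pc$markers_per_line,
                            n_lines = pc$n_marker_lines,
                            markers_per_line = pc$markers_per_line,
                            marker_diameter = pc$marker_diameter)
      for (s in seq_len(config$steps)) {
        def <- deform_phantom(ph, s)
        tf <- register_rigid(def$ct, ph$ct, mode = "caudal")
        mks <- detect_markers(def$ct, expected_n = nrow(mk0),
                              n_lines = pc$n_marker_lines,
                              markers_per_line = pc$markers_per_line,
                              marker_diameter = pc$marker_diameter)
        back <- invert_transform(tf)
        reg <- transform_points(back, as.matrix(mks[, c("x", "y", "z")]))
        mks$x <- reg[, 1]; mks$y <- reg[, 2]; mks$z <- reg[, 3]
        bulge_iv[[length(bulge_iv) + 1]] <-
          compute_bulge(mk0, mks, specimen_id = sid, step = s)
      }
    } else {
      mk0 <- dplyr::filter(ph$truth$markers, .data$step == 0)
      for (s in seq_len(config$steps)) {
        mks <- dplyr::filter(ph$truth$markers, .data$step == !!s)
        bulge_iv[[length(bulge_iv) + 1]] <-
          compute_bulge(mk0, mks, specimen_id = sid, step = s)
      }
    }
    lr <- generate_load_record(ph)
    loads_iv[[i]] <- dplyr::mutate(
      dplyr::filter(lr, .data$step > 0, .data$step <= config$steps),
      specimen_id = sid, load_N = .data$peak_load_N)

    for (nt in config$nucleus_types)
      models[[paste(sid, nt, sep = ".")]] <- list(
        specimen = sid, type = nt,
        model = build_specimen_model(ph, nucleus_type = nt,
                                     target_edge = config$target_edge))
  }

  bulge_iv <- dplyr::bind_rows(bulge_iv)
  loads_iv <- dplyr::bind_rows(loads_iv)

  # regional statistics per step on normalised bulge
  applied <- dplyr::bind_rows(lapply(seq_len(config$n_specimens), function(i)
    tibble::tibble(specimen_id = sprintf("s%02d", i),
                   step = specs[[i]]$truth$applied$step,
                   displacement_mm = specs[[i]]$truth$applied$cumulative_mm)))
  bulge_norm <- normalize_bulge(bulge_iv, applied)
  regional <- lapply(seq_len(config$steps), function(s)
    tryCatch(regional_comparison(bulge_norm, s), error = function(e) NULL))

  # --- in silico arm: one-to-one calibration ---
  calibs <- list()
  loads_is <- list()
  bulge_is <- list()
  for (key in names(models)) {
    mi <- models[[key]]
    rec <- loads_iv[loads_iv$specimen_id == mi$specimen, , drop = FALSE]
    rec <- tibble::tibble(displacement_mm = rec$displacement_mm,
                          peak_load_N = rec$load_N)
    cal <- calibrate(mi$model, rec, steps = config$steps,
                     max_nfev = config$max_nfev)
    calibs[[key]] <- cal
    if ("one_to_one" %in% config$calibration_modes) {
      fl <- forward_load_curve(mi$model, cal$materials, rec$displacement_mm,
                               keep_solutions = TRUE)
      sols <- attr(fl, "solutions")
      loads_is[[length(loads_is) + 1]] <- tibble::tibble(
        specimen_id = mi$specimen, model_type = mi$type,
        calibration_mode = "one_to_one", step = fl$step,
        load_N = fl$load_N)
      for (s in seq_along(sols))
        bulge_is[[length(bulge_is) + 1]] <- dplyr::mutate(
          predict_bulge(sols[[s]], mi$model, mi$specimen, s),
          model_type = mi$type, calibration_mode = "one_to_one")
    }
  }

  # --- average-compressibility mode ---
  if ("average" %in% config$calibration_modes) {
    for (nt in config$nucleus_types) {
      keys <- names(models)[vapply(models, function(m) m$type == nt,
                                   logical(1))]
      avg <- tryCatch(
        average_compressibility(calibs[keys]), error = function(e) NULL)
      if (is.null(avg)) next
      for (key in keys) {
        mi <- models[[key]]
        rec <- loads_iv[loads_iv$specimen_id == mi$specimen, , drop = FALSE]
        fl <- forward_load_curve(mi$model, avg, rec$displacement_mm,
                                 keep_solutions = TRUE)
        sols <- attr(fl, "solutions")
        loads_is[[length(loads_is) + 1]] <- tibble::tibble(
          specimen_id = mi$specimen, model_type = nt,
          calibration_mode = "average", step = fl$step, load_N = fl$load_N)
        for (s in seq_along(sols))
          bulge_is[[length(bulge_is) + 1]] <- dplyr::mutate(
            predict_bulge(sols[[s]], mi$model, mi$specimen, s),
            model_type = nt, calibration_mode = "average")
      }
    }
  }

  loads_is <- dplyr::bind_rows(loads_is)
  bulge_is <- dplyr::bind_rows(bulge_is)
  load_ccc <- if (nrow(loads_is)) load_agreement(loads_iv, loads_is)
              else tibble::tibble()
  bulge_ccc <- list()
  if (nrow(bulge_is)) {
    cells <- dplyr::distinct(bulge_is[, c("model_type", "calibration_mode")])
    for (i in seq_len(nrow(cells))) {
      sub <- bulge_is[bulge_is$model_type == cells$model_type[i] &
                        bulge_is$calibration_mode ==
                        cells$calibration_mode[i], , drop = FALSE]
      ag <- tryCatch(bulge_agreement(bulge_iv, sub), error = function(e) NULL)
      if (!is.null(ag))
        bulge_ccc[[length(bulge_ccc) + 1]] <- dplyr::bind_cols(
          cells[i, , drop = FALSE], tidy.agreement_result(ag))
    }
  }
  bulge_ccc <- dplyr::bind_rows(bulge_ccc)

  structure(list(
    bulge_invitro = bulge_norm, load_records = loads_iv,
    loads_insilico = loads_is, bulge_insilico = bulge_is,
    calibrations = calibs, load_ccc = load_ccc, bulge_ccc = bulge_ccc,
    regional = regional,
    provenance = list(seed = config$seed,
                      n_specimens = config$n_specimens,
                      nucleus_types = config$nucleus_types,
                      calibration_modes = config$calibration_modes,
                      config_hash = rlang::hash(config),
                      package_version =
                        as.character(utils::packageVersion("osteodisc")),
                      elapsed_s =
                        as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d specimens, %d model runs\n",
              x$provenance$n_specimens, length(x$calibrations)))
  ok <- vapply(x$calibrations, `[[`, logical(1), "success")
  cat(sprintf("  calibrations: %d/%d successful\n", sum(ok), length(ok)))
  if (nrow(x$load_ccc)) {
    cat("  load CCC per cell:\n")
    print(as.data.frame(x$load_ccc), row.names = FALSE)
  }
  invisible(x)
}

#' Write study outputs to a directory
#'
#' CSV tables for bulge and loads, JSON for calibrations, concordance and
#' provenance.
#'
#' @param report a `study_report`.
#' @param dir output directory (created).
#' @return `dir` invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$bulge_invitro, file.path(dir, "bulge_invitro.csv"),
            row.names = FALSE)
  write.csv(report$load_records, file.path(dir, "loads_invitro.csv"),
            row.names = FALSE)
  if (nrow(report$loads_insilico))
    write.csv(report$loads_insilico, file.path(dir, "loads_insilico.csv"),
              row.names = FALSE)
  cal <- lapply(report$calibrations, function(cc)
    list(K_af = cc$K_af, K_np = cc$K_np, cost = cc$cost,
         success = cc$success, termination = cc$termination,
         nu_af = cc$nu_af, nu_np = cc$nu_np))
  jsonlite::write_json(
    list(calibrations = cal,
         load_ccc = report$load_ccc, bulge_ccc = report$bulge_ccc,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}
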