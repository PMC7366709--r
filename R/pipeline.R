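#' Measure one en-face image: binarization, skeleton metrics, FAZ
#'
#' Runs the full per-image measurement chain:
#' Gaussian pre-smoothing (sigma from `params`), then
#' \itemize{
#'   \item global IsoData binarization -> Zhang-Suen skeleton ->
#'     merged junction count, branching-point density (/mm² over the
#'     full field) and total skeleton length (mm);
#'   \item Bradley-variant local binarization -> vessel density
#'     (foreground fraction);
#'   \item morphological closing + flood fill of the global mask ->
#'     automated FAZ area (mm²).
#' }
#' The two binarization routes mirror the two toolchains of the
#' original analysis (an ImageJ-style global threshold feeding the
#' skeleton, and an adaptive local threshold feeding the density).
#'
#' @param img an [enface_image()].
#' @param params a [threshold_params()].
#' @param closing_radius_px disk radius for the FAZ closing step.
#' @param faz_seed optional `(row, col)` FAZ seed; default image
#'   center.
#' @return List of class `eye_metrics`: `faz_area_mm2`,
#'   `branching_density`, `vessel_density`, `total_length_mm`,
#'   `junction_count`, `endpoint_count`, `area_mm2`,
#'   `global_threshold`, `bradley_window_px`, `faz_degenerate`.
#' @export
process_enface <- function(img, params = threshold_params(),
                           closing_radius_px = 4, faz_seed = NULL) {
  stopifnot(inherits(img, "enface_image"))
  sm <- smooth_gaussian(img, params$sigma_px)
  gmask <- global_threshold(sm)
  bmask <- local_threshold_bradley(sm, params)
  summ <- skeleton_summary(gmask, img$scale_um_per_px, density_mask = bmask)
  faz <- segment_faz(gmask, seed_point = faz_seed,
                     closing_radius_px = closing_radius_px,
                     scale_um_per_px = img$scale_um_per_px)
  structure(list(
    faz_area_mm2 = faz$area_mm2,
    branching_density = summ$branching_density_per_mm2,
    vessel_density = summ$vessel_density,
    total_length_mm = summ$total_length_mm,
    junction_count = summ$junction_count,
    endpoint_count = summ$endpoint_count,
    area_mm2 = summ$area_mm2,
    global_threshold = attr(gmask, "threshold"),
    bradley_window_px = attr(bmask, "window_px"),
    faz_degenerate = faz$degenerate
  ), class = "eye_metrics")
}

#' @export
print.eye_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "eye_metrics: FAZ %.3f mm2 | %.1f junctions/mm2 | ",
    "vessel density %.3f | length %.1f mm\n"),
    x$faz_area_mm2, x$branching_density, x$vessel_density,
    x$total_length_mm))
  invisible(x)
}

#' Process every rendered eye of a synthetic cohort
#'
#' Applies [process_enface()] to the SCP and DCP image of each
#' rendered eye and appends the measured metrics to the record table
#' (columns `scp_faz_area_mm2`, `dcp_branching_density`, ... without
#' the `_true` suffix).
#'
#' @param cohort a rendered `synthetic_cohort` from [make_cohort()].
#' @param params a [threshold_params()].
#' @param closing_radius_px forwarded to [process_enface()].
#' @return The record data frame with measured-metric columns added.
#' @export
process_cohort <- function(cohort, params = threshold_params(),
                           closing_radius_px = 4) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$eyes))
    stop("cohort was generated with render = FALSE; no images to process")
  recs <- cohort$records
  for (lo in c("scp", "dcp"))
    for (mm in c("faz_area_mm2", "branching_density", "vessel_density",
                 "total_length_mm"))
      recs[[paste0(lo, "_", mm)]] <- NA_real_
  for (i in seq_len(nrow(recs))) {
    for (lo in c("scp", "dcp")) {
      em <- process_enface(cohort$eyes[[i]][[lo]]$image, params,
                           closing_radius_px)
      recs[[paste0(lo, "_faz_area_mm2")]][i] <- em$faz_area_mm2
      recs[[paste0(lo, "_branching_density")]][i] <- em$branching_density
      recs[[paste0(lo, "_vessel_density")]][i] <- em$vessel_density
      recs[[paste0(lo, "_total_length_mm")]][i] <- em$total_length_mm
    }
  }
  recs
}

#' Full comparison report across groups, metrics and plexuses
#'
#' Builds the group-comparison rows (descriptives + the three pairwise
#' Mann-Whitney contrasts) for every requested metric and plexus, and
#' records how many tests were run (no multiplicity correction is
#' applied; significance is flagged at the stated alpha).
#'
#' @param records eye-record data frame with measured (or true)
#'   metric columns.
#' @param metrics metric stems to report.
#' @param plexuses plexus labels to report.
#' @inheritParams compare_groups
#' @return List of class `comparison_table`: `rows` (list of
#'   `comparison_row`), `n_tests`, `alpha`.
#' @export
report_comparisons <- function(records,
                               metrics = c("faz_area_mm2",
                                           "branching_density",
                                           "vessel_density"),
                               plexuses = c("SCP", "DCP"),
                               groups = c("HbSS", "HbSC", "control"),
                               alpha = 0.05) {
  rows <- list()
  for (pl in plexuses)
    for (mm in metrics) {
      col <- .metric_col(mm, pl)
      if (!col %in% names(records)) next
      rows[[paste(pl, mm, sep = ".")]] <-
        compare_groups(records, mm, pl, groups, alpha)
    }
  structure(list(rows = rows, n_tests = 3L * length(rows), alpha = alpha),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("comparison_table: %d rows, %d pairwise tests at alpha = %g\n",
              length(x$rows), x$n_tests, x$alpha))
  for (r in x$rows) print(r)
  invisible(x)
}

#' Write per-eye metrics as a JSON sidecar
#'
#' Serializes an `eye_metrics` object keyed by patient, eye and
#' plexus, including the thresholds the binarization chose.
#'
#' @param metrics an `eye_metrics` from [process_enface()].
#' @param path output JSON path.
#' @param patient_id,eye,plexus identifying keys stored alongside the
#'   metrics.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path, patient_id = NA, eye = NA,
                               plexus = NA) {
  stopifnot(inherits(metrics, "eye_metrics"))
  jsonlite::write_json(
    c(list(patient_id = patient_id, eye = eye, plexus = plexus),
      unclass(metrics)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Emit the cohort report tables as CSV files
#'
#' Writes the four standard tables to a directory:
#' `table1_demographics.csv` (per-group eye counts, stage distribution
#' and mean stage), `table2_comparisons.csv` (per-metric group
#' descriptives and the three pairwise Mann-Whitney p-values),
#' `table3_by_stage.csv` (per-stage means with the Kruskal-Wallis p),
#' and `table4_qualitative.csv` (lesion counts and percentages), plus
#' `report.json` with the same content.
#'
#' @param records eye-record data frame with metric columns.
#' @param dir output directory (created if needed).
#' @param metrics,plexuses,groups forwarded to the table builders.
#' @return Invisibly, the list of tables written.
#' @export
write_report_tables <- function(records, dir,
                                metrics = c("faz_area_mm2",
                                            "branching_density",
                                            "vessel_density",
                                            "total_length_mm"),
                                plexuses = c("SCP", "DCP"),
                                groups = intersect(
                                  c("HbSS", "HbSC", "control"),
                                  unique(records$group))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t1 <- do.call(rbind, lapply(groups, function(g) {
    sd_ <- stage_distribution(records, g)
    ms <- mean_stage(records, g)
    data.frame(group = g, n_eyes = ms$n,
               stage = sd_$stage, stage_n = sd_$n_eyes, stage_pct = sd_$pct,
               mean_stage = ms$mean, sd_stage = ms$sd)
  }))
  comp <- report_comparisons(records, metrics = metrics,
                             plexuses = plexuses, groups = groups)
  t2 <- do.call(rbind, lapply(comp$rows, function(r) {
    desc <- do.call(rbind, lapply(names(r$groups), function(g) {
      d <- r$groups[[g]]
      data.frame(metric = r$metric, plexus = r$plexus, group = g,
                 mean = d$mean, sd = d$sd, min = d$min, max = d$max,
                 n = d$n)
    }))
    desc$contrast <- NA; desc$p_value <- NA; desc$significant <- NA
    tst <- data.frame(metric = r$metric, plexus = r$plexus, group = NA,
                      mean = NA, sd = NA, min = NA, max = NA, n = NA,
                      contrast = r$tests$contrast,
                      p_value = r$tests$p_value,
                      significant = r$tests$significant)
    rbind(desc, tst)
  }))
  t3 <- NULL
  for (pl in plexuses) for (mm in metrics) {
    col <- .metric_col(mm, pl)
    if (!col %in% names(records)) next
    tb <- tryCatch(by_stage(records, mm, pl), error = function(e) NULL)
    if (is.null(tb)) next
    t3 <- rbind(t3, data.frame(metric = mm, plexus = pl,
                               stage = tb$per_stage$stage,
                               n = tb$per_stage$n,
                               mean = tb$per_stage$mean,
                               kruskal_wallis_p = tb$test$p_value))
  }
  t4 <- qualitative_summary(records,
                            groups = setdiff(groups, "control"))
  tables <- list(table1_demographics = t1, table2_comparisons = t2,
                 table3_by_stage = t3, table4_qualitative = t4)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]))
      utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(tables, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(tables)
}
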