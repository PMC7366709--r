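.roman_stage <- c(I = 1L, II = 2L, III = 3L, IV = 4L, V = 5L)

#' Validate and normalize a table of per-eye records
#'
#' Checks the invariants of the cohort data model: Goldberg stage in
#' 0-5 (Roman numerals I-V accepted and converted), control eyes at
#' stage 0, non-negative metrics. Extra columns pass through.
#'
#' @param df data frame with at least `patient_id`, `eye`, `group`,
#'   `goldberg_stage`.
#' @return The normalized data frame (stage as integer 0-5).
#' @export
as_eye_records <- function(df) {
  need <- c("patient_id", "eye", "group", "goldberg_stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  st <- df$goldberg_stage
  if (is.character(st)) {
    rom <- st %in% names(.roman_stage)
    st[rom] <- .roman_stage[st[rom]]
    st <- as.integer(st)
  }
  st <- as.integer(st)
  if (anyNA(st) || any(st < 0 | st > 5))
    stop("goldberg_stage must be an integer 0-5 (or Roman I-V)")
  df$goldberg_stage <- st
  if (any(df$group == "control" & st != 0))
    warning("control eyes with nonzero retinopathy stage")
  metric_cols <- grep("faz_area|branching_density|vessel_density|total_length",
                      names(df), value = TRUE)
  for (cc in metric_cols)
    if (any(df[[cc]] < 0, na.rm = TRUE)) stop("negative metric in ", cc)
  df
}

#' Write per-eye records to CSV
#' @param records eye-record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read per-eye records from CSV
#' @param path CSV path written by [write_cohort_csv()] (or assembled
#'   externally with the documented column names).
#' @return Validated eye-record data frame.
#' @export
read_cohort_csv <- function(path) {
  as_eye_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Retinopathy-stage distribution of one group
#'
#' Counts and percentages of eyes per Goldberg stage within a group
#' (percentages to one decimal, half-up).
#'
#' @param records eye-record data frame.
#' @param group group label to summarize.
#' @return Data frame: `stage`, `n_eyes`, `pct` (only stages present).
#' @export
stage_distribution <- function(records, group) {
  st <- records$goldberg_stage[records$group == group]
  if (!length(st)) stop("no eyes in group ", group)
  tab <- table(factor(st, levels = 0:5))
  keep <- tab > 0
  data.frame(stage = as.integer(names(tab))[keep],
             n_eyes = as.integer(tab)[keep],
             pct = floor(1000 * as.integer(tab)[keep] / length(st) + 0.5) / 10)
}

#' Mean and SD of the Goldberg stage in one group
#'
#' Arithmetic mean of the integer stages over the group's eyes, SD
#' with the n-1 denominator.
#'
#' @inheritParams stage_distribution
#' @return List: `mean`, `sd`, `n`.
#' @export
mean_stage <- function(records, group) {
  st <- records$goldberg_stage[records$group == group]
  if (!length(st)) stop("no eyes in group ", group)
  list(mean = mean(st), sd = if (length(st) > 1) stats::sd(st) else 0,
       n = length(st))
}

#' Qualitative lesion summary (per group and plexus)
#'
#' Counts and integer percentages for the three lesion categories:
#' rarefied/dilated perifoveal capillaries (SCP and DCP), capillary
#' non-perfusion (SCP and DCP), and disruption of the perifoveal
#' anastomotic arcade (SCP only; reported `NA` for the DCP).
#'
#' @param records eye-record data frame carrying the logical flag
#'   columns.
#' @param groups groups to tabulate (default: all except `control`).
#' @return Data frame: `group`, `plexus`, `lesion`, `n`, `n_eyes`,
#'   `pct` (integer percent, half-up; `NA` where not applicable).
#' @export
qualitative_summary <- function(records,
                                groups = setdiff(unique(records$group),
                                                 "control")) {
  lesions <- c(rarefied_dilated = "rarefied_dilated",
               nonperfusion = "nonperfusion",
               arcade_disruption = "arcade_disruption")
  out <- list()
  for (g in groups) {
    sub <- records[records$group == g, ]
    for (pl in c("SCP", "DCP")) {
      for (le in names(lesions)) {
        col <- paste0(lesions[[le]], "_", pl)
        if (!col %in% names(records)) {
          n <- NA_integer_; pct <- NA_real_
        } else {
          n <- sum(sub[[col]]); pct <- floor(100 * n / nrow(sub) + 0.5)
        }
        out[[length(out) + 1]] <- data.frame(
          group = g, plexus = pl, lesion = le, n = n, n_eyes = nrow(sub),
          pct = pct, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

.metric_col <- function(metric, plexus) {
  paste0(tolower(plexus), "_", metric)
}

#' Group comparison row for one metric and plexus
#'
#' Per-group descriptive statistics ([describe()]) plus the three
#' pairwise Mann-Whitney p-values (each disease group vs control, and
#' disease vs disease), with a significance flag at p < 0.05. Eyes
#' with a missing value for the metric are excluded (and counted in
#' `n_excluded`).
#'
#' @param records eye-record data frame.
#' @param metric metric stem, e.g. `"faz_area_mm2"`,
#'   `"branching_density"`, `"vessel_density"`, `"total_length_mm"`;
#'   the column used is `<plexus>_<metric>`.
#' @param plexus `"SCP"` or `"DCP"`.
#' @param groups three group labels, ordered (disease1, disease2,
#'   control-like reference last).
#' @param alpha significance level for the flag (default 0.05).
#' @return List of class `comparison_row`: `metric`, `plexus`,
#'   `groups` (per-group [describe()] output), `tests` (data frame of
#'   the three contrasts: `contrast`, `p_value`, `significant`),
#'   `n_excluded`.
#' @export
compare_groups <- function(records, metric, plexus,
                           groups = c("HbSS", "HbSC", "control"),
                           alpha = 0.05) {
  col <- .metric_col(metric, plexus)
  if (!col %in% names(records)) stop("no column ", col, " in records")
  vals <- lapply(groups, function(g) {
    v <- records[[col]][records$group == g]
    v[!is.na(v)]
  })
  names(vals) <- groups
  if (any(lengths(vals) < 2)) stop("need >= 2 eyes with data per group")
  n_excl <- sum(is.na(records[[col]][records$group %in% groups]))
  if (n_excl > 0)
    message(n_excl, " eye(s) without ", col, " excluded from comparison")
  contrasts <- list(c(groups[1], groups[3]), c(groups[2], groups[3]),
                    c(groups[2], groups[1]))
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    tr <- mann_whitney_u(vals[[ct[1]]], vals[[ct[2]]])
    data.frame(contrast = paste(ct[1], "vs", ct[2]),
               statistic = tr$statistic, p_value = tr$p_value,
               method = tr$method, significant = tr$p_value < alpha,
               stringsAsFactors = FALSE)
  }))
  structure(list(metric = metric, plexus = plexus,
                 groups = lapply(vals, describe), tests = tests,
                 n_excluded = n_excl),
            class = "comparison_row")
}

#' @export
print.comparison_row <- function(x, ...) {
  cat(sprintf("%s (%s):\n", x$metric, x$plexus))
  for (g in names(x$groups)) {
    d <- x$groups[[g]]
    cat(sprintf("  %-8s %5.3g +/- %.3g (%.3g-%.3g), n = %d\n",
                g, d$mean, d$sd, d$min, d$max, d$n))
  }
  for (i in seq_len(nrow(x$tests)))
    cat(sprintf("  %-18s p = %.4g%s\n", x$tests$contrast[i],
                x$tests$p_value[i],
                ifelse(x$tests$significant[i], " *", "")))
  invisible(x)
}

#' Per-stage metric summary with a Kruskal-Wallis test
#'
#' Mean of the metric within each represented Goldberg stage and the
#' tie-corrected Kruskal-Wallis p-value across stages. Control-type
#' eyes (stage 0) are excluded by default so the comparison spans
#' retinopathy stages only.
#'
#' @inheritParams compare_groups
#' @param include_stage0 include stage-0 eyes as their own stratum
#'   (default `FALSE`).
#' @return List of class `stage_table`: `metric`, `plexus`,
#'   `per_stage` (data frame `stage`, `n`, `mean`), `test`
#'   (the `octa_test`).
#' @export
by_stage <- function(records, metric, plexus, include_stage0 = FALSE) {
  col <- .metric_col(metric, plexus)
  if (!col %in% names(records)) stop("no column ", col, " in records")
  sub <- records[!is.na(records[[col]]), ]
  if (!include_stage0) sub <- sub[sub$goldberg_stage > 0, ]
  stages <- sort(unique(sub$goldberg_stage))
  if (length(stages) < 2)
    stop("need at least two represented stages")
  groups <- lapply(stages, function(s) sub[[col]][sub$goldberg_stage == s])
  kw <- kruskal_wallis(groups)
  structure(list(
    metric = metric, plexus = plexus,
    per_stage = data.frame(stage = stages, n = lengths(groups),
                           mean = vapply(groups, mean, 0)),
    test = kw), class = "stage_table")
}

#' @export
print.stage_table <- function(x, ...) {
  cat(sprintf("%s (%s) by stage: ", x$metric, x$plexus))
  cat(paste(sprintf("stage %d: %.3g (n=%d)", x$per_stage$stage,
                    x$per_stage$mean, x$per_stage$n), collapse = ", "))
  cat(sprintf("; Kruskal-Wallis p = %.3g\n", x$test$p_value))
  invisible(x)
}

#' Cross-foot consistency checks for a cohort table
#'
#' Verifies that per-stage counts and qualitative lesion counts are
#' consistent with the group totals, and reports the implied
#' mean-stage values; any mismatch between a supplied printed mean and
#' the count-implied mean is surfaced as a warning rather than forced.
#'
#' @param records eye-record data frame.
#' @param printed_mean_stage optional named numeric of externally
#'   printed per-group mean stages to check against the counts.
#' @return Data frame of per-group totals and implied mean stages.
#' @export
crossfoot_check <- function(records, printed_mean_stage = NULL) {
  groups <- unique(records$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sd_ <- stage_distribution(records, g)
    ms <- mean_stage(records, g)
    stopifnot(sum(sd_$n_eyes) == ms$n)
    data.frame(group = g, n_eyes = ms$n, implied_mean_stage = ms$mean)
  }))
  if (!is.null(printed_mean_stage)) {
    for (g in intersect(names(printed_mean_stage), out$group)) {
      imp <- out$implied_mean_stage[out$group == g]
      if (abs(imp - printed_mean_stage[[g]]) > 0.015)
        warning(sprintf(
          "group %s: printed mean stage %.2f conflicts with the %.4f implied by the stage counts",
          g, printed_mean_stage[[g]], imp))
    }
  }
  out
}
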