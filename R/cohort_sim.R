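#' Specification of a synthetic OCTA cohort
#'
#' Per-genotype-group eye counts and per-plexus generating
#' distributions (mean, SD) for FAZ area, branching-point density and
#' vessel density, plus Goldberg-stage distributions and qualitative
#' lesion-flag probabilities. Defaults reproduce the structure of the
#' reference sickle-cell retinopathy cohort: 27 HbSS, 19 HbSC and 16
#' control eyes, with DCP FAZ means 0.84 / 0.86 / 0.57 mm² (SD 0.30 /
#' 0.28 / 0.09), SCP branching densities near 92-101 /mm² and DCP
#' branching densities near 28-37 /mm².
#'
#' @param n_eyes named integer vector of eye counts per group.
#' @param faz_mean,faz_sd per-plexus, per-group FAZ-area distribution
#'   parameters (mm²): named lists `list(SCP = c(HbSS=, HbSC=,
#'   control=), DCP = ...)`.
#' @param bd_mean,bd_sd branching-density distributions (/mm²), same
#'   shape.
#' @param vd_mean,vd_sd vessel-density distributions (0-1 fraction),
#'   same shape.
#' @param stage_probs per-group probability vector over Goldberg
#'   stages 0-5 (each must sum to 1; controls are all stage 0).
#' @param crt_mean,crt_sd central retinal thickness (µm) per group.
#' @param flag_probs per-group probabilities of the qualitative lesion
#'   flags (rarefied/dilated capillaries per plexus, non-perfusion per
#'   plexus, SCP arcade disruption).
#' @param seed master RNG seed; per-eye image seeds are derived
#'   deterministically from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(
  n_eyes = c(HbSS = 27L, HbSC = 19L, control = 16L),
  faz_mean = list(SCP = c(HbSS = 0.44, HbSC = 0.48, control = 0.42),
                  DCP = c(HbSS = 0.84, HbSC = 0.86, control = 0.57)),
  faz_sd   = list(SCP = c(HbSS = 0.16, HbSC = 0.12, control = 0.09),
                  DCP = c(HbSS = 0.30, HbSC = 0.28, control = 0.09)),
  bd_mean  = list(SCP = c(HbSS = 92,   HbSC = 101,  control = 98),
                  DCP = c(HbSS = 27.9, HbSC = 29.9, control = 37.3)),
  bd_sd    = list(SCP = c(HbSS = 21,   HbSC = 17,   control = 17),
                  DCP = c(HbSS = 5.6,  HbSC = 6.8,  control = 9.4)),
  vd_mean  = list(SCP = c(HbSS = 0.79, HbSC = 0.85, control = 0.85),
                  DCP = c(HbSS = 0.25, HbSC = 0.26, control = 0.29)),
  vd_sd    = list(SCP = c(HbSS = 0.01, HbSC = 0.01, control = 0.01),
                  DCP = c(HbSS = 0.02, HbSC = 0.01, control = 0.02)),
  stage_probs = list(HbSS = c(0, 18, 4, 5, 0, 0) / 27,
                     HbSC = c(0, 6, 1, 12, 0, 0) / 19,
                     control = c(1, 0, 0, 0, 0, 0)),
  crt_mean = c(HbSS = 173.8, HbSC = 180, control = 179.7),
  crt_sd   = c(HbSS = 15.7, HbSC = 14.6, control = 11.5),
  flag_probs = list(
    HbSS = c(rarefied_dilated_SCP = 11 / 27, rarefied_dilated_DCP = 20 / 27,
             nonperfusion_SCP = 1 / 27, nonperfusion_DCP = 6 / 27,
             arcade_disruption_SCP = 15 / 27),
    HbSC = c(rarefied_dilated_SCP = 10 / 19, rarefied_dilated_DCP = 16 / 19,
             nonperfusion_SCP = 1 / 19, nonperfusion_DCP = 4 / 19,
             arcade_disruption_SCP = 14 / 19),
    control = c(rarefied_dilated_SCP = 0, rarefied_dilated_DCP = 0,
                nonperfusion_SCP = 0, nonperfusion_DCP = 0,
                arcade_disruption_SCP = 0)),
  seed = 1) {
  groups <- names(n_eyes)
  stopifnot(length(groups) >= 1, all(n_eyes > 0))
  for (pl in c("SCP", "DCP")) {
    stopifnot(all(faz_sd[[pl]] >= 0), all(bd_sd[[pl]] >= 0),
              all(vd_sd[[pl]] >= 0))
  }
  for (g in groups) {
    p <- stage_probs[[g]]
    stopifnot(length(p) == 6, all(p >= 0),
              abs(sum(p) - 1) < 1e-9)
  }
  structure(list(n_eyes = n_eyes, faz_mean = faz_mean, faz_sd = faz_sd,
                 bd_mean = bd_mean, bd_sd = bd_sd,
                 vd_mean = vd_mean, vd_sd = vd_sd,
                 stage_probs = stage_probs,
                 crt_mean = crt_mean, crt_sd = crt_sd,
                 flag_probs = flag_probs, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Normal draw truncated below at `lower` (and optionally above), by
# rejection; degenerates to pmax clamping when sd = 0.
.rnorm_trunc <- function(n, mean, sd, lower, upper = Inf) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lower), upper))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0
  while (length(bad) && tries < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1
  }
  pmin(pmax(out, lower), upper)
}

#' Generate a synthetic cohort of eyes
#'
#' Draws, for every eye of every group, the generating truths (per-
#' plexus FAZ area, branching density, vessel density, stage, central
#' retinal thickness, qualitative flags) from the cohort
#' specification, and optionally renders the SCP and DCP angiograms
#' for each eye. The returned records carry the true generating values
#' (columns `*_true`) so downstream measurement can be validated
#' against them.
#'
#' @param spec a [cohort_spec()].
#' @param render if `TRUE` (default), simulate the SCP and DCP images
#'   for each eye; `FALSE` returns records only (used for the
#'   statistical simulation harness, which operates on the true
#'   values).
#' @param image_size,noise_level forwarded to [plexus_params()] when
#'   rendering.
#' @return List of class `synthetic_cohort`: `records` (data frame,
#'   one row per eye) and `eyes` (when rendered: per-eye list of
#'   `scp`/`dcp` simulations from [simulate_enface()], else `NULL`).
#' @export
make_cohort <- function(spec = cohort_spec(), render = TRUE,
                        image_size = 232, noise_level = 0.15) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$n_eyes)
  recs <- .with_seed(spec$seed, {
    rows <- list()
    eye_no <- 0L
    for (g in groups) {
      n <- spec$n_eyes[[g]]
      stage <- sample(0:5, n, replace = TRUE, prob = spec$stage_probs[[g]])
      crt <- .rnorm_trunc(n, spec$crt_mean[[g]], spec$crt_sd[[g]], 50)
      draws <- list()
      for (pl in c("SCP", "DCP")) {
        draws[[pl]] <- list(
          faz = .rnorm_trunc(n, spec$faz_mean[[pl]][[g]],
                             spec$faz_sd[[pl]][[g]], 0.05),
          bd = .rnorm_trunc(n, spec$bd_mean[[pl]][[g]],
                            spec$bd_sd[[pl]][[g]], 5),
          vd = .rnorm_trunc(n, spec$vd_mean[[pl]][[g]],
                            spec$vd_sd[[pl]][[g]], 0.01, 0.95))
      }
      flags <- vapply(spec$flag_probs[[g]],
                      function(p) stats::runif(n) < p,
                      logical(n))
      if (n == 1) flags <- matrix(flags, nrow = 1,
                                  dimnames = list(NULL, names(spec$flag_probs[[g]])))
      for (i in seq_len(n)) {
        eye_no <- eye_no + 1L
        rows[[eye_no]] <- data.frame(
          patient_id = sprintf("%s_P%02d", g, ceiling(i / 2)),
          eye = c("OD", "OS")[(i - 1) %% 2 + 1],
          group = g,
          goldberg_stage = stage[i],
          crt_um = crt[i],
          scp_faz_area_mm2_true = draws$SCP$faz[i],
          dcp_faz_area_mm2_true = draws$DCP$faz[i],
          scp_branching_density_true = draws$SCP$bd[i],
          dcp_branching_density_true = draws$DCP$bd[i],
          scp_vessel_density_true = draws$SCP$vd[i],
          dcp_vessel_density_true = draws$DCP$vd[i],
          rarefied_dilated_SCP = flags[i, "rarefied_dilated_SCP"],
          rarefied_dilated_DCP = flags[i, "rarefied_dilated_DCP"],
          nonperfusion_SCP = flags[i, "nonperfusion_SCP"],
          nonperfusion_DCP = flags[i, "nonperfusion_DCP"],
          arcade_disruption_SCP = flags[i, "arcade_disruption_SCP"],
          eye_seed = (spec$seed + 104729L * eye_no) %% 2147483647L,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  eyes <- NULL
  if (render) {
    eyes <- vector("list", nrow(recs))
    for (i in seq_len(nrow(recs))) {
      per_plexus <- list()
      for (pl in c("SCP", "DCP")) {
        lo <- tolower(pl)
        pp <- plexus_params(
          plexus = pl, image_size = image_size,
          faz_radius_mm = sqrt(recs[[paste0(lo, "_faz_area_mm2_true")]][i] / pi),
          target_junction_density =
            recs[[paste0(lo, "_branching_density_true")]][i],
          noise_level = noise_level,
          seed = recs$eye_seed[i] + (pl == "DCP"))
        per_plexus[[lo]] <- simulate_enface(pp)
      }
      eyes[[i]] <- per_plexus
    }
    names(eyes) <- paste(recs$patient_id, recs$eye, sep = "_")
  }
  structure(list(records = recs, eyes = eyes, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$records$group)
  cat("synthetic_cohort:",
      paste(sprintf("%s n=%d", names(tab), as.integer(tab)), collapse = ", "),
      if (is.null(x$eyes)) "(records only)" else "(with rendered images)",
      "\n")
  invisible(x)
}
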