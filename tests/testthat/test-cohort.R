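# Records built from the published per-group stage and lesion counts:
# HbSS 27 eyes (stages I/II/III = 18/4/5), HbSC 19 eyes (6/1/12),
# 16 control eyes at stage 0.
paper_count_records <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:62),
    eye = rep(c("OD", "OS"), 31),
    group = rep(c("HbSS", "HbSC", "control"), c(27, 19, 16)),
    goldberg_stage = c(rep(c(1, 2, 3), c(18, 4, 5)),
                       rep(c(1, 2, 3), c(6, 1, 12)),
                       rep(0, 16)),
    rarefied_dilated_SCP = c(rep(c(TRUE, FALSE), c(11, 16)),
                             rep(c(TRUE, FALSE), c(10, 9)),
                             rep(FALSE, 16)),
    rarefied_dilated_DCP = c(rep(c(TRUE, FALSE), c(20, 7)),
                             rep(c(TRUE, FALSE), c(16, 3)),
                             rep(FALSE, 16)),
    nonperfusion_SCP = c(rep(c(TRUE, FALSE), c(1, 26)),
                         rep(c(TRUE, FALSE), c(1, 18)),
                         rep(FALSE, 16)),
    nonperfusion_DCP = c(rep(c(TRUE, FALSE), c(6, 21)),
                         rep(c(TRUE, FALSE), c(4, 15)),
                         rep(FALSE, 16)),
    arcade_disruption_SCP = c(rep(c(TRUE, FALSE), c(15, 12)),
                              rep(c(TRUE, FALSE), c(14, 5)),
                              rep(FALSE, 16)),
    stringsAsFactors = FALSE)
}

test_that("stage distributions and means follow from the counts", {
  recs <- paper_count_records()
  sd_hbsc <- stage_distribution(recs, "HbSC")
  expect_equal(sd_hbsc$n_eyes[sd_hbsc$stage == 3], 12)
  expect_equal(sd_hbsc$pct[sd_hbsc$stage == 3], 63.2)
  expect_equal(sum(sd_hbsc$n_eyes), 19)

  ms <- mean_stage(recs, "HbSC")
  expect_equal(ms$mean, 44 / 19, tolerance = 1e-12)
  expect_equal(mean_stage(recs, "HbSS")$mean, 41 / 27, tolerance = 1e-12)

  single <- recs[1, ]
  expect_equal(stage_distribution(single, "HbSS")$pct, 100)
  expect_error(stage_distribution(recs, "nosuch"), "no eyes")
})

test_that("cross-foot checks surface a printed-vs-implied mean-stage conflict", {
  recs <- paper_count_records()
  cf <- crossfoot_check(recs)
  expect_equal(sum(cf$n_eyes), 62)
  # consistent value passes silently (44/19 = 2.316 prints as 2.31)
  expect_silent(crossfoot_check(recs, printed_mean_stage = c(HbSC = 2.31)))
  # the implied HbSS mean 41/27 = 1.52 conflicts with a printed 1.44
  expect_warning(crossfoot_check(recs, printed_mean_stage = c(HbSS = 1.44)),
                 "conflicts")
})

test_that("qualitative lesion summary replicates group x plexus percentages", {
  recs <- paper_count_records()
  qs <- qualitative_summary(recs)
  pick <- function(g, pl, le) qs$pct[qs$group == g & qs$plexus == pl &
                                       qs$lesion == le]
  expect_equal(pick("HbSS", "DCP", "rarefied_dilated"), 74)
  expect_equal(pick("HbSC", "DCP", "rarefied_dilated"), 84)
  expect_equal(pick("HbSS", "SCP", "rarefied_dilated"), 41)
  expect_true(all(qs$n <= qs$n_eyes, na.rm = TRUE))
  zero <- recs; zero$rarefied_dilated_DCP <- FALSE
  qz <- qualitative_summary(zero)
  expect_equal(qz$pct[qz$lesion == "rarefied_dilated" & qz$plexus == "DCP"],
               c(0, 0))
})

test_that("group comparison rows: descriptives, three contrasts, invariances", {
  set.seed(19)
  recs <- paper_count_records()
  recs$dcp_faz_area_mm2 <- c(rnorm(27, 0.84, 0.3), rnorm(19, 0.86, 0.28),
                             rnorm(16, 0.57, 0.09))
  row <- compare_groups(recs, "faz_area_mm2", "DCP")
  expect_equal(nrow(row$tests), 3)
  expect_equal(row$groups$HbSS$n, 27)
  expect_true(all(row$tests$p_value >= 0 & row$tests$p_value <= 1))

  # identical values everywhere: all p capped at 1
  same <- recs
  same$dcp_faz_area_mm2 <- 0.6
  row_same <- compare_groups(same, "faz_area_mm2", "DCP")
  expect_true(all(row_same$tests$p_value == 1))

  # record order does not matter
  shuf <- recs[sample(nrow(recs)), ]
  row2 <- compare_groups(shuf, "faz_area_mm2", "DCP")
  expect_equal(row2$tests$p_value, row$tests$p_value)
  expect_equal(row2$groups$control$mean, row$groups$control$mean)

  # missing values are excluded with a note
  holey <- recs; holey$dcp_faz_area_mm2[c(1, 30)] <- NA
  expect_message(compare_groups(holey, "faz_area_mm2", "DCP"), "excluded")
})

test_that("per-stage tables run a Kruskal-Wallis across represented stages", {
  recs <- paper_count_records()
  set.seed(20)
  recs$dcp_vessel_density <- 0.26 + rnorm(62, 0, 0.02)
  tab <- by_stage(recs, "vessel_density", "DCP")
  expect_equal(tab$per_stage$stage, c(1, 2, 3))
  expect_equal(sum(tab$per_stage$n), 46)    # stage-0 controls excluded
  expect_s3_class(tab$test, "octa_test")

  # stage-coded copies of identical values: H = 0, p = 1
  flat <- recs; flat$dcp_vessel_density <- 0.25
  tflat <- by_stage(flat, "vessel_density", "DCP")
  expect_equal(tflat$test$statistic, 0)
  expect_equal(tflat$test$p_value, 1)

  one_stage <- recs[recs$goldberg_stage == 1, ]
  expect_error(by_stage(one_stage, "vessel_density", "DCP"), "two represented")
})

test_that("cohort records survive a CSV round trip, including Roman stages", {
  recs <- paper_count_records()
  recs$crt_um <- seq(160, 190, length.out = 62)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(recs, f)
  back <- read_cohort_csv(f)
  expect_equal(back, as_eye_records(recs))

  roman <- recs[1:5, ]
  roman$goldberg_stage <- c("I", "II", "III", "I", "0")
  conv <- as_eye_records(roman)
  expect_equal(conv$goldberg_stage, c(1L, 2L, 3L, 1L, 0L))
  bad <- recs[1, ]; bad$goldberg_stage <- 7
  expect_error(as_eye_records(bad), "0-5")
})

test_that("comparison report counts its tests and flags significance", {
  set.seed(22)
  recs <- paper_count_records()
  recs$dcp_faz_area_mm2 <- c(rnorm(27, 0.84, 0.3), rnorm(19, 0.86, 0.28),
                             rnorm(16, 0.57, 0.09))
  recs$scp_faz_area_mm2 <- c(rnorm(27, 0.44, 0.16), rnorm(19, 0.48, 0.12),
                             rnorm(16, 0.42, 0.09))
  rep_ <- report_comparisons(recs, metrics = "faz_area_mm2")
  expect_equal(length(rep_$rows), 2)
  expect_equal(rep_$n_tests, 6)
  expect_identical(rep_$rows$DCP.faz_area_mm2$tests$significant,
                   rep_$rows$DCP.faz_area_mm2$tests$p_value < 0.05)
})
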