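# small, fast parameter set used across generator tests
dcp_small <- function(seed = 1, target_junction_density = 25, ...) {
  plexus_params("DCP", image_size = 116, field_mm = 1.5,
                faz_radius_mm = 0.3,
                target_junction_density = target_junction_density,
                seed = seed, ...)
}

test_that("plexus parameters validate their invariants", {
  expect_error(plexus_params(image_size = 16), "image_size")
  expect_error(plexus_params(faz_radius_mm = 2), "faz_radius_mm")
  expect_error(plexus_params(target_junction_density = 0))
  expect_error(plexus_params(vessel_width_px = c(0.5, 2)))
  expect_error(plexus_params(noise_level = 1))
  p <- plexus_params("SCP")
  expect_equal(p$vessel_width_px, c(2, 4))
  expect_equal(p$target_junction_density, 95)
})

test_that("grown networks carry self-consistent ground truth", {
  pp <- plexus_params("DCP", faz_radius_mm = 0.5, seed = 2)
  net <- grow_network(pp)
  expect_equal(net$true_faz_area_mm2, pi * 0.25)
  # totals recomputable from nodes/segments
  len <- with(net$segments,
              sqrt((net$nodes[node_i, 1] - net$nodes[node_j, 1])^2 +
                   (net$nodes[node_i, 2] - net$nodes[node_j, 2])^2))
  expect_equal(net$true_total_length_mm, sum(len), tolerance = 1e-9)
  expect_false(any(len == 0))
  expect_equal(net$true_junction_count, brute_junctions(net))
  expect_true(all(net$nodes >= 0 & net$nodes <= net$field_mm))
})

test_that("same parameters and seed reproduce the identical network", {
  a <- grow_network(dcp_small(seed = 5))
  b <- grow_network(dcp_small(seed = 5))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$segments, b$segments)
  c <- grow_network(dcp_small(seed = 6))
  expect_false(identical(a$nodes, c$nodes))
})

test_that("realized junction count tracks the requested density", {
  pp <- plexus_params("DCP", faz_radius_mm = 0.42,
                      target_junction_density = 30, seed = 3)
  net <- grow_network(pp)
  target <- 30 * (9 - pi * 0.42^2)
  expect_lt(abs(brute_junctions(net) / target - 1), 0.15)
  # and for the dense preset
  scp <- grow_network(plexus_params("SCP", seed = 3))
  target_scp <- 95 * (9 - pi * 0.37^2)
  expect_lt(abs(brute_junctions(scp) / target_scp - 1), 0.15)
})

test_that("raising the junction target never lowers the realized count", {
  counts <- vapply(c(10, 25, 40), function(tj) {
    brute_junctions(grow_network(dcp_small(seed = 9,
                                           target_junction_density = tj)))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("an unreachable junction target fails explicitly", {
  expect_error(grow_network(plexus_params("DCP", image_size = 64,
                                          field_mm = 0.8,
                                          faz_radius_mm = 0.3,
                                          target_junction_density = 2000,
                                          seed = 1)),
               "unreachable")
})

test_that("rasterization draws exact-width strokes in pixel-center convention", {
  pp <- plexus_params("DCP", image_size = 64, field_mm = 64 * 3 / 232,
                      faz_radius_mm = 0, seed = 1)
  ppmm <- 64 / pp$field_mm
  net <- structure(list(
    nodes = rbind(c(4.5, 19.5), c(55.5, 19.5)) / ppmm,
    segments = data.frame(node_i = 1L, node_j = 2L, width_px = 1),
    true_faz_area_mm2 = 0, true_junction_count = 0,
    true_total_length_mm = 51 / ppmm,
    field_mm = pp$field_mm, faz_radius_mm = 0), class = "vascular_network")
  ras <- rasterize(net, pp)
  # the stroke centerline runs along y = 19.5 px, the center of pixel
  # row 20; neighbouring rows sit a full pixel away -> one row set
  expect_equal(sort(unique(which(ras$mask, arr.ind = TRUE)[, 1])), 20)
  expect_equal(range(which(ras$mask, arr.ind = TRUE)[, 2]), c(5, 56))

  empty <- net; empty$segments <- net$segments[0, ]
  ras0 <- rasterize(empty, pp)
  expect_false(any(ras0$mask))
  expect_true(all(ras0$image$pixels == 0))

  wide <- net; wide$segments$width_px <- 100
  expect_error(rasterize(wide, pp), "width")
})

test_that("no foreground pixel center falls inside the planted FAZ disk", {
  pp <- dcp_small(seed = 4)
  ras <- rasterize(grow_network(pp), pp)
  idx <- which(ras$mask, arr.ind = TRUE)
  ppmm <- pp$image_size / pp$field_mm
  d <- sqrt((idx[, 2] - 0.5 - pp$field_mm / 2 * ppmm)^2 +
            (idx[, 1] - 0.5 - pp$field_mm / 2 * ppmm)^2) / ppmm
  expect_true(all(d >= pp$faz_radius_mm))
})

test_that("noise model: identity case, determinism, stated moments", {
  pp <- dcp_small(seed = 7, noise_level = 0, blur_sigma_px = 0, haze = 0)
  img <- enface_image(matrix(runif(50 * 50), 50, 50))
  expect_identical(add_noise(img, pp), img)

  ppn <- dcp_small(seed = 7, noise_level = 0.3, blur_sigma_px = 0, haze = 0)
  flat <- enface_image(matrix(0.5, 116, 116))
  n1 <- add_noise(flat, ppn)
  n2 <- add_noise(flat, ppn)
  expect_identical(n1, n2)
  ratio <- var(as.vector(n1$pixels)) / mean(n1$pixels)^2
  expect_lt(abs(ratio / 0.09 - 1), 0.2)
})

test_that("simulated cohorts reproduce the requested group structure", {
  spec <- cohort_spec(seed = 11)
  coh <- make_cohort(spec, render = FALSE)
  expect_equal(nrow(coh$records), 62)
  expect_equal(as.integer(table(coh$records$group)[c("HbSS", "HbSC",
                                                     "control")]),
               c(27L, 19L, 16L))
  expect_true(all(coh$records$goldberg_stage[coh$records$group == "control"] == 0))
  expect_true(all(coh$records$dcp_faz_area_mm2_true > 0))

  # zero SDs collapse a group onto identical generating values
  z <- cohort_spec(seed = 2)
  for (pl in c("SCP", "DCP")) {
    z$faz_sd[[pl]][] <- 0; z$bd_sd[[pl]][] <- 0; z$vd_sd[[pl]][] <- 0
  }
  cz <- make_cohort(z, render = FALSE)
  hbss <- cz$records[cz$records$group == "HbSS", ]
  expect_equal(length(unique(hbss$dcp_faz_area_mm2_true)), 1)
  expect_equal(length(unique(hbss$scp_branching_density_true)), 1)

  # reproducible under the master seed
  coh2 <- make_cohort(cohort_spec(seed = 11), render = FALSE)
  expect_identical(coh$records, coh2$records)
})

test_that("simulation round-trips through the PNG/JSON sidecar writer", {
  pp <- dcp_small(seed = 8)
  sim <- simulate_enface(pp)
  stem <- file.path(tempdir(), "eye1")
  write_simulation(sim, stem)
  img <- read_enface(paste0(stem, ".png"),
                     scale_um_per_px = pp$field_mm * 1000 / pp$image_size)
  expect_equal(dim(img$pixels), dim(sim$image$pixels))
  expect_lt(max(abs(img$pixels - sim$image$pixels)), 1 / 255)
  truth <- jsonlite::read_json(paste0(stem, "_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_junction_count, sim$network$true_junction_count)
  expect_equal(truth$true_total_length_mm, sim$network$true_total_length_mm)
})
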