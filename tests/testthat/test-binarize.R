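test_that("Gaussian smoothing: identity, constancy, impulse response", {
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(smooth_gaussian(img, 0), img)
  flat <- matrix(0.4, 20, 20)
  expect_equal(smooth_gaussian(flat, 2), flat)
  # unit impulse, sigma 1: center/orthogonal-neighbor ratio is
  # exp(1/2) for the discrete sampled kernel
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- smooth_gaussian(imp, 1)
  expect_equal(sm[11, 11] / sm[11, 12], exp(0.5), tolerance = 1e-12)
  # mean preserved on interior-dominated images
  expect_equal(mean(smooth_gaussian(img, 1)), mean(img), tolerance = 1e-3)
})

test_that("window formula: raw value, odd adjustment, and bounds", {
  expect_equal(window_size(232, adjust = FALSE), 30)  # printed formula value
  expect_equal(window_size(232), 31)   # even 30 bumped to the odd 31
  expect_equal(window_size(16), 3)
  expect_equal(window_size(160), 21)
  expect_error(window_size(8), ">= 16")
  for (s in seq(16, 400, by = 7)) {
    w <- window_size(s)
    expect_true(w %% 2 == 1 && w >= 3)
  }
})

test_that("Bradley local threshold equals the brute-force windowed mean exactly", {
  set.seed(2)
  for (rep in 1:5) {
    px <- matrix(runif(32 * 32), 32, 32)
    params <- threshold_params(window_px = 7)
    mine <- local_threshold_bradley(px, params)
    expect_identical(unname(mine[, ]), brute_bradley(px, 7, 0.3))
  }
})

test_that("Bradley threshold: flat-region behaviour, monotonicity, scale invariance", {
  flat <- matrix(0.6, 40, 40)
  expect_true(all(local_threshold_bradley(flat, threshold_params(window_px = 9))))

  # a bright thin line on black stays foreground, far background does not
  img <- matrix(0, 64, 64); img[32, ] <- 0.9
  m <- local_threshold_bradley(img, threshold_params(window_px = 31))
  expect_true(all(m[32, ]))
  expect_false(any(m[1:10, ]))

  set.seed(3)
  px <- matrix(runif(30 * 30), 30, 30)
  m1 <- local_threshold_bradley(px, threshold_params(local_threshold_c = 0.2,
                                                     window_px = 9))
  m2 <- local_threshold_bradley(px, threshold_params(local_threshold_c = 0.5,
                                                     window_px = 9))
  expect_false(any(m1 & !m2))    # raising c lowers the bar: only adds

  m3 <- local_threshold_bradley(px * 0.5, threshold_params(window_px = 9))
  expect_identical(local_threshold_bradley(px, threshold_params(window_px = 9)),
                   m3)
  expect_error(
    local_threshold_bradley(px, structure(list(local_threshold_c = 0.3,
                                               window_px = 8), class = "threshold_params")),
    "odd")
})

test_that("IsoData global threshold separates bimodal images and is a fixed point", {
  px <- matrix(0.2, 50, 50)
  px[1:5, ] <- 0.8    # 10% bright class
  m <- global_threshold(px)
  t <- attr(m, "threshold")
  expect_gt(t, 0.2); expect_lt(t, 0.8)
  expect_identical(unname(which(m, arr.ind = TRUE)[, 1] <= 5),
                   rep(TRUE, sum(m)))
  expect_equal(sum(m), 5 * 50)

  # fixed point: t = (mean below + mean above) / 2 on the histogram
  set.seed(4)
  px2 <- matrix(c(rnorm(1200, 0.25, 0.05), rnorm(400, 0.75, 0.05)), 40, 40)
  px2 <- pmin(pmax(px2, 0), 1)
  m2 <- global_threshold(px2)
  t2 <- attr(m2, "threshold")
  v <- as.vector(px2)
  lv <- (floor(pmin(v, 0.999999) * 256) + 0.5) / 256
  expect_equal(t2, (mean(lv[lv <= t2]) + mean(lv[lv > t2])) / 2,
               tolerance = 1e-9)

  # inverted image gives the complementary mask (up to the bin boundary)
  m_inv <- global_threshold(1 - px)
  expect_equal(sum(m_inv), 50 * 50 - sum(m))
  expect_error(global_threshold(matrix(0.5, 10, 10)), "constant")
})

test_that("binarize dispatches on the configured method", {
  set.seed(6)
  px <- enface_image(matrix(runif(64 * 64), 64, 64))
  mb <- binarize(px, threshold_params(method = "local_bradley", window_px = 9))
  mg <- binarize(px, threshold_params(method = "global_isodata"))
  expect_type(mb, "logical"); expect_type(mg, "logical")
  expect_equal(attr(mb, "window_px"), 9)
  expect_true(!is.null(attr(mg, "threshold")))
})
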