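test_that("Mann-Whitney U statistic and exact p match closed cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2 / choose(6, 3)
  expect_identical(r$method, "exact")

  # identical multisets: U = nm/2, p capped at 1 (ties force the
  # normal path)
  x <- c(1, 2, 3, 4)
  r2 <- mann_whitney_u(x, x)
  expect_equal(r2$statistic, length(x)^2 / 2)
  expect_equal(r2$p_value, 1)
  expect_identical(r2$method, "normal_tie_corrected")

  # U + U' = n m
  set.seed(11)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(mann_whitney_u(a, b)$statistic +
                 mann_whitney_u(b, a)$statistic, 35)
})

test_that("exact Mann-Whitney p equals full enumeration on random tie-free cases", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    x <- rnorm(n); y <- rnorm(m)
    r <- mann_whitney_u(x, y)
    expect_identical(r$method, "exact")
    expect_equal(r$p_value, brute_mw_exact_p(x, y))
  }
})

test_that("normal-approximation p agrees with wilcox.test and enumeration direction", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(20); y <- rnorm(25, 0.3)
    r <- mann_whitney_u(x, y)
    w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
  }
  # tied data: tie-corrected variance path
  x <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8)
  y <- c(2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8, 8, 9)
  expect_equal(mann_whitney_u(x, y)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("rank tests are invariant under strictly increasing transforms", {
  set.seed(5)
  x <- rexp(12); y <- rexp(15, 0.6)
  f <- function(v) log(v + 1) * 3 + 2
  expect_equal(mann_whitney_u(x, y)$p_value,
               mann_whitney_u(f(x), f(y))$p_value)
  g <- list(rexp(6), rexp(8), rexp(5))
  expect_equal(kruskal_wallis(g)$p_value,
               kruskal_wallis(lapply(g, f))$p_value)
})

test_that("Kruskal-Wallis H matches hand-rank arithmetic and kruskal.test", {
  # ranks 1..6 in three groups: R = (3, 7, 11),
  # H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 32/7
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21)
  expect_equal(r$p_value, pchisq(r$statistic, df = 2, lower.tail = FALSE))

  set.seed(9)
  g <- list(rnorm(8), rnorm(10, 0.5), rnorm(7, 1), rnorm(5))
  mine <- kruskal_wallis(g)
  ref <- kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))

  # degenerate: identical values are not an error
  same <- kruskal_wallis(list(rep(2, 4), rep(2, 5), rep(2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("two groups: the Kruskal-Wallis H is the squared Mann-Whitney z", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 9; m <- 11; N <- n + m
    x <- rnorm(n); y <- rnorm(m, 0.4)
    kw <- kruskal_wallis(list(x, y))
    u <- mann_whitney_u(x, y, exact = FALSE)$statistic
    z2 <- (u - n * m / 2)^2 / (n * m * (N + 1) / 12)
    expect_equal(kw$statistic, z2, tolerance = 1e-12)
  }
})

test_that("ICC consistency: closed cases and ANOVA oracle", {
  x <- c(0.4, 0.6, 0.9, 1.2, 0.5)
  expect_equal(icc_consistency(cbind(x, x))$icc, 1)
  expect_equal(icc_consistency(cbind(x, x + 0.3))$icc, 1)

  set.seed(21)
  subj <- rnorm(100, 0.8, 0.3)
  ratings <- cbind(subj + rnorm(100, 0, 0.05), subj + rnorm(100, 0, 0.05))
  mine <- icc_consistency(ratings)
  # oracle: two-way ANOVA mean squares via aov
  d <- data.frame(y = as.vector(ratings),
                  subject = factor(rep(1:100, 2)),
                  rater = factor(rep(1:2, each = 100)))
  ms <- summary(aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  expect_equal(mine$ms_subjects, ms[1], tolerance = 1e-10)
  expect_equal(mine$ms_raters, ms[2], tolerance = 1e-10)
  expect_equal(mine$ms_error, ms[3], tolerance = 1e-10)
  expect_equal(mine$icc, (ms[1] - ms[3]) / ms[1], tolerance = 1e-10)
  # theoretical ICC(C,2) = 2 s^2 / (2 s^2 + e^2); recovery within 0.05
  theo <- 2 * 0.3^2 / (2 * 0.3^2 + 0.05^2)
  expect_lt(abs(mine$icc - theo), 0.05)

  expect_error(icc_consistency(cbind(rep(1, 5), rep(1, 5))), "undefined")
  expect_error(icc_consistency(cbind(1:2, 1:2)), "3 subjects")
})

test_that("describe reports n-1 SD, range and flags the single-value case", {
  d <- describe(c(1, 2, 3))
  expect_equal(d$mean, 2); expect_equal(d$sd, 1)
  expect_equal(d$median, 2); expect_equal(c(d$min, d$max), c(1, 3))
  one <- describe(0.5)
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)
  expect_error(describe(numeric(0)))
})
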