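#' Mann-Whitney U test (rank-sum)
#'
#' Computes `U = sum(ranks of x) - n(n+1)/2` with midranks for ties.
#' The two-sided p-value is exact by full enumeration of all
#' `choose(n + m, n)` group labelings when `n + m <= 14` and the pooled
#' data are tie-free; otherwise a normal approximation with
#' tie-corrected variance and a 0.5 continuity correction is used.
#' `U + U' = n * m` always holds.
#'
#' @param x,y non-empty numeric samples.
#' @param exact `"auto"` (default rule above), `TRUE` to force
#'   enumeration (refused in the presence of ties), or `FALSE` to force
#'   the normal approximation.
#' @return List of class `octa_test`: `statistic` (U for `x`),
#'   `p_value`, `method` (`"exact"` or `"normal_tie_corrected"`), and
#'   group sizes `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, exact = "auto") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  rk <- rank(pooled)                 # midranks
  U <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- if (identical(exact, "auto")) (N <= 14 && !ties) else isTRUE(exact)
  if (use_exact && ties)
    stop("exact enumeration is not defined with ties; use exact = FALSE")
  if (use_exact) {
    combos <- utils::combn(N, n)
    u_all <- colSums(matrix(rk[combos], nrow = n)) - n * (n + 1) / 2
    dev <- abs(u_all - n * m / 2)
    p <- mean(dev >= abs(U - n * m / 2) - 1e-9)
    method <- "exact"
  } else {
    tt <- table(pooled)
    tie_term <- sum(tt^3 - tt) / (N * (N - 1))
    v <- n * m / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(U - n * m / 2) - 0.5) / sqrt(v)
      z <- max(z, 0)
      p <- 2 * stats::pnorm(-z)
    }
    method <- "normal_tie_corrected"
  }
  structure(list(statistic = U, p_value = min(p, 1), method = method,
                 n1 = n, n2 = m),
            class = "octa_test")
}

#' Kruskal-Wallis rank test across groups
#'
#' `H = 12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)` on midranks,
#' divided by the tie correction `1 - sum(t^3 - t) / (N^3 - N)`; the
#' p-value comes from a chi-square distribution with `g - 1` degrees
#' of freedom. When every pooled value is identical the statistic is 0
#' and p = 1 (not an error).
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return List of class `octa_test` with `statistic` (H), `p_value`,
#'   `method = "chi_square"`, `df`, and `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("all groups must be non-empty")
  N <- sum(sizes)
  if (N < 3) stop("need at least 3 observations in total")
  pooled <- unlist(groups, use.names = FALSE)
  rk <- rank(pooled)
  gidx <- rep(seq_along(groups), sizes)
  R <- tapply(rk, gidx, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / sizes) - 3 * (N + 1)
  tt <- table(pooled)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  H <- max(H, 0)   # guard tiny negative rounding
  df <- length(groups) - 1
  p <- if (H == 0) 1 else stats::pchisq(H, df = df, lower.tail = FALSE)
  structure(list(statistic = H, p_value = min(p, 1), method = "chi_square",
                 df = df, group_sizes = as.integer(sizes)),
            class = "octa_test")
}

#' @export
print.octa_test <- function(x, ...) {
  cat(sprintf("octa_test (%s): statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Intraclass correlation, two-way random effects, consistency, k = 2
#'
#' Average-measures consistency ICC from the two-way ANOVA without
#' interaction: `ICC(C, k) = (MS_subjects - MS_error) / MS_subjects`.
#' A constant offset between the two measurement columns does not
#' lower the value (consistency, not absolute agreement): identical
#' columns, or columns differing by a constant, give exactly 1.
#'
#' @param ratings numeric matrix or data frame with one row per
#'   subject (n >= 3) and exactly 2 complete measurement columns.
#' @return List of class `icc_result`: `icc`, `ms_subjects`,
#'   `ms_raters`, `ms_error`, `n`, `k`.
#' @export
icc_consistency <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 2) stop("exactly 2 measurement columns required")
  if (nrow(ratings) < 3) stop("at least 3 subjects required")
  if (anyNA(ratings)) stop("ratings must be complete")
  n <- nrow(ratings); k <- 2
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- max(ss_err, 0) / ((n - 1) * (k - 1))
  if (ms_rows <= 0)
    stop("zero between-subject variance: ICC is undefined")
  structure(list(icc = (ms_rows - ms_err) / ms_rows,
                 ms_subjects = ms_rows, ms_raters = ms_cols,
                 ms_error = ms_err, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(C,%d) = %.4f  (MS subjects %.4g, MS error %.4g, n = %d)\n",
              x$k, x$icc, x$ms_subjects, x$ms_error, x$n))
  invisible(x)
}

#' Descriptive summary: mean, SD, range, median, n
#'
#' SD uses the `n - 1` denominator; for a single observation the SD is
#' reported as 0 with `sd_defined = FALSE`. `min`/`max` give the
#' printed "(range)".
#'
#' @param values non-empty numeric vector (NAs dropped).
#' @return List: `mean`, `sd`, `min`, `max`, `median`, `n`,
#'   `sd_defined`.
#' @export
describe <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to describe")
  n <- length(values)
  list(mean = mean(values),
       sd = if (n > 1) stats::sd(values) else 0,
       min = min(values), max = max(values),
       median = stats::median(values), n = n,
       sd_defined = n > 1)
}
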