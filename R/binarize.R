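#' Threshold parameters for vessel binarization
#'
#' Collects the knobs of the two binarization routes: pre-smoothing
#' sigma, the Bradley relative offset on a 0-1 scale, the local window
#' side, and the method.
#'
#' The local offset is interpreted as the Bradley rule "foreground iff
#' I > windowed_mean * (1 - c)": raising `local_threshold_c` lowers the
#' cutoff and can only add foreground. The window default is derived
#' from the image size with [window_size()].
#'
#' @param sigma_px Gaussian pre-smoothing sigma in pixels (default 1).
#' @param local_threshold_c Bradley relative offset on a 0-1 scale
#'   (default 0.3).
#' @param window_px odd local-window side in pixels, or `NULL` to derive
#'   it from the image size at threshold time.
#' @param method `"local_bradley"` or `"global_isodata"`.
#' @return A list of class `threshold_params`.
#' @export
threshold_params <- function(sigma_px = 1, local_threshold_c = 0.3,
                             window_px = NULL,
                             method = c("local_bradley", "global_isodata")) {
  method <- match.arg(method)
  stopifnot(sigma_px >= 0,
            local_threshold_c > 0, local_threshold_c < 1)
  if (!is.null(window_px)) {
    stopifnot(window_px >= 3, window_px %% 2 == 1)
  }
  structure(list(sigma_px = sigma_px, local_threshold_c = local_threshold_c,
                 window_px = window_px, method = method),
            class = "threshold_params")
}

# Reflect 1-based indices 1..n about the borders (for padding).
.reflect_idx <- function(idx, n) {
  if (n == 1) return(rep(1L, length(idx)))
  period <- 2L * n
  m <- ((idx - 1L) %% period + period) %% period
  ifelse(m < n, m + 1L, period - m)
}

#' Gaussian pre-smoothing
#'
#' Separable Gaussian convolution with reflective border handling.
#' `sigma_px = 0` is the identity. The kernel is truncated at
#' `ceiling(4 * sigma)` and renormalized, so a constant image is exactly
#' preserved and the mean intensity of interior-dominated images is
#' preserved to well under 0.1%.
#'
#' @param img `enface_image` or numeric matrix.
#' @param sigma_px Gaussian sigma in pixels (>= 0).
#' @return Smoothed image of the same class as the input.
#' @export
smooth_gaussian <- function(img, sigma_px = 1) {
  stopifnot(sigma_px >= 0)
  if (sigma_px == 0) return(img)
  px <- .img_pixels(img)
  r <- ceiling(4 * sigma_px)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  n <- nrow(px); m <- ncol(px)
  # rows (vertical pass), reflective padding
  out <- matrix(0, n, m)
  for (o in seq(-r, r)) {
    out <- out + k[o + r + 1] * px[.reflect_idx(seq_len(n) + o, n), , drop = FALSE]
  }
  out2 <- matrix(0, n, m)
  for (o in seq(-r, r)) {
    out2 <- out2 + k[o + r + 1] * out[, .reflect_idx(seq_len(m) + o, m), drop = FALSE]
  }
  .img_like(img, out2)
}

#' Local-threshold window size from the image size
#'
#' Evaluates the window formula `T = 2 * (size / 16) + 1`. For the
#' standard 232-pixel en-face image the raw formula gives 30
#' (`2 * 14.5 + 1`); because a centered windowed mean needs an odd side,
#' the adjusted value rounds half-up to the nearest integer and then
#' bumps even results up by one, giving 31 at size 232. Pass
#' `adjust = FALSE` to obtain the raw formula value.
#'
#' @param image_size image side length in pixels (>= 16).
#' @param adjust if `TRUE` (default) return the nearest odd integer
#'   >= 3; if `FALSE` return the raw formula value.
#' @return Window side in pixels (odd integer when `adjust = TRUE`).
#' @export
window_size <- function(image_size, adjust = TRUE) {
  if (image_size < 16) stop("image_size must be >= 16")
  raw <- 2 * (image_size / 16) + 1
  if (!adjust) return(raw)
  w <- floor(raw + 0.5)            # round half up
  if (w %% 2 == 0) w <- w + 1
  max(as.integer(w), 3L)
}

# Quantize [0,1] intensities to a 16-bit integer grid. Integer-valued
# doubles keep the integral-image sums exact (232^2 * 65535 << 2^53),
# so the fast path agrees bit-for-bit with a brute-force windowed mean.
.quantize16 <- function(px) round(pmin(pmax(px, 0), 1) * 65535)

# Windowed sums over a (2r+1)^2 replicate-padded window via an integral
# image. Returns the matrix of window sums of `q` at every pixel.
.window_sums <- function(q, r) {
  n <- nrow(q); m <- ncol(q)
  ri <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
  ci <- pmin(pmax(seq_len(m + 2 * r) - r, 1L), m)
  padded <- q[ri, ci, drop = FALSE]
  ii <- apply(apply(padded, 2, cumsum), 1, cumsum)  # transposed integral
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  w <- 2L * r + 1L
  rows <- seq_len(n); cols <- seq_len(m)
  ii[rows + w, cols + w, drop = FALSE] -
    ii[rows, cols + w, drop = FALSE] -
    ii[rows + w, cols, drop = FALSE] +
    ii[rows, cols, drop = FALSE]
}

#' Bradley-variant local adaptive threshold
#'
#' A pixel is foreground iff `I(x, y)` strictly exceeds
#' `mu_W(x, y) * (1 - c)`, where `mu_W` is the mean intensity over the
#' odd window centered at the pixel (replicate-padded at the borders)
#' and `c` is the relative offset on a 0-1 scale; raising `c` lowers
#' the cutoff and can only add foreground. The windowed means are
#' computed with an integral image over 16-bit-quantized intensities,
#' so the result is identical to a direct windowed-mean evaluation.
#'
#' Note the flat-region property of this rule: in a window of constant
#' positive intensity `I = mu > mu * (1 - c)`, so featureless bright
#' regions classify as foreground (zero-signal regions do not). This
#' matches the adaptive-threshold behaviour of the original analysis
#' chain and is one reason reported vessel densities from this route
#' run high.
#'
#' @param img `enface_image` or matrix, intensities in `[0, 1]`.
#' @param params a [threshold_params()] object; `window_px = NULL`
#'   derives the window from the image side via [window_size()].
#' @return Logical matrix (`TRUE` = vessel), with attribute
#'   `"window_px"` recording the window used.
#' @export
local_threshold_bradley <- function(img, params = threshold_params()) {
  px <- .img_pixels(img)
  w <- params$window_px
  if (is.null(w)) w <- window_size(min(dim(px)))
  if (w %% 2 == 0) stop("window_px must be odd")
  if (w > min(dim(px))) stop("window_px exceeds the image size")
  r <- (w - 1L) %/% 2L
  q <- .quantize16(px)
  s <- .window_sums(q, r)
  mu <- s / (w * w)
  mask <- q > mu * (1 - params$local_threshold_c)
  attr(mask, "window_px") <- w
  mask
}

#' Global IsoData (iterative intermeans) threshold
#'
#' The ImageJ default automatic threshold: starting from the image
#' mean, iterate `t <- (mean below t + mean above t) / 2` on a 256-bin
#' histogram until the threshold stabilizes. Pixels strictly above the
#' returned threshold are foreground.
#'
#' @param img `enface_image` or matrix, intensities in `[0, 1]`.
#' @return Logical matrix with attribute `"threshold"` (the chosen
#'   cutpoint on the 0-1 scale).
#' @export
global_threshold <- function(img) {
  px <- .img_pixels(img)
  v <- as.vector(px)
  if (max(v) - min(v) < .Machine$double.eps * 4)
    stop("global_threshold: constant image has no separable classes")
  bins <- pmin(floor(pmin(pmax(v, 0), 1) * 256), 255)   # 0..255
  h <- tabulate(bins + 1L, nbins = 256L)
  lv <- (0:255 + 0.5) / 256
  t_old <- -1
  t_cur <- sum(h * lv) / sum(h)
  for (it in 1:256) {
    below <- lv <= t_cur
    n_lo <- sum(h[below]); n_hi <- sum(h[!below])
    if (n_lo == 0 || n_hi == 0) {  # step toward the populated side
      t_cur <- if (n_lo == 0) min(lv[h > 0]) else max(lv[h > 0])
      below <- lv <= t_cur
      n_lo <- sum(h[below]); n_hi <- sum(h[!below])
      if (n_lo == 0 || n_hi == 0) break
    }
    m_lo <- sum(h[below] * lv[below]) / n_lo
    m_hi <- sum(h[!below] * lv[!below]) / n_hi
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t_cur) < 1e-12) break
    t_cur <- t_new
  }
  mask <- px > t_cur
  attr(mask, "threshold") <- t_cur
  mask
}

#' Binarize an en-face image by either route
#'
#' Applies Gaussian pre-smoothing followed by the selected threshold.
#'
#' @inheritParams local_threshold_bradley
#' @return Logical vessel mask.
#' @export
binarize <- function(img, params = threshold_params()) {
  sm <- smooth_gaussian(img, params$sigma_px)
  switch(params$method,
         local_bradley = local_threshold_bradley(sm, params),
         global_isodata = global_threshold(sm))
}
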