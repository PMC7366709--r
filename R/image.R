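#' En-face OCTA image container
#'
#' Bundles a grayscale raster with its physical scale and plexus label.
#' Everything downstream of acquisition consumes this container.
#'
#' Coordinate convention (used everywhere in the package): pixels are
#' row-major with the origin at the top-left corner; matrix row `i`,
#' column `j` (1-based in R) has its center at physical position
#' `x_mm = (j - 0.5) * scale_um_per_px / 1000`,
#' `y_mm = (i - 0.5) * scale_um_per_px / 1000`. Physical units are mm
#' internally; the pixel scale is carried in µm/px.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]` (rows = image
#'   rows, columns = image columns).
#' @param scale_um_per_px physical pixel pitch in µm/px. The default
#'   corresponds to a 3 x 3 mm field sampled at 232 x 232 pixels
#'   (3000/232 ~ 12.93 µm/px).
#' @param plexus slab label, `"SCP"` (superficial) or `"DCP"` (deep
#'   capillary plexus), or `NA` when unknown.
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, scale_um_per_px = 3000 / 232,
                         plexus = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!is.na(plexus)) plexus <- match.arg(toupper(plexus), c("SCP", "DCP"))
  if (!is.numeric(scale_um_per_px) || scale_um_per_px <= 0)
    stop("`scale_um_per_px` must be positive")
  structure(
    list(pixels = pixels, scale_um_per_px = scale_um_per_px, plexus = plexus),
    class = "enface_image"
  )
}

#' @export
print.enface_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "enface_image: %d x %d px, %.3f um/px (%.2f x %.2f mm), plexus %s\n",
    d[1], d[2], x$scale_um_per_px,
    d[2] * x$scale_um_per_px / 1000, d[1] * x$scale_um_per_px / 1000,
    ifelse(is.na(x$plexus), "<unset>", x$plexus)
  ))
  invisible(x)
}

# Accept either an enface_image or a bare matrix; return the matrix.
.img_pixels <- function(img) {
  if (inherits(img, "enface_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected an `enface_image` or a numeric matrix")
}

.img_scale <- function(img, scale_um_per_px = NULL) {
  if (!is.null(scale_um_per_px)) return(scale_um_per_px)
  if (inherits(img, "enface_image")) return(img$scale_um_per_px)
  stop("a pixel scale (um/px) is required when passing a bare matrix")
}

# Rebuild an enface_image around new pixel data, keeping metadata.
.img_like <- function(img, pixels) {
  if (inherits(img, "enface_image"))
    enface_image(pixels, img$scale_um_per_px, img$plexus)
  else pixels
}

#' Read a grayscale image file into an en-face container
#'
#' Reads 8- or 16-bit grayscale PNG (via the `png` package) or TIFF
#' (via `EBImage`). Intensities are normalized to `[0, 1]` by the dtype
#' maximum (already done by both readers), never by the per-image
#' maximum, so thresholds are comparable across eyes.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @inheritParams enface_image
#' @return An `enface_image`.
#' @export
read_enface <- function(path, scale_um_per_px = 3000 / 232,
                        plexus = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]  # collapse gray-encoded-as-RGB
    a
  } else if (ext %in% c("tif", "tiff")) {
    a <- EBImage::readImage(path)
    m <- EBImage::imageData(a)
    if (length(dim(m)) == 3) m <- m[, , 1]
    t(m)  # EBImage stores x-major; convert to row-major
  } else stop("unsupported image extension: ", ext)
  enface_image(px, scale_um_per_px, plexus)
}

#' Write an image or mask as 8-bit grayscale PNG
#'
#' Binary masks are written as 0/255; continuous images are clipped to
#' `[0, 1]` and quantized to 8 bits.
#'
#' @param img an `enface_image`, numeric matrix, or logical mask matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enface_png <- function(img, path) {
  px <- if (is.logical(img)) img + 0 else .img_pixels(img)
  px <- pmin(pmax(px, 0), 1)
  png::writePNG(px, path)
  invisible(path)
}
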