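# Proper segment intersection test (shared endpoints allowed) used to
# reject self-intersecting polygon tracings.
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Polygon area by the shoelace formula
#'
#' Area of a simple closed polygon given its vertices in order (either
#' orientation; the absolute value is returned). Used for manual FAZ
#' tracings supplied as vertex lists in mm.
#'
#' @param vertices two-column matrix or data frame of `(x_mm, y_mm)`
#'   vertices, at least 3, forming a simple (non-self-intersecting)
#'   closed chain; the closing edge is implicit.
#' @return Area in mm².
#' @export
polygon_area_mm2 <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stop("a polygon needs at least 3 vertices")
  n <- nrow(v)
  nxt <- c(2:n, 1)
  # reject self-intersection (non-adjacent edge pairs crossing)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next
      if (.segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        stop("self-intersecting polygon")
    }
  }
  abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
}

# 4-connected flood fill over a logical "open" matrix from a seed
# (row, col). Returns the filled logical region.
.flood4 <- function(open, seed_rc) {
  n <- nrow(open); m <- ncol(open)
  reg <- matrix(FALSE, n, m)
  start <- (seed_rc[2] - 1L) * n + seed_rc[1]
  if (!open[start]) stop("seed pixel is not in the fillable region")
  queue <- integer(1024); queue[1] <- start; qn <- 1L
  reg[start] <- TRUE
  while (qn > 0L) {
    p <- queue[qn]; qn <- qn - 1L
    r <- ((p - 1L) %% n) + 1L
    cc <- ((p - 1L) %/% n) + 1L
    for (k in 1:4) {
      rr <- r + c(-1L, 1L, 0L, 0L)[k]
      c2 <- cc + c(0L, 0L, -1L, 1L)[k]
      if (rr >= 1L && rr <= n && c2 >= 1L && c2 <= m) {
        q <- (c2 - 1L) * n + rr
        if (open[q] && !reg[q]) {
          reg[q] <- TRUE
          qn <- qn + 1L
          if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qn] <- q
        }
      }
    }
  }
  reg
}

#' Automated FAZ segmentation by closing and flood fill
#'
#' Automated stand-in for manual FAZ tracing, for use on segmented
#' vessel masks (typically the global-threshold mask): the vessel mask
#' is morphologically closed with a disk of `closing_radius_px`
#' (sealing inter-capillary gaps), then the avascular region is the
#' 4-connected background component flood-filled from the seed point
#' (default: image center). Each region pixel contributes
#' `(scale_um_per_px / 1000)^2` mm².
#'
#' @param mask logical vessel mask.
#' @param seed_point integer `(row, col)` seed; default image center.
#'   Must be background after closing, else an error asks for an
#'   explicit seed.
#' @param closing_radius_px disk radius for morphological closing
#'   (default 4 px, ~52 µm at the standard scale: larger than typical
#'   capillary gaps, well below the FAZ scale). `0` skips closing.
#' @param scale_um_per_px pixel pitch in µm/px.
#' @return List of class `faz_region`: `region` (logical matrix),
#'   `area_mm2`, `source = "auto_region"`, `degenerate` (`TRUE` when
#'   the region is the whole image, e.g. an empty mask).
#' @export
segment_faz <- function(mask, seed_point = NULL, closing_radius_px = 4,
                        scale_um_per_px = 3000 / 232) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (is.null(seed_point))
    seed_point <- c(round(nrow(mask) / 2), round(ncol(mask) / 2))
  closed <- if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    EBImage::imageData(EBImage::closing(EBImage::Image(mask + 0), brush)) > 0.5
  } else mask
  if (closed[seed_point[1], seed_point[2]])
    stop("seed lies on a vessel after closing; supply a background ",
         "seed_point inside the avascular zone")
  reg <- .flood4(!closed, seed_point)
  area <- sum(reg) * (scale_um_per_px / 1000)^2
  structure(list(region = reg, area_mm2 = area, source = "auto_region",
                 degenerate = all(reg)),
            class = "faz_region")
}

#' @export
print.faz_region <- function(x, ...) {
  cat(sprintf("faz_region (%s): %.4f mm2 (%d px)%s\n", x$source,
              x$area_mm2, sum(x$region),
              if (x$degenerate) " [degenerate: whole image]" else ""))
  invisible(x)
}

#' Read manual FAZ polygon annotations
#'
#' Reads a CSV of manual tracings with columns `image_id`, `rater`,
#' `vertex_index`, `x_mm`, `y_mm` (image-frame coordinates in mm) and
#' returns one area per (image, rater) tracing.
#'
#' @param path CSV file path.
#' @return Data frame with columns `image_id`, `rater`, `n_vertices`,
#'   `area_mm2`, `source`.
#' @export
read_faz_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "rater", "vertex_index", "x_mm", "y_mm")
  if (!all(need %in% names(ann)))
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  parts <- split(ann, interaction(ann$image_id, ann$rater, drop = TRUE))
  out <- lapply(parts, function(d) {
    d <- d[order(d$vertex_index), ]
    data.frame(image_id = d$image_id[1], rater = d$rater[1],
               n_vertices = nrow(d),
               area_mm2 = polygon_area_mm2(cbind(d$x_mm, d$y_mm)),
               source = "manual_polygon", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$image_id, out$rater), ]
}

#' Reproducibility of paired FAZ measurements
#'
#' Intraclass correlation for two measurement passes (two raters, or
#' two passes of one rater) over the same images: two-way random
#' effects, consistency, average of k = 2 measures. Delegates to
#' [icc_consistency()].
#'
#' @param measurements numeric matrix or data frame, one row per image
#'   (>= 3), two columns (the two passes).
#' @return An `icc_result` (see [icc_consistency()]).
#' @export
icc_pair_report <- function(measurements) {
  icc_consistency(measurements)
}
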