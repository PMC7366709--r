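# Shift a matrix by (dr, dc), zero-filling the exposed border.
.shift0 <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0L, n, p)
  rs <- seq_len(n) - dr; cs <- seq_len(p) - dc
  rok <- rs >= 1 & rs <= n; cok <- cs >= 1 & cs <= p
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# 8-neighbour sum for every pixel of a 0/1 matrix.
.neigh8 <- function(b) {
  .shift0(b, -1, -1) + .shift0(b, -1, 0) + .shift0(b, -1, 1) +
  .shift0(b,  0, -1)                     + .shift0(b,  0, 1) +
  .shift0(b,  1, -1) + .shift0(b,  1, 0) + .shift0(b,  1, 1)
}

#' Skeletonize a binary vessel mask
#'
#' Zhang-Suen iterative thinning: repeatedly peels boundary pixels in
#' two sub-iterations until stable, leaving an 8-connected unit-width
#' medial skeleton. The skeleton is a subset of the mask and thinning
#' never splits or removes an 8-connected component, so component
#' counts are preserved. An empty mask yields an empty skeleton.
#'
#' @param mask logical (or 0/1) matrix, `TRUE` = vessel.
#' @return Logical skeleton matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  b <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  if (!any(b == 1)) return(b == 1)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- .shift0(b, -1,  0); p3 <- .shift0(b, -1,  1)
      p4 <- .shift0(b,  0,  1); p5 <- .shift0(b,  1,  1)
      p6 <- .shift0(b,  1,  0); p7 <- .shift0(b,  1, -1)
      p8 <- .shift0(b,  0, -1); p9 <- .shift0(b, -1, -1)
      bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # transitions 0 -> 1 in the ordered ring p2 p3 ... p9 p2
      an <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
            (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
            (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
            (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- b == 1 & bn >= 2 & bn <= 6 & an == 1 & cond
      if (any(del)) {
        b[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b == 1
}

# 8-connected labelling of a logical matrix by queue flood fill.
# Returns an integer matrix of labels (0 = background).
.label8 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nb_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- integer(256); queue[1] <- start; qn <- 1L
    lab[start] <- cur
    while (qn > 0L) {
      p <- queue[qn]; qn <- qn - 1L
      r <- ((p - 1L) %% n) + 1L
      cc <- ((p - 1L) %/% n) + 1L
      for (k in 1:8) {
        rr <- r + nb_dr[k]; c2 <- cc + nb_dc[k]
        if (rr >= 1L && rr <= n && c2 >= 1L && c2 <= m) {
          q <- (c2 - 1L) * n + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            qn <- qn + 1L
            if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[qn] <- q
          }
        }
      }
    }
  }
  lab
}

#' Classify skeleton pixels into endpoints, junctions, and slab pixels
#'
#' Pixels are classified by their crossing number: the number of
#' distinct branches leaving a skeleton pixel, counted as 0-to-1
#' transitions around its 8-neighbour ring. An endpoint has one
#' leaving branch, a junction pixel three or more. (The raw neighbour
#' count misclassifies staircase pixels on shallow diagonals, which
#' touch three neighbours but connect only two branches.) Adjacent
#' junction pixels arising from one anatomical branch point are
#' merged: 8-connected clusters of junction pixels count as a single
#' junction, mirroring the junction-voxel clustering of standard
#' skeleton analyzers.
#'
#' @param skel logical skeleton matrix (unit width). Wider input
#'   triggers a warning; counts are still computed.
#' @return List with `junction_count` (merged), `endpoint_count`,
#'   `junction_pixels`, `endpoint_pixels`, `slab_pixels` (logical
#'   matrices).
#' @export
classify_pixels <- function(skel) {
  b <- matrix(as.integer(as.logical(skel)), nrow(skel), ncol(skel))
  nb <- .neigh8(b)
  if (any(b == 1 & nb == 8))
    warning("input does not look unit-width; counts may be inflated")
  p2 <- .shift0(b, -1,  0); p3 <- .shift0(b, -1,  1)
  p4 <- .shift0(b,  0,  1); p5 <- .shift0(b,  1,  1)
  p6 <- .shift0(b,  1,  0); p7 <- .shift0(b,  1, -1)
  p8 <- .shift0(b,  0, -1); p9 <- .shift0(b, -1, -1)
  cross <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  ep <- b == 1 & cross == 1 & nb >= 1
  jp <- b == 1 & cross >= 3
  slab <- b == 1 & !ep & !jp
  jl <- .label8(jp)
  list(
    junction_count = max(jl),
    endpoint_count = sum(ep),
    junction_pixels = jp,
    endpoint_pixels = ep,
    slab_pixels = slab
  )
}

#' Total skeleton length
#'
#' Sums, over each adjacent pair of skeleton pixels counted once, one
#' pixel unit for orthogonal neighbours and `sqrt(2)` for diagonal
#' neighbours, then converts to mm with the pixel scale. A diagonal
#' pair that shares an orthogonal skeleton neighbour is a shortcut
#' across a right-angle corner, not a path step, and is excluded
#' (otherwise every corner would be charged both its two orthogonal
#' steps and the phantom diagonal).
#'
#' @param skel logical skeleton matrix.
#' @param scale_um_per_px pixel pitch in µm/px.
#' @return Total length in mm (0 for an empty skeleton).
#' @export
total_length <- function(skel, scale_um_per_px = 3000 / 232) {
  b <- skel != 0
  n <- nrow(b); m <- ncol(b)
  if (n < 2 || m < 2) return(0)
  ortho <- sum(b[, -m] & b[, -1]) + sum(b[-n, ] & b[-1, ])
  # diagonal (r,c)-(r+1,c+1), excluded when (r,c+1) or (r+1,c) is set
  d1 <- b[-n, -m] & b[-1, -1] & !(b[-n, -1] | b[-1, -m])
  # anti-diagonal (r,c+1)-(r+1,c), excluded when (r,c) or (r+1,c+1) is set
  d2 <- b[-n, -1] & b[-1, -m] & !(b[-n, -m] | b[-1, -1])
  (ortho + sqrt(2) * (sum(d1) + sum(d2))) * scale_um_per_px / 1000
}

#' Vessel density of a binary mask
#'
#' The foreground fraction of the mask over the whole analyzed field,
#' on a 0-1 scale.
#'
#' @param mask logical matrix.
#' @return Fraction in `[0, 1]`.
#' @export
vessel_density <- function(mask) {
  mean(as.logical(mask))
}

#' Branching-point density
#'
#' @param junction_count number of merged skeleton junctions.
#' @param area_mm2 analyzed area in mm² (> 0); the full scan area by
#'   convention.
#' @return Junctions per mm².
#' @export
branching_density <- function(junction_count, area_mm2) {
  if (area_mm2 <= 0) stop("area_mm2 must be positive")
  junction_count / area_mm2
}

#' Summarize a vessel mask: skeleton topology and density metrics
#'
#' Skeletonizes the mask and reports merged junction count, endpoint
#' count, total skeleton length (mm), branching-point density (per
#' mm², over the full field area), vessel density (foreground
#' fraction), and the analyzed area.
#'
#' @param mask logical vessel mask.
#' @param scale_um_per_px pixel pitch in µm/px.
#' @param density_mask optional mask to use for vessel density (e.g.
#'   the adaptive-threshold mask when the skeleton comes from the
#'   global-threshold mask); defaults to `mask`.
#' @return List of class `skeleton_summary`.
#' @export
skeleton_summary <- function(mask, scale_um_per_px = 3000 / 232,
                             density_mask = mask) {
  skel <- skeletonize(mask)
  cl <- classify_pixels(skel)
  area <- prod(dim(mask)) * (scale_um_per_px / 1000)^2
  structure(list(
    junction_count = cl$junction_count,
    endpoint_count = cl$endpoint_count,
    total_length_mm = total_length(skel, scale_um_per_px),
    branching_density_per_mm2 = branching_density(cl$junction_count, area),
    vessel_density = vessel_density(density_mask),
    area_mm2 = area,
    skeleton = skel
  ), class = "skeleton_summary")
}

#' @export
print.skeleton_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "skeleton_summary: %d junctions (%.1f /mm2), %d endpoints,\n",
    "  total length %.2f mm, vessel density %.3f over %.2f mm2\n"),
    x$junction_count, x$branching_density_per_mm2, x$endpoint_count,
    x$total_length_mm, x$vessel_density, x$area_mm2))
  invisible(x)
}
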