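# Run expr under a temporary RNG seed, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Parameters of a synthetic capillary plexus
#'
#' Defines one simulated en-face acquisition: a 3 x 3 mm field sampled
#' at 232 x 232 pixels by default, with plexus-specific presets. The
#' SCP preset uses wider vessels (2-4 px) and a higher junction density
#' (95 /mm²); the DCP preset uses fine vessels (1-2 px) and a sparser
#' skeleton (30 /mm²), matching the measured ranges of the two plexus
#' morphologies.
#'
#' @param plexus `"SCP"` or `"DCP"`; selects preset defaults for the
#'   unset parameters below.
#' @param image_size pixels per side (>= 32; default 232).
#' @param field_mm physical side length in mm (default 3).
#' @param faz_radius_mm radius of the avascular exclusion disk at the
#'   field center (must be < `field_mm / 2`); preset: 0.37 mm SCP
#'   (~0.43 mm²), 0.45 mm DCP (~0.64 mm²).
#' @param target_junction_density junctions per mm² of perfused area
#'   (> 0); preset 95 (SCP) / 30 (DCP).
#' @param vessel_width_px length-2 numeric: min/max stroke width in
#'   pixels (min >= 1); preset 2-4 (SCP) / 1-2 (DCP).
#' @param noise_level multiplicative speckle amplitude in `[0, 1)`
#'   (default 0.15).
#' @param blur_sigma_px point-spread blur sigma in pixels (default 0.7).
#' @param haze additive background haze level on the 0-1 intensity
#'   scale (default 0.15, the diffuse signal floor of en-face
#'   angiograms; set 0 for a noise-free identity pipeline).
#' @param seed integer RNG seed; the generator is a pure function of
#'   (params, seed).
#' @return List of class `plexus_params`.
#' @export
plexus_params <- function(plexus = c("SCP", "DCP"), image_size = 232,
                          field_mm = 3, faz_radius_mm = NULL,
                          target_junction_density = NULL,
                          vessel_width_px = NULL, noise_level = 0.15,
                          blur_sigma_px = 0.7, haze = 0.15, seed = 1) {
  plexus <- match.arg(plexus)
  if (is.null(faz_radius_mm))
    faz_radius_mm <- if (plexus == "SCP") 0.37 else 0.45
  if (is.null(target_junction_density))
    target_junction_density <- if (plexus == "SCP") 95 else 30
  if (is.null(vessel_width_px))
    vessel_width_px <- if (plexus == "SCP") c(2, 4) else c(1, 2)
  stopifnot(image_size >= 32, field_mm > 0,
            faz_radius_mm >= 0, faz_radius_mm < field_mm / 2,
            target_junction_density > 0,
            length(vessel_width_px) == 2, vessel_width_px[1] >= 1,
            vessel_width_px[2] >= vessel_width_px[1],
            noise_level >= 0, noise_level < 1,
            blur_sigma_px >= 0, haze >= 0)
  structure(list(plexus = plexus, image_size = as.integer(image_size),
                 field_mm = field_mm, faz_radius_mm = faz_radius_mm,
                 target_junction_density = target_junction_density,
                 vessel_width_px = vessel_width_px,
                 noise_level = noise_level, blur_sigma_px = blur_sigma_px,
                 haze = haze, seed = as.integer(seed)),
            class = "plexus_params")
}

# Nodes placed every ~spacing along the field border, chained in
# perimeter order (closed), plus a closed perifoveal arcade ring whose
# chords stay tangent to the planted FAZ disk.
.initial_scaffold <- function(L, r_faz, spacing = 0.15, ring_spacing = 0.06,
                              inset = 0) {
  a <- inset; b <- L - inset
  per_side <- max(2L, round((b - a) / spacing))
  s <- seq(a, b, length.out = per_side + 1)[-(per_side + 1)]
  border <- rbind(cbind(s, a), cbind(b, s), cbind(b - s + a, b), cbind(a, b - s + a))
  nb <- nrow(border)
  border_edges <- cbind(seq_len(nb), c(seq_len(nb)[-1], 1L))
  ring <- NULL; ring_edges <- NULL
  if (r_faz > 0) {
    n_ring <- max(8L, ceiling(2 * pi * r_faz / ring_spacing))
    r_ring <- r_faz / cos(pi / n_ring)      # chords tangent to the disk
    th <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
    ring <- cbind(L / 2 + r_ring * cos(th), L / 2 + r_ring * sin(th))
    ring_edges <- cbind(seq_len(n_ring), c(seq_len(n_ring)[-1], 1L)) + nb
  }
  list(nodes = rbind(border, ring),
       edges = rbind(border_edges, ring_edges),
       n_border = nb)
}

# Minimum distance from point q to segment a-b (all length-2 vectors),
# vectorized over rows of a/b being scalars and q a matrix.
.pt_seg_dist <- function(qx, qy, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx * vx + vy * vy
  t <- ((qx - ax) * vx + (qy - ay) * vy) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  sqrt((qx - (ax + t * vx))^2 + (qy - (ay + t * vy))^2)
}

# Perturbed honeycomb mesh for junction targets near the packing limit
# of resolvable branch points. Returns nodes/edges/widths like the
# colonization path; junction count is trimmed to the target by
# deleting scattered interior walls (capillary rarefaction).
.lattice_network <- function(L, r_faz, inset, target_j) {
  # honeycomb vertex density is 0.770 / edge_len^2
  ell <- sqrt(0.770 * (L^2 - pi * r_faz^2) / target_j)
  cx <- L / 2; cy <- L / 2
  # hexagon centers on a triangular lattice
  dy <- 1.5 * ell; dxc <- sqrt(3) * ell
  nrow_ <- ceiling(L / dy) + 2L; ncol_ <- ceiling(L / dxc) + 2L
  key <- function(x, y) paste(round(x / ell * 1e4), round(y / ell * 1e4))
  vx <- numeric(0); vy <- numeric(0)
  ei <- integer(0); ej <- integer(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  get_vertex <- function(x, y) {
    k <- key(x, y)
    id <- seen[[k]]
    if (is.null(id)) {
      vx[[length(vx) + 1L]] <<- x; vy[[length(vy) + 1L]] <<- y
      id <- length(vx)
      seen[[k]] <- id
    }
    id
  }
  th <- pi / 6 + (0:5) * pi / 3
  hxv <- ell * cos(th); hyv <- ell * sin(th)
  for (r in 0:(nrow_ - 1)) {
    yc <- r * dy - ell
    xoff <- if (r %% 2 == 1) dxc / 2 else 0
    for (m in 0:(ncol_ - 1)) {
      xc <- m * dxc + xoff - ell
      ids <- integer(6)
      for (t in 1:6) ids[t] <- get_vertex(xc + hxv[t], yc + hyv[t])
      for (t in 1:6) {
        a <- ids[t]; b <- ids[if (t == 6) 1 else t + 1]
        ei[[length(ei) + 1L]] <- min(a, b); ej[[length(ej) + 1L]] <- max(a, b)
      }
    }
  }
  eu <- !duplicated(cbind(ei, ej))
  ei <- ei[eu]; ej <- ej[eu]
  vx <- unlist(vx); vy <- unlist(vy)
  # jitter for a natural look, then clip to the field
  n_v <- length(vx)
  vx <- vx + stats::rnorm(n_v, 0, 0.08 * ell)
  vy <- vy + stats::rnorm(n_v, 0, 0.08 * ell)
  keep_v <- vx >= inset & vx <= L - inset & vy >= inset & vy <= L - inset &
    (r_faz == 0 | sqrt((vx - cx)^2 + (vy - cy)^2) >= r_faz + 0.3 * ell)
  new_id <- cumsum(keep_v); new_id[!keep_v] <- 0L
  ok_e <- keep_v[ei] & keep_v[ej]
  ei <- new_id[ei[ok_e]]; ej <- new_id[ej[ok_e]]
  vx <- vx[keep_v]; vy <- vy[keep_v]
  # drop edges that would cross the avascular disk
  if (r_faz > 0) {
    dmin <- .pt_seg_dist(cx, cy, vx[ei], vy[ei], vx[ej], vy[ej])
    keep_e <- dmin >= r_faz
    ei <- ei[keep_e]; ej <- ej[keep_e]
  }
  list(x = vx, y = vy, ei = ei, ej = ej, ell = ell)
}

# Build the network on a perturbed honeycomb when the junction target
# approaches the packing limit of resolvable branch points (a random
# colonization mesh saturates well below it; an open-cell quasi-regular
# mesh is the geometry that accommodates such densities, and is what a
# dense superficial plexus looks like on en-face projection).
.grow_lattice <- function(params, L, r_faz, inset, step, target_j,
                          wmin, wmax) {
  cx <- L / 2; cy <- L / 2
  .with_seed(params$seed, {
    sc <- .initial_scaffold(L, r_faz, ring_spacing = max(0.06, step),
                            inset = inset)
    n_sc <- nrow(sc$nodes)
    # build with headroom, then rarefy down to the target
    lat <- .lattice_network(L, r_faz, inset, ceiling(1.2 * target_j))
    nodes <- rbind(sc$nodes, cbind(lat$x, lat$y))
    n_nodes <- nrow(nodes)
    e_i <- c(sc$edges[, 1], lat$ei + n_sc)
    e_j <- c(sc$edges[, 2], lat$ej + n_sc)
    w_border <- stats::runif(1, wmin, wmax)
    e_w <- c(ifelse(sc$edges[, 1] <= sc$n_border, w_border, wmax),
             stats::runif(length(lat$ei), wmin, wmax))
    deg <- tabulate(c(e_i, e_j), n_nodes)
    # stitch the scaffold (border chain and perifoveal arcade) into
    # the mesh
    for (s in seq_len(n_sc)) {
      d2 <- (nodes[s, 1] - lat$x)^2 + (nodes[s, 2] - lat$y)^2
      jb <- which.min(d2)
      db <- sqrt(d2[jb]); v <- jb + n_sc
      if (db > 1.7 * lat$ell || db < 1e-9) next
      if (deg[v] > 2) next
      if (r_faz > 0 &&
          .pt_seg_dist(cx, cy, nodes[s, 1], nodes[s, 2],
                       nodes[v, 1], nodes[v, 2]) < r_faz - 1e-12) next
      e_i <- c(e_i, s); e_j <- c(e_j, v)
      e_w <- c(e_w, stats::runif(1, wmin, wmax))
      deg[s] <- deg[s] + 1L; deg[v] <- deg[v] + 1L
    }
    alive_e <- rep(TRUE, length(e_i))
    # strip dangling chains left by the avascular hole and the rim
    repeat {
      leaf <- which(deg == 1L)
      if (!length(leaf)) break
      for (lf in leaf) {
        ke <- which(alive_e & (e_i == lf | e_j == lf))
        if (length(ke) != 1L) next
        alive_e[ke] <- FALSE
        deg[e_i[ke]] <- deg[e_i[ke]] - 1L
        deg[e_j[ke]] <- deg[e_j[ke]] - 1L
      }
    }
    # keep the main connected component
    parent <- seq_len(n_nodes)
    find <- function(a) {
      while (parent[a] != a) {
        parent[a] <<- parent[parent[a]]
        a <- parent[a]
      }
      a
    }
    for (k in which(alive_e)) {
      ra <- find(e_i[k]); rb <- find(e_j[k])
      if (ra != rb) parent[rb] <- ra
    }
    roots <- vapply(seq_len(n_nodes), find, 0L)
    tab <- table(roots[deg > 0])
    main <- as.integer(names(tab)[which.max(tab)])
    drop_n <- deg > 0 & roots != main
    if (any(drop_n)) {
      for (k in which(alive_e)) {
        if (drop_n[e_i[k]] || drop_n[e_j[k]]) {
          alive_e[k] <- FALSE
          deg[e_i[k]] <- deg[e_i[k]] - 1L
          deg[e_j[k]] <- deg[e_j[k]] - 1L
        }
      }
    }
    # rarefy: delete scattered interior walls (both ends degree 3)
    # until the junction count reaches the target
    junctions <- sum(deg >= 3L)
    if (junctions > target_j) {
      cand <- which(alive_e & e_i > n_sc & e_j > n_sc &
                      deg[e_i] == 3L & deg[e_j] == 3L)
      cand <- sample(cand)
      blocked <- logical(n_nodes)
      for (k in cand) {
        if (junctions <= target_j + 1L) break
        a <- e_i[k]; b <- e_j[k]
        if (blocked[a] || blocked[b]) next
        if (deg[a] != 3L || deg[b] != 3L) next
        alive_e[k] <- FALSE
        deg[a] <- 2L; deg[b] <- 2L
        junctions <- junctions - 2L
        blocked[a] <- TRUE; blocked[b] <- TRUE
      }
    }
    if (getOption("octaquant.verbose", FALSE))
      message("lattice mesh: ", junctions, "/", target_j, " junctions")
    if (junctions < ceiling(0.86 * target_j) || junctions > 1.15 * target_j)
      stop("unreachable target junction density (",
           params$target_junction_density, " /mm2) in a ",
           L, " mm field")
    keep_e <- which(alive_e)
    segs <- data.frame(node_i = e_i[keep_e], node_j = e_j[keep_e],
                       width_px = e_w[keep_e])
    len <- sqrt((nodes[segs$node_i, 1] - nodes[segs$node_j, 1])^2 +
                (nodes[segs$node_i, 2] - nodes[segs$node_j, 2])^2)
    structure(list(
      nodes = nodes, segments = segs,
      true_faz_area_mm2 = pi * r_faz^2,
      true_junction_count = sum(deg >= 3L),
      true_total_length_mm = sum(len),
      field_mm = L, faz_radius_mm = r_faz
    ), class = "vascular_network")
  })
}

#' Grow a synthetic capillary network by space colonization
#'
#' Seeds a perimeter chain on the field border and a perifoveal arcade
#' ring around the planted avascular disk, then grows the network
#' toward uniformly sampled attractor points by iterative attraction:
#' each attractor pulls its nearest node, nodes step toward the mean
#' attraction direction, and attractors are retired when reached.
#' No node, and no segment, enters the FAZ disk interior. Attractor
#' batches are replenished until the number of degree->=3 nodes reaches
#' `target_junction_density * (field area - FAZ area)`; if the target
#' is still unreached after many replenishments the function fails
#' explicitly rather than returning a short network. Output is a pure
#' function of the parameters (including the seed).
#'
#' @param params a [plexus_params()] object.
#' @return List of class `vascular_network`: `nodes` (matrix of
#'   `(x_mm, y_mm)`), `segments` (data frame `node_i`, `node_j`,
#'   `width_px`), and ground truth `true_faz_area_mm2`,
#'   `true_junction_count` (degree >= 3 nodes),
#'   `true_total_length_mm`, plus `field_mm` and `faz_radius_mm`.
#' @export
grow_network <- function(params) {
  stopifnot(inherits(params, "plexus_params"))
  L <- params$field_mm; r_faz <- params$faz_radius_mm
  cx <- L / 2; cy <- L / 2
  pitch <- L / params$image_size                  # mm per pixel
  wmin <- params$vessel_width_px[1]; wmax <- params$vessel_width_px[2]
  # clearance keeps distinct branches separable at raster scale:
  # centerlines about (mean width + 2.5 px) apart
  wavg <- (wmin + wmax) / 2
  step <- max(0.042, (wavg + 2.5) * pitch)
  clr <- 0.9 * step
  kill <- step
  infl <- 0.9
  inset <- 2.5 * pitch      # keep strokes clear of the image edge
  # branch points closer than this fuse into one blob at raster scale;
  # capped so sparse targets are not starved by oversized blocking disks
  j_sep <- min(0.15, max(0.7 / sqrt(params$target_junction_density),
                         0.8 * step))
  eff_area <- L^2 - pi * r_faz^2
  target_j <- ceiling(params$target_junction_density * eff_area)
  batch_size <- max(400L, ceiling(250 * eff_area))

  # near the packing limit of resolvable branch points a colonization
  # mesh saturates short of the target; switch to the open-cell mesh
  ell_t <- sqrt(0.770 * eff_area / target_j)
  if (ell_t < 1.5 * (wavg + 1) * pitch)
    stop("unreachable target junction density (",
         params$target_junction_density, " /mm2) in a ", L,
         " mm field: cells would be narrower than the vessels")
  if (ell_t < 2 * step)
    return(.grow_lattice(params, L, r_faz, inset, step, target_j,
                         wmin, wmax))

  .with_seed(params$seed, {
    sc <- .initial_scaffold(L, r_faz, ring_spacing = max(0.06, step),
                            inset = inset)
    max_nodes <- 200000L
    nodes <- rbind(sc$nodes, matrix(NA_real_, max_nodes, 2))[seq_len(max_nodes), ]
    n_nodes <- nrow(sc$nodes)
    deg <- integer(max_nodes)
    dir_x <- numeric(max_nodes); dir_y <- numeric(max_nodes)  # incoming direction
    w_in <- numeric(max_nodes)                                 # incoming width
    e_i <- integer(0); e_j <- integer(0); e_w <- numeric(0)
    junctions <- 0L
    junc_idx <- integer(0)        # node indices that are junctions
    add_edge <- function(i, j, w) {
      e_i[[length(e_i) + 1L]] <<- i
      e_j[[length(e_j) + 1L]] <<- j
      e_w[[length(e_w) + 1L]] <<- w
      deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
      if (deg[i] == 3L) { junctions <<- junctions + 1L
                          junc_idx[[length(junc_idx) + 1L]] <<- i }
      if (deg[j] == 3L) { junctions <<- junctions + 1L
                          junc_idx[[length(junc_idx) + 1L]] <<- j }
    }
    junction_room <- function(x, y) {
      # TRUE when (x, y) keeps the minimum branch-point separation
      if (!length(junc_idx)) return(TRUE)
      min((x - nodes[junc_idx, 1])^2 + (y - nodes[junc_idx, 2])^2) >= j_sep^2
    }
    w_border <- stats::runif(1, wmin, wmax)
    w_ring <- wmax   # the perifoveal arcade is continuous and prominent
    for (k in seq_len(nrow(sc$edges))) {
      on_border <- sc$edges[k, 1] <= sc$n_border
      add_edge(sc$edges[k, 1], sc$edges[k, 2],
               if (on_border) w_border else w_ring)
    }
    w_in[seq_len(sc$n_border)] <- w_border
    if (n_nodes > sc$n_border)
      w_in[(sc$n_border + 1):n_nodes] <- w_ring

    # clearance points: nodes plus segment midpoints, so the gap test
    # sees the polyline, not just its vertices
    cpts <- matrix(NA_real_, 2L * max_nodes, 2)
    n_cpts <- 0L
    add_cpt <- function(xy) {
      n_cpts <<- n_cpts + 1L
      cpts[n_cpts, ] <<- xy
    }
    for (k in seq_len(n_nodes)) add_cpt(nodes[k, ])
    for (k in seq_along(e_i))
      add_cpt((nodes[e_i[k], ] + nodes[e_j[k], ]) / 2)

    sample_attractors <- function(n) {
      out <- matrix(NA_real_, 0, 2)
      while (nrow(out) < n) {
        cand <- cbind(stats::runif(2 * n, inset, L - inset),
                      stats::runif(2 * n, inset, L - inset))
        keep <- (cand[, 1] - cx)^2 + (cand[, 2] - cy)^2 >= (r_faz + kill / 2)^2
        out <- rbind(out, cand[keep, , drop = FALSE])
      }
      out[seq_len(n), , drop = FALSE]
    }
    min_dist_to <- function(px_, py_, pts, npts) {
      best <- rep(Inf, length(px_))
      for (blk in split(seq_len(npts), ceiling(seq_len(npts) / 2000))) {
        d2 <- outer(px_, pts[blk, 1], "-")^2 + outer(py_, pts[blk, 2], "-")^2
        best <- pmin(best, apply(d2, 1, min))
      }
      sqrt(best)
    }
    nearest_against <- function(attr, node_idx) {
      best_d2 <- rep(Inf, nrow(attr))
      best_w <- rep(NA_integer_, nrow(attr))
      for (blk in split(node_idx, ceiling(seq_along(node_idx) / 2000))) {
        d2 <- outer(attr[, 1], nodes[blk, 1], "-")^2 +
              outer(attr[, 2], nodes[blk, 2], "-")^2
        w <- max.col(-d2, ties.method = "first")
        dmin <- d2[cbind(seq_len(nrow(attr)), w)]
        upd <- dmin < best_d2
        best_d2[upd] <- dmin[upd]
        best_w[upd] <- blk[w[upd]]
      }
      list(dist = sqrt(best_d2), which = best_w)
    }

    attr_pts <- sample_attractors(batch_size)
    na_ <- nearest_against(attr_pts, seq_len(n_nodes))
    a_dist <- na_$dist; a_near <- na_$which
    alive <- a_dist >= kill
    max_rounds <- 40L
    e_alive <- logical(0)

    # alternate growth with twig pruning and loop closing: a network
    # stopped right at the target still carries immature one-step
    # branches whose junctions do not survive pruning, so regrow (and
    # re-anastomose) until the pruned count stands
    relax <- 0L
    for (phase in 1:4) {
    rounds <- 0L; saturated <- FALSE
    extend <- 0L   # post-target maturation iterations (twigs lengthen)

    while (!saturated && (junctions < target_j || extend < 3L)) {
      act <- which(alive & a_dist <= infl)
      grew <- FALSE
      if (length(act)) {
        by_node <- split(act, a_near[act])
        n_prop <- length(by_node)
        p_src <- integer(n_prop); p_x <- numeric(n_prop); p_y <- numeric(n_prop)
        ok <- logical(n_prop)
        for (q in seq_len(n_prop)) {
          src <- as.integer(names(by_node)[q])
          aa <- by_node[[q]]
          dx <- attr_pts[aa, 1] - nodes[src, 1]
          dy <- attr_pts[aa, 2] - nodes[src, 2]
          nr <- sqrt(dx^2 + dy^2)
          ux <- sum(dx / nr); uy <- sum(dy / nr)
          un <- sqrt(ux^2 + uy^2)
          if (un < 1e-6) {       # opposing pulls cancel: jitter
            th <- stats::runif(1, 0, 2 * pi)
            ux <- cos(th); uy <- sin(th); un <- 1
          }
          ux <- ux / un; uy <- uy / un
          px_ <- dir_x[src]; py_ <- dir_y[src]
          if (deg[src] <= 2 && (px_ != 0 || py_ != 0)) {
            # continuing a chain: clamp the turn so paths stay smooth
            # (sharp polyline corners thin into spurious junctions)
            cosang <- ux * px_ + uy * py_
            if (cosang < 0.5) {                   # > 60 degrees
              sgn <- if (ux * (-py_) + uy * px_ >= 0) 1 else -1
              ca <- 0.5; sa <- sgn * sqrt(1 - ca^2)
              ux <- ca * px_ - sa * py_
              uy <- sa * px_ + ca * py_
            }
          }
          nx <- nodes[src, 1] + step * ux
          ny <- nodes[src, 2] + step * uy
          p_src[q] <- src; p_x[q] <- nx; p_y[q] <- ny
          # a second child turns src into a branch point: keep branch
          # points apart so they stay resolvable after rasterization,
          # and stop branching once the target is met (chains still
          # extend so young side branches mature past pruning length)
          branch_ok <- deg[src] < 2 ||
            (deg[src] == 2 && junctions < target_j &&
               junction_room(nodes[src, 1], nodes[src, 2]))
          ok[q] <- branch_ok && deg[src] > 0 &&
            nx >= inset && nx <= L - inset &&
            ny >= inset && ny <= L - inset &&
            !(r_faz > 0 &&
              .pt_seg_dist(cx, cy, nodes[src, 1], nodes[src, 2], nx, ny) <
                r_faz - 1e-12)
        }
        if (any(ok)) {
          cand <- which(ok)
          # clearance against everything except the parent (one step
          # away, just above the threshold by construction)
          mind <- min_dist_to(p_x[cand], p_y[cand], cpts, n_cpts)
          ok[cand] <- mind >= clr
        }
        new_idx <- integer(0)
        for (q in which(ok)) {
          if (n_nodes >= max_nodes) break
          src <- p_src[q]
          if (deg[src] == 2 &&
              (junctions >= target_j ||
                 !junction_room(nodes[src, 1], nodes[src, 2])))
            next  # target met, or a junction accepted this round moved in
          if (length(new_idx)) {  # clearance against this round's tips
            d2n <- (p_x[q] - nodes[new_idx, 1])^2 +
                   (p_y[q] - nodes[new_idx, 2])^2
            if (min(d2n) < clr^2) next
          }
          n_nodes <- n_nodes + 1L
          nodes[n_nodes, ] <- c(p_x[q], p_y[q])
          w_new <- if (deg[src] <= 2 && w_in[src] > 0)
            min(max(w_in[src] * stats::runif(1, 0.97, 1.03), wmin), wmax)
          else stats::runif(1, wmin, wmax)
          add_edge(src, n_nodes, w_new)
          w_in[n_nodes] <- w_new
          dir_x[n_nodes] <- (p_x[q] - nodes[src, 1]) / step
          dir_y[n_nodes] <- (p_y[q] - nodes[src, 2]) / step
          add_cpt(nodes[n_nodes, ])
          add_cpt((nodes[n_nodes, ] + nodes[src, ]) / 2)
          new_idx <- c(new_idx, n_nodes)
          grew <- TRUE
        }
        if (length(new_idx)) {
          ai <- which(alive)
          nn <- nearest_against(attr_pts[ai, , drop = FALSE], new_idx)
          upd <- nn$dist < a_dist[ai]
          a_dist[ai[upd]] <- nn$dist[upd]
          a_near[ai[upd]] <- nn$which[upd]
          alive[ai][nn$dist < kill] <- FALSE
        }
      }
      extend <- if (junctions >= target_j) extend + 1L else 0L
      if (!grew || sum(alive) < batch_size * 0.02) {
        rounds <- rounds + 1L
        if (rounds > max_rounds || n_nodes >= max_nodes) {
          saturated <- TRUE
        } else {
          fresh <- sample_attractors(batch_size)
          nf <- nearest_against(fresh, which(deg[seq_len(n_nodes)] > 0L))
          keep <- nf$dist >= kill
          if (!grew && mean(keep) < 0.005) saturated <- TRUE  # field is full
          attr_pts <- rbind(attr_pts[alive, , drop = FALSE],
                            fresh[keep, , drop = FALSE])
          a_dist <- c(a_dist[alive], nf$dist[keep])
          a_near <- c(a_near[alive], nf$which[keep])
          alive <- rep(TRUE, nrow(attr_pts))
        }
      }
    }

    if (getOption("octaquant.verbose", FALSE))
      message("growth phase ", phase, ": ", junctions, "/", target_j,
              " junctions, ", n_nodes, " nodes")

    e_alive <- c(e_alive, rep(TRUE, length(e_i) - length(e_alive)))
    adj <- vector("list", n_nodes)
    node_edge <- vector("list", n_nodes)  # incident edge ids
    for (k in which(e_alive)) {
      adj[[e_i[k]]] <- c(adj[[e_i[k]]], e_j[k])
      adj[[e_j[k]]] <- c(adj[[e_j[k]]], e_i[k])
      node_edge[[e_i[k]]] <- c(node_edge[[e_i[k]]], k)
      node_edge[[e_j[k]]] <- c(node_edge[[e_j[k]]], k)
    }

    # prune short terminal twigs: a one- or two-segment side branch is
    # below the resolution of the smoothing + thresholding chain, so
    # it would carry a ground-truth junction the measurement can never
    # see; drop it (and with it the branch point, when degree falls)
    prune_k <- 2L
    for (lf in which(deg[seq_len(n_nodes)] == 1L)) {
      chain_e <- integer(0)
      cur <- lf; prev <- 0L
      repeat {
        ke <- node_edge[[cur]]
        ke <- ke[e_alive[ke]]
        nxt_e <- ke[e_i[ke] != prev & e_j[ke] != prev]
        if (length(nxt_e) != 1L) { chain_e <- integer(0); break }
        nxt <- if (e_i[nxt_e] == cur) e_j[nxt_e] else e_i[nxt_e]
        chain_e <- c(chain_e, nxt_e)
        if (deg[nxt] >= 3L) break
        if (deg[nxt] != 2L || length(chain_e) > prune_k) {
          chain_e <- integer(0); break
        }
        prev <- cur; cur <- nxt
      }
      if (length(chain_e) && length(chain_e) <= prune_k) {
        for (ke in chain_e) {
          e_alive[ke] <- FALSE
          deg[e_i[ke]] <- deg[e_i[ke]] - 1L
          deg[e_j[ke]] <- deg[e_j[ke]] - 1L
          adj[[e_i[ke]]] <- setdiff(adj[[e_i[ke]]], e_j[ke])
          adj[[e_j[ke]]] <- setdiff(adj[[e_j[ke]]], e_i[ke])
        }
      }
    }
    junc_idx <- which(deg[seq_len(n_nodes)] >= 3L)
    junctions <- length(junc_idx)
    if (getOption("octaquant.verbose", FALSE))
      message("after twig pruning: ", junctions, "/", target_j)

    while (junctions < target_j) {
      # anastomosis phase: capillary plexuses are looped meshes, so
      # close loops by connecting free tips/chain nodes either to
      # other free nodes or T-wise into the interior of an existing
      # segment (splitting it); each connection adds a junction pair.
      # Iterated: fresh connectors and split halves become candidates
      # for further loops until the junction target is met.
      junctions_before <- junctions
      free <- which(deg[seq_len(n_nodes)] == 2L)
      mid_x <- (nodes[e_i, 1] + nodes[e_j, 1]) / 2
      mid_y <- (nodes[e_i, 2] + nodes[e_j, 2]) / 2
      lo <- max(0.8 * step, j_sep); hi <- max(3 * kill, 1.25 * lo)
      # candidates: free node -> free node (type 0) and
      #             free node -> edge midpoint (type 1)
      cand_a <- integer(0); cand_b <- integer(0)
      cand_t <- integer(0); cand_d <- numeric(0)
      for (blk in split(free, ceiling(seq_along(free) / 1200))) {
        d2 <- outer(nodes[blk, 1], nodes[free, 1], "-")^2 +
              outer(nodes[blk, 2], nodes[free, 2], "-")^2
        hit <- which(d2 >= lo^2 & d2 <= hi^2, arr.ind = TRUE)
        if (nrow(hit)) {
          ii <- blk[hit[, 1]]; jj <- free[hit[, 2]]
          keep <- ii < jj
          cand_a <- c(cand_a, ii[keep]); cand_b <- c(cand_b, jj[keep])
          cand_t <- c(cand_t, rep(0L, sum(keep)))
          cand_d <- c(cand_d, sqrt(d2[hit][keep]))
        }
        d2m <- outer(nodes[blk, 1], mid_x, "-")^2 +
               outer(nodes[blk, 2], mid_y, "-")^2
        hitm <- which(d2m >= lo^2 & d2m <= hi^2, arr.ind = TRUE)
        if (nrow(hitm)) {
          cand_a <- c(cand_a, blk[hitm[, 1]])
          cand_b <- c(cand_b, hitm[, 2])          # edge id
          cand_t <- c(cand_t, rep(1L, nrow(hitm)))
          cand_d <- c(cand_d, sqrt(d2m[hitm]))
        }
      }
      ord <- order(cand_d, cand_t, cand_a, cand_b)
      for (q in ord) {
        if (junctions >= target_j) break
        a <- cand_a[q]
        if (deg[a] != 2) next
        if (!junction_room(nodes[a, 1], nodes[a, 2])) next
        if (any(deg[adj[[a]]] < 2L)) next   # branch ends at a tip
        if (cand_t[q] == 0L) {
          b <- cand_b[q]
          if (deg[b] != 2) next
          if (any(deg[adj[[b]]] < 2L)) next
          if (b %in% adj[[a]]) next
          if (length(intersect(adj[[a]], adj[[b]]))) next   # no triangles
          bx <- nodes[b, 1]; by_ <- nodes[b, 2]
          excl <- c(a, b, adj[[a]], adj[[b]])
        } else {
          k <- cand_b[q]
          if (!e_alive[k]) next
          if (e_i[k] == a || e_j[k] == a) next
          if (deg[e_i[k]] < 2L || deg[e_j[k]] < 2L) next
          if (deg[e_i[k]] > 2L && deg[e_j[k]] > 2L) next
          if (e_i[k] %in% adj[[a]] || e_j[k] %in% adj[[a]]) next
          bx <- mid_x[k]; by_ <- mid_y[k]
          excl <- c(a, adj[[a]], e_i[k], e_j[k])
        }
        if (!junction_room(bx, by_)) next
        if (r_faz > 0 &&
            .pt_seg_dist(cx, cy, nodes[a, 1], nodes[a, 2], bx, by_) <
              r_faz - 1e-12) next
        # the connecting segment must not brush other structure
        mx <- (nodes[a, 1] + bx) / 2; my <- (nodes[a, 2] + by_) / 2
        dmid <- sqrt((mx - nodes[seq_len(n_nodes), 1])^2 +
                     (my - nodes[seq_len(n_nodes), 2])^2)
        dmid[excl] <- Inf
        if (min(dmid) < max(0.5 * clr, 0.25 * cand_d[q])) next
        if (cand_t[q] == 0L) {
          add_edge(a, b, stats::runif(1, wmin, wmax))
          e_alive <- c(e_alive, TRUE)
          adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
        } else {
          # split edge k at its midpoint and T the free node into it
          if (n_nodes >= max_nodes) break
          n_nodes <- n_nodes + 1L
          m <- n_nodes
          nodes[m, ] <- c(mid_x[k], mid_y[k])
          i0 <- e_i[k]; j0 <- e_j[k]; w0 <- e_w[k]
          e_alive[k] <- FALSE
          # replace edge i0-j0 by i0-m-j0: endpoint degrees are
          # unchanged, so bypass add_edge's junction accounting
          e_i <- c(e_i, i0, m); e_j <- c(e_j, m, j0)
          e_w <- c(e_w, w0, w0)
          e_alive <- c(e_alive, TRUE, TRUE)
          deg[m] <- 2L
          adj[[i0]] <- c(setdiff(adj[[i0]], j0), m)
          adj[[j0]] <- c(setdiff(adj[[j0]], i0), m)
          adj[[m]] <- c(i0, j0)
          add_edge(a, m, stats::runif(1, wmin, wmax))
          e_alive <- c(e_alive, TRUE)
          adj[[a]] <- c(adj[[a]], m); adj[[m]] <- c(adj[[m]], a)
        }
      }
      e_alive <- c(e_alive, rep(TRUE, length(e_i) - length(e_alive)))
      if (junctions == junctions_before) {
        # no further loop fits at this branch-point separation; in
        # cramped configurations allow branch points to pack tighter
        # before giving up
        if (relax >= 3L) break
        relax <- relax + 1L
        j_sep <- 0.75 * j_sep
      }
    }

    if (getOption("octaquant.verbose", FALSE))
      message("after anastomosis: ", junctions, "/", target_j, " junctions")
    if (junctions >= target_j || phase == 4L) break
    # refresh the clearance points and attractor assignments so the
    # next growth phase can reclaim the space freed by pruning
    n_cpts <- 0L
    for (k in which(deg[seq_len(n_nodes)] > 0L)) add_cpt(nodes[k, ])
    for (k in which(e_alive))
      add_cpt((nodes[e_i[k], ] + nodes[e_j[k], ]) / 2)
    ai <- which(alive)
    if (length(ai)) {
      nn <- nearest_against(attr_pts[ai, , drop = FALSE],
                            which(deg[seq_len(n_nodes)] > 0L))
      a_dist[ai] <- nn$dist; a_near[ai] <- nn$which
    }
    }  # end growth/prune phases

    if (junctions < ceiling(0.85 * target_j))
      stop("unreachable target junction density (",
           params$target_junction_density, " /mm2) in a ",
           L, " mm field")

    nodes <- nodes[seq_len(n_nodes), , drop = FALSE]
    keep_e <- which(e_alive[seq_along(e_i)])
    segs <- data.frame(node_i = e_i[keep_e], node_j = e_j[keep_e],
                       width_px = e_w[keep_e])
    len <- sqrt((nodes[segs$node_i, 1] - nodes[segs$node_j, 1])^2 +
                (nodes[segs$node_i, 2] - nodes[segs$node_j, 2])^2)
    structure(list(
      nodes = nodes, segments = segs,
      true_faz_area_mm2 = pi * r_faz^2,
      true_junction_count = sum(deg[seq_len(n_nodes)] >= 3),
      true_total_length_mm = sum(len),
      field_mm = L, faz_radius_mm = r_faz
    ), class = "vascular_network")
  })
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf(paste0(
    "vascular_network: %d nodes, %d segments in a %.1f mm field\n",
    "  truth: FAZ %.3f mm2, %d junctions, total length %.1f mm\n"),
    nrow(x$nodes), nrow(x$segments), x$field_mm,
    x$true_faz_area_mm2, x$true_junction_count, x$true_total_length_mm))
  invisible(x)
}

#' Rasterize a vascular network to an en-face image and truth mask
#'
#' Draws each segment as a stroke of its stated width: the exact
#' boolean ground-truth mask contains every pixel whose center lies
#' within `width / 2` of the segment, and the grayscale image adds an
#' anti-aliased (linear-coverage) edge. Pixel (1,1) is top-left with
#' its center at `(0.5, 0.5) * scale`; `scale = field_mm * 1000 /
#' image_size` µm/px. No pixel whose center lies inside the FAZ disk
#' is ever foreground.
#'
#' @param net a `vascular_network`.
#' @param params the matching [plexus_params()].
#' @return List: `image` (an [enface_image()]), `mask` (logical
#'   ground-truth vessel mask).
#' @export
rasterize <- function(net, params) {
  n <- params$image_size
  if (nrow(net$segments) && max(net$segments$width_px) > n)
    stop("vessel width exceeds the image size")
  ppmm <- n / params$field_mm
  img <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  # pixel-center coordinates in px units (x = column, y = row)
  segs <- net$segments
  for (k in seq_len(nrow(segs))) {
    a <- net$nodes[segs$node_i[k], ] * ppmm
    b <- net$nodes[segs$node_j[k], ] * ppmm
    hw <- segs$width_px[k] / 2
    cmin <- max(1L, floor(min(a[1], b[1]) - hw + 0.5 - 1))
    cmax <- min(n, ceiling(max(a[1], b[1]) + hw + 0.5 + 1))
    rmin <- max(1L, floor(min(a[2], b[2]) - hw + 0.5 - 1))
    rmax <- min(n, ceiling(max(a[2], b[2]) + hw + 0.5 + 1))
    if (cmin > cmax || rmin > rmax) next
    rows <- rmin:rmax; cols <- cmin:cmax
    gx <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
    gy <- matrix(rows - 0.5, length(rows), length(cols))
    d <- .pt_seg_dist(gx, gy, a[1], a[2], b[1], b[2])
    mask[rows, cols] <- mask[rows, cols] | (d <= hw)
    # flow signal saturates: a pixel at least half-covered by the
    # stroke renders at full brightness, the edge falls off linearly
    cov <- pmin(pmax(2 * (hw + 0.5 - d), 0), 1)
    img[rows, cols] <- pmax(img[rows, cols], cov)
  }
  if (net$faz_radius_mm > 0) {
    ctr <- params$field_mm / 2 * ppmm
    cc <- matrix((seq_len(n) - 0.5) - ctr, n, n, byrow = TRUE)
    rr <- matrix((seq_len(n) - 0.5) - ctr, n, n)
    inside <- (cc^2 + rr^2) < (net$faz_radius_mm * ppmm)^2
    img[inside] <- 0
    mask[inside] <- FALSE
  }
  list(image = enface_image(img, params$field_mm * 1000 / n, params$plexus),
       mask = mask)
}

#' Add acquisition-like degradation to a synthetic image
#'
#' Applies, in order: point-spread Gaussian blur of `blur_sigma_px`,
#' multiplicative speckle `pixel * (1 + noise_level * eps)` with
#' `eps ~ N(0, 1)` i.i.d. per pixel, additive background haze, and a
#' clip to `[0, 1]`. With `noise_level = 0` and `blur_sigma_px = 0`
#' (and zero haze, the default) the image passes through unchanged.
#' The noise stream is derived deterministically from the parameter
#' seed, independently of the network-growth stream.
#'
#' @param img an [enface_image()] or matrix.
#' @param params a [plexus_params()].
#' @return Degraded image, same class as the input.
#' @export
add_noise <- function(img, params) {
  px <- .img_pixels(img)
  if (params$blur_sigma_px > 0)
    px <- .img_pixels(smooth_gaussian(px, params$blur_sigma_px))
  if (params$noise_level > 0 || params$haze > 0) {
    px <- .with_seed(params$seed + 500009, {
      eps <- matrix(stats::rnorm(length(px)), nrow(px), ncol(px))
      px * (1 + params$noise_level * eps) + params$haze
    })
  }
  px <- pmin(pmax(px, 0), 1)
  .img_like(img, px)
}

#' Generate one complete synthetic en-face acquisition
#'
#' Convenience wrapper: [grow_network()], [rasterize()], [add_noise()].
#'
#' @param params a [plexus_params()].
#' @return List: `image` (degraded [enface_image()]), `clean`
#'   (noise-free image), `mask` (ground-truth vessel mask), `network`
#'   (the `vascular_network` with its ground truth).
#' @export
simulate_enface <- function(params) {
  net <- grow_network(params)
  ras <- rasterize(net, params)
  list(image = add_noise(ras$image, params), clean = ras$image,
       mask = ras$mask, network = net)
}

#' Write a synthetic acquisition to disk
#'
#' Writes the degraded image (8-bit grayscale PNG) and a JSON sidecar
#' with the network nodes/segments and ground-truth metrics.
#'
#' @param sim output of [simulate_enface()].
#' @param stem output path stem; writes `<stem>.png`, `<stem>_mask.png`
#'   and `<stem>_truth.json`.
#' @return `stem`, invisibly.
#' @export
write_simulation <- function(sim, stem) {
  write_enface_png(sim$image, paste0(stem, ".png"))
  write_enface_png(sim$mask, paste0(stem, "_mask.png"))
  truth <- list(
    nodes = unname(sim$network$nodes),
    segments = sim$network$segments,
    true_faz_area_mm2 = sim$network$true_faz_area_mm2,
    true_junction_count = sim$network$true_junction_count,
    true_total_length_mm = sim$network$true_total_length_mm
  )
  jsonlite::write_json(truth, paste0(stem, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
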