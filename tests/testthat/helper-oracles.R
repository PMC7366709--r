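# Brute-force oracles used across tests. Kept deliberately naive and
# independent of the package's computational shortcuts.

# Windowed-mean Bradley threshold by direct double loop over the
# replicate-padded window, on the same 16-bit quantization grid.
brute_bradley <- function(px, window, c_off) {
  q <- round(pmin(pmax(px, 0), 1) * 65535)
  r <- (window - 1) / 2
  n <- nrow(q); m <- ncol(q)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- min(max(i + di, 1), n)
          jj <- min(max(j + dj, 1), m)
          s <- s + q[ii, jj]
        }
      }
      mu <- s / (window * window)
      out[i, j] <- q[i, j] > mu * (1 - c_off)
    }
  }
  out
}

# Two-sided exact Mann-Whitney p by full enumeration of group labels.
brute_mw_exact_p <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(N, n)
  u_all <- apply(combos, 2, function(id) sum(rk[id]) - n * (n + 1) / 2)
  mean(abs(u_all - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-9)
}

# 8-connected component count via igraph on the pixel adjacency graph.
brute_components8 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(0L)
  id <- seq_len(nrow(idx))
  key <- paste(idx[, 1], idx[, 2])
  lookup <- stats::setNames(id, key)
  edges <- c()
  for (k in id) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- lookup[paste(idx[k, 1] + dr, idx[k, 2] + dc)]
      if (!is.na(nb) && nb > k) edges <- c(edges, k, nb)
    }
  }
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# Degree->=3 node count recomputed from a network's edge list.
brute_junctions <- function(net) {
  deg <- tabulate(c(net$segments$node_i, net$segments$node_j),
                  nrow(net$nodes))
  sum(deg >= 3)
}
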