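# Independent brute-force oracles used to validate the package's optimised
# implementations. These deliberately share no code with the package
# internals.

# Breadth-first flood fill with 6-connectivity; returns an integer array of
# component labels (1..K in raster order of the component seeds).
oracle_flood_fill6 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  k <- 0L
  nbr <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    k <- k + 1L
    queue <- matrix(arrayInd(seed, d), ncol = 3)
    labels[seed] <- k
    while (nrow(queue) > 0L) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (n in seq_len(6)) {
        p <- cur + nbr[n, ]
        if (any(p < 1L) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && labels[p[1], p[2], p[3]] == 0L) {
          labels[p[1], p[2], p[3]] <- k
          queue <- rbind(queue, p)
        }
      }
    }
  }
  labels
}

# Are two labelings the same partition (labels may be permuted)?
same_partition <- function(la, lb) {
  if (!all((la > 0) == (lb > 0))) return(FALSE)
  fg <- la > 0
  key <- paste(la[fg], lb[fg])
  ua <- tapply(lb[fg], la[fg], function(x) length(unique(x)))
  ub <- tapply(la[fg], lb[fg], function(x) length(unique(x)))
  all(ua == 1L) && all(ub == 1L)
}

# Distance from points (n x 3) to the closed segment a-b, straightforwardly.
oracle_segment_distance <- function(p, a, b) {
  vapply(seq_len(nrow(p)), function(i) {
    w <- p[i, ] - a
    ab <- b - a
    t <- sum(w * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p[i, ] - (a + t * ab))^2))
  }, 0)
}

# All-pairs nearest-neighbour distances from rows of a to rows of b.
oracle_nn_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min(colSums((t(b) - a[i, ])^2)))
  }, 0)
}

# Boundary voxels (foreground with a background/out-of-volume face
# neighbour), by explicit neighbour enumeration.
oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  nbr <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
               c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (v in which(mask)) {
    ijk <- arrayInd(v, d)
    for (n in seq_len(6)) {
      p <- ijk + nbr[n, ]
      if (any(p < 1L) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        out[v] <- TRUE
        break
      }
    }
  }
  out
}

# Pooled symmetric 95th-percentile Hausdorff distance between two boundary
# point sets, quadratic time.
oracle_hd95 <- function(pa, pb, probs = 0.95) {
  dists <- c(oracle_nn_dist(pa, pb), oracle_nn_dist(pb, pa))
  quantile(dists, probs, names = FALSE, type = 7)
}
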