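# Independent brute-force oracles used by the unit and acceptance tests.
# Deliberately slow and literal; none of them share code with the package
# internals beyond the public API they are checked against.

# DBSCAN by explicit O(N^2) distance-matrix density connectivity.
# pts: m x 2 matrix of (row, col); returns a list of sorted index vectors
# (one per cluster, referring to rows of pts), order-normalized.
oracle_dbscan <- function(pts, R, M) {
  n <- nrow(pts)
  if (n == 0L) return(list())
  D <- as.matrix(stats::dist(pts))
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= R))  # includes self
  core <- vapply(nbr, length, integer(1)) >= M
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    lab <- lab + 1L
    labels[i] <- lab
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) {
        for (q in nbr[[p]]) {
          if (labels[q] == 0L) {
            labels[q] <- lab
            if (core[q]) nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
  }
  lapply(seq_len(lab), function(k) sort(which(labels == k)))
}

# canonical form of a cluster list for comparison: pixel sets sorted
# internally and clusters sorted by their first pixel
canon_clusters <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, min, numeric(1)))]
}

# pixel-set representation (linear indices) of cluster_doppler output
cluster_pixel_sets <- function(clusters, H) {
  lapply(clusters, function(cl) sort((cl$pixels[, 2] - 1L) * H + cl$pixels[, 1]))
}

# Radon sinogram recomputed by a literal per-pixel scalar loop under the
# same square-pixel (trapezoid shadow) projection model, with the bin mass
# obtained by numerically integrating the shadow profile rather than through
# the closed-form CDF the implementation uses.
oracle_radon <- function(mat, angles) {
  H <- nrow(mat); W <- ncol(mat)
  rmax <- ceiling(sqrt(((H - 1) / 2)^2 + ((W - 1) / 2)^2)) + 1L
  rho <- (-rmax):rmax
  sino <- matrix(0, length(rho), length(angles))
  for (j in seq_along(angles)) {
    th <- angles[j] * pi / 180
    w1 <- abs(cos(th)); w2 <- abs(sin(th))
    a <- w1 / 2; b <- w2 / 2
    # shadow density of a centered unit square at offset u: overlap of the
    # two box supports, normalized (piecewise linear, so the trapezoid-rule
    # quadrature below is essentially exact on a fine grid)
    dens <- function(u) {
      if (w1 < 1e-12) return(as.numeric(abs(u) <= b) / w2)
      if (w2 < 1e-12) return(as.numeric(abs(u) <= a) / w1)
      pmax(0, pmin(a, u + b) - pmax(-a, u - b)) / (w1 * w2)
    }
    binmass <- function(delta) {  # mass in [delta - 0.5, delta + 0.5]
      g <- seq(delta - 0.5, delta + 0.5, length.out = 513)
      v <- dens(g)
      sum((v[-1] + v[-length(v)]) / 2) * (g[2] - g[1])
    }
    for (r in seq_len(H)) {
      for (cc in seq_len(W)) {
        w <- mat[r, cc]
        if (w == 0) next
        x <- cc - (W + 1) / 2
        y <- r - (H + 1) / 2
        p <- x * cos(th) + y * sin(th)
        k0 <- round(p)
        for (k in (k0 - 1L):(k0 + 1L)) {
          m <- binmass(k - p)
          if (m > 0) sino[k + rmax + 1L, j] <- sino[k + rmax + 1L, j] + w * m
        }
      }
    }
  }
  list(sinogram = sino, rho = rho, angles = angles)
}

# literal double-loop evaluation of the binary separation score
oracle_spd <- function(b) {
  L <- length(b)
  vapply(seq_len(L), function(i) {
    before <- sum(b[seq_len(i)])
    after <- if (i < L) sum(1 - b[(i + 1):L]) else 0
    (before + after) / L
  }, numeric(1))
}

# draw a small line-segment image for radon tests
draw_segment <- function(H, W, p0, angle_deg, len, value = 1) {
  m <- matrix(0, H, W)
  a <- angle_deg * pi / 180
  for (t in seq(0, len, by = 0.25)) {
    r <- round(p0[1] + t * sin(a)); c <- round(p0[2] + t * cos(a))
    if (r >= 1 && r <= H && c >= 1 && c <= W) m[r, c] <- value
  }
  m
}
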