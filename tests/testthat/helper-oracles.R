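# Independent brute-force oracles used to cross-check the fast kernels.

# O(pixels x nuclei) nearest-mask Voronoi assignment with the same
# conventions as the implementation: Euclidean pixel-centre distance to the
# nuclear mask, cap in pixels, ties to the lower label.
bruteVoronoi <- function(lab, capPx) {
  nr <- nrow(lab); nc <- ncol(lab)
  labels <- sort(unique(lab[lab > 0]))
  coords <- lapply(labels, function(l) which(lab == l, arr.ind = TRUE))
  assign <- matrix(0L, nr, nc)
  dist <- matrix(Inf, nr, nc)
  for (yy in seq_len(nr)) {
    for (xx in seq_len(nc)) {
      if (lab[yy, xx] > 0) {
        assign[yy, xx] <- lab[yy, xx]; dist[yy, xx] <- 0
        next
      }
      bestD <- Inf; bestL <- 0L
      for (j in seq_along(labels)) {
        d2 <- min((coords[[j]][, 1] - yy)^2 + (coords[[j]][, 2] - xx)^2)
        if (d2 < bestD - 1e-12) { bestD <- d2; bestL <- labels[j] }
      }
      if (sqrt(bestD) <= capPx) { assign[yy, xx] <- bestL; dist[yy, xx] <- sqrt(bestD) }
    }
  }
  list(label = assign, dist = dist)
}

# reference grayscale opening with a disc (erosion then dilation), direct
# min/max scan
bruteOpening <- function(img, rPx) {
  nr <- nrow(img); nc <- ncol(img)
  off <- as.integer(floor(rPx))
  disc <- expand.grid(dy = -off:off, dx = -off:off)
  disc <- disc[disc$dy^2 + disc$dx^2 <= rPx^2, ]
  scan <- function(m, fun, init) {
    out <- matrix(init, nr, nc)
    for (i in seq_len(nrow(disc))) {
      ys <- pmin(pmax(seq_len(nr) + disc$dy[i], 1), nr)
      xs <- pmin(pmax(seq_len(nc) + disc$dx[i], 1), nc)
      out <- fun(out, m[ys, xs, drop = FALSE])
    }
    out
  }
  er <- scan(img, pmin, Inf)
  scan(er, pmax, -Inf)
}

# a tiny labelled fixture: nDisks disks of radius r on a blank raster
diskLabels <- function(dim, centers, r) {
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    for (yy in seq_len(dim[1])) for (xx in seq_len(dim[2])) {
      if ((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <= r^2)
        lab[yy, xx] <- i
    }
  }
  lab
}

# draw intensities from the quantal mixture directly
drawQuantal <- function(n, q, sigma, weights, seed) {
  set.seed(seed)
  k <- sample(seq_along(weights), n, replace = TRUE, prob = weights)
  k * q + rnorm(n, 0, sigma * sqrt(k))
}

# draw from a 3-component Gaussian mixture
drawGfp <- function(n, comp, seed) {
  set.seed(seed)
  g <- sample(1:3, n, replace = TRUE, prob = comp[, 3])
  rnorm(n, comp[g, 1], comp[g, 2])
}
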