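# Internal planar-geometry helpers shared by the mask, distance and
# synthetic-tissue code. All coordinates are microns; polygons are closed
# rings (last vertex repeats the first).

# shoelace area, absolute value
.polygonArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# TRUE when a point lies inside or on the boundary of any ring
.inAnyRing <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    hit <- sp::point.in.polygon(px, py, ring[, 1], ring[, 2]) > 0
    inside <- inside | hit
  }
  inside
}

# unsigned distance from points to the nearest ring boundary, with the index
# of the nearest ring; vectorised over points, looping over segments
.distToRings <- function(px, py, rings) {
  n <- length(px)
  best <- rep(Inf, n)
  nearest <- rep(NA_integer_, n)
  for (ri in seq_along(rings)) {
    ring <- rings[[ri]]
    for (i in seq_len(nrow(ring) - 1L)) {
      ax <- ring[i, 1]; ay <- ring[i, 2]
      bx <- ring[i + 1L, 1]; by <- ring[i + 1L, 2]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx * vx + vy * vy
      if (len2 == 0) {
        dx <- px - ax; dy <- py - ay
      } else {
        t <- ((px - ax) * vx + (py - ay) * vy) / len2
        t[t < 0] <- 0; t[t > 1] <- 1
        dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
      }
      d2 <- dx * dx + dy * dy
      upd <- d2 < best
      if (any(upd)) {
        best[upd] <- d2[upd]
        nearest[upd] <- ri
      }
    }
  }
  list(dist = sqrt(best), nest = nearest)
}

# signed distance: negative inside any ring (closed boundary -> 0, tumour)
.signedDistToRings <- function(px, py, rings) {
  d <- .distToRings(px, py, rings)
  inside <- .inAnyRing(px, py, rings)
  d$dist <- ifelse(inside, -d$dist, d$dist)
  d$inside <- inside
  d
}

# equally spaced points along a ring at the given arc-length step
.resampleRing <- function(ring, step) {
  seg <- sqrt(diff(ring[, 1])^2 + diff(ring[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(ring[1, , drop = FALSE])
  at <- seq(0, total, by = step)
  cbind(stats::approx(s, ring[, 1], xout = at)$y,
        stats::approx(s, ring[, 2], xout = at)$y)
}

# separable Gaussian smoothing of a matrix (zero-padded), sigma in cells
.gaussSmooth <- function(mat, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) rbind(matrix(0, n, ncol(m)), m, matrix(0, n, ncol(m)))
  conv1 <- function(m) {
    p <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * p[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(mat))))
}

# closed perturbed-circle ring: radius R * (1 + sum_m a_m cos(m theta + phi_m))
.blobRing <- function(cx, cy, radius, nVertices = 120L, harmonics = 2:4, amp = 0.06) {
  theta <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  pert <- rep(0, length(theta))
  for (m in harmonics) {
    a <- stats::rnorm(1L, 0, amp)
    phi <- stats::runif(1L, 0, 2 * pi)
    pert <- pert + a * cos(m * theta + phi)
  }
  pert <- pmax(pert, -0.45)  # keep the ring star-shaped and simple
  r <- radius * (1 + pert)
  ring <- cbind(cx + r * cos(theta), cy + r * sin(theta))
  rbind(ring, ring[1, , drop = FALSE])
}
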