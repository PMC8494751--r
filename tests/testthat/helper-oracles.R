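# Independent oracles and small shared fixtures for the test suite.

# Small acquisition setup used by most unit tests: 16 detectors on a 270
# degree arc, 20 mm radius, 128 time samples over a 16 mm field of view.
tiny_setup <- function(n_pixels = 20L, n_detectors = 16L, n_times = 128L,
                       fov = 0.016, radius = 0.020) {
  geom <- arc_detector_geometry(n_detectors, radius = radius)
  list(geometry = geom, fov = fov,
       coords = make_image_coords(n_pixels, fov),
       time_axis = default_time_axis(geom, fov, n = n_times))
}

# Lawson-Hanson active-set non-negative least squares: the independent
# oracle for the projected-gradient solvers (small dense systems only).
nnls_active_set <- function(A, b, tol = 1e-12, max_outer = 200L) {
  n <- ncol(A)
  P <- logical(n)
  x <- numeric(n)
  w <- crossprod(A, b - A %*% x)
  outer <- 0L
  while (any(!P) && any(w[!P] > tol * max(1, max(abs(w))))) {
    outer <- outer + 1L
    if (outer > max_outer) break
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, P, drop = FALSE]
      s[P] <- qr.solve(Ap, b)
      if (all(s[P] > tol)) break
      neg <- P & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  x
}

# Exact in-FOV arc length of a circle, computed independently of the model
# builders: intersect the circle with each boundary segment of the square
# via atan2 of explicit intersection points, then classify angular
# sub-intervals by their midpoints.
arc_length_in_square <- function(cx, cy, rho, half) {
  ang <- numeric(0)
  # vertical edges x = +-half, y in [-half, half]
  for (xe in c(-half, half)) {
    dx <- xe - cx
    if (abs(dx) < rho) {
      dy <- sqrt(rho^2 - dx^2)
      for (ye in c(cy + dy, cy - dy))
        if (ye >= -half && ye <= half)
          ang <- c(ang, atan2(ye - cy, dx))
    }
  }
  for (ye in c(-half, half)) {
    dy <- ye - cy
    if (abs(dy) < rho) {
      dx <- sqrt(rho^2 - dy^2)
      for (xe in c(cx + dx, cx - dx))
        if (xe >= -half && xe <= half)
          ang <- c(ang, atan2(dy, xe - cx))
    }
  }
  ang <- sort(unique(ang %% (2 * pi)))
  if (length(ang) == 0L) {
    inside <- abs(cx + rho) <= half && abs(cy) <= half
    return(if (inside) 2 * pi * rho else 0)
  }
  a0 <- ang
  a1 <- c(ang[-1L], ang[1L] + 2 * pi)
  mid <- (a0 + a1) / 2
  px <- cx + rho * cos(mid)
  py <- cy + rho * sin(mid)
  keep <- abs(px) <= half & abs(py) <= half
  sum(rho * (a1 - a0)[keep])
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
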