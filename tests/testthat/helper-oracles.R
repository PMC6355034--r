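# Independent oracles used across the suite. Each is written from the
# mathematical definition, by a different route than the package code.

# Proper-crossing count between all raw and average-path segment pairs,
# by solving the 2x2 parametric system for each pair (the package uses
# orientation sign tests instead).
bcf_crossings_bruteforce <- function(p, q) {
  count <- 0L
  for (t in seq_len(nrow(p) - 1)) {
    for (z in seq_len(nrow(q) - 1)) {
      a <- p[t, ]; b <- p[t + 1, ]; c_ <- q[z, ]; d <- q[z + 1, ]
      r <- b - a; s_ <- d - c_
      den <- r[1] * s_[2] - r[2] * s_[1]
      if (den == 0) next                       # parallel or collinear
      tt <- ((c_[1] - a[1]) * s_[2] - (c_[2] - a[2]) * s_[1]) / den
      uu <- ((c_[1] - a[1]) * r[2] - (c_[2] - a[2]) * r[1]) / den
      eps <- 1e-12  # parameter values this close to an endpoint are
                    # touches, which the crossing convention excludes
      if (tt > eps && tt < 1 - eps && uu > eps && uu < 1 - eps) {
        count <- count + 1L
      }
    }
  }
  count
}

# Caliper widths by exhaustive rotation: project all points on a grid of
# directions and take extreme widths.
feret_rotation_oracle <- function(points, step_deg = 0.1) {
  p <- as.matrix(points)
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(th, function(a) {
    proj <- p[, 1] * cos(a) + p[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  list(feret = max(widths), min_feret = min(widths))
}

# Distance from a point to a segment by dense sampling.
point_seg_dist_sampled <- function(pt, a, b, n = 2000) {
  tt <- seq(0, 1, length.out = n)
  min(sqrt((a[1] + tt * (b[1] - a[1]) - pt[1])^2 +
             (a[2] + tt * (b[2] - a[2]) - pt[2])^2))
}

# Rayleigh test of circular uniformity; p-value ~ exp(-n * rbar^2) for
# large n.
rayleigh_p <- function(angles_rad) {
  n <- length(angles_rad)
  rbar <- sqrt(mean(cos(angles_rad))^2 + mean(sin(angles_rad))^2)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# Random convex polygon: convex hull of n random points.
random_convex_polygon <- function(n = 12, scale = 50) {
  p <- matrix(stats::runif(2 * n, -scale, scale), ncol = 2)
  p[grDevices::chull(p), , drop = FALSE]
}

# A straight-line track tibble.
straight_track <- function(n = 20, step = 1, angle = 0, id = 1L) {
  tibble::tibble(track_id = id, frame = 0:(n - 1),
                 x = step * cos(angle) * (0:(n - 1)),
                 y = step * sin(angle) * (0:(n - 1)))
}

# Draw filled ellipses into a blank image matrix (independent of the
# package renderer: direct pixel-centre test, no heading machinery).
draw_ellipses <- function(w, h, centres, a, b, angle = 0, value = 255) {
  img <- matrix(0, w, h)
  for (i in seq_len(nrow(centres))) {
    for (x in seq_len(w)) {
      dx <- x - centres[i, 1]
      if (abs(dx) > max(a, b) + 1) next
      for (y in seq_len(h)) {
        dy <- y - centres[i, 2]
        u <- dx * cos(angle) + dy * sin(angle)
        v <- -dx * sin(angle) + dy * cos(angle)
        if ((u / a)^2 + (v / b)^2 <= 1) img[x, y] <- value
      }
    }
  }
  img
}
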