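# Independent numerical oracles used to cross-check the package's
# closed-form geometry.  These deliberately avoid the code paths they
# verify: quadrature here is fixed-order Gauss-Legendre (not the adaptive
# integrator), curvature is finite differences on sampled points, areas are
# dense polygon shoelace sums.

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (symmetric
# tridiagonal Jacobi matrix eigendecomposition).
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * (e$vectors[1, idx])^2)
}

# Fixed-order Gauss-Legendre arc length of a quadratic Bezier curve,
# applied on a few fixed equal panels: near-collinear controls give the
# speed a near-cusp that a single panel resolves only to ~1e-8.
gl_arc_length <- function(curve, ta = 0, tb = 1, n = 64, panels = 8) {
  gl <- gauss_legendre(n)
  edges <- seq(ta, tb, length.out = panels + 1)
  total <- 0
  for (k in seq_len(panels)) {
    a <- edges[k]; b <- edges[k + 1]
    t <- (b - a) / 2 * gl$nodes + (a + b) / 2
    d1x <- 2 * ((1 - t) * (curve$p1[1] - curve$p0[1]) +
                  t * (curve$p2[1] - curve$p1[1]))
    d1y <- 2 * ((1 - t) * (curve$p1[2] - curve$p0[2]) +
                  t * (curve$p2[2] - curve$p1[2]))
    total <- total + (b - a) / 2 * sum(gl$weights * sqrt(d1x^2 + d1y^2))
  }
  total
}

# Curvature from central finite differences of the sampled curve.  The
# second difference uses a wider step: central differences of a quadratic
# are exact at any step, and h^2 = 1e-10 in the denominator would amplify
# roundoff past the 1e-6 comparison tolerance.
fd_curvature <- function(curve, t, h = 1e-5, h2 = 1e-2) {
  pm <- bezier_point(curve, t - h)
  pp <- bezier_point(curve, t + h)
  d1 <- (pp - pm) / (2 * h)
  q0 <- bezier_point(curve, t)
  qm <- bezier_point(curve, max(t - h2, 0))
  qp <- bezier_point(curve, min(t + h2, 1))
  hm <- t - max(t - h2, 0); hp <- min(t + h2, 1) - t
  # unequal-step second difference (exact for a quadratic)
  d2 <- 2 * (hm * qp + hp * qm - (hm + hp) * q0) / (hm * hp * (hm + hp))
  unname(abs(d1[1] * d2[2] - d1[2] * d2[1]) / sum(d1^2)^1.5)
}

# Radius of the circle through three points.
circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  area2 <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                 (p3[1] - p1[1]) * (p2[2] - p1[2]))
  unname(a * b * cc / (2 * area2))
}

# Dense polyline length of a curve segment.
polyline_length <- function(curve, ta = 0, tb = 1, n = 1e5) {
  pts <- bezier_point(curve, seq(ta, tb, length.out = n))
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

# Shoelace area of the closed profile contour sampled densely.
shoelace_area <- function(lm, n = 5e4) {
  up <- bezier_point(upper_segment(lm), seq(0, 1, length.out = n))
  lo <- bezier_point(lower_segment(lm), seq(0, 1, length.out = n))
  pts <- rbind(up, lo[-1, ])           # closure back to P0 is the x=0 axis
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Random non-degenerate profile landmark set for oracle sweeps.  Uses the
# current RNG state; callers seed.  The shapes span gentle-to-pronounced
# bulges on both segments with an anterior inferior control so the lower
# x-extremum is usually interior.
random_profile <- function() {
  repeat {
    h <- runif(1, 120, 400)
    y3 <- h * runif(1, 0.3, 0.55)
    x3 <- runif(1, 2, 30)
    x5 <- runif(1, 2, 35)
    y5 <- h * runif(1, 0.1, 0.35)
    x6 <- runif(1, x3 + 1, x3 + 80)   # anterior control: interior x-max
    y6 <- h * runif(1, 0.6, 1.2)
    lm <- tryCatch(
      profile_landmarks(p0 = c(0, 0), p2 = c(0, h), p3 = c(x3, y3),
                        p5 = c(x5, y5), p6 = c(x6, y6)),
      error = function(e) NULL)
    if (is.null(lm)) next
    m <- tryCatch(suppressWarnings(compute_metrics(lm)),
                  error = function(e) NULL)
    if (is.null(m)) next
    # keep interior extrema so t1/t4 closed forms are well-posed
    if (m$t1 <= 0.01 || m$t1 >= 0.99 || m$t4 <= 0.01 || m$t4 >= 0.99) next
    attr(lm, "metrics") <- m
    return(lm)
  }
}

# Random generic quadratic Bezier (not a profile) for property sweeps.
random_curve <- function(scale = 10) {
  repeat {
    p <- matrix(runif(6, -scale, scale), 3, 2)
    if (sum((p[1, ] - p[3, ])^2) > 1e-4) break
  }
  quad_bezier(p[1, ], p[2, ], p[3, ])
}
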