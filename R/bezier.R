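# Quadratic Bezier primitives: Bernstein basis, evaluation, subdivision,
# curvature, osculating radius and arc length.  All plane-curve formulas are
# closed-form in the control points; arc length uses adaptive quadrature.

#' Bernstein basis polynomial
#'
#' Evaluates \eqn{b_{k,n}(t) = \binom{n}{k} t^k (1-t)^{n-k}}, the weight that
#' control point \eqn{P_k} carries on a degree-\eqn{n} Bezier curve at
#' parameter \eqn{t}.  For fixed \eqn{n} and \eqn{t} the values over
#' \eqn{k = 0, \dots, n} form a partition of unity.
#'
#' @param k Index of the basis polynomial, integer in `0:n`.
#' @param n Degree of the basis, non-negative integer.
#' @param t Curve parameter(s) in `[0, 1]`; vectorized.
#' @return Numeric vector of basis values, same length as `t`.
#' @examples
#' bernstein(1, 2, 0.5)              # 0.5
#' sum(sapply(0:5, bernstein, n = 5, t = 0.37))  # 1
#' @export
bernstein <- function(k, n, t) {
  if (length(k) != 1L || length(n) != 1L || k != round(k) || n != round(n))
    stop("'k' and 'n' must be single integers", call. = FALSE)
  if (k < 0 || k > n)
    stop(sprintf("'k' must lie in 0..n (got k=%s, n=%s)", k, n), call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop("'t' must be finite and in [0, 1]", call. = FALSE)
  choose(n, k) * t^k * (1 - t)^(n - k)
}

#' Construct a quadratic Bezier curve
#'
#' @param start,control,end Numeric length-2 points `c(x, y)`.
#' @return An object of class `"quad_bezier"` with fields `p0`, `p1`, `p2`.
#' @examples
#' qb <- quad_bezier(c(0, 0), c(1, 0), c(1, 1))
#' bezier_point(qb, 0.5)   # c(0.75, 0.25)
#' @export
quad_bezier <- function(start, control, end) {
  pts <- list(p0 = as.numeric(start), p1 = as.numeric(control),
              p2 = as.numeric(end))
  for (nm in names(pts))
    if (length(pts[[nm]]) != 2L || any(!is.finite(pts[[nm]])))
      stop(sprintf("'%s' must be a finite length-2 point", nm), call. = FALSE)
  if (pts$p0[1] == pts$p2[1] && pts$p0[2] == pts$p2[2])
    stop("degenerate curve: start and end coincide", call. = FALSE)
  structure(pts, class = "quad_bezier")
}

#' @export
print.quad_bezier <- function(x, ...) {
  cat("Quadratic Bezier curve\n")
  cat(sprintf("  start   (%g, %g)\n", x$p0[1], x$p0[2]))
  cat(sprintf("  control (%g, %g)\n", x$p1[1], x$p1[2]))
  cat(sprintf("  end     (%g, %g)\n", x$p2[1], x$p2[2]))
  invisible(x)
}

check_t01 <- function(t) {
  if (any(!is.finite(t)) || any(t < -1e-12) || any(t > 1 + 1e-12))
    stop("parameter 't' must lie in [0, 1]", call. = FALSE)
  pmin(pmax(t, 0), 1)
}

#' Evaluate a quadratic Bezier curve
#'
#' \eqn{B(t) = (1-t)^2 P_0 + 2t(1-t) P_1 + t^2 P_2}.  `B(0)` is the start
#' point, `B(1)` the end point, and every value lies in the convex hull of
#' the three controls.
#'
#' @param curve A [quad_bezier()] object.
#' @param t Parameter(s) in `[0, 1]`.
#' @return For scalar `t` a length-2 point; for vector `t` a `length(t) x 2`
#'   matrix with columns `x`, `y`.
#' @export
bezier_point <- function(curve, t) {
  t <- check_t01(t)
  b0 <- (1 - t)^2; b1 <- 2 * t * (1 - t); b2 <- t^2
  x <- b0 * curve$p0[1] + b1 * curve$p1[1] + b2 * curve$p2[1]
  y <- b0 * curve$p0[2] + b1 * curve$p1[2] + b2 * curve$p2[2]
  if (length(t) == 1L) c(x = x, y = y) else cbind(x = x, y = y)
}

#' Evaluate a Bezier curve of arbitrary degree
#'
#' General Bernstein-form evaluation \eqn{B(t) = \sum_k P_k b_{k,n}(t)} for
#' `n + 1` control points.  For three controls it agrees exactly with
#' [bezier_point()].
#'
#' @param controls List of length-2 numeric points (at least two).
#' @param t Parameter(s) in `[0, 1]`.
#' @return Point or matrix as in [bezier_point()].
#' @export
bezier_general <- function(controls, t) {
  if (!is.list(controls) || length(controls) < 2L)
    stop("need at least 2 control points", call. = FALSE)
  t <- check_t01(t)
  n <- length(controls) - 1L
  x <- numeric(length(t)); y <- numeric(length(t))
  for (k in 0:n) {
    w <- bernstein(k, n, t)
    x <- x + w * controls[[k + 1L]][1]
    y <- y + w * controls[[k + 1L]][2]
  }
  if (length(t) == 1L) c(x = x, y = y) else cbind(x = x, y = y)
}

#' Subdivide a quadratic Bezier curve (de Casteljau)
#'
#' Splits the curve at parameter `t` into two quadratic Bezier curves that
#' together trace the same locus.
#'
#' @param curve A [quad_bezier()] object.
#' @param t Split parameter strictly inside `(0, 1)`.
#' @return List with components `left` and `right`, both `"quad_bezier"`.
#' @export
bezier_split <- function(curve, t) {
  if (length(t) != 1L || !is.finite(t) || t <= 0 || t >= 1)
    stop("split parameter must lie strictly in (0, 1)", call. = FALSE)
  q0 <- (1 - t) * curve$p0 + t * curve$p1
  q1 <- (1 - t) * curve$p1 + t * curve$p2
  m  <- (1 - t) * q0 + t * q1
  list(left  = quad_bezier(curve$p0, q0, m),
       right = quad_bezier(m, q1, curve$p2))
}

# First and second parametric derivatives at t.
bezier_deriv <- function(curve, t) {
  d1 <- 2 * ((1 - t) * (curve$p1 - curve$p0) + t * (curve$p2 - curve$p1))
  d2 <- 2 * (curve$p2 - 2 * curve$p1 + curve$p0)
  list(d1 = d1, d2 = d2)
}

#' Unsigned curvature of a quadratic Bezier curve
#'
#' \eqn{K(t) = |x'y'' - y'x''| / (x'^2 + y'^2)^{3/2}}.  Invariant under rigid
#' motions of the control points; zero for collinear controls.
#'
#' @param curve A [quad_bezier()] object.
#' @param t Parameter in `[0, 1]` (scalar).
#' @return Unsigned curvature in reciprocal profile units.
#' @export
bezier_curvature <- function(curve, t) {
  t <- check_t01(t)
  if (length(t) != 1L) stop("'t' must be scalar", call. = FALSE)
  d <- bezier_deriv(curve, t)
  speed2 <- sum(d$d1^2)
  if (speed2 < .Machine$double.eps)
    stop("degenerate curve: vanishing speed at t", call. = FALSE)
  abs(d$d1[1] * d$d2[2] - d$d1[2] * d$d2[1]) / speed2^1.5
}

#' Osculating circle radius
#'
#' Reciprocal of the unsigned curvature, \eqn{R = 1/K}.  A locally straight
#' curve (zero curvature) yields `Inf` rather than an error: near-straight
#' lower profiles legitimately approach this limit.
#'
#' @inheritParams bezier_curvature
#' @return Radius in profile units; `Inf` when curvature is zero.
#' @export
osculating_radius <- function(curve, t) {
  k <- bezier_curvature(curve, t)
  if (k == 0) Inf else 1 / k
}

#' Arc length of a quadratic Bezier curve
#'
#' Integrates the parametric speed \eqn{\sqrt{x'(t)^2 + y'(t)^2}} between
#' `ta` and `tb` by adaptive quadrature (absolute tolerance `1e-10`).
#'
#' @param curve A [quad_bezier()] object.
#' @param ta,tb Parameter bounds, `0 <= ta <= tb <= 1`.
#' @return Arc length in profile units.
#' @export
bezier_arc_length <- function(curve, ta = 0, tb = 1) {
  ta <- check_t01(ta); tb <- check_t01(tb)
  if (ta > tb) stop("'ta' must not exceed 'tb'", call. = FALSE)
  if (ta == tb) return(0)
  speed <- function(t) {
    d1x <- 2 * ((1 - t) * (curve$p1[1] - curve$p0[1]) +
                  t * (curve$p2[1] - curve$p1[1]))
    d1y <- 2 * ((1 - t) * (curve$p1[2] - curve$p0[2]) +
                  t * (curve$p2[2] - curve$p1[2]))
    sqrt(d1x^2 + d1y^2)
  }
  stats::integrate(speed, ta, tb, abs.tol = 1e-10, rel.tol = 1e-12,
                   subdivisions = 500L)$value
}

# Exact antiderivative of the quadratic-Bezier speed, used internally where
# many arc lengths are needed (rejection sampling).  The speed squared is the
# quadratic 4(A t^2 + B t + C) with A = |e-d|^2, B = 2 d.(e-d), C = |d|^2,
# d = P1-P0, e = P2-P1.  Agrees with the adaptive quadrature to ~1e-12.
arc_length_closed <- function(curve, ta = 0, tb = 1) {
  if (ta == tb) return(0)
  d <- curve$p1 - curve$p0
  e <- curve$p2 - curve$p1
  A <- sum((e - d)^2); B <- 2 * sum(d * (e - d)); C <- sum(d^2)
  scale <- max(A, abs(B), C)
  if (A <= 1e-14 * scale) {
    # uniform or linearly varying speed (d == e up to roundoff)
    if (abs(B) <= 1e-14 * scale)
      return(2 * sqrt(C) * (tb - ta))
    FF <- function(t) (C + B * t)^1.5 * 2 / (3 * B)
    return(2 * (FF(tb) - FF(ta)))
  }
  disc <- 4 * A * C - B^2          # >= 0 up to roundoff
  if (disc <= 1e-12 * scale^2) {
    # collinear controls: speed = 2 sqrt(A) |t - r| with a cusp at r
    r <- -B / (2 * A)
    FF <- function(t) sign(t - r) * (t - r)^2 / 2
    return(2 * sqrt(A) * abs(FF(tb) - FF(ta)))
  }
  FF <- function(t) {
    s <- sqrt(A * t^2 + B * t + C)
    (2 * A * t + B) * s / (4 * A) +
      disc / (8 * A^1.5) * log(2 * A * t + B + 2 * sqrt(A) * s)
  }
  2 * (FF(tb) - FF(ta))
}

#' Parameter of a point known to lie on the curve
#'
#' Numerically recovers `t` such that `bezier_point(curve, t)` equals `pt`,
#' used to locate the profile's extreme points P1 and P4 on their segments.
#' The closed-form parameter expressions (see [t_extreme_closed()]) are
#' cross-checks; the numeric solution is authoritative because their
#' denominators can degenerate.
#'
#' @param curve A [quad_bezier()] object.
#' @param pt Length-2 point expected to lie on the curve.
#' @param tol On-curve tolerance as a fraction of the control-point
#'   bounding-box diagonal (default `1e-6`).
#' @return Parameter `t` in `[0, 1]`.
#' @export
param_at_point <- function(curve, pt, tol = 1e-6) {
  pt <- as.numeric(pt)
  dist2 <- function(t) {
    b <- bezier_point(curve, t)
    (b[1] - pt[1])^2 + (b[2] - pt[2])^2
  }
  # candidate parameters: roots of the per-coordinate quadratics
  # coord(t) = a t^2 + b t + c - target = 0, plus the endpoints
  cands <- c(0, 1)
  for (j in 1:2) {
    a <- curve$p0[j] - 2 * curve$p1[j] + curve$p2[j]
    b <- 2 * (curve$p1[j] - curve$p0[j])
    cc <- curve$p0[j] - pt[j]
    if (abs(a) > .Machine$double.eps) {
      disc <- b^2 - 4 * a * cc
      if (disc >= 0)
        cands <- c(cands, (-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    } else if (abs(b) > .Machine$double.eps) {
      cands <- c(cands, -cc / b)
    }
  }
  cands <- unique(pmin(pmax(cands[is.finite(cands)], 0), 1))
  d2 <- vapply(cands, dist2, numeric(1))
  tstar <- cands[which.min(d2)]
  allpts <- rbind(curve$p0, curve$p1, curve$p2)
  diag_len <- sqrt(sum((apply(allpts, 2, max) - apply(allpts, 2, min))^2))
  # polish off-grid candidates unless the root is already on the curve to
  # roundoff (guards against near-tangent root pairs)
  if (tstar > 0 && tstar < 1 &&
      sqrt(min(d2)) > 1e-10 * max(diag_len, 1)) {
    opt <- stats::optimize(dist2, c(max(0, tstar - 1e-3),
                                    min(1, tstar + 1e-3)),
                           tol = .Machine$double.eps^0.5)
    if (opt$objective < dist2(tstar)) tstar <- opt$minimum
  }
  if (sqrt(dist2(tstar)) > tol * max(diag_len, 1))
    stop(sprintf(
      "point (%g, %g) does not lie on the curve (residual %.3g)",
      pt[1], pt[2], sqrt(dist2(tstar))), call. = FALSE)
  tstar
}
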