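# Derived geometric adiposity parameters of the two-segment profile curve:
# extreme-point parameters t1/t4, curvatures K1/K2 and osculating radii,
# superior/inferior/total arc lengths, areas above and below the waist
# plane, the half volume of revolution of the lower belly, and the
# anterior/inferior projections.

#' Closed-form parameter of an extreme point
#'
#' The published closed forms for the parameter of the extreme point on each
#' segment (t1 for P1 on the superior segment, t4 for P4 on the inferior
#' one).  These serve as cross-checks on the numeric on-curve solution of
#' [param_at_point()], which is authoritative: the closed-form denominators
#' vanish for some geometries (e.g. `x5*y3 == x3*y5`).
#'
#' @param lm A [profile_landmarks()] object.
#' @param which `"t1"` or `"t4"`.
#' @return The closed-form parameter, or `NA` with a warning when the
#'   denominator is degenerate.
#' @export
t_extreme_closed <- function(lm, which = c("t1", "t4")) {
  which <- match.arg(which)
  x1 <- lm$p1[1]; y1 <- lm$p1[2]; y2 <- lm$p2[2]
  x3 <- lm$p3[1]; y3 <- lm$p3[2]; x4 <- lm$p4[1]; y4 <- lm$p4[2]
  x5 <- lm$p5[1]; y5 <- lm$p5[2]; x6 <- lm$p6[1]; y6 <- lm$p6[2]
  if (which == "t1") {
    den <- 2 * (x5 * y3 - x3 * y5)
    num <- x1 * y3 - 2 * x1 * y5 + 2 * x5 * y1 - x3 * y1
  } else {
    den <- 2 * (x6 * y2 - x6 * y3 - x3 * y2 + x3 * y6)
    num <- x4 * y2 + x4 * y3 - 2 * x4 * y6 - x3 * y2 + 2 * x3 * y6 +
      2 * x6 * y4 - 2 * x6 * y3 - x3 * y4
  }
  if (abs(den) < 1e-12 * max(abs(num), 1)) {
    warning(sprintf("degenerate denominator in closed form for %s; use the numeric solution", which),
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Superior arc length SupArc
#'
#' Length of the superior segment from the axillary fold P0 to the waist
#' extreme P1, i.e. the speed integral over `[0, t1]`.
#'
#' @param lm A [profile_landmarks()] object.
#' @param t1 Parameter of P1 on the superior segment; computed from the
#'   landmarks when omitted.
#' @return Arc length in profile units.
#' @export
sup_arc <- function(lm, t1 = NULL) {
  if (is.null(t1)) t1 <- param_at_point(upper_segment(lm), lm$p1)
  bezier_arc_length(upper_segment(lm), 0, t1)
}

#' Inferior arc length InfArc
#'
#' Length of the inferior segment from the extreme point P4 down to the
#' iliac-crest point P2, i.e. the speed integral over `[t4, 1]`.  This is
#' the profile parameter most strongly coupled to liver size in the
#' screening model.
#'
#' @param lm A [profile_landmarks()] object.
#' @param t4 Parameter of P4 on the inferior segment; computed when omitted.
#' @return Arc length in profile units.
#' @export
inf_arc <- function(lm, t4 = NULL) {
  if (is.null(t4)) t4 <- param_at_point(lower_segment(lm), lm$p4)
  bezier_arc_length(lower_segment(lm), t4, 1)
}

#' Total arc length TotalArc
#'
#' Full length of both segments (t in `[0, 1]` on each), covering also the
#' mid-portion P1 -> P3 -> P4 that SupArc and InfArc exclude.
#'
#' @param lm A [profile_landmarks()] object.
#' @return Arc length in profile units.
#' @export
total_arc <- function(lm) {
  bezier_arc_length(upper_segment(lm), 0, 1) +
    bezier_arc_length(lower_segment(lm), 0, 1)
}

#' Axial parabola of the area/volume model
#'
#' The areas and the lower-belly volume are computed from a parabola
#' `x(y) = a*y^2 + b*y` through the origin, the waist extreme `(x1, y1)` and
#' the junction `(x3, y3)` — an axial (function-of-y) simplification of the
#' profile.  Coefficients come from solving the 2x2 interpolation system;
#' the published quotient formula is algebraically identical and is checked
#' in the tests.
#'
#' @param lm A [profile_landmarks()] object.
#' @return List with elements `a` and `b`.
#' @export
area_model <- function(lm) {
  x1 <- lm$p1[1]; y1 <- lm$p1[2]; x3 <- lm$p3[1]; y3 <- lm$p3[2]
  if (abs(y1) < 1e-12 || abs(y3) < 1e-12 || abs(y1 - y3) < 1e-12)
    stop("degenerate geometry: y1, y3 must be distinct and non-zero",
         call. = FALSE)
  m <- rbind(c(y1^2, y1), c(y3^2, y3))
  ab <- solve(m, c(x1, x3))
  resid <- max(abs(m %*% ab - c(x1, x3)))
  if (resid > 1e-6 * max(abs(c(x1, x3)), 1))
    stop("axial parabola failed to interpolate the landmarks", call. = FALSE)
  list(a = ab[[1]], b = ab[[2]])
}

#' Area above the waist plane (Area1)
#'
#' \eqn{Area1 = a y_1^3/3 + b y_1^2/2}: the area between the axial parabola
#' and the vertical reference line from P0 down to the waist level y1.
#'
#' @param lm A [profile_landmarks()] object.
#' @param coeffs Optional precomputed [area_model()] coefficients.
#' @return Area in squared profile units.
#' @export
area1 <- function(lm, coeffs = NULL) {
  if (is.null(coeffs)) coeffs <- area_model(lm)
  y1 <- lm$p1[2]
  coeffs$a * y1^3 / 3 + coeffs$b * y1^2 / 2
}

#' Total profile area
#'
#' Area enclosed by the superior segment, the inferior segment and the
#' closing axis segment P2 -> P0, by the Green's-theorem line integral
#' \eqn{\frac12 \oint (x\,dy - y\,dx)} over the parametric boundary.
#' Returned as a positive number; the axis closure contributes nothing
#' (x = 0 along it).
#'
#' @param lm A [profile_landmarks()] object.
#' @return Area in squared profile units.
#' @export
total_area <- function(lm) {
  seg_area <- function(curve) {
    f <- function(t) {
      b0 <- (1 - t)^2; b1 <- 2 * t * (1 - t); b2 <- t^2
      x <- b0 * curve$p0[1] + b1 * curve$p1[1] + b2 * curve$p2[1]
      y <- b0 * curve$p0[2] + b1 * curve$p1[2] + b2 * curve$p2[2]
      dx <- 2 * ((1 - t) * (curve$p1[1] - curve$p0[1]) +
                   t * (curve$p2[1] - curve$p1[1]))
      dy <- 2 * ((1 - t) * (curve$p1[2] - curve$p0[2]) +
                   t * (curve$p2[2] - curve$p1[2]))
      x * dy - y * dx
    }
    # the integrand is cubic in t: two-point Gauss-Legendre is exact
    r <- 1 / (2 * sqrt(3))
    (f(0.5 - r) + f(0.5 + r)) / 4
  }
  abs(seg_area(upper_segment(lm)) + seg_area(lower_segment(lm)))
}

#' Area below the waist plane (Area2)
#'
#' Complement of [area1()] within the total enclosed area,
#' `Area2 = TotalArea - Area1`, representing the abdominal area below the
#' waist-circumference plane `y = y1`.  (The source model's printed relation
#' adds the two; the subtraction is the sign convention consistent with
#' `Area1 + Area2 = TotalArea` in the y-down frame.)
#'
#' @param lm A [profile_landmarks()] object.
#' @param total Optional precomputed [total_area()].
#' @param a1 Optional precomputed [area1()].
#' @return Area in squared profile units.
#' @export
area2 <- function(lm, total = NULL, a1 = NULL) {
  if (is.null(total)) total <- total_area(lm)
  if (is.null(a1)) a1 <- area1(lm)
  out <- total - a1
  if (out < 0)
    warning("negative Area2: landmarks inconsistent with the axial parabola model",
            call. = FALSE)
  out
}

#' Lower-belly half volume of revolution (Vlow)
#'
#' Half the volume swept by the axial parabola profile about the vertical
#' reference axis, evaluated from the closed-form quintic
#' \deqn{V_{low} = \frac{\pi}{2}\left[2F(y_4) - F(y_1) - F(y_2)\right],
#'   \quad F(y) = \frac{a^2 y^5}{5} + \frac{a b y^4}{2} + \frac{b^2 y^3}{3}}
#' where \eqn{F} is the antiderivative of \eqn{x(y)^2 = (a y^2 + b y)^2}.
#' The half factor reflects that the belly develops only anteriorly.
#'
#' @param lm A [profile_landmarks()] object.
#' @param coeffs Optional precomputed [area_model()] coefficients.
#' @return Volume in cubed profile units.
#' @export
vlow <- function(lm, coeffs = NULL) {
  if (is.null(coeffs)) coeffs <- area_model(lm)
  y1 <- lm$p1[2]; y2 <- lm$p2[2]; y4 <- lm$p4[2]
  if (y4 < y1 || y4 < y2)
    warning("P4 lies above a reference level (expected y4 >= y1 and y4 >= y2)",
            call. = FALSE)
  a <- coeffs$a; b <- coeffs$b
  FF <- function(y) a^2 * y^5 / 5 + a * b * y^4 / 2 + b^2 * y^3 / 3
  pi / 2 * (2 * FF(y4) - FF(y1) - FF(y2))
}

#' Numeric companion of [vlow()]
#'
#' Quadrature evaluation of the same quantity,
#' \eqn{\frac{\pi}{2}\left(\int_{y_1}^{y_4} + \int_{y_2}^{y_4}\right) x(y)^2 \, dy},
#' used as an independent cross-check of the closed-form quintic.
#'
#' @inheritParams vlow
#' @return Volume in cubed profile units.
#' @export
vlow_numeric <- function(lm, coeffs = NULL) {
  if (is.null(coeffs)) coeffs <- area_model(lm)
  a <- coeffs$a; b <- coeffs$b
  xsq <- function(y) (a * y^2 + b * y)^2
  int <- function(lo, hi) {
    s <- if (lo <= hi) 1 else -1
    s * stats::integrate(xsq, min(lo, hi), max(lo, hi), abs.tol = 1e-12,
                         rel.tol = 1e-12, subdivisions = 500L)$value
  }
  pi / 2 * (int(lm$p1[2], lm$p4[2]) + int(lm$p2[2], lm$p4[2]))
}

#' Anterior and inferior projections
#'
#' `AntPr = x4 - x2` (anterior advancement of the belly's lowest extreme
#' past the reference axis; equals `x4` in the canonical frame) and
#' `InfPr = y4 - y2` (how far P4 hangs below the iliac-crest level).
#'
#' @param lm A [profile_landmarks()] object.
#' @return Named numeric vector `c(ant_pr, inf_pr)`.
#' @export
projections <- function(lm) {
  c(ant_pr = lm$p4[1] - lm$p2[1], inf_pr = lm$p4[2] - lm$p2[2])
}

#' Compute the full geometric parameter vector
#'
#' Orchestrates the per-profile computations into one metrics record:
#' extreme-point parameters, curvatures and radii at P1/P4, the three arc
#' lengths, the three areas, the lower-belly volume and the projections.
#' Deterministic for a fixed landmark set.
#'
#' @param lm A [profile_landmarks()] object.
#' @return An object of class `"profile_metrics"`: a named list with fields
#'   `t1`, `t4`, `k1`, `k2`, `r1`, `r2`, `sup_arc`, `inf_arc`, `total_arc`,
#'   `area1`, `area2`, `total_area`, `vlow`, `ant_pr`, `inf_pr`.
#' @examples
#' lm <- profile_landmarks(
#'   p0 = c(0, 0), p3 = c(28, 95), p5 = c(30, 45),
#'   p6 = c(26, 150), p2 = c(0, 170))
#' m <- compute_metrics(lm)
#' m$inf_arc
#' @export
compute_metrics <- function(lm) {
  stopifnot(inherits(lm, "profile_landmarks"))
  up <- upper_segment(lm); lo <- lower_segment(lm)
  fail <- function(what, e)
    stop(sprintf("failed computing %s: %s", what, conditionMessage(e)),
         call. = FALSE)
  t1 <- tryCatch(param_at_point(up, lm$p1), error = function(e) fail("t1", e))
  t4 <- tryCatch(param_at_point(lo, lm$p4), error = function(e) fail("t4", e))
  k1 <- tryCatch(bezier_curvature(up, t1), error = function(e) fail("K1", e))
  k2 <- tryCatch(bezier_curvature(lo, t4), error = function(e) fail("K2", e))
  coeffs <- tryCatch(area_model(lm), error = function(e) fail("area model", e))
  tot <- total_area(lm)
  a1 <- area1(lm, coeffs)
  pr <- projections(lm)
  out <- list(
    t1 = t1, t4 = t4, k1 = k1, k2 = k2,
    r1 = if (k1 == 0) Inf else 1 / k1,
    r2 = if (k2 == 0) Inf else 1 / k2,
    sup_arc = sup_arc(lm, t1), inf_arc = inf_arc(lm, t4),
    total_arc = total_arc(lm),
    area1 = a1, area2 = area2(lm, tot, a1), total_area = tot,
    vlow = vlow(lm, coeffs),
    ant_pr = unname(pr["ant_pr"]), inf_pr = unname(pr["inf_pr"]))
  structure(out, class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat("Thoracic-abdominal profile metrics\n")
  fmt <- function(nm) sprintf("  %-10s %12.6g\n", nm, x[[nm]])
  for (nm in names(x)) cat(fmt(nm))
  invisible(x)
}

#' Published closed-form arc lengths (diagnostic)
#'
#' Verbatim implementation of the printed closed-form expressions for
#' SupArc and InfArc, including their coefficient tables.  These forms are
#' typographically suspect in the source (the InfArc discriminant contains
#' a cancelling pair of cubic terms and the prefactors/discriminant scalings
#' do not match a standard antiderivative), so they are exposed only as a
#' diagnostic: [arc_closed_form_report()] quantifies their deviation from
#' the quadrature values, which are authoritative.
#'
#' @param lm A [profile_landmarks()] object.
#' @param t1,t4 Extreme-point parameters; computed when omitted.
#' @return Named list with `sup_closed`, `inf_closed` (printed expressions,
#'   `NA` when a square root or logarithm goes out of domain) and
#'   `sup_quad`, `inf_quad` (quadrature references).
#' @export
arc_closed_forms <- function(lm, t1 = NULL, t4 = NULL) {
  if (is.null(t1)) t1 <- param_at_point(upper_segment(lm), lm$p1)
  if (is.null(t4)) t4 <- param_at_point(lower_segment(lm), lm$p4)
  y2 <- lm$p2[2]; x3 <- lm$p3[1]; y3 <- lm$p3[2]
  x5 <- lm$p5[1]; y5 <- lm$p5[2]; x6 <- lm$p6[1]; y6 <- lm$p6[2]

  guard <- function(expr) tryCatch({
    v <- expr
    if (!is.finite(v)) NA_real_ else v
  }, warning = function(w) NA_real_, error = function(e) NA_real_)

  # superior segment, printed coefficients
  a_s <- x3^2 - 4 * x3 * x5 + 4 * x5^2 + y3^2 - 4 * y3 * y5 + 4 * y5^2
  b_s <- 2 * (3 * x3 * x5 + y3 * y5 - 2 * x5^2 - 2 * y5^2)
  delta_s <- -3 * x3^2 * x5^2 - 3 * y3^2 * y5^2 - 12 * x5^4 - 12 * y5^4 +
    2 * x3 * x5 * y3 * y5 + 12 * x3 * x5^3 + 12 * x3 * x5 * y3 * y5^2 +
    12 * x5^2 * y3 * y5 + 12 * y3 * y5^3 - 24 * x5^2 * y5^2 -
    4 * x5^2 * y3^2 - 4 * x3^2 * y5^2
  sup_closed <- guard({
    d <- t1 + b_s / (2 * a_s); e <- b_s / (2 * a_s)
    ksq <- -delta_s / (4 * a_s)
    a_s * (d * sqrt(d^2 + ksq) - e * sqrt(e^2 + ksq) +
             ksq * log(d + sqrt(d^2 + ksq)) - ksq * log(e + sqrt(e^2 + ksq)))
  })

  # inferior segment, printed coefficients (Delta' kept verbatim: the
  # -12*x3*x6^3 and +12*x3*x6^3 terms cancel)
  a_i <- x3^2 + 4 * x6^2 - 4 * x3 * x6 + y3^2 + y2^2 + 4 * y6^2 +
    2 * y2 * y3 - 4 * y3 * y6 - 4 * y2 * y6
  b_i <- 2 * (3 * x3 * x6 + 3 * y3 * y6 - 2 * x6^2 - 2 * y6^2 - x3^2 -
                y3^2 + y2 * y6 - y2 * y3)
  delta_i <- y3^2 * y6^2 + 4 * y6^4 + y3^4 + y2^2 * y6^2 + y2^2 * y3^2 +
    2 * x3 * x6 * y3 * y6 - 12 * x3 * x6^3 - 4 * x3 * x6 * y6^2 -
    4 * x3 * x6 * y3^2 - 2 * x3 * x6 * y2 * y6 - x3 * x6 * y2 * y3 -
    4 * y3 * y6^3 - 4 * y3^3 * y6 + 2 * y2 * y3 * y6^2 -
    4 * y2 * y3^2 * y6 + 4 * x6^2 * y6^2 + 3 * x6^2 * y3^2 +
    2 * x6^2 * y2 * y3 - 4 * y2 * y6^3 + x3^2 * y3^2 +
    2 * x3^2 * y2 * y6 + 2 * y2 * y3^3 + 12 * x3 * x6^3 -
    x6^2 * y2^2 - x3^2 * y2^2 + 2 * x3 * x6 * y2^2
  inf_closed <- guard({
    e <- 1 + b_i / (2 * a_i); dprime <- t4 + b_i / (2 * a_i)
    ksq <- -delta_i / a_i^2
    a_i * (e * sqrt(e^2 + ksq) - dprime * sqrt(dprime^2 + ksq) +
             ksq * log(e + sqrt(e^2 + ksq)) -
             ksq * log(dprime + sqrt(dprime^2 + ksq)))
  })

  list(sup_closed = sup_closed, inf_closed = inf_closed,
       sup_quad = sup_arc(lm, t1), inf_quad = inf_arc(lm, t4))
}

#' Agreement report for the published arc-length closed forms
#'
#' Evaluates [arc_closed_forms()] over a list of landmark sets and reports
#' how often each printed expression agrees with adaptive quadrature.
#'
#' @param lms List of [profile_landmarks()] objects.
#' @param rel_tol Relative agreement tolerance (default `1e-6`).
#' @return Data frame with per-profile relative deviations and an
#'   `agree` flag for each form.
#' @export
arc_closed_form_report <- function(lms, rel_tol = 1e-6) {
  rows <- lapply(lms, function(lm) {
    cf <- arc_closed_forms(lm)
    sup_dev <- abs(cf$sup_closed - cf$sup_quad) / max(cf$sup_quad, 1e-12)
    inf_dev <- abs(cf$inf_closed - cf$inf_quad) / max(cf$inf_quad, 1e-12)
    data.frame(sup_dev = sup_dev, inf_dev = inf_dev,
               sup_agree = is.finite(sup_dev) && sup_dev <= rel_tol,
               inf_agree = is.finite(inf_dev) && inf_dev <= rel_tol)
  })
  do.call(rbind, rows)
}
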