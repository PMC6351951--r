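# Derived profile metrics: segments, extreme-point parameters, arcs, areas,
# volume, projections, and the orchestrating compute_metrics().

make_lm <- function(h = 170, p3 = c(28, 95), p5 = c(30, 45), p6 = c(40, 150))
  profile_landmarks(p0 = c(0, 0), p2 = c(0, h), p3 = p3, p5 = p5, p6 = p6)

test_that("profile segments use the documented control points", {
  lm <- make_lm()
  up <- upper_segment(lm); lo <- lower_segment(lm)
  expect_equal(unname(bezier_point(up, 0)), c(0, 0))
  expect_equal(unname(bezier_point(up, 1)), lm$p3)
  expect_equal(unname(bezier_point(lo, 0)), lm$p3)
  expect_equal(unname(bezier_point(lo, 1)), lm$p2)
  # canonical-frame closed form of the superior segment
  t <- 0.25
  expect_equal(bezier_point(up, t)[["x"]],
               2 * t * (1 - t) * lm$p5[1] + t^2 * lm$p3[1])
  expect_equal(bezier_point(up, t)[["y"]],
               2 * t * (1 - t) * lm$p5[2] + t^2 * lm$p3[2])
})

test_that("closed-form t1/t4 agree with the numeric on-curve solution", {
  set.seed(31)
  for (i in 1:100) {
    lm <- random_profile()
    m <- attr(lm, "metrics")
    t1c <- t_extreme_closed(lm, "t1")
    t4c <- t_extreme_closed(lm, "t4")
    if (is.finite(t1c)) expect_equal(t1c, m$t1, tolerance = 1e-6)
    if (is.finite(t4c)) expect_equal(t4c, m$t4, tolerance = 1e-6)
  }
})

test_that("closed form flags the degenerate denominator", {
  # x5*y3 == x3*y5 makes the t1 denominator vanish
  lm <- suppressWarnings(
    profile_landmarks(p0 = c(0, 0), p2 = c(0, 170), p3 = c(20, 100),
                      p5 = c(10, 50), p6 = c(30, 150)))
  expect_warning(v <- t_extreme_closed(lm, "t1"), "degenerate denominator")
  expect_true(is.na(v))
})

test_that("sup/inf arcs: empty and full sub-arcs, Gauss-Legendre oracle", {
  lm <- make_lm()
  expect_equal(sup_arc(lm, t1 = 0), 0)
  expect_equal(sup_arc(lm, t1 = 1), bezier_arc_length(upper_segment(lm)))
  expect_equal(inf_arc(lm, t4 = 1), 0)
  expect_equal(inf_arc(lm, t4 = 0), bezier_arc_length(lower_segment(lm)))
  set.seed(32)
  for (i in 1:50) {
    lm <- random_profile()
    m <- attr(lm, "metrics")
    expect_equal(m$sup_arc, gl_arc_length(upper_segment(lm), 0, m$t1),
                 tolerance = 1e-9)
    expect_equal(m$inf_arc, gl_arc_length(lower_segment(lm), m$t4, 1),
                 tolerance = 1e-9)
  }
})

test_that("total arc covers both whole segments and bounds the sub-arcs", {
  # straight segments with chord lengths 1 and 2
  lm <- suppressWarnings(profile_landmarks(
    p0 = c(0, 0), p2 = c(0, 3), p3 = c(0.0, 1), p5 = c(0, 0.5),
    p6 = c(0, 2), normalize = FALSE))
  expect_equal(total_arc(lm), 3, tolerance = 1e-9)
  set.seed(33)
  for (i in 1:10) {
    lm <- random_profile()
    m <- attr(lm, "metrics")
    expect_gte(m$total_arc, m$sup_arc + m$inf_arc - 1e-9)
    expect_equal(m$total_arc,
                 polyline_length(upper_segment(lm)) +
                   polyline_length(lower_segment(lm)),
                 tolerance = 1e-6)
  }
})

test_that("axial parabola: hand system, interpolation, printed quotient", {
  lm <- list(p1 = c(1, 1), p3 = c(0, 2))
  cf <- area_model(lm)
  expect_equal(cf$a, -1)
  expect_equal(cf$b, 2)
  set.seed(34)
  for (i in 1:50) {
    x1 <- runif(1, 0.5, 40); y1 <- runif(1, 10, 100)
    x3 <- runif(1, 0.5, 40); y3 <- y1 + runif(1, 5, 80)
    cf <- area_model(list(p1 = c(x1, y1), p3 = c(x3, y3)))
    expect_equal(cf$a * y1^2 + cf$b * y1, x1, tolerance = 1e-9)
    expect_equal(cf$a * y3^2 + cf$b * y3, x3, tolerance = 1e-9)
    # published quotient form of the same coefficients
    a_pub <- (x3 * y1 - x1 * y3) / (y1 * y3^2 - y1^2 * y3)
    b_pub <- x3 / y3 - a_pub * y3
    expect_equal(cf$a, a_pub, tolerance = 1e-9)
    expect_equal(cf$b, b_pub, tolerance = 1e-9)
  }
  expect_error(area_model(list(p1 = c(1, 50), p3 = c(2, 50))), "degenerate")
})

test_that("area1: triangle and parabola hand values, quadrature oracle", {
  expect_equal(area1(list(p1 = c(NA, 2)), coeffs = list(a = 0, b = 1)), 2)
  expect_equal(area1(list(p1 = c(NA, 1)), coeffs = list(a = -1, b = 2)),
               2 / 3)
  set.seed(35)
  for (i in 1:30) {
    a <- runif(1, -0.01, 0.01); b <- runif(1, 0, 1); y1 <- runif(1, 10, 120)
    quad <- integrate(function(y) a * y^2 + b * y, 0, y1,
                      rel.tol = 1e-12)$value
    expect_equal(area1(list(p1 = c(NA, y1)), coeffs = list(a = a, b = b)),
                 quad, tolerance = 1e-10)
  }
})

test_that("total area: shoelace on a degenerate triangle and random profiles", {
  tri <- suppressWarnings(profile_landmarks(
    p0 = c(0, 0), p2 = c(0, 2), p3 = c(1, 1), p5 = c(0.5, 0.5),
    p6 = c(0.5, 1.5), normalize = FALSE))
  expect_equal(total_area(tri), 1, tolerance = 1e-9)
  set.seed(36)
  for (i in 1:10) {
    lm <- random_profile()
    expect_equal(total_area(lm), shoelace_area(lm),
                 tolerance = 1e-6)
  }
})

test_that("area2 is the complement of area1 within the total", {
  lm <- make_lm()
  expect_equal(area2(lm, total = 10, a1 = 4), 6)
  expect_equal(area2(lm, total = 10, a1 = 10), 0)
  expect_warning(area2(lm, total = 4, a1 = 10), "negative Area2")
  set.seed(37)
  for (i in 1:10) {
    lm <- random_profile()
    m <- attr(lm, "metrics")
    expect_equal(m$area1 + m$area2, m$total_area, tolerance = 1e-9)
  }
})

test_that("vlow: cone half-volume, zero profile, antiderivative oracle", {
  # linear profile x = y (a = 0, b = 1) from apex to height h: the printed
  # combination reduces to pi/2 * (2/3) h^3 = pi h^3 / 3
  h <- 7
  fake <- list(p1 = c(0, 0), p2 = c(0, 0), p4 = c(h, h))
  expect_equal(suppressWarnings(vlow(fake, coeffs = list(a = 0, b = 1))),
               pi * h^3 / 3)
  expect_equal(suppressWarnings(vlow(fake, coeffs = list(a = 0, b = 0))), 0)
  set.seed(38)
  for (i in 1:30) {
    lm <- random_profile()
    v <- suppressWarnings(vlow(lm))
    vn <- suppressWarnings(vlow_numeric(lm))
    expect_equal(v, vn, tolerance = 1e-10)
  }
})

test_that("projections subtract P2 from P4", {
  fake <- list(p4 = c(50, 120), p2 = c(0, 100))
  expect_equal(unname(projections(fake)), c(50, 20))
  expect_equal(unname(projections(list(p4 = c(0, 100), p2 = c(0, 100)))),
               c(0, 0))
  set.seed(39)
  lm <- random_profile()
  expect_equal(projections(lm)[["ant_pr"]], lm$p4[1])  # x2 = 0 canonically
})

test_that("compute_metrics is complete, finite and deterministic", {
  set.seed(40)
  lm <- random_profile()
  m1 <- suppressWarnings(compute_metrics(lm))
  expect_s3_class(m1, "profile_metrics")
  expect_length(unclass(m1), 15L)
  expect_true(all(vapply(m1, is.finite, logical(1))))
  m2 <- suppressWarnings(compute_metrics(lm))
  expect_identical(m1, m2)
  # reciprocal radius invariants
  expect_equal(m1$r1 * m1$k1, 1)
  expect_equal(m1$r2 * m1$k2, 1)
})

test_that("published arc-length closed forms are reported, not trusted", {
  set.seed(41)
  lms <- replicate(20, random_profile(), simplify = FALSE)
  rep <- arc_closed_form_report(lms)
  expect_identical(nrow(rep), 20L)
  expect_true(all(c("sup_dev", "inf_dev", "sup_agree", "inf_agree") %in%
                    names(rep)))
  # the report must at least quantify every profile (NA deviations allowed
  # when the printed expression leaves its real domain)
  expect_true(all(is.na(rep$sup_dev) | rep$sup_dev >= 0))
  expect_true(all(is.na(rep$inf_dev) | rep$inf_dev >= 0))
})
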