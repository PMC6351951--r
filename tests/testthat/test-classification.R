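# Interval classification: the three criteria, composite steatosis types,
# exhaustiveness/monotonicity properties, and a brute-force oracle.

th <- classification_thresholds()


test_that("criterion I worked examples", {
  expect_identical(classify_criterion1(0.01, 150, th), "RP")
  expect_identical(classify_criterion1(0.05, 300, th), "FP")
  expect_identical(classify_criterion1(0.028, 220, th), "indeterminate")
  expect_error(classify_criterion1(-0.1, 100, th), "non-negative")
})

test_that("criterion II worked examples including the Area2 overlap", {
  expect_identical(classify_criterion2(0.001, 50, th), "FTP")
  expect_identical(classify_criterion2(0.01, 150, th), "PP")
  # Area2 = 93 lies in both printed intervals; K1 membership decides
  expect_identical(classify_criterion2(0.001, 93, th), "FTP")
  expect_identical(classify_criterion2(0.01, 93, th), "PP")
  expect_identical(classify_criterion2(0.006, 93, th), "indeterminate")
})

test_that("criterion III worked examples and boundary convention", {
  expect_identical(classify_criterion3(40, 80, th),
                   list(antpr_band = "below_average",
                        infpr_band = "above_average"))
  # exact split point goes to the upper band
  expect_identical(classify_criterion3(69.16, 42.85, th),
                   list(antpr_band = "above_average",
                        infpr_band = "above_average"))
  expect_identical(classify_criterion3(200, -5, th),
                   list(antpr_band = "out_of_range",
                        infpr_band = "out_of_range"))
})

test_that("composite steatosis types", {
  st <- steatosis_types("RP", "FTP", "below_average", "below_average")
  expect_identical(st, list(type_a = "non_steatosic",
                            type_b = "non_steatosic"))
  st <- steatosis_types("FP", "PP", "above_average", "above_average")
  expect_identical(st, list(type_a = "steatosic", type_b = "steatosic"))
  st <- steatosis_types("indeterminate", "PP", "below_average",
                        "below_average")
  expect_identical(st$type_a, "indeterminate")
  expect_identical(st$type_b, "indeterminate")
})

test_that("classification agrees with the brute-force oracle on fuzzed tuples", {
  set.seed(51)
  n <- 1e4
  k2 <- runif(n, 0, 0.12); inf <- runif(n, 0, 450)
  k1 <- runif(n, 0, 0.02); a2 <- runif(n, 0, 250)
  ant <- runif(n, -10, 150); ip <- runif(n, -20, 150)
  c1 <- classify_criterion1(k2, inf, th)
  c2 <- classify_criterion2(k1, a2, th)
  c3 <- classify_criterion3(ant, ip, th)
  st <- steatosis_types(c1, c2, c3$antpr_band, c3$infpr_band)
  for (i in sample(n, 2000)) {
    bf <- brute_force_classify(k2[i], inf[i], k1[i], a2[i], ant[i], ip[i])
    expect_identical(c1[i], unname(bf["c1"]))
    expect_identical(c2[i], unname(bf["c2"]))
    expect_identical(c3$antpr_band[i], unname(bf["ab"]))
    expect_identical(c3$infpr_band[i], unname(bf["ib"]))
    expect_identical(st$type_a[i], unname(bf["ta"]))
    expect_identical(st$type_b[i], unname(bf["tb"]))
  }
  # exhaustiveness: every fuzzed tuple got exactly one label per criterion
  expect_true(all(c1 %in% c("RP", "FP", "indeterminate")))
  expect_true(all(c2 %in% c("FTP", "PP", "indeterminate")))
  expect_true(all(st$type_b %in%
                    c("steatosic", "non_steatosic", "indeterminate")))
})

test_that("raising inf_pr never demotes type B from steatosic", {
  set.seed(52)
  ranks <- c(non_steatosic = 1, indeterminate = 2, steatosic = 3)
  for (i in 1:200) {
    c1 <- sample(c("RP", "FP", "indeterminate"), 1)
    ips <- sort(runif(2, 0, 120))
    b <- classify_criterion3(50, ips, th)$infpr_band
    st <- steatosis_types(rep(c1, 2), rep("PP", 2), rep("above_average", 2),
                          b)
    # moving inf_pr up cannot move type_b from steatosic to non_steatosic
    expect_false(st$type_b[1] == "steatosic" &&
                   st$type_b[2] == "non_steatosic")
  }
})

test_that("nearest mode snaps gap values to the closer interval", {
  thn <- classification_thresholds(mode = "nearest")
  # K2 in the narrow gap between the RP and FP curvature intervals,
  # InfArc likewise between the two printed ranges
  expect_identical(classify_criterion1(0.0272, 216, thn), "RP")
  expect_identical(classify_criterion1(0.0293, 225.5, thn), "FP")
  # strict mode leaves both indeterminate
  expect_identical(classify_criterion1(0.0272, 216, th), "indeterminate")
})

test_that("threshold scaling is dimensionally consistent", {
  th2 <- classification_thresholds(scale = 2)
  expect_equal(th2$infarc_rp_lo, th$infarc_rp_lo * 2)
  expect_equal(th2$k2_rp_lo, th$k2_rp_lo / 2)
  expect_equal(th2$area2_ftp_hi, th$area2_ftp_hi * 4)
  expect_equal(th2$antpr_split, th$antpr_split * 2)
  # a geometry scaled by s classifies identically under scaled thresholds
  set.seed(53)
  lm <- random_profile()
  m <- attr(lm, "metrics")
  lm2 <- profile_landmarks(p0 = 2 * lm$p0, p2 = 2 * lm$p2, p3 = 2 * lm$p3,
                           p5 = 2 * lm$p5, p6 = 2 * lm$p6)
  m2 <- suppressWarnings(compute_metrics(lm2))
  expect_identical(unclass(classify_profile(m2, th2)),
                   unclass(classify_profile(m, th)))
  expect_error(classification_thresholds(k2_rp_lo = 1), "empty")
  expect_error(classification_thresholds(nope = 1), "unknown threshold")
})
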