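# Profile-type classification from the published interval thresholds.
#
# Three criteria, each read off the derived metrics:
#   I   (K2, InfArc)  -> raised (RP) vs fallen (FP) profile
#   II  (K1, Area2)   -> flat (FTP) vs prominent (PP) profile
#   III (AntPr, InfPr)-> below/above-average anterior and inferior advancement
# plus the composite A/B steatosis categories built from II+III and I+III.
#
# The intervals are empirical ranges from the originating cohort, not a
# partition of the plane: values falling in the gaps (or straddling the two
# intervals of a criterion) are labelled "indeterminate" by default; a
# "nearest" mode snaps them to the closer interval instead.

#' Classification thresholds
#'
#' The twelve interval bounds of the published classification, in the
#' conventional units of the digitized profiles, plus the below/above
#' average split points for the projection bands.  A `scale` factor rescales
#' all length-dimension bounds for users digitizing at a different display
#' resolution (lengths scale linearly, curvatures inversely, areas
#' quadratically).
#'
#' @param scale Length scale factor relative to the conventional units of
#'   the published thresholds (default 1).
#' @param mode `"strict"` (gaps are indeterminate) or `"nearest"`
#'   (gap values snap to the closer interval).
#' @param ... Named overrides for individual bounds (e.g. `k2_rp_lo = 5e-4`),
#'   applied after scaling.
#' @return Object of class `"classification_thresholds"`.
#' @export
classification_thresholds <- function(scale = 1, mode = c("strict", "nearest"),
                                      ...) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  th <- list(
    # criterion I: curvature at P4 and inferior arc length
    k2_rp_lo = 0.000493763, k2_rp_hi = 0.027066286,
    infarc_rp_lo = 108.0939, infarc_rp_hi = 214.7204,
    k2_fp_lo = 0.029424926, k2_fp_hi = 0.080514181,
    infarc_fp_lo = 225.8813, infarc_fp_hi = 391.5648,
    # criterion II: curvature at P1 and area below the waist plane
    k1_ftp_lo = 0.000194215, k1_ftp_hi = 0.005002445,
    area2_ftp_lo = 7.56, area2_ftp_hi = 94.89,
    k1_pp_lo = 0.006819941, k1_pp_hi = 0.014204314,
    area2_pp_lo = 91.35, area2_pp_hi = 187.54,
    # criterion III: projection ranges and average split points
    antpr_lo = 22.39, antpr_split = 69.16, antpr_hi = 115.9,
    infpr_lo = 2.41, infpr_split = 42.85, infpr_hi = 108.88)
  # dimensional rescaling: K ~ 1/length, arcs/projections ~ length,
  # areas ~ length^2
  kf <- grepl("^k[12]_", names(th))
  af <- grepl("^area2_", names(th))
  lf <- !(kf | af)
  th[kf] <- lapply(th[kf], function(v) v / scale)
  th[af] <- lapply(th[af], function(v) v * scale^2)
  th[lf] <- lapply(th[lf], function(v) v * scale)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(th))
    if (length(bad))
      stop("unknown threshold override(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    th[names(ov)] <- ov
  }
  pairs <- matrix(c("k2_rp_lo", "k2_rp_hi", "infarc_rp_lo", "infarc_rp_hi",
                    "k2_fp_lo", "k2_fp_hi", "infarc_fp_lo", "infarc_fp_hi",
                    "k1_ftp_lo", "k1_ftp_hi", "area2_ftp_lo", "area2_ftp_hi",
                    "k1_pp_lo", "k1_pp_hi", "area2_pp_lo", "area2_pp_hi",
                    "antpr_lo", "antpr_hi", "infpr_lo", "infpr_hi"),
                  ncol = 2, byrow = TRUE)
  for (i in seq_len(nrow(pairs)))
    if (th[[pairs[i, 1]]] >= th[[pairs[i, 2]]])
      stop(sprintf("threshold interval %s..%s is empty",
                   pairs[i, 1], pairs[i, 2]), call. = FALSE)
  th$mode <- mode
  structure(th, class = "classification_thresholds")
}

in_closed <- function(v, lo, hi) v >= lo & v <= hi

# distance from v to the closed interval [lo, hi], for "nearest" mode
interval_dist <- function(v, lo, hi) pmax(lo - v, v - hi, 0)

# Shared two-interval decision: membership in both coordinates of one class
# wins; under "nearest" an undecided case goes to the class with the smaller
# normalized distance.
decide_two_class <- function(v1, v2, b1a, b1b, b2a, b2b, labels, mode) {
  in_a <- in_closed(v1, b1a[1], b1a[2]) & in_closed(v2, b1b[1], b1b[2])
  in_b <- in_closed(v1, b2a[1], b2a[2]) & in_closed(v2, b2b[1], b2b[2])
  out <- rep("indeterminate", length(v1))
  out[in_a & !in_b] <- labels[1]
  out[in_b & !in_a] <- labels[2]
  amb <- in_a & in_b
  und <- !in_a & !in_b
  if (any(amb)) {
    # both memberships hold: the first coordinate (curvature) decides, its
    # intervals being disjoint
    first_a <- in_closed(v1[amb], b1a[1], b1a[2])
    out[amb] <- ifelse(first_a, labels[1], labels[2])
  }
  if (mode == "nearest" && any(und)) {
    da <- interval_dist(v1[und], b1a[1], b1a[2]) / diff(b1a) +
      interval_dist(v2[und], b1b[1], b1b[2]) / diff(b1b)
    db <- interval_dist(v1[und], b2a[1], b2a[2]) / diff(b2a) +
      interval_dist(v2[und], b2b[1], b2b[2]) / diff(b2b)
    out[und] <- ifelse(da <= db, labels[1], labels[2])
  }
  out
}

#' Criterion I: raised vs fallen profile
#'
#' RP when both the curvature at P4 and the inferior arc length fall in the
#' raised-profile intervals; FP when both fall in the fallen-profile
#' intervals; indeterminate otherwise (interval gaps, mixed membership, or
#' out of range) under strict mode.
#'
#' @param k2 Curvature at P4 (non-negative); vectorized.
#' @param inf_arc Inferior arc length (non-negative); vectorized.
#' @param th A [classification_thresholds()] object.
#' @return Character vector in `{"RP", "FP", "indeterminate"}`.
#' @export
classify_criterion1 <- function(k2, inf_arc, th = classification_thresholds()) {
  if (any(k2 < 0) || any(inf_arc < 0))
    stop("'k2' and 'inf_arc' must be non-negative", call. = FALSE)
  decide_two_class(k2, inf_arc,
                   c(th$k2_rp_lo, th$k2_rp_hi),
                   c(th$infarc_rp_lo, th$infarc_rp_hi),
                   c(th$k2_fp_lo, th$k2_fp_hi),
                   c(th$infarc_fp_lo, th$infarc_fp_hi),
                   c("RP", "FP"), th$mode)
}

#' Criterion II: flat vs prominent profile
#'
#' FTP/PP from the curvature at P1 and the area below the waist plane.  The
#' published Area2 intervals overlap on `[91.35, 94.89]`; inside the overlap
#' the disjoint K1 intervals decide, and if K1 is in neither the result is
#' indeterminate.
#'
#' @param k1 Curvature at P1 (non-negative); vectorized.
#' @param area2 Area below the waist plane (non-negative); vectorized.
#' @param th A [classification_thresholds()] object.
#' @return Character vector in `{"FTP", "PP", "indeterminate"}`.
#' @export
classify_criterion2 <- function(k1, area2, th = classification_thresholds()) {
  if (any(k1 < 0) || any(area2 < 0))
    stop("'k1' and 'area2' must be non-negative", call. = FALSE)
  decide_two_class(k1, area2,
                   c(th$k1_ftp_lo, th$k1_ftp_hi),
                   c(th$area2_ftp_lo, th$area2_ftp_hi),
                   c(th$k1_pp_lo, th$k1_pp_hi),
                   c(th$area2_pp_lo, th$area2_pp_hi),
                   c("FTP", "PP"), th$mode)
}

#' Criterion III: projection bands
#'
#' Bands the anterior projection (`x4 - x2`) and the inferior projection
#' (`y4 - y2`) into below/above-average relative to the published split
#' points; a value outside the published overall range is `out_of_range`.
#' The exact split point belongs to the above-average band (half-open
#' convention).
#'
#' @param ant_pr,inf_pr Projections in profile units; vectorized.
#' @param th A [classification_thresholds()] object.
#' @return List with character vectors `antpr_band` and `infpr_band`, each
#'   in `{"below_average", "above_average", "out_of_range"}`.
#' @export
classify_criterion3 <- function(ant_pr, inf_pr,
                                th = classification_thresholds()) {
  band <- function(v, lo, split, hi) {
    out <- rep("out_of_range", length(v))
    out[v >= lo & v < split] <- "below_average"
    out[v >= split & v <= hi] <- "above_average"
    out
  }
  list(antpr_band = band(ant_pr, th$antpr_lo, th$antpr_split, th$antpr_hi),
       infpr_band = band(inf_pr, th$infpr_lo, th$infpr_split, th$infpr_hi))
}

#' Composite A/B steatosis categories
#'
#' Type A: steatosic when prominent profile (PP) co-occurs with an
#' above-average anterior projection; non-steatosic when flat profile (FTP)
#' co-occurs with a below-average anterior projection; otherwise
#' indeterminate.  Type B: the analogue built from criterion I and the
#' inferior projection (steatosic = FP + above-average InfPr,
#' non-steatosic = RP + below-average InfPr).
#'
#' @param criterion1 Labels from [classify_criterion1()]; vectorized.
#' @param criterion2 Labels from [classify_criterion2()]; vectorized.
#' @param antpr_band,infpr_band Bands from [classify_criterion3()].
#' @return List with character vectors `type_a` and `type_b`, each in
#'   `{"steatosic", "non_steatosic", "indeterminate"}`.
#' @export
steatosis_types <- function(criterion1, criterion2, antpr_band, infpr_band) {
  composite <- function(cls, pos, neg, band) {
    out <- rep("indeterminate", length(cls))
    out[cls == pos & band == "above_average"] <- "steatosic"
    out[cls == neg & band == "below_average"] <- "non_steatosic"
    out
  }
  list(type_a = composite(criterion2, "PP", "FTP", antpr_band),
       type_b = composite(criterion1, "FP", "RP", infpr_band))
}

#' Classify a metrics record
#'
#' Applies all three criteria and the composite steatosis categories to a
#' [compute_metrics()] result.
#'
#' @param metrics A `"profile_metrics"` object (or any list with fields
#'   `k1`, `k2`, `inf_arc`, `area2`, `ant_pr`, `inf_pr`).
#' @param th A [classification_thresholds()] object.
#' @return Object of class `"profile_classification"`: list with fields
#'   `criterion1`, `criterion2`, `antpr_band`, `infpr_band`, `type_a`,
#'   `type_b`.
#' @examples
#' lm <- profile_landmarks(
#'   p0 = c(0, 0), p3 = c(28, 95), p5 = c(30, 45),
#'   p6 = c(26, 150), p2 = c(0, 170))
#' classify_profile(compute_metrics(lm))
#' @export
classify_profile <- function(metrics, th = classification_thresholds()) {
  c1 <- classify_criterion1(metrics$k2, metrics$inf_arc, th)
  c2 <- classify_criterion2(metrics$k1, max(metrics$area2, 0), th)
  c3 <- classify_criterion3(metrics$ant_pr, metrics$inf_pr, th)
  st <- steatosis_types(c1, c2, c3$antpr_band, c3$infpr_band)
  structure(list(criterion1 = c1, criterion2 = c2,
                 antpr_band = c3$antpr_band, infpr_band = c3$infpr_band,
                 type_a = st$type_a, type_b = st$type_b),
            class = "profile_classification")
}

#' @export
print.profile_classification <- function(x, ...) {
  cat("Profile classification\n")
  for (nm in names(x)) cat(sprintf("  %-11s %s\n", nm, x[[nm]]))
  invisible(x)
}
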