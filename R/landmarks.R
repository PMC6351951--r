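# The nine named landmarks of the thoracic-abdominal profile and their
# canonical coordinate frame.
#
# Frame convention: x grows anteriorly (toward the belly), y grows downward
# from P0 (anterior axillary fold) to P2 (iliac-crest point on the vertical
# reference line).  All derived geometry assumes this frame; raw digitized
# coordinates are brought into it by a rigid motion (translate P0 to the
# origin, rotate P2 onto the positive y axis), which leaves curvatures, arc
# lengths, areas and the volume unchanged.

LANDMARK_LABELS <- paste0("P", 0:8)

#' Assemble a profile landmark set
#'
#' The profile is a two-segment quadratic Bezier chain: the superior segment
#' has controls (P0, P5, P3) and the inferior segment (P3, P6, P2).  P1 is
#' the most anterior point of the superior segment (the waist level), P4 the
#' lowest/most anterior extreme of the inferior segment, P8 the foot of the
#' horizontal through P1 on the vertical reference line, and P7 an auxiliary
#' digitized point kept for completeness but unused by any formula.
#'
#' @param p0,p1,p2,p3,p4,p5,p6,p8 Length-2 numeric points `c(x, y)`.
#'   `p1`, `p4` and `p8` may be `NULL`, in which case they are derived:
#'   P1/P4 as the x-extreme on-curve points of their segments and
#'   P8 as `(0, y1)`.
#' @param p7 Optional auxiliary point (may be `NULL`).
#' @param normalize Bring the set into the canonical frame first
#'   (default `TRUE`).
#' @return An object of class `"profile_landmarks"`: a list of named points
#'   in the canonical frame.
#' @examples
#' lm <- profile_landmarks(
#'   p0 = c(0, 0), p3 = c(28, 95), p5 = c(30, 45),
#'   p6 = c(26, 150), p2 = c(0, 170))
#' lm$p1   # derived waist-level extreme point
#' @export
profile_landmarks <- function(p0, p2, p3, p5, p6,
                              p1 = NULL, p4 = NULL, p7 = NULL, p8 = NULL,
                              normalize = TRUE) {
  pts <- list(p0 = p0, p1 = p1, p2 = p2, p3 = p3, p4 = p4,
              p5 = p5, p6 = p6, p7 = p7, p8 = p8)
  for (nm in c("p0", "p2", "p3", "p5", "p6"))
    if (is.null(pts[[nm]]) || length(pts[[nm]]) != 2L ||
        any(!is.finite(as.numeric(pts[[nm]]))))
      stop(sprintf("landmark '%s' must be a finite length-2 point",
                   toupper(nm)), call. = FALSE)
  pts <- lapply(pts, function(p) if (is.null(p)) NULL else as.numeric(p))
  if (normalize) pts <- normalize_points(pts)
  pts <- derive_extremes(pts)
  validate_landmarks(pts)
  structure(pts, class = "profile_landmarks")
}

# Rigid motion: translate p0 to origin, rotate p2 onto the +y axis.
normalize_points <- function(pts) {
  o <- pts$p0
  v <- pts$p2 - o
  len <- sqrt(sum(v^2))
  if (len == 0) stop("P0 and P2 coincide", call. = FALSE)
  u <- v / len
  rot <- rbind(c(u[2], -u[1]), c(u[1], u[2]))   # maps v to (0, |v|)
  lapply(pts, function(p) if (is.null(p)) NULL else as.numeric(rot %*% (p - o)))
}

# Fill in P1, P4 (x-extreme on-curve points) and P8 when absent.  The
# segments fall back differently when no interior anterior extremum exists:
# the waist point P1 goes to the upper segment's more anterior endpoint,
# while the belly point P4 degenerates to P2 itself (the "minimum at P2"
# case), giving a zero inferior projection.
derive_extremes <- function(pts) {
  if (is.null(pts$p1))
    pts$p1 <- segment_x_extreme(quad_bezier(pts$p0, pts$p5, pts$p3))
  if (is.null(pts$p4))
    pts$p4 <- segment_x_extreme(quad_bezier(pts$p3, pts$p6, pts$p2),
                                fallback = "end")
  if (is.null(pts$p8)) pts$p8 <- c(0, pts$p1[2])
  pts
}

# On-curve point of maximal x on a quadratic segment.  Without an interior
# x-extremum the fallback is either the more anterior endpoint ("wider") or
# the segment end ("end", the degenerate minimum-at-P2 convention).
segment_x_extreme <- function(curve, fallback = c("wider", "end")) {
  fallback <- match.arg(fallback)
  a2 <- curve$p0[1] - 2 * curve$p1[1] + curve$p2[1]  # second difference in x
  if (abs(a2) > .Machine$double.eps) {
    tstar <- (curve$p0[1] - curve$p1[1]) / a2
    if (tstar > 0 && tstar < 1) {
      cand <- bezier_point(curve, tstar)
      if (cand[1] >= max(curve$p0[1], curve$p2[1]) - 1e-12)
        return(as.numeric(cand))
    }
  }
  if (fallback == "end") curve$p2
  else if (curve$p0[1] >= curve$p2[1]) curve$p0 else curve$p2
}

validate_landmarks <- function(pts, tol = 1e-6) {
  scale <- max(abs(unlist(pts)), 1)
  if (any(abs(pts$p0) > tol * scale))
    stop("P0 must sit at the origin of the canonical frame", call. = FALSE)
  if (abs(pts$p2[1]) > tol * scale)
    stop("P2 must lie on the vertical reference axis (x = 0)", call. = FALSE)
  if (pts$p2[2] <= 0)
    stop("P2 must lie strictly below P0 (y2 > 0 in the y-down frame)",
         call. = FALSE)
  for (nm in c("p1", "p3", "p4", "p5", "p6"))
    if (pts[[nm]][1] < -tol * scale)
      stop(sprintf("landmark %s must have non-negative x (anterior side)",
                   toupper(nm)), call. = FALSE)
  if (abs(pts$p8[1]) > tol * scale || abs(pts$p8[2] - pts$p1[2]) > tol * scale)
    stop("P8 must be the axis foot of P1, (0, y1)", call. = FALSE)
  invisible(pts)
}

#' Superior profile segment
#'
#' The quadratic Bezier curve from the axillary fold P0 to the junction P3,
#' with control point P5.
#'
#' @param lm A [profile_landmarks()] object.
#' @return A [quad_bezier()] object.
#' @export
upper_segment <- function(lm) quad_bezier(lm$p0, lm$p5, lm$p3)

#' Inferior profile segment
#'
#' The quadratic Bezier curve from the junction P3 to the iliac-crest point
#' P2, with control point P6.
#'
#' @param lm A [profile_landmarks()] object.
#' @return A [quad_bezier()] object.
#' @export
lower_segment <- function(lm) quad_bezier(lm$p3, lm$p6, lm$p2)

#' @export
print.profile_landmarks <- function(x, ...) {
  cat("Thoracic-abdominal profile landmarks (canonical frame, y down)\n")
  for (nm in LANDMARK_LABELS) {
    p <- x[[tolower(nm)]]
    if (is.null(p)) cat(sprintf("  %-2s  <unset>\n", nm))
    else cat(sprintf("  %-2s  (%9.4f, %9.4f)\n", nm, p[1], p[2]))
  }
  invisible(x)
}
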