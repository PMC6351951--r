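# Reading and writing the package's plain-text interchange formats.
#
# Landmark CSV: long table, one row per digitized point:
#   patient_id,point_label,x,y        (labels P0..P8; P7 optional, and
#   P1/P4/P8 may be omitted -- they are then derived from the segments)
# Patient table: one flat row per patient carrying identifiers,
#   anthropometric/ultrasound fields, the landmark coordinates, metrics and
#   classification labels.  Comma-delimited, decimal point, UTF-8.
# SVG: a <path> with exactly two quadratic ("Q") segments sharing the
#   junction point, as exported from a vector-graphics profile overlay.
#   SVG's y axis already points down, matching the canonical frame.

#' Read digitized landmarks from a long-format CSV
#'
#' @param path File with header `patient_id,point_label,x,y`.
#' @return Named list of [profile_landmarks()] objects, one per patient id
#'   (in first-appearance order).
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "point_label", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!df$point_label %in% LANDMARK_LABELS |
                 !is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop(sprintf("malformed landmark row(s) at line(s) %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  ids <- unique(df$patient_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$patient_id == id, ]
    if (anyDuplicated(sub$point_label))
      stop(sprintf("patient '%s': duplicated landmark label(s): %s", id,
                   paste(unique(sub$point_label[duplicated(sub$point_label)]),
                         collapse = ", ")), call. = FALSE)
    required <- c("P0", "P2", "P3", "P5", "P6")
    missing <- setdiff(required, sub$point_label)
    if (length(missing))
      stop(sprintf("patient '%s': missing required landmark(s): %s", id,
                   paste(missing, collapse = ", ")), call. = FALSE)
    get <- function(lab) {
      i <- match(lab, sub$point_label)
      if (is.na(i)) NULL else c(sub$x[i], sub$y[i])
    }
    profile_landmarks(p0 = get("P0"), p1 = get("P1"), p2 = get("P2"),
                      p3 = get("P3"), p4 = get("P4"), p5 = get("P5"),
                      p6 = get("P6"), p7 = get("P7"), p8 = get("P8"))
  })
  names(out) <- ids
  out
}

#' Write landmarks to the long-format CSV
#'
#' @param lms Named list of [profile_landmarks()] objects (names become
#'   patient ids) or a single object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(lms, path) {
  if (inherits(lms, "profile_landmarks")) lms <- list(profile = lms)
  rows <- lapply(names(lms), function(id) {
    lm <- lms[[id]]
    labs <- LANDMARK_LABELS[!vapply(LANDMARK_LABELS, function(l)
      is.null(lm[[tolower(l)]]), logical(1))]
    data.frame(patient_id = id, point_label = labs,
               x = vapply(labs, function(l) lm[[tolower(l)]][1], numeric(1)),
               y = vapply(labs, function(l) lm[[tolower(l)]][2], numeric(1)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Tokenize an SVG path "d" string into command letters and numbers.
parse_path_d <- function(d) {
  toks <- regmatches(d, gregexpr("[A-Za-z]|-?(?:\\d+\\.?\\d*|\\.\\d+)(?:[eE][+-]?\\d+)?", d))[[1]]
  toks
}

#' Read a profile from a two-segment quadratic SVG path
#'
#' Expects an SVG document whose first `<path>` draws the profile as
#' `M x0,y0 Q x5,y5 x3,y3 Q x6,y6 x2,y2` (absolute coordinates).  The
#' extreme points P1/P4 are recomputed as the on-curve x-extrema of their
#' segments rather than trusted from the file, and P8 is derived.  Cubic
#' segments or a segment count other than two are rejected.
#'
#' @param path SVG file.
#' @return A [profile_landmarks()] object in the canonical frame.
#' @export
read_profile_svg <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name() = 'path']")
  if (length(nodes) == 0) stop("no <path> element found", call. = FALSE)
  d <- xml2::xml_attr(nodes[[1]], "d")
  toks <- parse_path_d(d)
  cmds <- toks[grepl("^[A-Za-z]$", toks)]
  if (any(toupper(cmds) %in% c("C", "S")))
    stop("unsupported path: cubic segments present (expected two quadratic 'Q' segments)",
         call. = FALSE)
  nq <- sum(toupper(cmds) == "Q")
  if (!identical(toupper(cmds[1]), "M") || nq != 2L)
    stop(sprintf(
      "unsupported path: expected 'M' followed by exactly 2 quadratic segments, found %d",
      nq), call. = FALSE)
  nums <- as.numeric(toks[!grepl("^[A-Za-z]$", toks)])
  if (length(nums) != 10L)
    stop("unsupported path: expected 10 coordinates (M + 2 Q segments)",
         call. = FALSE)
  if (any(cmds == "q")) {  # relative quadratics: accumulate
    p0 <- nums[1:2]
    c1 <- p0 + nums[3:4]; j <- p0 + nums[5:6]
    c2 <- j + nums[7:8]; pe <- j + nums[9:10]
  } else {
    p0 <- nums[1:2]; c1 <- nums[3:4]; j <- nums[5:6]
    c2 <- nums[7:8]; pe <- nums[9:10]
  }
  profile_landmarks(p0 = p0, p5 = c1, p3 = j, p6 = c2, p2 = pe)
}

#' Write a profile as a two-segment quadratic SVG path
#'
#' Emits a minimal SVG document that [read_profile_svg()] round-trips.
#'
#' @param lm A [profile_landmarks()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_svg <- function(lm, path) {
  fmtp <- function(p) sprintf("%.9g,%.9g", p[1], p[2])
  d <- sprintf("M %s Q %s %s Q %s %s", fmtp(lm$p0), fmtp(lm$p5), fmtp(lm$p3),
               fmtp(lm$p6), fmtp(lm$p2))
  w <- ceiling(max(abs(c(lm$p1[1], lm$p3[1], lm$p4[1], lm$p5[1], lm$p6[1]))) + 10)
  h <- ceiling(max(lm$p2[2], lm$p4[2]) + 10)
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="-10 -10 %d %d">', w + 10, h + 10),
           sprintf('  <path d="%s" fill="none" stroke="black"/>', d),
           '</svg>')
  writeLines(svg, path)
  invisible(path)
}

# Column order of the flat patient table.
patient_scalar_cols <- function() {
  c("patient_id", "sex", "age", "height", "weight", "bmi", "wc",
    "rhd", "lhd", "shd")
}
metric_cols <- function() {
  c("t1", "t4", "k1", "k2", "r1", "r2", "sup_arc", "inf_arc", "total_arc",
    "area1", "area2", "total_area", "vlow", "ant_pr", "inf_pr")
}
class_cols <- function() {
  c("criterion1", "criterion2", "antpr_band", "infpr_band",
    "type_a", "type_b")
}
landmark_cols <- function() {
  as.vector(t(outer(LANDMARK_LABELS, c("x", "y"),
                    function(l, a) paste0(tolower(l), "_", a))))
}

#' Assemble a patient record
#'
#' Bundles identifiers, anthropometric and ultrasound fields with the
#' landmark set and (optionally precomputed) metrics and classification.
#' Validates that `shd = rhd + lhd` and that BMI is consistent with
#' height/weight within 0.1 when all fields are present.
#'
#' @param patient_id Identifier string.
#' @param landmarks A [profile_landmarks()] object.
#' @param sex,age,height,weight,bmi,wc,rhd,lhd,shd Anthropometric and
#'   ultrasound fields: sex `"M"`/`"F"`, age in years, height cm, weight
#'   kg, BMI kg/m^2, waist circumference cm, lobe diameters mm.  All
#'   optional (`NA`).
#' @param metrics,classification Optional precomputed results; computed
#'   from the landmarks when omitted.
#' @param th Thresholds used when classifying.
#' @return Object of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, landmarks, sex = NA, age = NA,
                           height = NA, weight = NA, bmi = NA, wc = NA,
                           rhd = NA, lhd = NA, shd = NA,
                           metrics = NULL, classification = NULL,
                           th = classification_thresholds()) {
  if (!is.na(sex) && !sex %in% c("M", "F"))
    stop("'sex' must be \"M\" or \"F\"", call. = FALSE)
  if (!is.na(rhd) && !is.na(lhd) && !is.na(shd) &&
      abs(shd - (rhd + lhd)) > 1e-6)
    stop("'shd' must equal rhd + lhd", call. = FALSE)
  if (!is.na(bmi) && !is.na(height) && !is.na(weight) &&
      abs(bmi - weight / (height / 100)^2) > 0.1)
    stop("'bmi' inconsistent with height and weight", call. = FALSE)
  if (is.null(metrics)) metrics <- compute_metrics(landmarks)
  if (is.null(classification)) classification <- classify_profile(metrics, th)
  structure(list(patient_id = as.character(patient_id), sex = sex,
                 age = age, height = height, weight = weight, bmi = bmi,
                 wc = wc, rhd = rhd, lhd = lhd, shd = shd,
                 landmarks = landmarks, metrics = metrics,
                 classification = classification),
            class = "patient_record")
}

#' Flatten patient records to a data frame
#'
#' One row per patient: scalar fields, landmark coordinates (suffixed
#' `_x`/`_y`; unset P7 becomes `NA`), the fifteen metrics and the six
#' classification labels.
#'
#' @param records List of `"patient_record"` objects.
#' @return A `data.frame` with the documented column schema.
#' @export
patients_to_table <- function(records) {
  if (inherits(records, "patient_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    row <- as.list(r[patient_scalar_cols()])
    for (lab in LANDMARK_LABELS) {
      p <- r$landmarks[[tolower(lab)]]
      row[[paste0(tolower(lab), "_x")]] <- if (is.null(p)) NA_real_ else p[1]
      row[[paste0(tolower(lab), "_y")]] <- if (is.null(p)) NA_real_ else p[2]
    }
    row <- c(row, r$metrics[metric_cols()], r$classification[class_cols()])
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read the flat patient table
#'
#' Lossless round trip of all scalar fields, landmark coordinates, metrics
#' and classification labels through a comma-delimited file.  Unknown extra
#' columns on read are dropped with a warning; missing schema columns are a
#' parse error.
#'
#' @param records List of `"patient_record"` objects.
#' @param path File path.
#' @return `write_patient_table()` returns `path` invisibly;
#'   `read_patient_table()` returns a list of `"patient_record"` objects.
#' @export
write_patient_table <- function(records, path) {
  df <- if (length(records) == 0)
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol =
      length(c(patient_scalar_cols(), landmark_cols(), metric_cols(),
               class_cols())))),
      c(patient_scalar_cols(), landmark_cols(), metric_cols(), class_cols()))
  else patients_to_table(records)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_patient_table
#' @param th Thresholds attached to re-read records.
#' @export
read_patient_table <- function(path, th = classification_thresholds()) {
  # sex must stay character: a column of bare "F" would otherwise be
  # parsed as logical FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sex = "character",
                                       patient_id = "character"))
  schema <- c(patient_scalar_cols(), landmark_cols(), metric_cols(),
              class_cols())
  extra <- setdiff(names(df), schema)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop("patient table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    getp <- function(lab) {
      p <- c(row[[paste0(lab, "_x")]], row[[paste0(lab, "_y")]])
      if (any(is.na(p))) NULL else p
    }
    lm <- profile_landmarks(p0 = getp("p0"), p1 = getp("p1"), p2 = getp("p2"),
                            p3 = getp("p3"), p4 = getp("p4"), p5 = getp("p5"),
                            p6 = getp("p6"), p7 = getp("p7"), p8 = getp("p8"),
                            normalize = FALSE)
    metrics <- structure(as.list(row[metric_cols()]),
                         class = "profile_metrics")
    classification <- structure(as.list(row[class_cols()]),
                                class = "profile_classification")
    patient_record(row$patient_id, lm, sex = row$sex, age = row$age,
                   height = row$height, weight = row$weight, bmi = row$bmi,
                   wc = row$wc, rhd = row$rhd, lhd = row$lhd, shd = row$shd,
                   metrics = metrics, classification = classification,
                   th = th)
  })
}
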