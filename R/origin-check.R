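# The user-origin check: locate the three CT simulation marker contours,
# compute their intersection, and flag plans whose user origin deviates
# beyond tolerance.
#
# The intersection rule: the two lateral markers define the
# anterior/posterior (y) and superior/inferior (z) coordinates as the
# average over the pair; the lateral (x) coordinate is taken from the marker
# on the anterior or posterior surface alone (its y and z are ignored).
# When both an anterior and a posterior marker exist, their x coordinates
# are averaged.

#' Marker naming convention and tolerance
#'
#' Patterns are case-insensitive globs (`*` and `?` wildcards) matched
#' against ROI names. Exactly one ROI must match per role; zero matches make
#' the check not evaluable, several are an ambiguity error.
#'
#' @param left,right,ap non-empty character vectors of glob patterns for the
#'   left-lateral, right-lateral and anterior/posterior marker ROIs.
#' @param tolerance_mm flag threshold on the Euclidean distance between the
#'   marker intersection and the plan user origin. Default 2.0 mm: below
#'   the smallest clinically observed origin offset, above contouring noise.
#' @return an `rt_naming_config` list.
#' @export
naming_config <- function(left = c("*BB*LT*", "*BB*LEFT*", "*MARKER*LT*"),
                          right = c("*BB*RT*", "*BB*RIGHT*", "*MARKER*RT*"),
                          ap = c("*BB*ANT*", "*BB*POST*", "*MARKER*ANT*", "*MARKER*POST*"),
                          tolerance_mm = 2.0) {
  if (!length(left) || !length(right) || !length(ap)) {
    abort_value("pattern lists must be non-empty")
  }
  if (!is.numeric(tolerance_mm) || length(tolerance_mm) != 1 ||
      !is.finite(tolerance_mm) || tolerance_mm <= 0) {
    abort_value("tolerance_mm must be a single positive number")
  }
  structure(list(
    left = as.character(left), right = as.character(right), ap = as.character(ap),
    tolerance_mm = tolerance_mm
  ), class = "rt_naming_config")
}

glob_match <- function(patterns, x) {
  hit <- rep(FALSE, length(x))
  for (p in patterns) {
    hit <- hit | grepl(utils::glob2rx(p), x, ignore.case = TRUE)
  }
  hit
}

#' Centroid of a structure contour
#'
#' The markers are radiopaque BBs a few millimeters across; the check treats
#' each as the point at its contour centroid, the per-axis arithmetic mean
#' of all vertices.
#'
#' @param contour an `rt_contour` (from [read_structure_set()]) or an
#'   n x 3 matrix of vertices (mm).
#' @return an `rt_vec3` in the `DICOM_PATIENT` frame.
#' @export
contour_centroid <- function(contour) {
  pts <- if (inherits(contour, "rt_contour")) contour$points else contour
  if (is.null(dim(pts)) || nrow(pts) < 1 || ncol(pts) != 3) {
    abort_value("contour must have at least one x,y,z vertex")
  }
  vec3(colMeans(pts))
}

marker_set <- function(left, right, anterior = NULL, posterior = NULL) {
  check_frame(left, "DICOM_PATIENT", "left marker")
  check_frame(right, "DICOM_PATIENT", "right marker")
  if (is.null(anterior) && is.null(posterior)) {
    abort_value("a marker set needs an anterior or posterior marker")
  }
  if (vec3_norm(left - right) == 0) abort_value("left and right markers coincide")
  surface <- if (!is.null(anterior) && !is.null(posterior)) "BOTH"
             else if (!is.null(anterior)) "ANTERIOR" else "POSTERIOR"
  structure(list(left = left, right = right, anterior = anterior,
                 posterior = posterior, ap_surface = surface),
            class = "rt_marker_set")
}

#' Find the three simulation marker contours by name
#'
#' Matches ROI names against the naming convention and assigns the
#' left-lateral, right-lateral and anterior/posterior roles. An AP-matched
#' contour is classified as anterior or posterior geometrically (its y
#' versus the lateral markers' mean y); one marker on each surface yields
#' `ap_surface = "BOTH"` and both centroids are kept.
#'
#' @param structures list of `rt_contour` objects (see
#'   [read_structure_set()]).
#' @param cfg an [naming_config()].
#' @return an `rt_marker_set`: centroids `left`, `right`, `anterior` and/or
#'   `posterior`, plus `ap_surface`.
#' @export
find_marker_contours <- function(structures, cfg = naming_config()) {
  names_all <- vapply(structures, function(s) s$roi_name, character(1))
  pick_one <- function(patterns, role) {
    idx <- which(glob_match(patterns, names_all))
    if (length(idx) == 0) {
      abort_not_evaluable(sprintf("marker not found: %s", role))
    }
    if (length(idx) > 1) {
      abort_ambiguous(sprintf(
        "ambiguous %s marker: %s", role, paste(sQuote(names_all[idx]), collapse = ", ")
      ))
    }
    contour_centroid(structures[[idx]])
  }
  left <- pick_one(cfg$left, "left lateral")
  right <- pick_one(cfg$right, "right lateral")

  ap_idx <- which(glob_match(cfg$ap, names_all))
  if (length(ap_idx) == 0) abort_not_evaluable("marker not found: anterior/posterior")
  if (length(ap_idx) > 2) {
    abort_ambiguous(sprintf(
      "ambiguous anterior/posterior marker: %s",
      paste(sQuote(names_all[ap_idx]), collapse = ", ")
    ))
  }
  lat_y <- (left[["y"]] + right[["y"]]) / 2
  anterior <- NULL; posterior <- NULL
  for (i in ap_idx) {
    cen <- contour_centroid(structures[[i]])
    if (cen[["y"]] < lat_y) { # smaller y = toward patient anterior in LPS
      if (!is.null(anterior)) {
        abort_ambiguous("two anterior surface markers matched the AP patterns")
      }
      anterior <- cen
    } else {
      if (!is.null(posterior)) {
        abort_ambiguous("two posterior surface markers matched the AP patterns")
      }
      posterior <- cen
    }
  }
  marker_set(left, right, anterior = anterior, posterior = posterior)
}

#' Assign marker roles geometrically (naming-free fallback)
#'
#' For structure sets whose marker names do not follow any convention:
#' of three unlabeled centroids, the two with extreme x are the laterals
#' (larger x is the patient-left marker under LPS), the remaining one is the
#' AP marker, anterior or posterior by its y relative to the lateral mean.
#' The configuration is rejected as ambiguous when the lateral x-span is
#' under 20 mm or the AP marker's x falls outside the central half of the
#' lateral x-interval.
#'
#' @param centroids list of exactly three `rt_vec3` centroids (or length-3
#'   numerics, mm).
#' @return an `rt_marker_set`.
#' @export
classify_fallback <- function(centroids) {
  if (length(centroids) != 3) abort_value("exactly three marker centroids are required")
  cens <- lapply(centroids, as_vec3)
  xs <- vapply(cens, function(v) v[["x"]], numeric(1))
  ord <- order(xs)
  span <- xs[ord[3]] - xs[ord[1]]
  if (span < 20) {
    abort_ambiguous(sprintf(
      "marker roles ambiguous: lateral x-span %.1f mm is too small", span
    ))
  }
  midrange <- (xs[ord[1]] + xs[ord[3]]) / 2
  if (abs(xs[ord[2]] - midrange) > span / 4) {
    abort_ambiguous("marker roles ambiguous: middle marker is not laterally centered")
  }
  right <- cens[[ord[1]]]
  left <- cens[[ord[3]]]
  ap <- cens[[ord[2]]]
  lat_y <- (left[["y"]] + right[["y"]]) / 2
  if (ap[["y"]] < lat_y) marker_set(left, right, anterior = ap)
  else marker_set(left, right, posterior = ap)
}

#' Marker-intersection estimate of the user origin
#'
#' Applies the intersection rule: y and z are averaged over the two lateral
#' markers; x comes from the anterior/posterior marker (averaged over both
#' when both surfaces are contoured). The AP marker's y and z play no part.
#'
#' @param m an `rt_marker_set`.
#' @return an `rt_vec3` in the `DICOM_PATIENT` frame.
#' @export
expected_user_origin <- function(m) {
  stopifnot(inherits(m, "rt_marker_set"))
  x <- switch(m$ap_surface,
    ANTERIOR = m$anterior[["x"]],
    POSTERIOR = m$posterior[["x"]],
    BOTH = (m$anterior[["x"]] + m$posterior[["x"]]) / 2
  )
  vec3(x, (m$left[["y"]] + m$right[["y"]]) / 2, (m$left[["z"]] + m$right[["z"]]) / 2)
}

#' Compare expected and actual user origin
#'
#' @param expected marker-intersection origin ([expected_user_origin()]).
#' @param actual the plan's user origin.
#' @param tolerance_mm flag threshold (mm) on the Euclidean deviation.
#' @return an `rt_origin_check`: `expected_origin`, `actual_origin`,
#'   `per_axis_delta` (expected - actual), `magnitude`, `tolerance_mm`, and
#'   `verdict` (`"PASS"` or `"FLAG"`; FLAG iff magnitude > tolerance).
#' @export
check_user_origin <- function(expected, actual, tolerance_mm = 2.0) {
  check_frame(expected, "DICOM_PATIENT", "expected origin")
  check_frame(actual, "DICOM_PATIENT", "actual origin")
  if (!is.numeric(tolerance_mm) || length(tolerance_mm) != 1 ||
      !is.finite(tolerance_mm) || tolerance_mm <= 0) {
    abort_value("tolerance_mm must be a single positive number")
  }
  delta <- expected - actual
  magnitude <- vec3_norm(delta)
  structure(list(
    expected_origin = expected,
    actual_origin = actual,
    per_axis_delta = delta,
    magnitude = magnitude,
    tolerance_mm = tolerance_mm,
    verdict = if (magnitude > tolerance_mm) "FLAG" else "PASS"
  ), class = "rt_origin_check")
}

#' @export
print.rt_origin_check <- function(x, ...) {
  cat(sprintf("User origin check: %s\n", x$verdict))
  cat(sprintf("  expected (marker intersection): (%.3f, %.3f, %.3f) mm\n",
              x$expected_origin[1], x$expected_origin[2], x$expected_origin[3]))
  cat(sprintf("  actual (plan user origin):      (%.3f, %.3f, %.3f) mm\n",
              x$actual_origin[1], x$actual_origin[2], x$actual_origin[3]))
  cat(sprintf("  deviation: (%.3f, %.3f, %.3f) mm, |delta| = %.3f mm (tolerance %.2f mm)\n",
              x$per_axis_delta[1], x$per_axis_delta[2], x$per_axis_delta[3],
              x$magnitude, x$tolerance_mm))
  if (x$verdict == "FLAG") {
    cat("  ** User origin is NOT at the intersection of the simulation markers **\n")
  }
  invisible(x)
}

origin_check_to_list <- function(x) {
  list(
    verdict = x$verdict,
    expected_origin_mm = as.numeric(unclass(x$expected_origin)),
    actual_origin_mm = as.numeric(unclass(x$actual_origin)),
    per_axis_delta_mm = as.numeric(unclass(x$per_axis_delta)),
    magnitude_mm = x$magnitude,
    tolerance_mm = x$tolerance_mm
  )
}

#' Run the user-origin check on an RT Structure Set
#'
#' End-to-end wrapper: reads the structure set, finds the marker contours
#' (by name, with an optional geometric fallback), computes the
#' marker-intersection origin, and compares it with the plan user origin.
#'
#' @param rtstruct_file path to the RT Structure Set.
#' @param rtplan_file optional RT Plan; when given, its frame of reference
#'   must match the structure set's.
#' @param cfg an [naming_config()].
#' @param origin explicit plan user origin override (default: exported
#'   DICOM origin, see [resolve_user_origin()]).
#' @param geometric_fallback when `TRUE` and name matching fails, assign
#'   roles with [classify_fallback()] provided exactly three contours exist.
#' @return an `rt_origin_check`.
#' @export
run_origin_check <- function(rtstruct_file, rtplan_file = NULL,
                             cfg = naming_config(), origin = NULL,
                             geometric_fallback = FALSE) {
  ss <- read_structure_set(rtstruct_file)
  if (!is.null(rtplan_file)) {
    # the origin check needs only the plan's frame of reference, not its
    # position, so the plan dataset is read directly
    plan_for <- dcm_get(dcm_read(rtplan_file)$data, 0x0020, 0x0052)
    same <- !is.na(ss$frame_of_reference) && !is.null(plan_for) &&
      identical(ss$frame_of_reference, plan_for)
    if (!same) {
      abort_not_evaluable("RT Plan and RT Structure Set are not on the same frame of reference")
    }
  }
  markers <- tryCatch(
    find_marker_contours(ss$structures, cfg),
    rtshift_not_evaluable = function(e) {
      if (geometric_fallback && length(ss$structures) == 3) {
        classify_fallback(lapply(ss$structures, contour_centroid))
      } else {
        stop(e)
      }
    }
  )
  check_user_origin(expected_user_origin(markers), resolve_user_origin(origin),
                    tolerance_mm = cfg$tolerance_mm)
}
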