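# Read the minimal geometry needed from DICOM CT / RT Structure Set /
# RT Plan files. All coordinates stay in the DICOM patient frame, in
# millimeters; no unit conversion happens here.

#' Resolve the plan's user origin
#'
#' The user origin is the reference point a planner sets at the patient's
#' simulation marks. Treatment planning systems commonly export DICOM with
#' coordinates shifted so that the user origin sits at the DICOM patient
#' origin, which is therefore the default here; an explicit override covers
#' vendors with other conventions.
#'
#' @param origin optional explicit origin: an [vec3()] or length-3 numeric
#'   (mm, DICOM patient frame).
#' @return an `rt_vec3` in the `DICOM_PATIENT` frame.
#' @export
resolve_user_origin <- function(origin = NULL) {
  if (is.null(origin)) return(vec3(0, 0, 0))
  if (inherits(origin, "rt_vec3")) {
    check_frame(origin, "DICOM_PATIENT", "user origin")
    return(origin)
  }
  vec3(as.numeric(origin)) # vec3() rejects non-finite components
}

#' Read plan geometry from a DICOM RT Plan
#'
#' Extracts the plan identity, frame-of-reference UID, patient position, and
#' the unique beam isocenter. Plans whose beams carry isocenters more than
#' 0.01 mm apart are rejected: a single shift instruction is only
#' well-defined for one isocenter.
#'
#' @param file path to an RT Plan file.
#' @param position fallback patient position code, used only when the plan
#'   carries no PatientSetupSequence position. Never silently assumed.
#' @param user_origin optional explicit user origin (see
#'   [resolve_user_origin()]).
#' @return an `rt_plan_geometry` list: `plan_id`, `patient_id`,
#'   `frame_of_reference`, `position`, `user_origin`, `isocenter`.
#' @export
read_plan_geometry <- function(file, position = NULL, user_origin = NULL) {
  ds <- dcm_read(file)$data
  sop <- dcm_get(ds, 0x0008, 0x0016)
  if (!identical(sop, unname(SOP_CLASS["rtplan"]))) {
    abort_parse(sprintf("%s is not an RT Plan (SOP class %s)", file, sop %||% "<missing>"))
  }
  for_uid <- dcm_get(ds, 0x0020, 0x0052)
  if (is.null(for_uid) || !nzchar(for_uid)) {
    abort_parse(sprintf("%s: missing FrameOfReferenceUID", file))
  }
  plan_id <- dcm_get(ds, 0x300A, 0x0002) %||% dcm_get(ds, 0x0008, 0x0018)
  patient_id <- dcm_get(ds, 0x0010, 0x0020) %||% NA_character_

  pos_file <- NULL
  setup <- dcm_get(ds, 0x300A, 0x0180)
  if (!is.null(setup) && length(setup) >= 1) {
    pos_file <- dcm_get(setup[[1]], 0x0018, 0x5100)
  }
  position <- if (!is.null(pos_file) && nzchar(pos_file)) pos_file else position
  if (is.null(position)) {
    abort_parse(sprintf("%s: no patient position in plan and none supplied", file))
  }
  position <- check_position(position)

  beams <- dcm_get(ds, 0x300A, 0x00B0)
  if (is.null(beams) || length(beams) == 0) abort_parse(sprintf("%s: empty plan (no beams)", file))
  isos <- list()
  for (beam in beams) {
    cps <- dcm_get(beam, 0x300A, 0x0111)
    if (is.null(cps) || length(cps) == 0) next
    iso <- dcm_get(cps[[1]], 0x300A, 0x012C)
    if (!is.null(iso)) {
      if (length(iso) != 3) abort_parse("isocenter position is not an x,y,z triplet")
      isos[[length(isos) + 1L]] <- iso
    }
  }
  if (length(isos) == 0) abort_parse(sprintf("%s: no beam carries an isocenter", file))
  ref <- isos[[1]]
  spread <- max(vapply(isos, function(p) max(abs(p - ref)), numeric(1)))
  if (spread > 0.01) {
    abort_value(sprintf(
      "multi-isocenter plan unsupported: beam isocenters differ by up to %.3f mm", spread
    ))
  }

  structure(list(
    plan_id = plan_id,
    patient_id = patient_id,
    frame_of_reference = for_uid,
    position = position,
    user_origin = resolve_user_origin(user_origin),
    isocenter = vec3(ref)
  ), class = "rt_plan_geometry")
}

#' @export
print.rt_plan_geometry <- function(x, ...) {
  cat(sprintf("RT plan '%s' (patient %s, position %s)\n", x$plan_id, x$patient_id, x$position))
  cat(sprintf("  frame of reference: %s\n", x$frame_of_reference))
  cat(sprintf("  isocenter:   (%.3f, %.3f, %.3f) mm\n",
              x$isocenter[1], x$isocenter[2], x$isocenter[3]))
  cat(sprintf("  user origin: (%.3f, %.3f, %.3f) mm\n",
              x$user_origin[1], x$user_origin[2], x$user_origin[3]))
  invisible(x)
}

#' Read contours from a DICOM RT Structure Set
#'
#' Every ROI with contour data is returned with its name and the
#' concatenated vertex list (all contour planes) in patient coordinates
#' (mm). ROIs without contour data are skipped with a warning.
#'
#' @param file path to an RT Structure Set file.
#' @return a list with `structures` (list of `rt_contour`: `roi_name`,
#'   `points` as an n x 3 matrix) and `frame_of_reference` (UID or `NA`).
#' @export
read_structure_set <- function(file) {
  ds <- dcm_read(file)$data
  sop <- dcm_get(ds, 0x0008, 0x0016)
  if (!identical(sop, unname(SOP_CLASS["rtstruct"]))) {
    abort_parse(sprintf("%s is not an RT Structure Set (SOP class %s)", file, sop %||% "<missing>"))
  }
  for_uid <- NA_character_
  rfor <- dcm_get(ds, 0x3006, 0x0010)
  if (!is.null(rfor) && length(rfor) >= 1) {
    for_uid <- dcm_get(rfor[[1]], 0x0020, 0x0052) %||% NA_character_
  }
  if (is.na(for_uid)) for_uid <- dcm_get(ds, 0x0020, 0x0052) %||% NA_character_

  roi_names <- character(0)
  for (item in dcm_get(ds, 0x3006, 0x0020) %||% list()) {
    num <- dcm_get(item, 0x3006, 0x0022)
    nm <- dcm_get(item, 0x3006, 0x0026)
    if (!is.null(num) && !is.null(nm)) roi_names[as.character(num)] <- nm
  }

  structures <- list()
  seen <- character(0)
  for (item in dcm_get(ds, 0x3006, 0x0039) %||% list()) {
    num <- as.character(dcm_get(item, 0x3006, 0x0084))
    nm <- roi_names[num]
    if (is.na(nm)) nm <- sprintf("ROI %s", num)
    seen <- c(seen, num)
    pts <- list()
    for (cont in dcm_get(item, 0x3006, 0x0040) %||% list()) {
      cd <- dcm_get(cont, 0x3006, 0x0050)
      if (is.null(cd)) next
      if (length(cd) %% 3 != 0) {
        abort_parse(sprintf("ROI '%s': ContourData length %d is not a multiple of 3", nm, length(cd)))
      }
      pts[[length(pts) + 1L]] <- matrix(cd, ncol = 3, byrow = TRUE)
    }
    if (length(pts) == 0) {
      warning(sprintf("ROI '%s' has no contour data; skipped", nm), call. = FALSE)
      next
    }
    points <- do.call(rbind, pts)
    if (!all(is.finite(points))) abort_parse(sprintf("ROI '%s': non-finite contour vertex", nm))
    colnames(points) <- c("x", "y", "z")
    structures[[length(structures) + 1L]] <-
      structure(list(roi_name = nm, points = points), class = "rt_contour")
  }
  for (num in setdiff(names(roi_names), seen)) {
    warning(sprintf("ROI '%s' has no contour data; skipped", roi_names[num]), call. = FALSE)
  }
  list(structures = structures, frame_of_reference = for_uid)
}

#' Read position and frame metadata from a DICOM CT file
#'
#' @param file path to a CT image file.
#' @return list with `position`, `frame_of_reference`, `patient_id`.
#' @export
read_ct_metadata <- function(file) {
  ds <- dcm_read(file)$data
  list(
    position = dcm_get(ds, 0x0018, 0x5100),
    frame_of_reference = dcm_get(ds, 0x0020, 0x0052),
    patient_id = dcm_get(ds, 0x0010, 0x0020)
  )
}

#' Check that two plans share a frame of reference
#'
#' Plan-to-plan shifts are only defined for plans created on the same CT
#' scan, i.e. sharing a FrameOfReferenceUID. A missing UID on either side
#' fails the check: it cannot be verified.
#'
#' @param a,b `rt_plan_geometry` objects.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
validate_frame_of_reference <- function(a, b) {
  ua <- a$frame_of_reference
  ub <- b$frame_of_reference
  if (is.null(ua) || is.null(ub) || is.na(ua) || is.na(ub) || !nzchar(ua) || !nzchar(ub)) {
    return(FALSE)
  }
  identical(ua, ub)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
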