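# Coordinate conventions: DICOM patient (LPS) frame, IEC 61217 fixed frame,
# and the patient-position-dependent transform between them.
#
# Each of the eight standard DICOM patient position codes fixes how the
# patient's anatomical axes sit in the treatment room, and therefore a unique
# proper rotation (a signed permutation) taking DICOM patient coordinates to
# the IEC fixed frame. The table below maps (x, y, z)_DICOM -> (X, Y, Z)_IEC
# with IEC: X = observer's right facing the gantry, Y = toward the gantry,
# Z = up.

.POSITIONS <- c("HFS", "HFP", "FFS", "FFP", "HFDR", "HFDL", "FFDR", "FFDL")

# rows are IEC X, Y, Z; columns are DICOM x, y, z
.ORIENTATION <- list(
  HFS  = rbind(c( 1, 0, 0), c(0, 0,  1), c( 0, -1, 0)), # (x,  z, -y)
  HFP  = rbind(c(-1, 0, 0), c(0, 0,  1), c( 0,  1, 0)), # (-x, z,  y)
  FFS  = rbind(c(-1, 0, 0), c(0, 0, -1), c( 0, -1, 0)), # (-x,-z, -y)
  FFP  = rbind(c( 1, 0, 0), c(0, 0, -1), c( 0,  1, 0)), # (x, -z,  y)
  HFDR = rbind(c( 0, 1, 0), c(0, 0,  1), c( 1,  0, 0)), # (y,  z,  x)
  HFDL = rbind(c( 0,-1, 0), c(0, 0,  1), c(-1,  0, 0)), # (-y, z, -x)
  FFDR = rbind(c( 0,-1, 0), c(0, 0, -1), c( 1,  0, 0)), # (-y,-z,  x)
  FFDL = rbind(c( 0, 1, 0), c(0, 0, -1), c(-1,  0, 0))  # (y, -z, -x)
)

#' Standard DICOM patient position codes
#'
#' @return character vector of the eight codes: head/feet first,
#'   supine/prone/decubitus right/decubitus left.
#' @export
patient_positions <- function() .POSITIONS

check_position <- function(position) {
  if (!is.character(position) || length(position) != 1 ||
      !(toupper(position) %in% .POSITIONS)) {
    abort_value(sprintf(
      "unknown patient position %s; expected one of %s",
      deparse(position), paste(.POSITIONS, collapse = ", ")
    ))
  }
  toupper(position)
}

#' Rotation from the DICOM patient frame to the IEC 61217 fixed frame
#'
#' Returns the 3x3 signed-permutation matrix (proper rotation, det = +1)
#' that maps DICOM patient (LPS) coordinates to the IEC fixed room frame for
#' a given patient position code. Row names are the IEC axes, column names
#' the DICOM axes.
#'
#' @param position one of [patient_positions()].
#' @return a 3x3 numeric matrix.
#' @examples
#' orientation_matrix("HFS") # (x, y, z) -> (x, z, -y)
#' @export
orientation_matrix <- function(position) {
  position <- check_position(position)
  m <- .ORIENTATION[[position]]
  dimnames(m) <- list(c("X", "Y", "Z"), c("x", "y", "z"))
  m
}

#' Transform a vector between the DICOM patient and IEC fixed frames
#'
#' `dicom_to_iec()` applies the position's orientation matrix; the input must
#' carry the `DICOM_PATIENT` frame. `iec_to_dicom()` is its inverse (the
#' matrix transpose, since the rotation is orthogonal) and requires the
#' `IEC_FIXED` frame. Both preserve the Euclidean norm.
#'
#' @param v an [vec3()] in the expected frame (mm).
#' @param position one of [patient_positions()].
#' @return an `rt_vec3` in the other frame.
#' @examples
#' dicom_to_iec(vec3(10, -20, 30), "HFS") # (10, 30, 20) in IEC
#' @export
dicom_to_iec <- function(v, position) {
  check_frame(v, "DICOM_PATIENT", "input to dicom_to_iec")
  m <- orientation_matrix(position)
  vec3(as.numeric(m %*% unclass(v)), frame = "IEC_FIXED")
}

#' @rdname dicom_to_iec
#' @export
iec_to_dicom <- function(v, position) {
  check_frame(v, "IEC_FIXED", "input to iec_to_dicom")
  m <- orientation_matrix(position)
  vec3(as.numeric(t(m) %*% unclass(v)), frame = "DICOM_PATIENT")
}

#' Label a patient-frame displacement with anatomical direction words
#'
#' Converts a displacement in the DICOM patient (LPS) frame into per-axis
#' (direction word, magnitude) pairs: +x is toward the patient's Left, +y
#' Posterior, +z Superior. Components smaller in magnitude than `zero_mm`
#' are labeled "No shift" (default 0.5 mm, below couch-positioning
#' resolution).
#'
#' @param delta an [vec3()] in the `DICOM_PATIENT` frame (mm).
#' @param zero_mm threshold below which a component counts as no shift.
#' @return a data.frame with columns `axis` (`lateral`, `ant/post`,
#'   `sup/inf`), `direction`, and `magnitude_mm` (absolute value).
#' @examples
#' anatomical_labels(vec3(15, 0, -42))
#' @export
anatomical_labels <- function(delta, zero_mm = 0.5) {
  check_frame(delta, "DICOM_PATIENT", "delta")
  if (!is.numeric(zero_mm) || length(zero_mm) != 1 || !is.finite(zero_mm) || zero_mm < 0) {
    abort_value("zero_mm must be a single non-negative number")
  }
  words <- list(
    c(neg = "Right",    pos = "Left"),
    c(neg = "Anterior", pos = "Posterior"),
    c(neg = "Inferior", pos = "Superior")
  )
  dir <- character(3)
  for (i in 1:3) {
    dir[i] <- if (abs(delta[[i]]) < zero_mm) "No shift"
              else if (delta[[i]] > 0) words[[i]][["pos"]] else words[[i]][["neg"]]
  }
  data.frame(
    axis = c("lateral", "ant/post", "sup/inf"),
    direction = dir,
    magnitude_mm = abs(as.numeric(unclass(delta))),
    stringsAsFactors = FALSE
  )
}
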