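#' Create a 3-vector in a named coordinate frame
#'
#' All geometry in this package is carried as `rt_vec3` objects: three finite
#' components in millimeters plus the coordinate frame they live in. Frames
#' are explicit because the error pathway this package targets is exactly a
#' frame/sign confusion: operations that mix frames are rejected rather than
#' silently coerced.
#'
#' Frames:
#' \describe{
#'   \item{`DICOM_PATIENT`}{the DICOM patient coordinate system (LPS):
#'     +x toward patient left, +y toward patient posterior, +z toward
#'     patient superior.}
#'   \item{`IEC_FIXED`}{the IEC 61217 fixed room frame: +X toward the
#'     observer's right when facing the gantry, +Y toward the gantry,
#'     +Z up.}
#' }
#'
#' @param x numeric scalar, or a length-3 numeric when `y` and `z` are
#'   omitted.
#' @param y,z numeric scalars (mm).
#' @param frame `"DICOM_PATIENT"` or `"IEC_FIXED"`.
#' @return an `rt_vec3`: a named numeric of length 3 with a `frame`
#'   attribute.
#' @examples
#' vec3(10, -20, 30)
#' vec3(c(0, 0, 0), frame = "IEC_FIXED")
#' @export
vec3 <- function(x, y = NULL, z = NULL, frame = c("DICOM_PATIENT", "IEC_FIXED")) {
  frame <- match.arg(frame)
  if (is.null(y) && is.null(z)) {
    if (inherits(x, "rt_vec3")) return(structure(unclass(x), frame = frame, class = "rt_vec3"))
    if (length(x) != 3) abort_value("a 3-vector needs exactly three components")
    z <- x[[3]]; y <- x[[2]]; x <- x[[1]]
  }
  v <- c(x = as.numeric(x)[1], y = as.numeric(y)[1], z = as.numeric(z)[1])
  if (!all(is.finite(v))) abort_value("3-vector components must be finite numbers")
  structure(v, frame = frame, class = "rt_vec3")
}

#' Coordinate frame of a vector
#' @param v an `rt_vec3`.
#' @return the frame string.
#' @export
vec3_frame <- function(v) {
  stopifnot(inherits(v, "rt_vec3"))
  attr(v, "frame")
}

as_vec3 <- function(x, frame = "DICOM_PATIENT") {
  if (inherits(x, "rt_vec3")) x else vec3(as.numeric(x), frame = frame)
}

check_frame <- function(v, frame, what = "vector") {
  if (!inherits(v, "rt_vec3")) abort_frame(sprintf("%s is not an rt_vec3; frame unknown", what))
  if (!identical(vec3_frame(v), frame)) {
    abort_frame(sprintf("%s is in frame %s; expected %s", what, vec3_frame(v), frame))
  }
  invisible(v)
}

#' @export
print.rt_vec3 <- function(x, ...) {
  cat(sprintf("<%s> (%.6g, %.6g, %.6g) mm\n", vec3_frame(x), x[1], x[2], x[3]))
  invisible(x)
}

#' @export
Ops.rt_vec3 <- function(e1, e2) {
  if (missing(e2)) { # unary +/-
    return(structure(get(.Generic)(unclass(e1)), frame = vec3_frame(e1), class = "rt_vec3"))
  }
  if (!.Generic %in% c("+", "-", "==")) {
    abort_value(sprintf("operation '%s' is not defined for rt_vec3", .Generic))
  }
  f1 <- if (inherits(e1, "rt_vec3")) vec3_frame(e1) else NULL
  f2 <- if (inherits(e2, "rt_vec3")) vec3_frame(e2) else NULL
  if (!is.null(f1) && !is.null(f2) && !identical(f1, f2)) {
    abort_frame(sprintf("cannot combine vectors in different frames (%s vs %s)", f1, f2))
  }
  out <- get(.Generic)(unclass(e1), unclass(e2))
  if (.Generic == "==") return(all(out))
  structure(out, frame = if (is.null(f1)) f2 else f1, class = "rt_vec3")
}

#' Euclidean norm of a 3-vector (mm)
#' @param v an `rt_vec3`.
#' @return numeric scalar.
#' @export
vec3_norm <- function(v) sqrt(sum(unclass(v)^2))
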