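# The "Treat Sheet": couch-shift instructions from the user origin (the
# simulation marks) to the beam isocenter, plan-to-plan shifts, manual
# override auditing, and rendering (text / JSON / PDF).
#
# Shift values are hardcoded to centimeters on every rendered line; wrong
# units (cm vs mm) are one of the classic manual-transcription errors this
# document exists to eliminate.

#' Displacement from the user origin to the isocenter
#'
#' @param user_origin,isocenter `rt_vec3` values in the `DICOM_PATIENT`
#'   frame (mm) on the same frame of reference.
#' @return `isocenter - user_origin` as an `rt_vec3` (mm).
#' @export
compute_shift_vector <- function(user_origin, isocenter) {
  check_frame(user_origin, "DICOM_PATIENT", "user origin")
  check_frame(isocenter, "DICOM_PATIENT", "isocenter")
  isocenter - user_origin
}

#' Convert a patient-frame displacement into a shift instruction
#'
#' Produces the three labeled anatomical entries (direction word + value in
#' centimeters, round-half-even to 2 decimals) and the IEC fixed-frame
#' components of the same displacement. The unit is centimeters and is not
#' configurable.
#'
#' @param delta displacement in mm, `DICOM_PATIENT` frame.
#' @param position patient position code (for the DICOM-to-IEC transform).
#' @param zero_mm no-shift threshold passed to [anatomical_labels()].
#' @return an `rt_shift_instruction`: `entries` (data.frame `axis`,
#'   `direction`, `value_cm`), `dicom_mm`, `iec_mm`, `position`, `source`
#'   (`"COMPUTED"`).
#' @export
to_instruction <- function(delta, position, zero_mm = 0.5) {
  check_frame(delta, "DICOM_PATIENT", "delta")
  position <- check_position(position)
  labels <- anatomical_labels(delta, zero_mm = zero_mm)
  entries <- data.frame(
    axis = labels$axis,
    direction = labels$direction,
    value_cm = round(labels$magnitude_mm / 10, 2), # round() is half-even
    stringsAsFactors = FALSE
  )
  structure(list(
    entries = entries,
    dicom_mm = delta,
    iec_mm = dicom_to_iec(delta, position),
    position = position,
    source = "COMPUTED"
  ), class = "rt_shift_instruction")
}

#' Shift between two plans on the same CT scan
#'
#' The instruction that moves the patient from plan `a`'s isocenter to plan
#' `b`'s. Requires a shared frame of reference (same CT scan) and the same
#' patient position.
#'
#' @param a,b `rt_plan_geometry` objects.
#' @param zero_mm no-shift threshold (mm).
#' @return an `rt_shift_instruction` for `b$isocenter - a$isocenter`.
#' @export
plan_to_plan_shift <- function(a, b, zero_mm = 0.5) {
  if (!validate_frame_of_reference(a, b)) {
    abort_frame("plans are not on the same frame of reference; plan-to-plan shifts are undefined")
  }
  if (!identical(a$position, b$position)) {
    abort_value(sprintf("patient position differs between plans (%s vs %s)",
                        a$position, b$position))
  }
  to_instruction(b$isocenter - a$isocenter, a$position, zero_mm = zero_mm)
}

#' Default pre-treatment checklist
#'
#' The sheet carries a short therapist checklist next to the shifts; the
#' items are a configurable template and this is the minimal default.
#'
#' @return character vector of checklist items.
#' @export
default_checklist <- function() {
  c(
    "Verify patient identity (two identifiers)",
    "Verify patient position and immobilization match the plan",
    "Align to the simulation marks (user origin)",
    "Apply the shifts below, then verify with imaging per protocol"
  )
}

#' Build a Treat Sheet for a plan
#'
#' Computes the origin-to-isocenter shift instruction and packages it with
#' the plan identity and the pre-treatment checklist.
#'
#' @param plan an `rt_plan_geometry` (see [read_plan_geometry()]).
#' @param checklist character vector of checklist items.
#' @param zero_mm no-shift threshold (mm).
#' @return an `rt_treat_sheet`: `patient_id`, `plan_id`, `position`,
#'   `instruction`, `checklist`, `override_record` (NULL until
#'   [apply_override()] is used).
#' @export
treat_sheet <- function(plan, checklist = default_checklist(), zero_mm = 0.5) {
  stopifnot(inherits(plan, "rt_plan_geometry"))
  delta <- compute_shift_vector(plan$user_origin, plan$isocenter)
  structure(list(
    patient_id = plan$patient_id,
    plan_id = plan$plan_id,
    position = plan$position,
    instruction = to_instruction(delta, plan$position, zero_mm = zero_mm),
    checklist = as.character(checklist),
    override_record = NULL
  ), class = "rt_treat_sheet")
}

#' Treat Sheet for the shift between two plans
#'
#' @param a,b `rt_plan_geometry` objects on the same frame of reference.
#' @inheritParams treat_sheet
#' @return an `rt_treat_sheet` whose plan id names both plans.
#' @export
treat_sheet_between <- function(a, b, checklist = default_checklist(), zero_mm = 0.5) {
  instruction <- plan_to_plan_shift(a, b, zero_mm = zero_mm)
  structure(list(
    patient_id = a$patient_id,
    plan_id = sprintf("%s -> %s", a$plan_id, b$plan_id),
    position = a$position,
    instruction = instruction,
    checklist = as.character(checklist),
    override_record = NULL
  ), class = "rt_treat_sheet")
}

#' Manually override the computed shifts (audited)
#'
#' Overriding is part of the design (in-room setups, e.g. electron
#' treatments) but is also a known error pathway, so it is audited: the
#' original computed instruction is retained in the override record, the
#' operator and timestamp are mandatory, and every render of an overridden
#' sheet carries a prominent MANUAL OVERRIDE banner.
#'
#' @param sheet an `rt_treat_sheet` with a computed instruction.
#' @param values_cm signed length-3 numeric, centimeters, in anatomical LPS
#'   order: lateral (+ = patient left), ant/post (+ = posterior), sup/inf
#'   (+ = superior).
#' @param operator operator identifier (required, non-empty).
#' @param timestamp character timestamp; defaults to the current UTC time.
#' @param note optional free-text reason.
#' @return the overridden `rt_treat_sheet`.
#' @export
apply_override <- function(sheet, values_cm, operator,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                           note = NULL) {
  stopifnot(inherits(sheet, "rt_treat_sheet"))
  if (missing(operator) || is.null(operator) || !nzchar(trimws(as.character(operator)[1]))) {
    abort_value("an override requires a non-empty operator id")
  }
  if (!is.numeric(values_cm) || length(values_cm) != 3 || !all(is.finite(values_cm))) {
    abort_value("override values must be three finite numbers in cm")
  }
  if (!identical(sheet$instruction$source, "COMPUTED")) {
    abort_value("sheet has already been overridden; start from the computed sheet")
  }
  delta_mm <- vec3(as.numeric(values_cm) * 10)
  new_instruction <- to_instruction(delta_mm, sheet$position)
  new_instruction$source <- "OVERRIDDEN"
  sheet$override_record <- list(
    operator = as.character(operator)[1],
    timestamp = as.character(timestamp)[1],
    note = if (is.null(note)) NULL else as.character(note)[1],
    original = sheet$instruction
  )
  sheet$instruction <- new_instruction
  sheet
}

# one rendered line per axis; every line carries "cm" (and never "mm")
axis_display <- c(lateral = "Lateral (left/right)",
                  `ant/post` = "Vertical (ant/post)",
                  `sup/inf` = "Longitudinal (sup/inf)")

shift_lines <- function(instruction) {
  e <- instruction$entries
  vapply(seq_len(nrow(e)), function(i) {
    if (e$direction[i] == "No shift") {
      sprintf("%-24s No shift (0.00 cm)", paste0(axis_display[[e$axis[i]]], ":"))
    } else {
      sprintf("%-24s %s %.2f cm", paste0(axis_display[[e$axis[i]]], ":"),
              e$direction[i], e$value_cm[i])
    }
  }, character(1))
}

iec_line <- function(instruction) {
  v <- instruction$iec_mm
  sprintf("IEC 61217 fixed frame [X, Y, Z]: %+.2f, %+.2f, %+.2f cm",
          v[1] / 10, v[2] / 10, v[3] / 10)
}

render_text <- function(sheet) {
  lines <- c(
    "==============================================",
    "                 TREAT SHEET",
    "=============================================="
  )
  if (!is.null(sheet$override_record)) {
    o <- sheet$override_record
    orig <- o$original$entries
    lines <- c(lines,
      "**********************************************",
      "*            MANUAL OVERRIDE                 *",
      "**********************************************",
      sprintf("Overridden by %s at %s", o$operator, o$timestamp),
      if (!is.null(o$note)) sprintf("Reason: %s", o$note),
      sprintf("Original computed shifts: %s",
              paste(sprintf("%s %.2f cm", orig$direction, orig$value_cm), collapse = " / ")),
      ""
    )
  }
  lines <- c(lines,
    sprintf("Patient ID:       %s", sheet$patient_id),
    sprintf("Plan:             %s", sheet$plan_id),
    sprintf("Patient position: %s", sheet$position),
    "",
    "Shifts from setup marks (user origin) to isocenter:",
    shift_lines(sheet$instruction),
    iec_line(sheet$instruction),
    "",
    "Pre-treatment checklist:",
    sprintf("  [ ] %s", sheet$checklist),
    "=============================================="
  )
  paste(lines, collapse = "\n")
}

vec3_to_list <- function(v) {
  list(x = v[["x"]], y = v[["y"]], z = v[["z"]], frame = vec3_frame(v))
}

vec3_from_list <- function(l) vec3(l$x, l$y, l$z, frame = l$frame)

instruction_to_list <- function(ins) {
  list(
    entries = lapply(seq_len(nrow(ins$entries)), function(i) {
      list(axis = ins$entries$axis[i], direction = ins$entries$direction[i],
           value_cm = ins$entries$value_cm[i], unit = "cm")
    }),
    dicom_mm = vec3_to_list(ins$dicom_mm),
    iec_mm = vec3_to_list(ins$iec_mm),
    position = ins$position,
    source = ins$source
  )
}

instruction_from_list <- function(l) {
  structure(list(
    entries = data.frame(
      axis = vapply(l$entries, `[[`, character(1), "axis"),
      direction = vapply(l$entries, `[[`, character(1), "direction"),
      value_cm = vapply(l$entries, `[[`, numeric(1), "value_cm"),
      stringsAsFactors = FALSE
    ),
    dicom_mm = vec3_from_list(l$dicom_mm),
    iec_mm = vec3_from_list(l$iec_mm),
    position = l$position,
    source = l$source
  ), class = "rt_shift_instruction")
}

sheet_to_list <- function(sheet) {
  out <- list(
    document = "treat_sheet",
    patient_id = sheet$patient_id,
    plan_id = sheet$plan_id,
    position = sheet$position,
    instruction = instruction_to_list(sheet$instruction),
    checklist = as.list(sheet$checklist)
  )
  if (!is.null(sheet$override_record)) {
    o <- sheet$override_record
    out$override <- list(
      banner = "MANUAL OVERRIDE",
      operator = o$operator,
      timestamp = o$timestamp,
      note = o$note,
      original = instruction_to_list(o$original)
    )
  }
  out
}

#' Rebuild a Treat Sheet from its JSON render
#'
#' The JSON format is lossless: `treat_sheet_from_json(render_treat_sheet(s,
#' "json"))` reproduces `s` exactly.
#'
#' @param json JSON string produced by [render_treat_sheet()].
#' @return an `rt_treat_sheet`.
#' @export
treat_sheet_from_json <- function(json) {
  l <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(l$document, "treat_sheet")) abort_parse("not a treat_sheet JSON document")
  sheet <- structure(list(
    patient_id = l$patient_id,
    plan_id = l$plan_id,
    position = l$position,
    instruction = instruction_from_list(l$instruction),
    checklist = vapply(l$checklist, identity, character(1)),
    override_record = NULL
  ), class = "rt_treat_sheet")
  if (!is.null(l$override)) {
    sheet$override_record <- list(
      operator = l$override$operator,
      timestamp = l$override$timestamp,
      note = l$override$note,
      original = instruction_from_list(l$override$original)
    )
  }
  sheet
}

render_pdf <- function(sheet, file) {
  lines <- strsplit(render_text(sheet), "\n", fixed = TRUE)[[1]]
  # compress = FALSE keeps the text streams readable so downstream QA can
  # grep the document for units
  grDevices::pdf(file, width = 8.5, height = 11, compress = FALSE,
                 title = "Treat Sheet")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  n <- length(lines)
  ys <- 0.97 - (seq_len(n) - 1) * 0.9 / max(n - 1, 1)
  graphics::text(0.05, ys, lines, adj = c(0, 1), family = "mono", cex = 0.8)
  invisible(file)
}

#' Render a Treat Sheet
#'
#' Every rendered shift line carries its value in centimeters with an
#' explicit `cm` token; `mm` never appears in a shift line, whatever the
#' format. Overridden sheets always carry the MANUAL OVERRIDE banner.
#'
#' @param sheet an `rt_treat_sheet`.
#' @param format `"text"`, `"json"` or `"pdf"`.
#' @param file optional output path; required semantics: text/json write the
#'   string, pdf writes the document. When `NULL`, pdf renders to a
#'   temporary file and returns its bytes.
#' @return text/json: the document as a character scalar; pdf: raw bytes.
#' @export
render_treat_sheet <- function(sheet, format = c("text", "json", "pdf"), file = NULL) {
  stopifnot(inherits(sheet, "rt_treat_sheet"))
  if (!is.null(sheet$override_record) && !identical(sheet$instruction$source, "OVERRIDDEN")) {
    abort_value("inconsistent sheet: override record present but source is not OVERRIDDEN")
  }
  if (is.null(sheet$override_record) && identical(sheet$instruction$source, "OVERRIDDEN")) {
    abort_value("inconsistent sheet: OVERRIDDEN instruction without an override record")
  }
  if (identical(format, c("text", "json", "pdf"))) format <- "text"
  if (!is.character(format) || length(format) != 1 || !format %in% c("text", "json", "pdf")) {
    abort_value(sprintf("unknown render format %s", deparse(format)))
  }
  if (format == "text") {
    out <- render_text(sheet)
    if (!is.null(file)) writeLines(out, file)
    return(out)
  }
  if (format == "json") {
    out <- as.character(jsonlite::toJSON(sheet_to_list(sheet), auto_unbox = TRUE,
                                         digits = NA, null = "null", pretty = TRUE))
    if (!is.null(file)) writeLines(out, file)
    return(out)
  }
  path <- if (is.null(file)) tempfile(fileext = ".pdf") else file
  render_pdf(sheet, path)
  if (is.null(file)) {
    on.exit(unlink(path), add = TRUE)
    return(readBin(path, "raw", n = file.size(path)))
  }
  invisible(readBin(path, "raw", n = file.size(path)))
}

#' @export
print.rt_treat_sheet <- function(x, ...) {
  cat(render_text(x), "\n")
  invisible(x)
}

#' @export
print.rt_shift_instruction <- function(x, ...) {
  cat(sprintf("Shift instruction (%s, position %s)\n", x$source, x$position))
  cat(paste0("  ", shift_lines(x), collapse = "\n"), "\n")
  cat(" ", iec_line(x), "\n")
  invisible(x)
}
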