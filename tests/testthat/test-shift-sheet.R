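# shift_sheet: shift vectors, instructions, overrides, rendering

plan_geom <- function(iso, origin = c(0, 0, 0), frame = "1.2.3", position = "HFS",
                      plan_id = "P1", patient_id = "PT1") {
  structure(list(plan_id = plan_id, patient_id = patient_id,
                 frame_of_reference = frame, position = position,
                 user_origin = vec3(origin), isocenter = vec3(iso)),
            class = "rt_plan_geometry")
}

test_that("shift vector is isocenter minus user origin and antisymmetric", {
  expect_equal(as.numeric(compute_shift_vector(vec3(0, 0, 0), vec3(12.3, -4, 250))),
               c(12.3, -4, 250))
  expect_equal(as.numeric(compute_shift_vector(vec3(1, 2, 3), vec3(1, 2, 3))),
               c(0, 0, 0))
  a <- vec3(1, 2, 3); b <- vec3(4, 5, 6)
  expect_equal(unclass(compute_shift_vector(a, b)), unclass(-compute_shift_vector(b, a)))
  expect_error(compute_shift_vector(vec3(0, 0, 0, frame = "IEC_FIXED"), vec3(1, 1, 1)),
               class = "rtshift_frame_error")
})

test_that("instructions carry anatomical labels in cm plus IEC components", {
  ins <- to_instruction(vec3(15, 0, -42), "HFS")
  expect_equal(ins$entries$direction, c("Left", "No shift", "Inferior"))
  expect_equal(ins$entries$value_cm, c(1.50, 0, 4.20))
  expect_equal(as.numeric(ins$iec_mm), c(15, -42, 0))
  expect_identical(vec3_frame(ins$iec_mm), "IEC_FIXED")
  expect_identical(ins$source, "COMPUTED")

  expect_equal(to_instruction(vec3(0, 0, 0), "FFDR")$entries$direction,
               rep("No shift", 3))
  # values are always cm = mm / 10
  expect_equal(to_instruction(vec3(7, 0, 0), "FFP")$entries$value_cm[1], 0.70)
})

test_that("cm rounding is 2-decimal round-half-even", {
  # exactly representable halves: 1.25 mm -> 0.125 cm rounds down to 0.12,
  # 3.75 mm -> 0.375 cm rounds up to 0.38 (both to the even digit)
  ins <- to_instruction(vec3(1.25, 3.75, 0), "HFS", zero_mm = 0)
  expect_equal(ins$entries$value_cm[1:2], c(0.12, 0.38))
})

test_that("plan-to-plan shifts need one CT scan and one position", {
  a <- plan_geom(c(10, 0, 0))
  b <- plan_geom(c(25, -5, 12), plan_id = "P2")
  ins <- plan_to_plan_shift(a, b)
  expect_equal(as.numeric(ins$dicom_mm), c(15, -5, 12))

  same <- plan_to_plan_shift(a, a)
  expect_equal(same$entries$direction, rep("No shift", 3))

  # linearity: shift(A->B) = shift(origin->B) - shift(origin->A)
  oa <- compute_shift_vector(a$user_origin, a$isocenter)
  ob <- compute_shift_vector(b$user_origin, b$isocenter)
  expect_equal(unclass(ins$dicom_mm), unclass(ob - oa))

  expect_error(plan_to_plan_shift(a, plan_geom(c(1, 1, 1), frame = "9.9.9")),
               class = "rtshift_frame_error")
  expect_error(plan_to_plan_shift(a, plan_geom(c(1, 1, 1), position = "FFS")),
               class = "rtshift_value_error")
})

test_that("override replaces values, keeps the originals, and demands an operator", {
  sheet <- treat_sheet(plan_geom(c(15, 0, -42)))
  over <- apply_override(sheet, c(0, 0, 0), operator = "jdoe",
                         note = "in-room electron setup")
  expect_identical(over$instruction$source, "OVERRIDDEN")
  expect_equal(over$instruction$entries$value_cm, c(0, 0, 0))
  # information is never destroyed
  expect_equal(over$override_record$original$entries$value_cm, c(1.5, 0, 4.2))
  expect_identical(over$override_record$operator, "jdoe")

  expect_error(apply_override(sheet, c(0, 0, 0), operator = ""),
               class = "rtshift_value_error")
  expect_error(apply_override(sheet, c(0, 0, 0)), class = "rtshift_value_error")
  expect_error(apply_override(sheet, c(0, NA, 0), operator = "x"),
               class = "rtshift_value_error")
})

test_that("text render contains identity, labeled cm lines, and checklist", {
  sheet <- treat_sheet(plan_geom(c(15, 0, -42), plan_id = "PLAN A", patient_id = "PT-7"))
  txt <- render_treat_sheet(sheet, "text")
  expect_match(txt, "PT-7", fixed = TRUE)
  expect_match(txt, "PLAN A", fixed = TRUE)
  expect_match(txt, "Patient position: HFS", fixed = TRUE)
  expect_match(txt, "Left 1.50 cm", fixed = TRUE)
  expect_match(txt, "Inferior 4.20 cm", fixed = TRUE)
  expect_match(txt, "No shift (0.00 cm)", fixed = TRUE)
  for (item in default_checklist()) expect_match(txt, item, fixed = TRUE)
  expect_false(grepl("MANUAL OVERRIDE", txt, fixed = TRUE))
})

test_that("overridden sheets always render the MANUAL OVERRIDE banner", {
  sheet <- apply_override(treat_sheet(plan_geom(c(15, 0, -42))), c(0.5, 0, -1),
                          operator = "op1", timestamp = "2026-01-02T03:04:05Z")
  txt <- render_treat_sheet(sheet, "text")
  expect_match(txt, "MANUAL OVERRIDE", fixed = TRUE)
  expect_match(txt, "op1", fixed = TRUE)
  expect_match(txt, "Original computed shifts", fixed = TRUE)

  js <- render_treat_sheet(sheet, "json")
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(parsed$override$banner, "MANUAL OVERRIDE")

  pdf_bytes <- render_treat_sheet(sheet, "pdf")
  expect_match(pdf_ascii(pdf_bytes), "MANUAL OVERRIDE", fixed = TRUE)

  # a sheet claiming OVERRIDDEN without a record refuses to render
  broken <- sheet
  broken$override_record <- NULL
  expect_error(render_treat_sheet(broken, "text"), class = "rtshift_value_error")
})

test_that("json render is lossless", {
  sheet <- treat_sheet(plan_geom(c(12.3, -4.0, 250.0), position = "FFDL",
                                 plan_id = "PL", patient_id = "PT"))
  back <- treat_sheet_from_json(render_treat_sheet(sheet, "json"))
  expect_equal(back, sheet)

  over <- apply_override(sheet, c(1, -2, 0.5), operator = "x",
                         timestamp = "2026-02-03T00:00:00Z", note = "n")
  back2 <- treat_sheet_from_json(render_treat_sheet(over, "json"))
  expect_equal(back2, over)
})

test_that("unknown render formats are rejected", {
  sheet <- treat_sheet(plan_geom(c(1, 2, 3)))
  expect_error(render_treat_sheet(sheet, "docx"), class = "rtshift_value_error")
})

test_that("pdf render writes a parseable single-page document with the shift lines", {
  sheet <- treat_sheet(plan_geom(c(15, 0, -42)))
  f <- tempfile(fileext = ".pdf")
  on.exit(unlink(f))
  render_treat_sheet(sheet, "pdf", file = f)
  bytes <- readBin(f, "raw", n = file.size(f))
  expect_identical(rawToChar(bytes[1:5]), "%PDF-")
  txt <- pdf_ascii(bytes)
  expect_match(txt, "Inferior 4.20 cm", fixed = TRUE)
  expect_match(txt, "/Count 1", fixed = TRUE) # single page
})
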