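# Synthetic DICOM bundles with known ground truth.
#
# Emulates the simulation workflow: three radiopaque markers (two lateral,
# one anterior or posterior) contoured on the CT, a user origin placed at --
# or deliberately displaced from -- their intersection, and one or more
# plans with isocenters on a shared frame of reference. Exported coordinates
# follow the TPS convention of shifting the patient frame so the user origin
# sits at (0,0,0).

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

uid_counter <- local({
  n <- 0L
  function() { n <<- n + 1L; n }
})

new_uid <- function() {
  # deterministic under with_seed(); the counter guards uniqueness within a
  # session even for identical seeds
  sprintf("1.2.826.0.1.3680043.9.7584.%d.%d.%d",
          sample.int(.Machine$integer.max, 1), sample.int(99999L, 1), uid_counter())
}

#' Describe a synthetic simulation/planning bundle
#'
#' The spec is the stated world: marker centroids in absolute CT
#' coordinates, the surface of the third marker, a deliberate origin offset
#' (the error the origin check exists to catch), and isocenter offsets from
#' the user origin. With `origin_offset = c(0,0,0)` the user origin
#' coincides exactly with the marker intersection.
#'
#' Defaults emulate a thorax-like setup: lateral markers ~115 mm either side
#' of midline, an anterior surface marker, and a single plan whose isocenter
#' sits 15 mm left, 42 mm inferior of the marks.
#'
#' @param position patient position code.
#' @param left,right lateral marker centroids, absolute mm (LPS; the left
#'   marker has the larger x).
#' @param anterior,posterior surface marker centroid(s), absolute mm; give
#'   one or both.
#' @param origin_offset displacement of the user origin from the marker
#'   intersection (mm); nonzero values inject the origin-setting error.
#' @param isocenter_offsets list of isocenter displacements from the user
#'   origin (mm); one plan is generated per entry.
#' @param roi_names named character: ROI names for `left`, `right`,
#'   `anterior`, `posterior`.
#' @param tolerance_mm origin-check tolerance recorded in the ground truth.
#' @param jitter_mm per-coordinate contour-vertex jitter bound (uniform,
#'   seeded, mean-centered per ring so centroids are exact).
#' @param seed integer; fully determines all jitter and UIDs.
#' @param patient_id synthetic patient identifier.
#' @param allow_degenerate keep deliberately degenerate marker layouts
#'   (e.g. collinear in x) instead of rejecting them.
#' @return an `rt_fixture_spec`.
#' @export
fixture_spec <- function(position = "HFS",
                         left = c(115, 18, 0),
                         right = c(-118, 22, 0),
                         anterior = c(1.5, -92, 0),
                         posterior = NULL,
                         origin_offset = c(0, 0, 0),
                         isocenter_offsets = list(c(15, 0, -42)),
                         roi_names = NULL,
                         tolerance_mm = 2.0,
                         jitter_mm = 0.05,
                         seed = 1L,
                         patient_id = "SYN-000001",
                         allow_degenerate = FALSE) {
  position <- check_position(position)
  left <- as_vec3(left); right <- as_vec3(right)
  anterior <- if (is.null(anterior)) NULL else as_vec3(anterior)
  posterior <- if (is.null(posterior)) NULL else as_vec3(posterior)
  markers <- marker_set(left, right, anterior = anterior, posterior = posterior)
  if (!allow_degenerate) {
    span <- abs(left[["x"]] - right[["x"]])
    if (span < 20) abort_value("degenerate marker layout: lateral x-span under 20 mm")
  }
  if (!is.list(isocenter_offsets)) isocenter_offsets <- list(isocenter_offsets)
  if (length(isocenter_offsets) < 1) abort_value("at least one isocenter is required")
  if (is.null(roi_names)) {
    roi_names <- c(left = "BB LT", right = "BB RT",
                   anterior = "BB ANT", posterior = "BB POST")
  }
  origin_offset <- as_vec3(origin_offset)
  intersection <- expected_user_origin(markers)
  spec <- structure(list(
    position = position,
    markers = markers,
    origin_offset = origin_offset,
    user_origin = intersection + origin_offset,
    intersection = intersection,
    isocenter_offsets = lapply(isocenter_offsets, as_vec3),
    roi_names = roi_names,
    tolerance_mm = tolerance_mm,
    jitter_mm = jitter_mm,
    seed = as.integer(seed),
    patient_id = patient_id
  ), class = "rt_fixture_spec")
  spec$expected_verdict <- if (vec3_norm(origin_offset) > tolerance_mm) "FLAG" else "PASS"
  spec
}

#' Displace the user origin of a fixture spec
#'
#' Models the clinical error class of an incorrectly set user origin: the
#' user origin is placed `offset` mm away from the marker intersection and
#' the ground-truth verdict is updated (FLAG iff its norm exceeds the
#' tolerance).
#'
#' @param spec an [fixture_spec()].
#' @param offset length-3 numeric or `rt_vec3` (mm).
#' @return the modified `rt_fixture_spec`.
#' @export
perturb_origin <- function(spec, offset) {
  stopifnot(inherits(spec, "rt_fixture_spec"))
  offset <- as_vec3(offset)
  spec$origin_offset <- offset
  spec$user_origin <- spec$intersection + offset
  spec$expected_verdict <- if (vec3_norm(offset) > spec$tolerance_mm) "FLAG" else "PASS"
  spec
}

# 8-vertex axial ring around a centroid; jitter is mean-centered per axis so
# the ring centroid equals the requested centroid exactly
marker_ring <- function(centroid, radius = 2, jitter_mm = 0) {
  ang <- seq(0, 2 * pi, length.out = 9)[1:8]
  centroid <- as.numeric(centroid)
  pts <- cbind(
    x = centroid[1] + radius * cos(ang),
    y = centroid[2] + radius * sin(ang),
    z = rep(centroid[3], 8)
  )
  if (jitter_mm > 0) {
    j <- matrix(stats::runif(24, -jitter_mm, jitter_mm), ncol = 3)
    j <- sweep(j, 2, colMeans(j))
    pts <- pts + j
  }
  pts
}

build_ct <- function(spec, frame_uid, study_uid, export) {
  ds <- list()
  ds[[tagkey(0x0008, 0x0016)]] <- dcm_el("UI", unname(SOP_CLASS["ct"]))
  ds[[tagkey(0x0008, 0x0018)]] <- dcm_el("UI", new_uid())
  ds[[tagkey(0x0008, 0x0060)]] <- dcm_el("CS", "CT")
  ds[[tagkey(0x0010, 0x0010)]] <- dcm_el("PN", "Synthetic^Fixture")
  ds[[tagkey(0x0010, 0x0020)]] <- dcm_el("LO", spec$patient_id)
  ds[[tagkey(0x0018, 0x5100)]] <- dcm_el("CS", spec$position)
  ds[[tagkey(0x0020, 0x000D)]] <- dcm_el("UI", study_uid)
  ds[[tagkey(0x0020, 0x000E)]] <- dcm_el("UI", new_uid())
  ds[[tagkey(0x0020, 0x0052)]] <- dcm_el("UI", frame_uid)
  slice_origin <- export(spec$intersection) # slice through the marks
  ds[[tagkey(0x0020, 0x0032)]] <- dcm_el("DS", c(slice_origin[1] - 8, slice_origin[2] - 8, slice_origin[3]))
  ds[[tagkey(0x0020, 0x0037)]] <- dcm_el("DS", c(1, 0, 0, 0, 1, 0))
  ds[[tagkey(0x0028, 0x0002)]] <- dcm_el("US", 1L)
  ds[[tagkey(0x0028, 0x0004)]] <- dcm_el("CS", "MONOCHROME2")
  ds[[tagkey(0x0028, 0x0010)]] <- dcm_el("US", 16L)
  ds[[tagkey(0x0028, 0x0011)]] <- dcm_el("US", 16L)
  ds[[tagkey(0x0028, 0x0030)]] <- dcm_el("DS", c(1, 1))
  ds[[tagkey(0x0028, 0x0100)]] <- dcm_el("US", 16L)
  ds[[tagkey(0x0028, 0x0101)]] <- dcm_el("US", 16L)
  ds[[tagkey(0x0028, 0x0102)]] <- dcm_el("US", 15L)
  ds[[tagkey(0x0028, 0x0103)]] <- dcm_el("US", 0L)
  ds[[tagkey(0x7FE0, 0x0010)]] <- dcm_el("OW", raw(16 * 16 * 2))
  ds
}

build_rtstruct <- function(spec, frame_uid, study_uid, export) {
  rois <- list(list(name = spec$roi_names[["left"]], centroid = spec$markers$left),
               list(name = spec$roi_names[["right"]], centroid = spec$markers$right))
  if (!is.null(spec$markers$anterior)) {
    rois <- c(rois, list(list(name = spec$roi_names[["anterior"]],
                              centroid = spec$markers$anterior)))
  }
  if (!is.null(spec$markers$posterior)) {
    rois <- c(rois, list(list(name = spec$roi_names[["posterior"]],
                              centroid = spec$markers$posterior)))
  }
  ssroi <- list(); rcont <- list()
  for (i in seq_along(rois)) {
    item <- list()
    item[[tagkey(0x3006, 0x0022)]] <- dcm_el("IS", i)
    item[[tagkey(0x3006, 0x0024)]] <- dcm_el("UI", frame_uid)
    item[[tagkey(0x3006, 0x0026)]] <- dcm_el("LO", rois[[i]]$name)
    ssroi[[i]] <- item

    ring <- marker_ring(export(rois[[i]]$centroid), radius = 2,
                        jitter_mm = spec$jitter_mm)
    cont <- list()
    cont[[tagkey(0x3006, 0x0042)]] <- dcm_el("CS", "CLOSED_PLANAR")
    cont[[tagkey(0x3006, 0x0046)]] <- dcm_el("IS", nrow(ring))
    cont[[tagkey(0x3006, 0x0050)]] <- dcm_el("DS", as.numeric(t(ring)))
    citem <- list()
    citem[[tagkey(0x3006, 0x0084)]] <- dcm_el("IS", i)
    citem[[tagkey(0x3006, 0x0040)]] <- dcm_el("SQ", list(cont))
    rcont[[i]] <- citem
  }
  rfor_item <- list()
  rfor_item[[tagkey(0x0020, 0x0052)]] <- dcm_el("UI", frame_uid)

  ds <- list()
  ds[[tagkey(0x0008, 0x0016)]] <- dcm_el("UI", unname(SOP_CLASS["rtstruct"]))
  ds[[tagkey(0x0008, 0x0018)]] <- dcm_el("UI", new_uid())
  ds[[tagkey(0x0008, 0x0060)]] <- dcm_el("CS", "RTSTRUCT")
  ds[[tagkey(0x0010, 0x0010)]] <- dcm_el("PN", "Synthetic^Fixture")
  ds[[tagkey(0x0010, 0x0020)]] <- dcm_el("LO", spec$patient_id)
  ds[[tagkey(0x0020, 0x000D)]] <- dcm_el("UI", study_uid)
  ds[[tagkey(0x0020, 0x000E)]] <- dcm_el("UI", new_uid())
  ds[[tagkey(0x3006, 0x0002)]] <- dcm_el("SH", "SIM MARKERS")
  ds[[tagkey(0x3006, 0x0010)]] <- dcm_el("SQ", list(rfor_item))
  ds[[tagkey(0x3006, 0x0020)]] <- dcm_el("SQ", ssroi)
  ds[[tagkey(0x3006, 0x0039)]] <- dcm_el("SQ", rcont)
  ds
}

build_rtplan <- function(spec, frame_uid, study_uid, export, iso_abs, plan_label) {
  iso_exported <- export(iso_abs)
  beams <- lapply(1:2, function(bn) { # two beams, coincident isocenters
    cp <- list()
    cp[[tagkey(0x300A, 0x0112)]] <- dcm_el("IS", 0L)
    cp[[tagkey(0x300A, 0x012C)]] <- dcm_el("DS", iso_exported)
    beam <- list()
    beam[[tagkey(0x300A, 0x00C0)]] <- dcm_el("IS", bn)
    beam[[tagkey(0x300A, 0x00C2)]] <- dcm_el("LO", sprintf("Field %d", bn))
    beam[[tagkey(0x300A, 0x0111)]] <- dcm_el("SQ", list(cp))
    beam
  })
  setup <- list()
  setup[[tagkey(0x0018, 0x5100)]] <- dcm_el("CS", spec$position)
  setup[[tagkey(0x300A, 0x0182)]] <- dcm_el("IS", 1L)

  ds <- list()
  ds[[tagkey(0x0008, 0x0016)]] <- dcm_el("UI", unname(SOP_CLASS["rtplan"]))
  ds[[tagkey(0x0008, 0x0018)]] <- dcm_el("UI", new_uid())
  ds[[tagkey(0x0008, 0x0060)]] <- dcm_el("CS", "RTPLAN")
  ds[[tagkey(0x0010, 0x0010)]] <- dcm_el("PN", "Synthetic^Fixture")
  ds[[tagkey(0x0010, 0x0020)]] <- dcm_el("LO", spec$patient_id)
  ds[[tagkey(0x0020, 0x000D)]] <- dcm_el("UI", study_uid)
  ds[[tagkey(0x0020, 0x000E)]] <- dcm_el("UI", new_uid())
  ds[[tagkey(0x0020, 0x0052)]] <- dcm_el("UI", frame_uid)
  ds[[tagkey(0x300A, 0x0002)]] <- dcm_el("SH", plan_label)
  ds[[tagkey(0x300A, 0x0180)]] <- dcm_el("SQ", list(setup))
  ds[[tagkey(0x300A, 0x00B0)]] <- dcm_el("SQ", beams)
  ds
}

#' Generate a synthetic DICOM bundle with ground truth
#'
#' Writes one CT slice (metadata-correct, 16x16 pixels), one RT Structure
#' Set with the three marker rings, and one RT Plan per isocenter, all on a
#' shared frame of reference, plus a `ground_truth.json` record of the exact
#' expected shifts and the expected origin-check verdict. Identical spec and
#' seed reproduce identical geometry.
#'
#' @param spec an [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with `ct`, `rtstruct`, `rtplan` (character vector of plan
#'   paths), `ground_truth_file`, and `ground_truth` (the record itself).
#' @export
generate_bundle <- function(spec, dir = tempfile("bundle-")) {
  stopifnot(inherits(spec, "rt_fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # exported DICOM coordinates put the user origin at (0,0,0)
  export <- function(v) as.numeric(unclass(v - spec$user_origin))

  with_seed(spec$seed, {
    frame_uid <- new_uid()
    study_uid <- new_uid()
    ct_file <- file.path(dir, "ct.dcm")
    rs_file <- file.path(dir, "rs.dcm")
    dcm_write(build_ct(spec, frame_uid, study_uid, export), ct_file)
    dcm_write(build_rtstruct(spec, frame_uid, study_uid, export), rs_file)
    rp_files <- character(0)
    plans <- list()
    for (i in seq_along(spec$isocenter_offsets)) {
      iso_abs <- spec$user_origin + spec$isocenter_offsets[[i]]
      label <- sprintf("PLAN%d", i)
      f <- file.path(dir, sprintf("rp%d.dcm", i))
      dcm_write(build_rtplan(spec, frame_uid, study_uid, export, iso_abs, label), f)
      rp_files <- c(rp_files, f)
      plans[[i]] <- list(
        plan_id = label,
        file = basename(f),
        expected_shift_mm = as.numeric(unclass(spec$isocenter_offsets[[i]]))
      )
    }
  })

  gt <- list(
    position = spec$position,
    seed = spec$seed,
    patient_id = spec$patient_id,
    tolerance_mm = spec$tolerance_mm,
    origin_offset_mm = as.numeric(unclass(spec$origin_offset)),
    origin_deviation_mm = vec3_norm(spec$origin_offset),
    expected_verdict = spec$expected_verdict,
    # in exported coordinates the marker intersection sits at minus the
    # injected offset, the user origin at (0,0,0)
    expected_origin_exported_mm = as.numeric(unclass(spec$intersection - spec$user_origin)),
    ap_surface = spec$markers$ap_surface,
    plans = plans
  )
  gt_file <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(ct = ct_file, rtstruct = rs_file, rtplan = rp_files,
       ground_truth_file = gt_file, ground_truth = gt)
}
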