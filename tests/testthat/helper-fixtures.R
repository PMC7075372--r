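# Shared helpers: in-memory contours and hand-assembled DICOM datasets.

make_contour <- function(name, points) {
  pts <- matrix(as.numeric(points), ncol = 3, byrow = TRUE,
                dimnames = list(NULL, c("x", "y", "z")))
  structure(list(roi_name = name, points = pts), class = "rt_contour")
}

point_contour <- function(name, center) {
  make_contour(name, center)
}

# standard three-marker layout used across tests (absolute coordinates, mm)
std_structures <- function(names = c("BB LT", "BB RT", "BB ANT"),
                           centers = list(c(115, 18, 0), c(-118, 22, 0), c(1.5, -92, 0))) {
  Map(point_contour, names, centers)
}

# build an RT Structure Set dataset directly (independent of the fixture
# generator) and write it with the package writer; rois is a list of
# list(name =, contours = list of n x 3 matrices) -- contours = NULL gives
# an ROI without contour data
write_custom_rtstruct <- function(rois, file, frame = "1.2.840.99.1") {
  tk <- rtshift:::tagkey
  el <- rtshift:::dcm_el
  ssroi <- list(); rcont <- list()
  for (i in seq_along(rois)) {
    item <- list()
    item[[tk(0x3006, 0x0022)]] <- el("IS", i)
    item[[tk(0x3006, 0x0024)]] <- el("UI", frame)
    item[[tk(0x3006, 0x0026)]] <- el("LO", rois[[i]]$name)
    ssroi[[i]] <- item
    if (is.null(rois[[i]]$contours)) next
    conts <- lapply(rois[[i]]$contours, function(m) {
      cont <- list()
      cont[[tk(0x3006, 0x0042)]] <- el("CS", "CLOSED_PLANAR")
      cont[[tk(0x3006, 0x0046)]] <- el("IS", nrow(m))
      cont[[tk(0x3006, 0x0050)]] <- el("DS", as.numeric(t(m)))
      cont
    })
    citem <- list()
    citem[[tk(0x3006, 0x0084)]] <- el("IS", i)
    citem[[tk(0x3006, 0x0040)]] <- el("SQ", conts)
    rcont[[length(rcont) + 1L]] <- citem
  }
  rfor <- list()
  rfor[[tk(0x0020, 0x0052)]] <- el("UI", frame)
  ds <- list()
  ds[[tk(0x0008, 0x0016)]] <- el("UI", "1.2.840.10008.5.1.4.1.1.481.3")
  ds[[tk(0x0008, 0x0018)]] <- el("UI", "1.2.840.99.2")
  ds[[tk(0x0008, 0x0060)]] <- el("CS", "RTSTRUCT")
  ds[[tk(0x3006, 0x0010)]] <- el("SQ", list(rfor))
  if (length(ssroi)) ds[[tk(0x3006, 0x0020)]] <- el("SQ", ssroi)
  if (length(rcont)) ds[[tk(0x3006, 0x0039)]] <- el("SQ", rcont)
  rtshift::dcm_write(ds, file)
  file
}

# RT Plan dataset with per-beam isocenters (list of length-3 numerics)
write_custom_rtplan <- function(isocenters, file, frame = "1.2.840.99.1",
                                position = "HFS", label = "PLANX") {
  tk <- rtshift:::tagkey
  el <- rtshift:::dcm_el
  beams <- lapply(seq_along(isocenters), function(i) {
    cp <- list()
    cp[[tk(0x300A, 0x0112)]] <- el("IS", 0L)
    if (!is.null(isocenters[[i]])) {
      cp[[tk(0x300A, 0x012C)]] <- el("DS", as.numeric(isocenters[[i]]))
    }
    beam <- list()
    beam[[tk(0x300A, 0x00C0)]] <- el("IS", i)
    beam[[tk(0x300A, 0x0111)]] <- el("SQ", list(cp))
    beam
  })
  ds <- list()
  ds[[tk(0x0008, 0x0016)]] <- el("UI", "1.2.840.10008.5.1.4.1.1.481.5")
  ds[[tk(0x0008, 0x0018)]] <- el("UI", "1.2.840.99.3")
  ds[[tk(0x0008, 0x0060)]] <- el("CS", "RTPLAN")
  ds[[tk(0x0010, 0x0020)]] <- el("LO", "PT1")
  if (!is.null(frame)) ds[[tk(0x0020, 0x0052)]] <- el("UI", frame)
  ds[[tk(0x300A, 0x0002)]] <- el("SH", label)
  if (!is.null(position)) {
    setup <- list()
    setup[[tk(0x0018, 0x5100)]] <- el("CS", position)
    ds[[tk(0x300A, 0x0180)]] <- el("SQ", list(setup))
  }
  if (length(beams)) ds[[tk(0x300A, 0x00B0)]] <- el("SQ", beams)
  rtshift::dcm_write(ds, file)
  file
}

# printable-ASCII view of a rendered PDF (the byte stream contains binary
# runs that are not valid UTF-8, which regex matching chokes on)
pdf_ascii <- function(bytes) {
  keep <- bytes >= as.raw(0x20) & bytes <= as.raw(0x7E) | bytes == as.raw(0x0A)
  rawToChar(bytes[keep])
}

marker_set_from <- function(left, right, ap) {
  rtshift:::marker_set(vec3(left), vec3(right), anterior = vec3(ap))
}

random_unit_vec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
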