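# origin_check: marker finding, intersection rule, tolerance flagging

test_that("contour centroid is the per-axis vertex mean", {
  expect_equal(as.numeric(contour_centroid(point_contour("P", c(1, 2, 3)))), c(1, 2, 3))
  sq <- make_contour("SQ", c(-1, 10, 5, 1, 10, 5, 0, 9, 5, 0, 11, 5)) # square about (0,10,5)
  expect_equal(as.numeric(contour_centroid(sq)), c(0, 10, 5))
  expect_equal(as.numeric(contour_centroid(make_contour("M", c(0, 0, 0, 2, 4, 6)))),
               c(1, 2, 3))
  expect_error(contour_centroid(matrix(numeric(0), ncol = 3)),
               class = "rtshift_value_error")
})

test_that("default naming convention finds the three roles", {
  m <- find_marker_contours(std_structures())
  expect_s3_class(m, "rt_marker_set")
  expect_identical(m$ap_surface, "ANTERIOR")
  expect_equal(as.numeric(m$left), c(115, 18, 0))
  expect_equal(as.numeric(m$right), c(-118, 22, 0))
  expect_equal(as.numeric(m$anterior), c(1.5, -92, 0))

  # alternative names from the default pattern table, posterior surface
  m2 <- find_marker_contours(std_structures(
    names = c("BB LEFT", "MARKER RT 1", "BB POST 1"),
    centers = list(c(115, 18, 0), c(-118, 22, 0), c(1.5, 95, 0))
  ))
  expect_identical(m2$ap_surface, "POSTERIOR")
})

test_that("missing roles are NOT-EVALUABLE, duplicates are ambiguous", {
  expect_error(
    find_marker_contours(std_structures(names = c("BB LT", "body", "BB ANT"))),
    "marker not found: right", class = "rtshift_not_evaluable"
  )
  structures <- c(std_structures(), std_structures(names = c("BB LT COPY", "x", "y"))[1])
  expect_error(find_marker_contours(structures),
               "ambiguous", class = "rtshift_ambiguous_marker")
  # NOT-EVALUABLE is distinct from a verdict: it is an error condition
  expect_error(
    find_marker_contours(std_structures(names = c("BB LT", "BB RT", "body"))),
    class = "rtshift_not_evaluable"
  )
})

test_that("anterior and posterior markers together give ap_surface BOTH", {
  structures <- std_structures(
    names = c("BB LT", "BB RT", "BB ANT", "BB POST"),
    centers = list(c(115, 18, 9), c(-118, 22, 11), c(2, -92, 0), c(4, 96, 0))
  )
  m <- find_marker_contours(structures)
  expect_identical(m$ap_surface, "BOTH")
  expect_equal(expected_user_origin(m)[["x"]], 3) # mean of anterior and posterior x
})

test_that("geometric fallback assigns roles by x extremes and y sign", {
  m <- classify_fallback(list(c(-120, 20, 10), c(118, 22, 10), c(0, -95, 10)))
  expect_equal(as.numeric(m$left), c(118, 22, 10))
  expect_equal(as.numeric(m$right), c(-120, 20, 10))
  expect_identical(m$ap_surface, "ANTERIOR")

  m2 <- classify_fallback(list(c(-120, 20, 10), c(118, 22, 10), c(0, 90, 10)))
  expect_identical(m2$ap_surface, "POSTERIOR")

  # degenerate layouts are refused
  expect_error(classify_fallback(list(c(0, 0, 0), c(0, 50, 0), c(0, -50, 0))),
               class = "rtshift_ambiguous_marker")
  expect_error(classify_fallback(list(c(-100, 0, 0), c(100, 0, 0), c(80, -90, 0))),
               class = "rtshift_ambiguous_marker")
  expect_error(classify_fallback(list(c(1, 2, 3), c(4, 5, 6))),
               class = "rtshift_value_error")
})

test_that("intersection rule: lateral y/z means, AP marker x only", {
  m <- find_marker_contours(std_structures(
    centers = list(c(-120, 18, 9), c(118, 22, 11), c(1.2, -95, 40))
  ))
  # note: left/right roles are taken from the names, not from x order
  expect_equal(as.numeric(expected_user_origin(m)), c(1.2, 20.0, 10.0))
  # the AP marker's y (-95) and z (40) are ignored entirely
})

test_that("expected origin is invariant to left/right swap and vertex order (property)", {
  set.seed(703)
  for (i in 1:20) {
    a <- c(stats::runif(1, 80, 140), stats::runif(2, -30, 30))
    b <- c(stats::runif(1, -140, -80), stats::runif(2, -30, 30))
    ap <- c(stats::runif(1, -5, 5), stats::runif(1, -120, -60), stats::runif(1, -30, 30))
    m1 <- marker_set_from(a, b, ap)
    m2 <- marker_set_from(b, a, ap) # swapped lateral inputs
    expect_equal(unclass(expected_user_origin(m1)), unclass(expected_user_origin(m2)))
  }
  ring <- matrix(stats::runif(24, -10, 10), ncol = 3)
  shuffled <- ring[sample(nrow(ring)), ]
  expect_equal(unclass(contour_centroid(ring)), unclass(contour_centroid(shuffled)))
})

test_that("check verdict flags strictly beyond tolerance", {
  origin <- vec3(0, 0, 0)
  r1 <- check_user_origin(vec3(2.7, 0, 0), origin, tolerance_mm = 2.0)
  expect_identical(r1$verdict, "FLAG") # smallest clinically observed offset
  expect_equal(r1$magnitude, 2.7)

  r2 <- check_user_origin(origin, origin)
  expect_identical(r2$verdict, "PASS")
  expect_equal(r2$magnitude, 0)

  r3 <- check_user_origin(vec3(0, 0, 82.3), origin, tolerance_mm = 2.0)
  expect_identical(r3$verdict, "FLAG") # largest clinically observed offset
  expect_equal(r3$magnitude, 82.3)

  expect_equal(as.numeric(r3$per_axis_delta), c(0, 0, 82.3))
  expect_equal(r1$magnitude, vec3_norm(r1$per_axis_delta))
})

test_that("verdict is monotone in tolerance (property)", {
  set.seed(704)
  for (i in 1:30) {
    delta <- vec3(stats::runif(3, -6, 6))
    tols <- sort(stats::runif(4, 0.5, 8))
    verdicts <- vapply(tols, function(t) {
      check_user_origin(delta, vec3(0, 0, 0), tolerance_mm = t)$verdict
    }, character(1))
    # once PASS at some tolerance, PASS at every larger tolerance
    expect_true(all(diff(verdicts == "PASS") >= 0))
  }
})

test_that("naming config validates tolerance and pattern lists", {
  expect_error(naming_config(tolerance_mm = 0), class = "rtshift_value_error")
  expect_error(naming_config(tolerance_mm = -1), class = "rtshift_value_error")
  expect_error(naming_config(left = character(0)), class = "rtshift_value_error")
})

test_that("end-to-end check on files: PASS at intersection, FLAG when displaced", {
  b <- generate_bundle(fixture_spec(seed = 21))
  res <- run_origin_check(b$rtstruct, rtplan_file = b$rtplan[1])
  expect_identical(res$verdict, "PASS")
  expect_lt(res$magnitude, 1e-6)

  b2 <- generate_bundle(perturb_origin(fixture_spec(seed = 21), c(6, 0, 8)))
  res2 <- run_origin_check(b2$rtstruct)
  expect_identical(res2$verdict, "FLAG")
  expect_equal(res2$magnitude, 10, tolerance = 1e-6)

  # plan on a different frame of reference makes the check not evaluable
  other <- tempfile(fileext = ".dcm")
  on.exit(unlink(other))
  write_custom_rtplan(list(c(0, 0, 0)), other, frame = "1.2.840.99.77")
  expect_error(run_origin_check(b$rtstruct, rtplan_file = other),
               class = "rtshift_not_evaluable")
})

test_that("geometric fallback engages only on request with exactly 3 contours", {
  spec <- fixture_spec(roi_names = c(left = "mk1", right = "mk2",
                                     anterior = "mk3", posterior = "mk4"),
                       seed = 22)
  b <- generate_bundle(spec)
  expect_error(run_origin_check(b$rtstruct), class = "rtshift_not_evaluable")
  res <- run_origin_check(b$rtstruct, geometric_fallback = TRUE)
  expect_identical(res$verdict, "PASS")
})
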