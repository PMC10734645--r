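test_that("body frame from axis-aligned landmarks is the canonical frame", {
  fr <- build_body_frame(c(0, 0, 100), c(0, 0, 0))
  expect_equal(fr$vertical_axis, c(0, 0, 1))
  expect_equal(fr$horizontal_axis, c(1, 0, 0))
  expect_equal(fr$ventral_axis, c(0, 1, 0))
})

test_that("a frontal-plane landmark tilt shifts downstream angles by the tilt", {
  fr <- tilted_frame(5)
  # a scanner-horizontal plate direction now reads 5 degrees
  expect_equal(ay_angle(c(1, 0, 0), fr), 5, tolerance = 1e-9)
  ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
  prof_tilt <- measure_profile(ph, frame = fr)
  prof <- measure_profile(ph)
  expect_equal(prof_tilt$ay_deg, prof$ay_deg + 5, tolerance = 1e-6)
})

test_that("frames from random landmark pairs are orthonormal", {
  set.seed(42)
  for (i in 1:100) {
    R <- random_rotation()
    s <- as.numeric(R %*% c(0, 0, 100)) + rnorm(3, sd = 10)
    a <- s - as.numeric(R %*% c(0, 0, runif(1, 50, 150)))
    fr <- build_body_frame(s, a)
    axes <- rbind(fr$vertical_axis, fr$horizontal_axis, fr$ventral_axis)
    gram <- axes %*% t(axes)
    expect_lt(max(abs(gram - diag(3))), 1e-12)
  }
})

test_that("coincident landmarks are rejected", {
  expect_error(build_body_frame(c(1, 2, 3), c(1, 2, 3)), "coincide")
})

test_that("layer labels follow the reference-layer index functions", {
  expect_identical(layer_index(-2, "axial"), 3L)   # two layers cranial
  expect_identical(layer_index(0, "axial"), 5L)    # the reference layer
  expect_identical(layer_index(4, "axial"), 9L)
  expect_identical(layer_index(3, "frontal"), 9L)  # three layers dorsal
  expect_identical(layer_index(-5, "frontal"), 1L)

  # bijective over the valid range, and layer_offset inverts cleanly
  for (l in 1:12) expect_identical(layer_index(layer_offset(l, "frontal"), "frontal"), l)
  for (l in 1:9) expect_identical(layer_index(layer_offset(l, "axial"), "axial"), l)

  expect_error(layer_index(7, "frontal"), "bounds")
  expect_error(layer_index(-5, "axial"), "bounds")
  expect_error(layer_offset(13, "frontal"), "1..12")
})

test_that("default slicing yields 12 frontal plate traces and 9 axial outlines", {
  ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
  fr <- slice_phantom(ph, "frontal")
  expect_length(fr$slices, 12L)
  expect_true(all(vapply(fr$slices, nrow, integer(1)) > 0))
  expect_identical(fr$labels, 1:12)
  expect_identical(fr$labels[fr$calibration_index], 6L)

  ax <- slice_phantom(ph, "axial")
  expect_length(ax$slices, 9L)
  expect_identical(ax$labels[ax$calibration_index], 5L)
  # the calibration outline really has the largest diameter
  diam <- vapply(ax$slices, function(s) max(dist(s)), numeric(1))
  expect_identical(which.max(diam), ax$calibration_index)
})

test_that("doubling slice thickness halves the count, keeping the calibration anatomy", {
  ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
  thick <- ph$plate_extent_mm / 6
  st <- slice_phantom(ph, "frontal", thick)
  expect_length(st$slices, 6L)
  # the calibration slab still contains the points of the original layer 6
  y6 <- ph$plate_patches[[6]][1, "y"]
  cal <- st$slices[[st$calibration_index]]
  expect_true(any(abs(cal[, "y"] - y6) < 1e-9))
})

test_that("calibration pick is the argmax with ventral tie-breaking", {
  mk <- function(lens) {
    slices <- lapply(lens, function(L) {
      cbind(x = seq(0, L, length.out = 5), y = 0, z = 0)
    })
    structure(list(orientation = "frontal", thickness_mm = 1,
                   slices = slices, slice_centers = seq_along(lens),
                   calibration_index = NA_integer_,
                   labels = seq_along(lens)),
              class = "slice_stack")
  }
  expect_identical(find_calibration_slice(mk(c(1, 2, 3, 4))), 4L)
  expect_identical(find_calibration_slice(mk(c(1, 5, 5, 2))), 2L)
})

test_that("calibration selection is invariant to translation and isotropic scale", {
  spec <- default_phantom_spec("pooled")
  ph <- generate_phantom(spec, seed = 1)
  base <- slice_phantom(ph, "frontal")

  shifted <- ph
  shifted$plate_patches <- lapply(ph$plate_patches, function(p) {
    sweep(p, 2, c(17, 0, -23), "+")  # in-plane translation
  })
  st <- slice_phantom(shifted, "frontal")
  expect_identical(st$calibration_index, base$calibration_index)
  expect_identical(st$labels, base$labels)

  spec2 <- spec
  spec2$scale_mm <- 2
  big <- generate_phantom(spec2, seed = 1)
  st2 <- slice_phantom(big, "frontal")
  expect_identical(st2$labels[st2$calibration_index], 6L)
})

test_that("slabs that miss the structure give an empty-stack error", {
  ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
  ph$plate_patches <- lapply(ph$plate_patches, function(p) {
    p[, "y"] <- p[, "y"] - 1000  # move the plate out of the slab range
    p
  })
  expect_error(slice_phantom(ph, "frontal"), "empty")
})
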