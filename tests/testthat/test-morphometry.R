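test_that("line fit recovers exact and degenerate traces", {
  d <- c(1, 1, 0) / sqrt(2)
  trace <- t(sapply(seq(-5, 5, length.out = 7), function(t) t * d + c(3, 2, 1)))
  expect_equal(fit_plate_line(trace), d, tolerance = 1e-12)

  # all points coincident
  expect_error(fit_plate_line(matrix(1, nrow = 4, ncol = 3)), "coincide")

  # symmetric V-shaped trace: the fit is the scatter's principal axis,
  # orthogonal to the symmetry axis
  x <- seq(-2, 2, length.out = 9)
  v <- cbind(x = x, y = 0, z = abs(x) * 0.5)
  expect_equal(abs(sum(fit_plate_line(v) * c(1, 0, 0))), 1, tolerance = 1e-9)
})

test_that("noisy line fits stay within half a degree", {
  set.seed(7)
  true_dir <- c(cos(30 * pi / 180), 0, sin(30 * pi / 180))
  errs <- replicate(100, {
    t <- seq(-20, 20, length.out = 9)
    pts <- t(sapply(t, function(u) u * true_dir)) +
      matrix(rnorm(27, sd = 0.1), ncol = 3)
    fit <- fit_plate_line(pts, normal = c(0, 1, 0))
    acos(pmin(1, abs(sum(fit * true_dir)))) * 180 / pi
  })
  expect_lt(max(errs), 0.5)
})

test_that("AY angle matches its defining cases", {
  fr <- default_body_frame()
  expect_equal(ay_angle(c(1, 0, 0), fr), 0)
  expect_equal(ay_angle(c(0, 0, 1), fr), 90)
  d <- c(cos(43.7 * pi / 180), 0, sin(43.7 * pi / 180))
  expect_equal(ay_angle(d, fr), 43.7, tolerance = 1e-9)
  expect_error(ay_angle(c(0, 1, 0), fr), "orthogonal")
})

test_that("AY angle is scale/translation invariant and rotation equivariant", {
  fr <- default_body_frame()
  set.seed(3)
  for (i in 1:50) {
    d <- rnorm(3)
    if (sqrt(d[1]^2 + d[3]^2) < 0.1) next
    a0 <- ay_angle(d, fr)
    expect_equal(ay_angle(3.7 * d, fr), a0, tolerance = 1e-9)   # scaling
    expect_equal(ay_angle(-d, fr), a0, tolerance = 1e-9)        # orientation
  }
  # rotating the frame within the frontal plane shifts the angle accordingly
  d <- c(cos(0.4), 0, sin(0.4))
  base <- ay_angle(d, fr)
  shifted <- ay_angle(d, tilted_frame(10))
  expect_equal(shifted, base + 10, tolerance = 1e-9)
})

test_that("measurement reproduces planted profiles and their summaries", {
  ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
  prof <- measure_profile(ph)
  expect_identical(prof$layer, 1:12)
  expect_equal(prof$ay_deg, unname(unclass(build_default_warp_profile("pooled"))),
               tolerance = 1e-6)

  s <- summarize_profile(prof)
  expect_equal(s$ventral_third_mean, 51.64, tolerance = 1e-6)
  expect_equal(s$dorsal_third_mean, 18.6, tolerance = 1e-6)
  expect_equal(s$calibration_angle, 43.7, tolerance = 1e-6)
  expect_equal(s$total_decrease, 33.44, tolerance = 1e-6)
  expect_identical(s$transition_pair, c(8L, 9L))

  flat <- generate_phantom(phantom_spec(warp = warp_profile(rep(30, 12))),
                           seed = 2)
  expect_equal(measure_profile(flat)$ay_deg, rep(30, 12), tolerance = 1e-6)
})

test_that("the mean of the thirds means equals the overall mean", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(12, 0, 90)
    s <- summarize_profile(ay_profile(a, 1:12))
    expect_equal(mean(c(s$ventral_third_mean, s$middle_third_mean,
                        s$dorsal_third_mean)),
                 mean(a), tolerance = 1e-12)
  }
})

test_that("summaries flag missing layers instead of guessing", {
  p <- ay_profile(runif(10, 10, 60), layers = c(1:9, 11))
  s <- summarize_profile(p)
  expect_true(is.na(s$total_decrease))     # layer 12 absent
  expect_true(is.na(s$dorsal_third_mean))
  expect_false(is.na(s$ventral_third_mean))
  expect_true(all(is.na(s$transition_pair)))
})

test_that("group comparison recovers a planted noise-free difference exactly", {
  juv <- replicate(5, ay_profile(unclass(build_default_warp_profile("juvenile")),
                                 1:12, group = "juvenile"),
                   simplify = FALSE)
  adu <- replicate(5, ay_profile(unclass(build_default_warp_profile("adult")),
                                 1:12, group = "adult"),
                   simplify = FALSE)
  cmp <- compare_groups(c(juv, adu), n_boot = 200, seed = 4)
  expect_equal(cmp$decrease_difference, 8, tolerance = 1e-9)
  expect_identical(cmp$juvenile$n, 5L)
  # bootstrap of identical patients is degenerate at the point estimate
  expect_equal(unname(cmp$decrease_ci), c(8, 8), tolerance = 1e-9)
})

test_that("identical planted groups give an interval covering zero", {
  set.seed(21)
  base <- unclass(build_default_warp_profile("pooled"))
  profs <- lapply(1:12, function(i) {
    ay_profile(pmin(90, pmax(0, base + rnorm(12))), 1:12,
               patient_id = paste0("p", i),
               group = if (i <= 6) "juvenile" else "adult")
  })
  cmp <- compare_groups(profs, n_boot = 1000, seed = 8)
  expect_lte(cmp$decrease_ci[1], 0)
  expect_gte(cmp$decrease_ci[2], 0)
})

test_that("single-group input yields no group delta", {
  profs <- replicate(3, ay_profile(rep(30, 12), 1:12, group = "adult"),
                     simplify = FALSE)
  cmp <- compare_groups(profs)
  expect_null(cmp$juvenile)
  expect_true(is.na(cmp$decrease_difference))
})
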