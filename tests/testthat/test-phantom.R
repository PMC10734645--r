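test_that("generation is deterministic for a fixed (spec, seed)", {
  spec <- default_phantom_spec("pooled")
  a <- generate_phantom(spec, seed = 11, noise_sd_mm = 0.7)
  b <- generate_phantom(spec, seed = 11, noise_sd_mm = 0.7)
  expect_identical(a, b)
  c <- generate_phantom(spec, seed = 12, noise_sd_mm = 0.7)
  expect_false(identical(a$plate_patches, c$plate_patches))
})

test_that("noise-free plate patches carry the planted warp exactly", {
  spec <- default_phantom_spec("pooled")
  ph <- generate_phantom(spec, seed = 1)
  elev <- vapply(ph$plate_patches, function(p) {
    d <- p[nrow(p), ] - p[1, ]
    atan2(abs(d[3]), abs(d[1])) * 180 / pi
  }, numeric(1))
  expect_equal(unname(elev), unname(unclass(spec$warp)), tolerance = 1e-9)

  flat <- phantom_spec(warp = warp_profile(rep(30, 12)))
  ph30 <- generate_phantom(flat, seed = 1)
  elev30 <- vapply(ph30$plate_patches, function(p) {
    d <- p[nrow(p), ] - p[1, ]
    atan2(abs(d[3]), abs(d[1])) * 180 / pi
  }, numeric(1))
  expect_equal(unname(elev30), rep(30, 12), tolerance = 1e-9)
})

test_that("degenerate specs are rejected with diagnostics", {
  expect_error(phantom_spec(plate_extent_mm = 0), "positive")
  expect_error(phantom_spec(ccd_angle = 100), "110")
  bad_map <- default_attachment_map("pooled")
  bad_map[1, c("px", "py", "pz")] <- bad_map[1, c("fx", "fy", "fz")]
  expect_error(phantom_spec(attachment_map = bad_map), "coincident")
})

test_that("realized attachments reproduce the target planar angles", {
  for (grp in c("pooled", "adult", "juvenile")) {
    ph <- generate_phantom(default_phantom_spec(grp), seed = 1)
    att <- ph$attachments
    fr <- build_body_frame(ph$landmarks$sacral_center, ph$landmarks$anus_center)
    for (i in seq_len(nrow(att))) {
      d <- straight_line_direction(c(att$fx[i], att$fy[i], att$fz[i]),
                                   c(att$px[i], att$py[i], att$pz[i]))
      expect_equal(frontal_angle(d, fr), att$target_frontal_deg[i],
                   tolerance = 1e-6)
      expect_equal(transverse_angle(d, fr), att$target_transverse_deg[i],
                   tolerance = 1e-6)
    }
  }
})

test_that("noise-free measurement round-trips the warp for random specs", {
  errs <- vapply(1:100, function(i) roundtrip_error(random_spec(i), seed = i),
                 numeric(1))
  expect_lt(max(errs), 1e-6)
})

test_that("cohorts are sized, grouped and reproducible", {
  cs <- cohort_spec(5, 5, noise_sd_mm = 0.3, angle_sd_deg = 0.5, seed = 42)
  coh1 <- sample_cohort(cs)
  coh2 <- sample_cohort(cs)
  expect_length(coh1, 10L)
  expect_identical(coh1, coh2)
  groups <- vapply(coh1, function(p) p$meta$spec$age_group, character(1))
  expect_identical(sum(groups == "juvenile"), 5L)
  expect_identical(sum(groups == "adult"), 5L)
  # juvenile CCD angles are drawn above the adult distribution
  ccd <- vapply(coh1, function(p) p$meta$spec$ccd_angle, numeric(1))
  expect_gt(min(ccd[groups == "juvenile"]), max(ccd[groups == "adult"]) - 15)
  expect_gt(mean(ccd[groups == "juvenile"]), mean(ccd[groups == "adult"]))
})

test_that("a noise-free cohort round-trips each member's planted warp", {
  coh <- sample_cohort(cohort_spec(2, 2, noise_sd_mm = 0, angle_sd_deg = 0,
                                   seed = 5))
  for (ph in coh) {
    prof <- measure_profile(ph)
    planted <- unclass(ph$meta$spec$warp)[prof$layer]
    expect_equal(prof$ay_deg, unname(planted), tolerance = 1e-6)
  }
})

test_that("a planted group difference is recovered with the right sign under noise", {
  # juvenile dorsal decline 10 deg smaller than adult, warp jitter SD 1 deg
  adult <- unclass(build_default_warp_profile("adult"))
  juv <- adult
  juv[9:12] <- juv[9:12] + 10
  hits <- vapply(1:200, function(r) {
    coh <- sample_cohort(cohort_spec(
      5, 5, noise_sd_mm = 0, angle_sd_deg = 1, seed = 10000 + r,
      warp_juvenile = warp_profile(juv), warp_adult = warp_profile(adult)
    ))
    profs <- lapply(coh, measure_profile)
    cmp <- compare_groups(profs, n_boot = 0L, seed = 1)
    cmp$decrease_difference > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("phantom serialization round-trips through plain text", {
  ph <- generate_phantom(default_phantom_spec("pooled"), seed = 9,
                         noise_sd_mm = 0.2)
  dir <- fresh_tempdir()
  write_phantom(ph, dir)
  back <- read_phantom(dir)
  expect_equal(measure_profile(back)$ay_deg, measure_profile(ph)$ay_deg,
               tolerance = 1e-4)
  expect_equal(back$landmarks$sacral_center, ph$landmarks$sacral_center,
               tolerance = 1e-6)
  # re-writing the re-read phantom is byte-stable
  dir2 <- fresh_tempdir()
  write_phantom(back, dir2)
  for (f in c("landmarks.tsv", "attachments.tsv", "plate_patches.tsv")) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir, f)))
  }
})
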