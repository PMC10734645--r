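test_that("straight-line directions are unit, oriented and scale invariant", {
  d <- straight_line_direction(c(0, 0, 0), c(10, 0, 10))
  expect_equal(d, c(1, 0, 1) / sqrt(2), tolerance = 1e-9)
  d3 <- straight_line_direction(c(0, 0, 0), 3 * c(10, 0, 10))
  expect_equal(d3, d, tolerance = 1e-12)
  expect_error(straight_line_direction(c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("planar angles obey the sign conventions", {
  fr <- default_body_frame()
  expect_equal(frontal_angle(c(-1, 0, 0), fr), 0)        # horizontal medial
  expect_equal(transverse_angle(c(-1, 0.2, 0), fr) > 0, TRUE)   # ventral-going
  expect_equal(transverse_angle(c(-1, -0.2, 0), fr) < 0, TRUE)  # dorsal-going
  expect_equal(frontal_angle(c(-1, 0, -0.3), fr) < 0, TRUE)     # caudomedial
  expect_equal(transverse_angle(c(-1, 0, 0.5), fr), 0)   # within frontal plane
  expect_error(frontal_angle(c(0, 1, 0), fr), "frontal")
  expect_error(transverse_angle(c(0, 0, 1), fr), "transverse")
})

test_that("default attachment map reproduces the published mean angles", {
  fr <- default_body_frame()
  cases <- list(
    # muscle, plane, region, group, expected angle
    list("gluteus_medius", "frontal", "ventral", "pooled", 22.55),
    list("vastus_lateralis", "frontal", "middle", "pooled", -6.35),
    list("piriformis", "frontal", "middle", "pooled", 48.64),
    list("triceps_coxae", "frontal", "ventral", "adult", 84),
    list("piriformis", "transverse", "cranial", "pooled", 22.38),
    list("gluteus_maximus", "transverse", "middle", "pooled", -8.34),
    list("quadratus_femoris", "transverse", "middle", "juvenile", -10.56)
  )
  for (cs in cases) {
    m <- default_attachment_map(cs[[4]])
    row <- m[m$muscle == cs[[1]] & m$plane == cs[[2]] & m$region == cs[[3]], ]
    expect_identical(nrow(row), 1L)
    d <- straight_line_direction(c(row$fx, row$fy, row$fz),
                                 c(row$px, row$py, row$pz))
    got <- if (cs[[2]] == "frontal") frontal_angle(d, fr) else transverse_angle(d, fr)
    expect_equal(got, cs[[5]], tolerance = 1e-6,
                 label = paste(cs[[1]], cs[[3]], cs[[4]]))
  }
})

test_that("the two planar angles reconstruct the direction up to reflection", {
  fr <- default_body_frame()
  set.seed(17)
  for (i in 1:100) {
    a <- runif(1, -89, 89)
    b <- runif(1, -89, 89)
    d <- direction_from_angles(a, b, fr)
    expect_lt(d[1], 0)  # resolved toward medial
    expect_equal(frontal_angle(d, fr), a, tolerance = 1e-9)
    expect_equal(transverse_angle(d, fr), b, tolerance = 1e-9)
  }
})

test_that("centroid method equals the straight line for prismatic muscles", {
  axis <- c(-0.5, 0.2, 0.9)
  axis <- axis / sqrt(sum(axis^2))
  square <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1), 0)
  sections <- lapply(seq(0, 80, by = 10), function(s) {
    sweep(square, 2, s * axis + c(5, 5, 5), "+")
  })
  expect_equal(centroid_direction(sections), axis, tolerance = 1e-9)
  # with exactly two sections the chord IS the straight line
  expect_equal(centroid_direction(sections[c(1, 9)]), axis, tolerance = 1e-9)
  expect_error(centroid_direction(sections[1]), "2")
})

test_that("for a curved belly the centroid direction is the chord of the arc", {
  # circular-arc centroid path: quarter circle of radius R in the x-z plane
  R <- 50
  ang <- seq(0, pi / 2, length.out = 20)
  sections <- lapply(ang, function(t) {
    ctr <- c(R * cos(t), 0, R * sin(t))
    sweep(cbind(c(-1, 1, 0), c(0, 0, 1), 0), 2, ctr, "+")
  })
  chord <- c(R * cos(pi / 2) - R, 0, R * sin(pi / 2) - 0)
  chord <- chord / sqrt(sum(chord^2))
  expect_equal(centroid_direction(sections), chord, tolerance = 1e-9)
  # ... which differs from any single fiber tangent
  tangent0 <- c(-sin(0), 0, cos(0))
  expect_gt(acos(abs(sum(chord * tangent0))) * 180 / pi, 30)
})

test_that("regional tables reproduce the published group columns", {
  adult <- generate_phantom(default_phantom_spec("adult"), seed = 1)
  tab <- regional_table(adult)
  gm <- tab[tab$muscle == "gluteus_medius" & tab$plane == "frontal", ]
  gm <- gm[match(c("ventral", "middle", "dorsal"), gm$region), ]
  expect_equal(gm$frontal_deg, c(26.44, 37.01, 39.21), tolerance = 1e-6)

  juv <- generate_phantom(default_phantom_spec("juvenile"), seed = 1)
  tj <- regional_table(juv)
  qf <- tj[tj$muscle == "quadratus_femoris" & tj$plane == "transverse" &
             tj$region == "middle", ]
  expect_equal(qf$transverse_deg, -10.56, tolerance = 1e-6)
})

test_that("a cohort of identical phantoms has zero between-member variance", {
  ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
  single <- regional_table(ph)
  trio <- regional_table(list(ph, ph, ph))
  expect_equal(trio$frontal_deg, single$frontal_deg, tolerance = 1e-12)
  expect_true(all(trio$n == 3L))
})

test_that("requesting a muscle missing from the map warns and omits it", {
  ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
  expect_warning(tab <- regional_table(ph, muscles = c("gluteus_medius",
                                                       "sartorius")),
                 "sartorius")
  expect_identical(unique(tab$muscle), "gluteus_medius")
})
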