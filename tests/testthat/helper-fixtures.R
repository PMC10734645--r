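# shared helpers: small random fixtures built in code

# a random phantom spec with an arbitrary warp profile in [0, 90]
random_spec <- function(seed) {
  set.seed(seed)
  phantom_spec(
    ccd_angle = runif(1, 115, 155),
    anteversion = runif(1, 0, 35),
    scale_mm = runif(1, 0.6, 1.4),
    warp = warp_profile(runif(12, 0, 90)),
    plate_extent_mm = runif(1, 24, 48),
    age_group = sample(c("adult", "juvenile"), 1)
  )
}

# planted-vs-measured maximal layer error for a noise-free spec
roundtrip_error <- function(spec, seed = 1L) {
  prof <- measure_profile(generate_phantom(spec, seed = seed))
  planted <- unclass(spec$warp)[prof$layer]
  max(abs(prof$ay_deg - planted))
}

# a frame whose vertical axis is tilted by `deg` within the frontal plane
tilted_frame <- function(deg) {
  t <- deg * pi / 180
  build_body_frame(c(sin(t) * 100, 0, cos(t) * 100), c(0, 0, 0))
}

# a fresh empty temporary directory
fresh_tempdir <- function() {
  d <- tempfile("trochwarp_test_")
  dir.create(d, recursive = TRUE)
  d
}

# random 3-D rotation matrix
random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m)) * sample(c(-1, 1), 1)
}
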