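# Synthetic proximal-femur phantoms.
#
# A phantom carries (i) a ruled plate surface: one short line segment per
# frontal layer, inclined in the frontal plane at the planted warp angle and
# tapering in length away from the calibration layer; (ii) a point cloud on
# an ellipsoidal greater-trochanter surface for axial slicing; (iii) body
# landmarks; (iv) realized muscle origin/insertion point pairs.

# fixed geometric constants (mm, at scale 1); these are cosmetic -- all
# measured angles are invariant to them
.PLATE_MAX_LEN <- 40      # plate trace length at the calibration layer
.PLATE_TAPER <- 0.02      # quadratic length taper per layer from layer 6
.PLATE_CENTER_X <- 38
.PLATE_CENTER_Z <- 5
.PLATE_NPTS <- 9L         # points per plate trace
.TROCH_RX <- 12           # trochanter ellipsoid semi-axes
.TROCH_RY <- 9
.TROCH_HALF_HEIGHT <- 13.5
.TROCH_NRINGS <- 27L
.TROCH_NPHI <- 24L

#' Phantom specification
#'
#' Describes the geometry of one synthetic proximal femur. The warp profile
#' fixes the frontal-plane inclination of the plate trace in each of the 12
#' layers; the caput-collum-diaphyseal (CCD) angle and anteversion place the
#' trochanter (children have larger CCD angles, coxa valga); the attachment
#' map lists per-muscle origin/insertion point pairs in the body frame.
#'
#' @param ccd_angle neck-shaft angle in degrees, within \[110, 160\].
#' @param anteversion axial femoral-neck torsion in degrees.
#' @param scale_mm overall isotropic size scalar (1 = adult-sized).
#' @param warp a [warp_profile()].
#' @param plate_extent_mm ventro-dorsal extent of the plate (> 0).
#' @param age_group `"juvenile"` or `"adult"`.
#' @param attachment_map data frame of per-muscle attachment point pairs, as
#'   produced by [default_attachment_map()].
#' @return An object of class `phantom_spec`.
#' @seealso [default_phantom_spec()], [generate_phantom()]
#' @export
phantom_spec <- function(ccd_angle = 130,
                         anteversion = 15,
                         scale_mm = 1,
                         warp = build_default_warp_profile("pooled"),
                         plate_extent_mm = 36,
                         age_group = c("adult", "juvenile"),
                         attachment_map = default_attachment_map("pooled")) {
  age_group <- match.arg(age_group)
  if (!inherits(warp, "warp_profile")) warp <- warp_profile(warp)
  if (!is.numeric(ccd_angle) || ccd_angle < 110 || ccd_angle > 160) {
    stop("ccd_angle must lie within [110, 160] degrees", call. = FALSE)
  }
  if (!is.numeric(plate_extent_mm) || plate_extent_mm <= 0) {
    stop("plate_extent_mm must be positive", call. = FALSE)
  }
  if (!is.numeric(scale_mm) || scale_mm <= 0) {
    stop("scale_mm must be positive", call. = FALSE)
  }
  .check_attachment_map(attachment_map)
  structure(
    list(ccd_angle = ccd_angle, anteversion = anteversion,
         scale_mm = scale_mm, warp = warp,
         plate_extent_mm = plate_extent_mm, age_group = age_group,
         attachment_map = attachment_map),
    class = "phantom_spec"
  )
}

.check_attachment_map <- function(map) {
  need <- c("muscle", "plane", "region", "group",
            "fx", "fy", "fz", "px", "py", "pz")
  if (!is.data.frame(map) || !all(need %in% names(map))) {
    stop("attachment_map must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  fem <- as.matrix(map[, c("fx", "fy", "fz")])
  pel <- as.matrix(map[, c("px", "py", "pz")])
  if (any(sqrt(rowSums((fem - pel)^2)) < 1e-9)) {
    stop("attachment_map contains coincident origin/insertion points",
         call. = FALSE)
  }
  invisible(map)
}

#' Default phantom specifications
#'
#' Reference specs for the three study groups. Adults use a CCD angle of
#' 130 deg; juveniles 145 deg (coxa valga) with a smaller overall size and
#' the juvenile warp profile (smaller dorsal decline).
#'
#' @param group `"pooled"`, `"adult"` or `"juvenile"`.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(group = c("pooled", "adult", "juvenile")) {
  group <- match.arg(group)
  if (group == "juvenile") {
    phantom_spec(ccd_angle = 145, anteversion = 25, scale_mm = 0.75,
                 warp = build_default_warp_profile("juvenile"),
                 age_group = "juvenile",
                 attachment_map = default_attachment_map("juvenile"))
  } else {
    phantom_spec(ccd_angle = 130, anteversion = 15, scale_mm = 1,
                 warp = build_default_warp_profile(group),
                 age_group = "adult",
                 attachment_map = default_attachment_map(group))
  }
}

#' Generate a phantom
#'
#' Realizes a [phantom_spec()] as explicit geometry. Plate traces reproduce
#' the spec's warp angles exactly (to machine precision) before noise;
#' attachment points are copied from the spec's map (scaled), so straight-line
#' trajectory angles reproduce the map's target angles. With
#' `noise_sd_mm > 0`, isotropic Gaussian noise is added to every plate-trace
#' and trochanter-surface point, emulating point-level measurement error.
#' Output is deterministic for fixed `(spec, seed, noise_sd_mm)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the phantom's noise draws.
#' @param noise_sd_mm standard deviation of the point noise, mm (default 0).
#' @return An object of class `phantom`.
#' @examples
#' ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
#' ph
#' @export
generate_phantom <- function(spec, seed = 1L, noise_sd_mm = 0) {
  if (!inherits(spec, "phantom_spec")) {
    stop("'spec' must be a phantom_spec", call. = FALSE)
  }
  if (!is.numeric(noise_sd_mm) || noise_sd_mm < 0) {
    stop("noise_sd_mm must be >= 0", call. = FALSE)
  }
  sc <- spec$scale_mm
  E <- spec$plate_extent_mm
  theta <- deg2rad(unclass(spec$warp))

  # plate traces: layer k at slab-center depth y_k, inclined at warp[k]
  y_edge <- E / 2
  y_k <- y_edge - (seq_len(12L) - 0.5) * E / 12
  len_k <- .PLATE_MAX_LEN * sc * (1 - .PLATE_TAPER * (seq_len(12L) - 6)^2)
  patches <- lapply(seq_len(12L), function(k) {
    t <- seq(-len_k[k] / 2, len_k[k] / 2, length.out = .PLATE_NPTS)
    cbind(x = .PLATE_CENTER_X * sc + t * cos(theta[k]),
          y = rep(y_k[k], .PLATE_NPTS),
          z = .PLATE_CENTER_Z * sc + t * sin(theta[k]))
  })

  # trochanter surface cloud (ellipsoid, anteversion-rotated in the axial
  # plane); maximal axial diameter at its equator
  ct <- c(40, 0, 10 + 0.4 * (spec$ccd_angle - 130)) * sc
  h <- .TROCH_HALF_HEIGHT * sc
  av <- deg2rad(spec$anteversion)
  dz <- seq(-0.98, 0.98, length.out = .TROCH_NRINGS) * h
  phi <- seq(0, 2 * pi, length.out = .TROCH_NPHI + 1L)[-(.TROCH_NPHI + 1L)]
  troch <- do.call(rbind, lapply(dz, function(z) {
    s <- sqrt(1 - (z / h)^2)
    ex <- .TROCH_RX * sc * s * cos(phi)
    ey <- .TROCH_RY * sc * s * sin(phi)
    cbind(x = ct[1] + ex * cos(av) - ey * sin(av),
          y = ct[2] + ex * sin(av) + ey * cos(av),
          z = ct[3] + z)
  }))
  colnames(troch) <- c("x", "y", "z")

  if (noise_sd_mm > 0) {
    noisy <- with_seed(seed, {
      list(
        patches = lapply(patches, function(p) {
          p + matrix(stats::rnorm(length(p), sd = noise_sd_mm),
                     nrow = nrow(p))
        }),
        troch = troch + matrix(stats::rnorm(length(troch), sd = noise_sd_mm),
                               nrow = nrow(troch))
      )
    })
    patches <- noisy$patches
    troch <- noisy$troch
  }

  map <- spec$attachment_map
  att <- map
  att[c("fx", "fy", "fz", "px", "py", "pz")] <-
    map[c("fx", "fy", "fz", "px", "py", "pz")] * sc

  landmarks <- list(
    sacral_center = c(-80, -30, 60) * sc,
    anus_center = c(-80, -30, -40) * sc,
    trochanter_tip = ct + c(0, 0, h)
  )

  structure(
    list(plate_patches = patches,
         plate_extent_mm = E,
         plate_ventral_edge_y = y_edge,
         trochanter_points = troch,
         trochanter_z_range = ct[3] + c(-h, h),
         landmarks = landmarks,
         attachments = att,
         meta = list(spec = spec, seed = as.integer(seed),
                     noise_sd_mm = noise_sd_mm,
                     patient_id = "phantom")),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("Synthetic proximal-femur phantom\n")
  cat("  age group    :", x$meta$spec$age_group, "\n")
  cat("  CCD angle    :", x$meta$spec$ccd_angle, "deg\n")
  cat("  plate extent :", x$plate_extent_mm, "mm in 12 layers\n")
  cat("  planted warp :", paste(round(unclass(x$meta$spec$warp), 1),
                                collapse = " "), "\n")
  cat("  noise SD     :", x$meta$noise_sd_mm, "mm; seed", x$meta$seed, "\n")
  invisible(x)
}

#' Cohort specification
#'
#' Describes a two-group synthetic cohort. Besides point-level measurement
#' noise (`noise_sd_mm`), members may vary biologically: each member's warp
#' profile is jittered by independent Gaussian angle noise (`angle_sd_deg`)
#' and its CCD angle is drawn around the group mean, juveniles above adults.
#'
#' @param n_juvenile,n_adult member counts (>= 0).
#' @param noise_sd_mm point-noise SD in mm (default 0.5).
#' @param angle_sd_deg per-member SD of the warp-angle jitter in degrees
#'   (default 0: every member carries the group profile exactly).
#' @param seed master seed; per-member seeds are derived from it by a fixed
#'   increment, so cohorts are reproducible.
#' @param warp_juvenile,warp_adult group warp profiles.
#' @param ccd_juvenile,ccd_adult,ccd_sd group CCD means (deg) and their SD.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_juvenile, n_adult,
                        noise_sd_mm = 0.5,
                        angle_sd_deg = 0,
                        seed = 1L,
                        warp_juvenile = build_default_warp_profile("juvenile"),
                        warp_adult = build_default_warp_profile("adult"),
                        ccd_juvenile = 145, ccd_adult = 130, ccd_sd = 3) {
  if (n_juvenile < 0 || n_adult < 0) stop("cohort counts must be >= 0", call. = FALSE)
  if (noise_sd_mm < 0 || angle_sd_deg < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(
    list(n_juvenile = as.integer(n_juvenile), n_adult = as.integer(n_adult),
         noise_sd_mm = noise_sd_mm, angle_sd_deg = angle_sd_deg,
         seed = as.integer(seed),
         warp_juvenile = if (inherits(warp_juvenile, "warp_profile"))
           warp_juvenile else warp_profile(warp_juvenile),
         warp_adult = if (inherits(warp_adult, "warp_profile"))
           warp_adult else warp_profile(warp_adult),
         ccd_juvenile = ccd_juvenile, ccd_adult = ccd_adult, ccd_sd = ccd_sd),
    class = "cohort_spec"
  )
}

#' Sample a synthetic cohort
#'
#' Generates `n_juvenile + n_adult` phantoms. Each member gets a
#' deterministic child seed derived from the master seed, a warp profile
#' jittered by `angle_sd_deg` (clamped to \[0, 90\]) and a CCD angle drawn
#' from the group distribution (clamped to \[110, 160\]); juveniles are drawn
#' around the larger juvenile CCD mean.
#'
#' @param cohort a [cohort_spec()].
#' @return A list of [generate_phantom()] phantoms (juveniles first), each
#'   tagged with a `patient_id` and its group.
#' @export
sample_cohort <- function(cohort) {
  if (!inherits(cohort, "cohort_spec")) {
    stop("'cohort' must be a cohort_spec", call. = FALSE)
  }
  groups <- c(rep("juvenile", cohort$n_juvenile),
              rep("adult", cohort$n_adult))
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    s_member <- child_seed(cohort$seed, i)
    base_warp <- if (g == "juvenile") cohort$warp_juvenile else cohort$warp_adult
    ccd_mean <- if (g == "juvenile") cohort$ccd_juvenile else cohort$ccd_adult
    draws <- with_seed(s_member, {
      list(warp = pmin(90, pmax(0, unclass(base_warp) +
                                  stats::rnorm(12L, sd = cohort$angle_sd_deg))),
           ccd = min(160, max(110, stats::rnorm(1L, ccd_mean, cohort$ccd_sd))))
    })
    spec <- phantom_spec(
      ccd_angle = draws$ccd,
      anteversion = if (g == "juvenile") 25 else 15,
      scale_mm = if (g == "juvenile") 0.75 else 1,
      warp = warp_profile(draws$warp),
      age_group = g,
      attachment_map = default_attachment_map(
        if (g == "juvenile") "juvenile" else "adult")
    )
    ph <- generate_phantom(spec, seed = child_seed(s_member, 1L),
                           noise_sd_mm = cohort$noise_sd_mm)
    ph$meta$patient_id <- sprintf("%s%02d", substr(g, 1, 3), i)
    out[[i]] <- ph
  }
  out
}
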