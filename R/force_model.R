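# PCSA-weighted tension-band force model.
#
# Three traction systems act on the greater trochanter: the internal band
# (small gluteals + vastus lateralis), the external band (gluteus maximus +
# tensor fasciae latae + iliotibial band) and the posterior system (the
# external rotators, which attach exclusively to the dorsal third and whose
# opposing force is supplied by a periosteal loop over the trochanter tip).
# Muscle force vectors are specific tension x PCSA x straight-line direction;
# the plate orientation predicted for a region is perpendicular to the
# region's resultant.

#' Tension-band system definitions
#'
#' @return Named list of the three systems, each with `members` (muscle
#'   names) and `counterforce` (whether the periosteal counterforce applies;
#'   posterior system only).
#' @export
tension_band_systems <- function() {
  list(
    internal = list(members = c("gluteus_medius", "gluteus_minimus",
                                "vastus_lateralis"),
                    counterforce = FALSE),
    external = list(members = c("gluteus_maximus", "tensor_fasciae_latae",
                                "iliotibial_band"),
                    counterforce = FALSE),
    posterior = list(members = c("piriformis", "triceps_coxae",
                                 "obturator_externus", "quadratus_femoris"),
                     counterforce = TRUE)
  )
}

#' Muscle force vector
#'
#' Force along a muscle direction with magnitude `sigma * pcsa`. The specific
#' tension `sigma` is a single multiplicative constant, so it cancels out of
#' every direction and angle downstream; forces are in arbitrary units.
#'
#' @param direction unit 3-vector (femoral to pelvic).
#' @param pcsa physiological cross-sectional area, cm^2, > 0.
#' @param sigma specific tension (force per cm^2), > 0.
#' @return Force 3-vector.
#' @examples
#' muscle_force_vector(c(1, 0, 0), pcsa = 2, sigma = 1)  # (2, 0, 0)
#' @export
muscle_force_vector <- function(direction, pcsa, sigma = 1) {
  d <- .check_point(direction, "direction")
  if (!is.numeric(pcsa) || pcsa <= 0) stop("pcsa must be positive", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive", call. = FALSE)
  sigma * pcsa * d
}

#' Calibrate the periosteal counterforce magnitude
#'
#' The periosteal loop has no opposing muscle to set its tension, so its
#' magnitude is fixed by frontal-plane horizontal equilibrium at the
#' trochanter tip: `beta` is chosen so the counterforce's lateral component
#' exactly cancels the medial component of the rotator resultant. With that
#' `beta` the posterior-system resultant is vertical in the frontal
#' projection ("almost vertical" once noise or parameter changes perturb it).
#'
#' @param rotator_resultant nonzero force 3-vector of the external rotators.
#' @param phi_deg lateral tilt of the counterforce (degrees from caudal
#'   toward lateral); must be > 0 for the balance to exist.
#' @param frame a body frame.
#' @return Scalar `beta` (counterforce magnitude as a fraction of the
#'   rotator-resultant magnitude).
#' @export
calibrate_periosteal_beta <- function(rotator_resultant, phi_deg = 75,
                                      frame = default_body_frame()) {
  .check_frame(frame)
  r <- .check_point(rotator_resultant, "rotator_resultant")
  nr <- vnorm(r)
  if (nr < 1e-12) stop("rotator resultant is zero", call. = FALSE)
  s <- sin(deg2rad(phi_deg))
  if (s <= 1e-9) {
    stop("phi_deg must be positive: a purely caudal counterforce cannot ",
         "balance the medial rotator pull", call. = FALSE)
  }
  abs(sum(r * frame$horizontal_axis)) / (nr * s)
}

#' Periosteal counterforce
#'
#' Passive counterforce created by the periosteal loop over the trochanter
#' tip, opposing the pull of the external rotators. It is directed caudally,
#' tilted toward lateral by `phi_deg` in the frontal plane, with magnitude
#' `beta` times the rotator-resultant magnitude. With `beta = NULL` (the
#' default) the magnitude is calibrated by [calibrate_periosteal_beta()] so
#' the posterior-system resultant becomes vertical in the frontal plane. The
#' default tilt `phi_deg = 75` encodes a loop that runs mostly laterally and
#' only slightly caudally at the tip.
#'
#' @param rotator_resultant nonzero force 3-vector.
#' @param phi_deg frontal-plane lateral tilt, degrees from caudal (0 = pure
#'   caudal).
#' @param beta magnitude as a fraction of `|rotator_resultant|` (>= 0), or
#'   `NULL` to calibrate.
#' @param frame a body frame.
#' @return Counterforce 3-vector.
#' @examples
#' periosteal_counterforce(c(0, 0, 1), phi_deg = 0, beta = 1)  # (0, 0, -1)
#' @export
periosteal_counterforce <- function(rotator_resultant, phi_deg = 75,
                                    beta = NULL,
                                    frame = default_body_frame()) {
  .check_frame(frame)
  r <- .check_point(rotator_resultant, "rotator_resultant")
  nr <- vnorm(r)
  if (nr < 1e-12) stop("rotator resultant is zero", call. = FALSE)
  if (is.null(beta)) beta <- calibrate_periosteal_beta(r, phi_deg, frame)
  if (!is.numeric(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  dir <- sin(deg2rad(phi_deg)) * frame$horizontal_axis -
    cos(deg2rad(phi_deg)) * frame$vertical_axis
  beta * nr * dir
}

#' Plate angle predicted from a force resultant
#'
#' Growth plates align perpendicular to the forces acting on them, so the
#' predicted AY angle is the complement of the resultant's unsigned
#' frontal-plane elevation: `90 - elevation`, in \[0, 90\]. A vertical
#' resultant predicts a horizontal plate (AY 0).
#'
#' @param resultant force 3-vector with nonzero frontal projection.
#' @param frame a body frame.
#' @return Predicted AY angle, degrees in \[0, 90\].
#' @export
predicted_ay_from_resultant <- function(resultant,
                                        frame = default_body_frame()) {
  90 - ay_angle(resultant, frame)
}

# Unit direction of a muscle from the packaged planar angles, with the split
# gluteus maximus handled as its two frontal parts (each half the area).
# Returns a list of (direction, weight-fraction) pairs.
.muscle_direction_parts <- function(ref, muscle, region, group, frame) {
  tr_region <- unname(.region_to_transverse[region])
  if (is.na(tr_region)) tr_region <- region
  if (muscle == "gluteus_maximus") {
    beta <- .ref_angle(ref, "gluteus_maximus", "transverse", tr_region, group)
    if (is.na(beta)) beta <- 0
    parts <- c("gluteus_maximus_cranial", "gluteus_maximus_caudal")
    return(lapply(parts, function(p) {
      a <- .ref_angle(ref, p, "frontal", region, group)
      list(direction = direction_from_angles(a, beta, frame), fraction = 0.5)
    }))
  }
  alpha <- .ref_angle(ref, muscle, "frontal", region, group)
  beta <- .ref_angle(ref, muscle, "transverse", tr_region, group)
  if (is.na(alpha)) {
    stop("no trajectory available for system member '", muscle, "'",
         call. = FALSE)
  }
  if (is.na(beta)) beta <- 0
  list(list(direction = direction_from_angles(alpha, beta, frame),
            fraction = 1))
}

# Area-weighted force sum of a member set at a given region. Muscles with no
# PCSA entry contribute the supplied equivalent area (default 0) with a
# warning unless listed in `extra_area`.
.system_resultant <- function(ref, members, region, group, pcsa, sigma,
                              frame, extra_area = list()) {
  total <- c(0, 0, 0)
  for (m in members) {
    area <- if (m %in% names(extra_area)) {
      extra_area[[m]]
    } else if (m %in% pcsa$muscle) {
      pcsa$pcsa_cm2[match(m, pcsa$muscle)]
    } else {
      warning("no PCSA for '", m, "'; contributing zero force", call. = FALSE)
      0
    }
    if (area <= 0) next
    for (part in .muscle_direction_parts(ref, m, region, group, frame)) {
      total <- total + muscle_force_vector(part$direction,
                                           area * part$fraction, sigma)
    }
  }
  total
}

#' Regional plate-angle prediction from the tension-band systems
#'
#' Assembles the acting systems per plate region and predicts the regional
#' AY angle from the perpendicularity principle:
#'
#' * ventral third: internal + external systems, member directions at their
#'   ventral-region trajectories;
#' * middle third: the same systems at their middle-region trajectories;
#' * dorsal third: the lateral systems as in the middle third plus the
#'   posterior system (rotators at their dorsal/caudal trajectories) with the
#'   periosteal counterforce. The dorsal third therefore differs from the
#'   middle third exactly by the posterior system, which attaches exclusively
#'   there; zeroing the rotator areas makes the two predictions equal.
#'
#' The iliotibial band and the fascial coupling of the vastus intermedius and
#' medialis carry no PCSA of their own; they enter through the configurable
#' equivalent areas `itb_area_cm2` (along the band's published course) and
#' `fascial_area_cm2` (along the vastus lateralis), both 0 by default.
#'
#' @param pcsa_source `"lube"`, `"brand"` or `"klein_horsmann"`; ignored when
#'   `pcsa` is given.
#' @param pcsa optional PCSA data frame (columns `muscle`, `pcsa_cm2`)
#'   overriding `pcsa_source`.
#' @param group trajectory group (`"pooled"`, `"adult"`, `"juvenile"`).
#' @param phi_deg,beta periosteal counterforce parameters, see
#'   [periosteal_counterforce()].
#' @param itb_area_cm2,fascial_area_cm2 equivalent areas (cm^2) of the
#'   iliotibial band and the vastus fascial coupling.
#' @param posterior_scale multiplier on the whole posterior system (rotators
#'   plus counterforce); 0 ablates it.
#' @param sigma specific tension; cancels out of all angles.
#' @param frame a body frame.
#' @return Object of class `force_resolution`: data frame with one row per
#'   region (`region`, `predicted_ay_deg`, resultant components `rx, ry,
#'   rz`), with the posterior-system diagnostics (`rotator_resultant`,
#'   `counterforce`, `beta_used`, `posterior_elevation_deg`) as attributes.
#' @examples
#' warp_prediction_profile("lube")
#' @export
warp_prediction_profile <- function(pcsa_source = c("lube", "brand",
                                                    "klein_horsmann"),
                                    pcsa = NULL,
                                    group = c("pooled", "adult", "juvenile"),
                                    phi_deg = 75, beta = NULL,
                                    itb_area_cm2 = 0, fascial_area_cm2 = 0,
                                    posterior_scale = 1, sigma = 1,
                                    frame = default_body_frame()) {
  group <- match.arg(group)
  .check_frame(frame)
  if (is.null(pcsa)) pcsa <- pcsa_table(match.arg(pcsa_source))
  if (posterior_scale < 0) stop("posterior_scale must be >= 0", call. = FALSE)
  ref <- trajectory_reference()
  sys <- tension_band_systems()
  lateral <- c(sys$internal$members, sys$external$members)
  extra <- list(iliotibial_band = itb_area_cm2)
  if (fascial_area_cm2 > 0) {
    pcsa <- rbind(pcsa[, c("muscle", "pcsa_cm2")],
                  data.frame(muscle = "vastus_fascial",
                             pcsa_cm2 = fascial_area_cm2))
    lateral <- c(lateral, "vastus_fascial")
    ref2 <- ref[ref$muscle == "vastus_lateralis", , drop = FALSE]
    ref2$muscle <- "vastus_fascial"
    ref <- rbind(ref, ref2)
  }

  lat_ventral <- .system_resultant(ref, lateral, "ventral", group, pcsa,
                                   sigma, frame, extra)
  lat_middle <- .system_resultant(ref, lateral, "middle", group, pcsa,
                                  sigma, frame, extra)

  rot <- .system_resultant(ref, sys$posterior$members, "dorsal", group, pcsa,
                           sigma, frame)
  rot <- posterior_scale * rot
  if (vnorm(rot) > 1e-12) {
    cf <- periosteal_counterforce(rot, phi_deg = phi_deg, beta = beta,
                                  frame = frame)
    beta_used <- vnorm(cf) / vnorm(rot)
    posterior <- rot + cf
    post_elev <- ay_angle(posterior, frame)
  } else {
    cf <- c(0, 0, 0)
    beta_used <- NA_real_
    posterior <- c(0, 0, 0)
    post_elev <- NA_real_
  }
  dorsal_total <- lat_middle + posterior

  res <- data.frame(
    region = c("ventral", "middle", "dorsal"),
    predicted_ay_deg = c(predicted_ay_from_resultant(lat_ventral, frame),
                         predicted_ay_from_resultant(lat_middle, frame),
                         predicted_ay_from_resultant(dorsal_total, frame)),
    rbind(rx_ry_rz(lat_ventral), rx_ry_rz(lat_middle),
          rx_ry_rz(dorsal_total)),
    stringsAsFactors = FALSE
  )
  structure(res,
            rotator_resultant = rot, counterforce = cf,
            beta_used = beta_used, phi_deg = phi_deg,
            posterior_elevation_deg = post_elev,
            class = c("force_resolution", "data.frame"))
}

rx_ry_rz <- function(v) {
  data.frame(rx = v[1], ry = v[2], rz = v[3])
}

#' @export
print.force_resolution <- function(x, ...) {
  cat("Tension-band force resolution (predicted plate AY angle per region):\n")
  print(data.frame(region = x$region,
                   predicted_ay_deg = round(x$predicted_ay_deg, 2)),
        row.names = FALSE)
  pe <- attr(x, "posterior_elevation_deg")
  if (!is.na(pe)) {
    cat(sprintf("posterior-system resultant: frontal elevation %.1f deg (beta = %.3f, phi = %.0f deg)\n",
                pe, attr(x, "beta_used"), attr(x, "phi_deg")))
  }
  invisible(x)
}
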