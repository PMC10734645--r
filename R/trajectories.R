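# Straight-line muscle trajectories and their planar angles.
#
# Sign conventions follow the measurement protocol: in the frontal plane the
# angle is taken to the body horizontal, negative for a caudomedial course;
# in the transverse plane it is taken to the frontal plane, negative for a
# dorsomedial course. Directions point from the femoral (trochanteric)
# attachment toward the other attachment, which makes abductor frontal
# angles positive.

#' Straight-line muscle direction
#'
#' The straight-line method connects a muscle's origin and insertion with a
#' line; the muscle direction is the unit vector from the femoral point
#' toward the pelvic (or distal) point.
#'
#' @param femoral_point,pelvic_point distinct 3-D points, mm.
#' @return Unit 3-vector.
#' @examples
#' straight_line_direction(c(0, 0, 0), c(10, 0, 10))
#' @export
straight_line_direction <- function(femoral_point, pelvic_point) {
  f <- .check_point(femoral_point, "femoral_point")
  p <- .check_point(pelvic_point, "pelvic_point")
  if (vnorm(p - f) < 1e-9) {
    stop("femoral and pelvic attachment points coincide", call. = FALSE)
  }
  unitize(p - f, "muscle direction")
}

#' Frontal-plane trajectory angle
#'
#' Signed elevation of the frontal-plane projection of a direction above the
#' body horizontal, in degrees within (-90, 90]. Negative values indicate a
#' caudally directed (caudomedial) course. A direction with zero frontal
#' projection is rejected.
#'
#' @param direction 3-vector (need not be unit length).
#' @param frame a [body_frame()][build_body_frame]; defaults to the canonical
#'   frame.
#' @return Signed degrees.
#' @export
frontal_angle <- function(direction, frame = default_body_frame()) {
  .check_frame(frame)
  d <- .check_point(direction, "direction")
  h <- sum(d * frame$horizontal_axis)
  v <- sum(d * frame$vertical_axis)
  if (sqrt(h^2 + v^2) < 1e-12 * max(vnorm(d), 1)) {
    stop("direction has no frontal-plane projection", call. = FALSE)
  }
  a <- rad2deg(atan2(v, abs(h)))
  if (a <= -90) a <- 90  # vertical directions map to +90 by convention
  a
}

#' Transverse-plane trajectory angle
#'
#' Signed angle of the transverse-plane projection of a direction relative to
#' the frontal plane, in degrees within (-90, 90]. Negative values indicate a
#' dorsally directed (dorsomedial) course.
#'
#' @inheritParams frontal_angle
#' @return Signed degrees.
#' @export
transverse_angle <- function(direction, frame = default_body_frame()) {
  .check_frame(frame)
  d <- .check_point(direction, "direction")
  h <- sum(d * frame$horizontal_axis)
  y <- sum(d * frame$ventral_axis)
  if (sqrt(h^2 + y^2) < 1e-12 * max(vnorm(d), 1)) {
    stop("direction has no transverse-plane projection", call. = FALSE)
  }
  a <- rad2deg(atan2(y, abs(h)))
  if (a <= -90) a <- 90
  a
}

#' Reconstruct a 3-D direction from its two planar angles
#'
#' Inverts the pair ([frontal_angle()], [transverse_angle()]). The two planar
#' angles determine a direction only up to reflection about the sagittal
#' plane; the ambiguity is resolved toward medial (negative lateral
#' component), the direction in which the muscles of interest pull the
#' trochanter.
#'
#' @param frontal_deg,transverse_deg planar angles in degrees, each strictly
#'   inside (-90, 90).
#' @param frame a body frame.
#' @return Unit 3-vector.
#' @export
direction_from_angles <- function(frontal_deg, transverse_deg,
                                  frame = default_body_frame()) {
  .check_frame(frame)
  if (abs(frontal_deg) >= 90 || abs(transverse_deg) >= 90) {
    stop("planar angles must lie strictly inside (-90, 90) degrees ",
         "to reconstruct a direction", call. = FALSE)
  }
  w <- -frame$horizontal_axis +
    tan(deg2rad(transverse_deg)) * frame$ventral_axis +
    tan(deg2rad(frontal_deg)) * frame$vertical_axis
  unitize(w, "reconstructed direction")
}

#' Centroid-method muscle direction
#'
#' The centroid method connects the centroids of successive muscle
#' cross-sections; the direction reported here is the endpoint-to-endpoint
#' chord of the centroid polyline. For a straight prismatic muscle this
#' equals the straight-line direction exactly; for a curved belly it is the
#' chord of the centroid path.
#'
#' @param cross_sections list (length >= 2) of point matrices (rows = points,
#'   columns = x, y, z), ordered along the muscle.
#' @return Unit 3-vector from the first section centroid toward the last.
#' @export
centroid_direction <- function(cross_sections) {
  if (!is.list(cross_sections) || length(cross_sections) < 2L) {
    stop("need at least 2 cross-sections for the centroid method", call. = FALSE)
  }
  cents <- t(vapply(cross_sections, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("cross-sections must have 3 columns", call. = FALSE)
    colMeans(m)
  }, numeric(3L)))
  chord <- cents[nrow(cents), ] - cents[1L, ]
  if (vnorm(chord) < 1e-9) {
    stop("first and last section centroids coincide", call. = FALSE)
  }
  unitize(chord, "centroid direction")
}

#' Published straight-line trajectory angles
#'
#' The packaged per-muscle, per-region mean trajectory angles: frontal-plane
#' angles by ventral/middle/dorsal thirds and transverse-plane angles by
#' cranial/middle/caudal layer groups, each for the pooled population and for
#' the adult and juvenile subgroups. Cells that were not measured are absent.
#'
#' @param group `"pooled"`, `"adult"` or `"juvenile"`; `NULL` returns all.
#' @param plane `"frontal"`, `"transverse"` or `NULL` for both.
#' @return Data frame with columns `muscle`, `plane`, `region`, `group`,
#'   `angle_deg`.
#' @export
trajectory_reference <- function(group = NULL, plane = NULL) {
  ref <- memo("trajectory_angles",
              utils::read.csv(.extdata("trajectory_angles.csv"),
                              stringsAsFactors = FALSE))
  if (!is.null(group)) {
    group <- match.arg(group, c("pooled", "adult", "juvenile"))
    ref <- ref[ref$group == group, , drop = FALSE]
  }
  if (!is.null(plane)) {
    plane <- match.arg(plane, c("frontal", "transverse"))
    ref <- ref[ref$plane == plane, , drop = FALSE]
  }
  rownames(ref) <- NULL
  ref
}

# region correspondence between the frontal (ventro-dorsal) and transverse
# (cranio-caudal) stratifications
.region_to_transverse <- c(ventral = "cranial", middle = "middle",
                           dorsal = "caudal", mean = "middle")
.region_to_frontal <- c(cranial = "ventral", middle = "middle",
                        caudal = "dorsal", mean = "middle")

# Look up a reference angle with documented fallbacks: exact (region, group),
# then the pooled group, then the middle region, then the muscle's available
# mean. The frontal course of the (unsplit) gluteus maximus is the average of
# its cranial and caudal parts. Returns NA when the muscle has no entry in
# the plane at all.
.ref_angle <- function(ref, muscle, plane, region, group) {
  if (plane == "frontal" && muscle == "gluteus_maximus") {
    parts <- c("gluteus_maximus_cranial", "gluteus_maximus_caudal")
    vals <- vapply(parts, .ref_angle, numeric(1L),
                   ref = ref, plane = plane, region = region, group = group)
    return(mean(vals))
  }
  rows <- ref[ref$muscle == muscle & ref$plane == plane, , drop = FALSE]
  if (nrow(rows) == 0L) return(NA_real_)
  pick <- function(r, g) {
    hit <- rows$angle_deg[rows$region == r & rows$group == g]
    if (length(hit)) hit[1L] else NA_real_
  }
  for (cand in list(c(region, group), c(region, "pooled"),
                    c("middle", group), c("middle", "pooled"),
                    c("mean", group), c("mean", "pooled"))) {
    v <- pick(cand[1L], cand[2L])
    if (!is.na(v)) return(v)
  }
  mean(rows$angle_deg)
}

#' Default muscle attachment map
#'
#' Builds the per-muscle origin/insertion point pairs used by the default
#' phantoms. The map is reverse-engineered: femoral points sit on the
#' trochanter (offset ventro-dorsally for frontal-plane regions,
#' cranio-caudally for transverse-plane layer groups) and the paired point is
#' placed along the direction reconstructed from the published planar mean
#' angles, so that [frontal_angle()] and [transverse_angle()] reproduce those
#' means exactly. It is a modelling fixture consistent with the published
#' angles, not measured anatomy. Where a muscle lacks an angle in one plane,
#' that plane's angle is taken from its middle region or set to 0 (see
#' `target_frontal_deg` / `target_transverse_deg` in the output).
#'
#' @param group `"pooled"`, `"adult"` or `"juvenile"`.
#' @param fiber_length_mm distance between the paired points, mm.
#' @return Data frame with one row per muscle x region x plane: target angles
#'   and the realized `fx, fy, fz` (femoral) and `px, py, pz` points.
#' @export
default_attachment_map <- function(group = c("pooled", "adult", "juvenile"),
                                   fiber_length_mm = 90) {
  group <- match.arg(group)
  if (fiber_length_mm == 90) {
    return(memo(paste0("attachment_map_", group),
                .build_attachment_map(group, 90)))
  }
  .build_attachment_map(group, fiber_length_mm)
}

.build_attachment_map <- function(group, fiber_length_mm) {
  ref <- trajectory_reference()
  rows <- ref[ref$group == group, , drop = FALSE]
  frame <- default_body_frame()
  tip <- c(40, 0, 23.5)  # trochanter tip of the scale-1 phantom
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$plane == "frontal") {
      alpha <- r$angle_deg
      beta_muscle <- if (startsWith(r$muscle, "gluteus_maximus"))
        "gluteus_maximus" else r$muscle
      beta <- .ref_angle(ref, beta_muscle, "transverse",
                         .region_to_transverse[[r$region]], group)
      if (is.na(beta)) beta <- 0
      off <- switch(r$region, ventral = c(0, 12, 0), dorsal = c(0, -12, 0),
                    c(0, 0, 0))
    } else {
      beta <- r$angle_deg
      alpha <- .ref_angle(ref, r$muscle, "frontal",
                          .region_to_frontal[[r$region]], group)
      if (is.na(alpha)) alpha <- 0
      off <- switch(r$region, cranial = c(0, 0, 9), caudal = c(0, 0, -9),
                    c(0, 0, 0))
    }
    fem <- tip + off
    pel <- fem + fiber_length_mm * direction_from_angles(alpha, beta, frame)
    data.frame(muscle = r$muscle, plane = r$plane, region = r$region,
               group = group,
               target_frontal_deg = alpha, target_transverse_deg = beta,
               fx = fem[1], fy = fem[2], fz = fem[3],
               px = pel[1], py = pel[2], pz = pel[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Regional trajectory table
#'
#' Recomputes the straight-line trajectory angles of every attachment of a
#' phantom (or of each member of a cohort) and tabulates them per muscle,
#' plane, region and group, averaging over cohort members.
#'
#' @param x a `phantom` or a list of phantoms.
#' @param frame body frame used for the angles; defaults to each phantom's
#'   landmark-derived frame.
#' @param muscles optional character vector restricting the table; requested
#'   muscles missing from the attachment map are dropped with a warning.
#' @return Data frame with columns `muscle`, `plane`, `region`, `group`,
#'   `frontal_deg`, `transverse_deg`, `n`.
#' @export
regional_table <- function(x, frame = NULL, muscles = NULL) {
  phantoms <- if (inherits(x, "phantom")) list(x) else x
  if (!length(phantoms) || !all(vapply(phantoms, inherits, logical(1L), "phantom"))) {
    stop("'x' must be a phantom or a list of phantoms", call. = FALSE)
  }
  per <- lapply(phantoms, function(ph) {
    fr <- frame %||% build_body_frame(ph$landmarks$sacral_center,
                                      ph$landmarks$anus_center)
    att <- ph$attachments
    dirs <- lapply(seq_len(nrow(att)), function(i) {
      straight_line_direction(c(att$fx[i], att$fy[i], att$fz[i]),
                              c(att$px[i], att$py[i], att$pz[i]))
    })
    data.frame(muscle = att$muscle, plane = att$plane, region = att$region,
               group = att$group,
               frontal_deg = vapply(dirs, frontal_angle, numeric(1L), frame = fr),
               transverse_deg = vapply(dirs, transverse_angle, numeric(1L),
                                       frame = fr),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per)
  if (!is.null(muscles)) {
    missing <- setdiff(muscles, unique(all$muscle))
    if (length(missing)) {
      warning("muscle(s) absent from the attachment map, omitted: ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
    all <- all[all$muscle %in% muscles, , drop = FALSE]
  }
  agg <- stats::aggregate(
    cbind(frontal_deg, transverse_deg) ~ muscle + plane + region + group,
    data = all, FUN = mean
  )
  counts <- stats::aggregate(
    cbind(n = frontal_deg) ~ muscle + plane + region + group,
    data = all, FUN = length
  )
  out <- merge(agg, counts, by = c("muscle", "plane", "region", "group"))
  out <- out[order(out$plane, out$muscle, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
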