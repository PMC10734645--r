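# AY-angle measurement: line fits on slice traces, the angle to the body
# horizontal, per-layer profiles and their summaries.

#' Total-least-squares line fit to a slice trace
#'
#' Fits a line direction to a planar polyline by total least squares (the
#' first principal axis of the point scatter). If the slice-plane normal is
#' supplied, points are first projected into that plane so out-of-plane noise
#' cannot tilt the fit. The sign is chosen so the direction has a positive
#' lateral (x) component (positive cranial if the lateral component
#' vanishes). For a degenerate symmetric trace (e.g. a balanced V shape) the
#' fit is the principal axis of the scatter, i.e. the axis orthogonal to the
#' symmetry axis.
#'
#' @param trace point matrix (rows = points, columns = x, y, z), >= 2
#'   distinct points.
#' @param normal optional unit 3-vector normal of the slice plane.
#' @return Unit 3-vector line direction.
#' @export
fit_plate_line <- function(trace, normal = NULL) {
  m <- as.matrix(trace)
  if (ncol(m) != 3L || nrow(m) < 2L) {
    stop("trace must be a matrix of >= 2 points with 3 columns", call. = FALSE)
  }
  ctr <- colMeans(m)
  x <- sweep(m, 2L, ctr)
  if (max(abs(x)) < 1e-9) {
    stop("all trace points coincide; no line direction", call. = FALSE)
  }
  if (!is.null(normal)) {
    nrm <- unitize(.check_point(normal, "normal"), "plane normal")
    # orthonormal in-plane basis
    seed <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    b1 <- unitize(seed - sum(seed * nrm) * nrm, "in-plane basis")
    b2 <- .cross3(nrm, b1)
    uv <- cbind(x %*% b1, x %*% b2)
    cv <- crossprod(uv) / nrow(uv)
    e <- eigen(cv, symmetric = TRUE)
    dir <- e$vectors[1L, 1L] * b1 + e$vectors[2L, 1L] * b2
  } else {
    e <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
    dir <- e$vectors[, 1L]
  }
  dir <- unitize(dir, "fitted direction")
  if (dir[1] < 0 || (abs(dir[1]) < 1e-12 && dir[3] < 0)) dir <- -dir
  dir
}

#' AY angle of a plate direction
#'
#' The AY angle is the unsigned acute angle, in degrees within \[0, 90\],
#' between the frontal-plane projection of a plate-trace direction and the
#' body horizontal axis. It is invariant to translation and isotropic
#' scaling of the underlying geometry and equivariant under frontal-plane
#' rotations of the frame.
#'
#' @param direction 3-vector (plate-trace line direction).
#' @param frame a body frame.
#' @return Degrees in \[0, 90\].
#' @examples
#' ay_angle(c(1, 0, 0), default_body_frame())  # 0
#' ay_angle(c(0, 0, 1), default_body_frame())  # 90
#' @export
ay_angle <- function(direction, frame = default_body_frame()) {
  .check_frame(frame)
  d <- .check_point(direction, "direction")
  h <- sum(d * frame$horizontal_axis)
  v <- sum(d * frame$vertical_axis)
  if (sqrt(h^2 + v^2) < 1e-12 * max(vnorm(d), 1)) {
    stop("direction is orthogonal to the frontal plane; AY angle undefined",
         call. = FALSE)
  }
  rad2deg(atan2(abs(v), abs(h)))
}

#' Per-patient AY-angle profile
#'
#' Container for up to 12 AY angles indexed by frontal layer label.
#'
#' @param angles_deg numeric vector of AY angles in \[0, 90\] (`NA` marks an
#'   unmeasured layer).
#' @param layers integer layer labels (default `1:length(angles_deg)`).
#' @param patient_id identifier.
#' @param group `"juvenile"`, `"adult"` or `NA`.
#' @return Object of class `ay_profile`: a data frame with columns `layer`
#'   and `ay_deg`, plus `patient_id` and `group` attributes.
#' @export
ay_profile <- function(angles_deg, layers = seq_along(angles_deg),
                       patient_id = "patient", group = NA_character_) {
  ok <- is.na(angles_deg) | (is.finite(angles_deg) &
                               angles_deg >= 0 & angles_deg <= 90)
  if (!all(ok)) {
    stop("AY angles must be within [0, 90] degrees (or NA for unmeasured layers)",
         call. = FALSE)
  }
  if (length(layers) != length(angles_deg) || anyDuplicated(layers) ||
      any(layers < 1 | layers > 12)) {
    stop("layers must be distinct labels in 1..12 matching angles_deg",
         call. = FALSE)
  }
  structure(
    data.frame(layer = as.integer(layers), ay_deg = as.numeric(angles_deg)),
    patient_id = patient_id, group = group,
    class = c("ay_profile", "data.frame")
  )
}

#' Measure the AY-angle profile of a phantom
#'
#' End-to-end measurement protocol: build the body frame from the phantom's
#' sacral and anus landmarks, cut a frontal slice stack, select the
#' calibration slice (maximal plate extent, label 6), assign layer labels,
#' fit a total-least-squares line to each slice trace and take its AY angle.
#' With zero noise this reproduces the phantom's planted warp profile to
#' numerical precision.
#'
#' @param phantom a phantom.
#' @param thickness_mm frontal slice thickness (default plate extent / 12).
#' @param frame body frame; default derived from the phantom's landmarks.
#' @return An [ay_profile()] holding the layers with labels in 1..12.
#' @export
measure_profile <- function(phantom, thickness_mm = NULL, frame = NULL) {
  if (!inherits(phantom, "phantom")) stop("'phantom' must be a phantom", call. = FALSE)
  frame <- frame %||% build_body_frame(phantom$landmarks$sacral_center,
                                       phantom$landmarks$anus_center)
  stack <- slice_phantom(phantom, "frontal", thickness_mm)
  keep <- stack$labels >= 1L & stack$labels <= 12L
  angs <- vapply(which(keep), function(i) {
    dir <- fit_plate_line(stack$slices[[i]], normal = c(0, 1, 0))
    ay_angle(dir, frame)
  }, numeric(1L))
  ay_profile(angs, layers = stack$labels[keep],
             patient_id = phantom$meta$patient_id %||% "phantom",
             group = phantom$meta$spec$age_group)
}

#' Summarize an AY-angle profile
#'
#' Thirds means (layers 1-4 ventral, 5-8 middle, 9-12 dorsal), the
#' calibration-layer angle (label 6), the total ventro-dorsal decrease
#' (layer 1 minus layer 12) and the transition pair: the consecutive layer
#' pair with the largest absolute angle change among pairs (k, k+1) with
#' k >= 2 (the ventral 1-to-2 rise is excluded so the detector reports the
#' dorsal jump). Statistics whose layers are missing are returned as `NA`.
#'
#' @param profile an [ay_profile()].
#' @return Object of class `profile_summary`: a list with fields
#'   `ventral_third_mean`, `middle_third_mean`, `dorsal_third_mean`,
#'   `calibration_angle`, `total_decrease`, `transition_pair`.
#' @export
summarize_profile <- function(profile) {
  if (!inherits(profile, "ay_profile")) {
    stop("'profile' must be an ay_profile", call. = FALSE)
  }
  a <- rep(NA_real_, 12L)
  a[profile$layer] <- profile$ay_deg
  third <- function(idx) if (all(!is.na(a[idx]))) mean(a[idx]) else NA_real_
  diffs <- abs(a[-1L] - a[-12L])          # pair k = (k, k+1)
  cand <- diffs[-1L]                      # exclude the ventral 1->2 rise
  trans <- if (all(!is.na(cand))) {
    k <- which.max(cand) + 1L
    c(k, k + 1L)
  } else c(NA_integer_, NA_integer_)
  structure(
    list(ventral_third_mean = third(1:4),
         middle_third_mean = third(5:8),
         dorsal_third_mean = third(9:12),
         calibration_angle = a[6L],
         total_decrease = if (!is.na(a[1L]) && !is.na(a[12L]))
           a[1L] - a[12L] else NA_real_,
         transition_pair = trans),
    class = "profile_summary"
  )
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("AY-profile summary (deg):\n")
  cat(sprintf("  thirds means       : ventral %.2f | middle %.2f | dorsal %.2f\n",
              x$ventral_third_mean, x$middle_third_mean, x$dorsal_third_mean))
  cat(sprintf("  calibration layer 6: %.2f\n", x$calibration_angle))
  cat(sprintf("  total decrease     : %.2f\n", x$total_decrease))
  cat(sprintf("  transition zone    : layers %s-%s\n",
              x$transition_pair[1L], x$transition_pair[2L]))
  invisible(x)
}

#' Compare juvenile and adult AY profiles
#'
#' Per-group layer means and summaries, plus the difference in the total
#' ventro-dorsal decrease (adult minus juvenile) with a patient-level
#' bootstrap percentile interval.
#'
#' @param profiles list of [ay_profile()] objects carrying a `group`
#'   attribute (`"juvenile"` / `"adult"`).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @return Object of class `group_comparison`: per-group layer mean matrix,
#'   per-group mean summary fields, `decrease_difference` and `decrease_ci`
#'   (both `NA` when a group is absent), and group sizes.
#' @export
compare_groups <- function(profiles, n_boot = 1000L, seed = 1L, conf = 0.95) {
  if (!length(profiles) || !all(vapply(profiles, inherits, logical(1L), "ay_profile"))) {
    stop("'profiles' must be a non-empty list of ay_profile objects", call. = FALSE)
  }
  groups <- vapply(profiles, function(p) as.character(attr(p, "group")),
                   character(1L))
  layer_mat <- t(vapply(profiles, function(p) {
    a <- rep(NA_real_, 12L); a[p$layer] <- p$ay_deg; a
  }, numeric(12L)))
  colnames(layer_mat) <- paste0("layer", 1:12)
  decreases <- layer_mat[, 1L] - layer_mat[, 12L]

  by_group <- function(g) {
    rows <- which(groups == g)
    if (!length(rows)) return(NULL)
    lm <- colMeans(layer_mat[rows, , drop = FALSE], na.rm = TRUE)
    lm[is.nan(lm)] <- NA_real_
    list(n = length(rows),
         layer_means = lm,
         mean_decrease = mean(decreases[rows], na.rm = TRUE),
         summary = summarize_profile(
           ay_profile(lm, 1:12, patient_id = paste0("mean_", g), group = g)))
  }
  juv <- by_group("juvenile")
  adu <- by_group("adult")

  diff_est <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!is.null(juv) && !is.null(adu)) {
    diff_est <- adu$mean_decrease - juv$mean_decrease
    ji <- which(groups == "juvenile")
    ai <- which(groups == "adult")
    if (n_boot >= 1L) {
      boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
        mean(decreases[sample(ai, replace = TRUE)], na.rm = TRUE) -
          mean(decreases[sample(ji, replace = TRUE)], na.rm = TRUE)
      }, numeric(1L)))
      alpha <- (1 - conf) / 2
      ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
    }
  }
  structure(
    list(juvenile = juv, adult = adu,
         decrease_difference = diff_est, decrease_ci = ci,
         n_boot = n_boot, conf = conf),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of AY profiles\n")
  for (g in c("juvenile", "adult")) {
    gi <- x[[g]]
    if (is.null(gi)) next
    cat(sprintf("  %-8s (n=%d): mean total decrease %.2f deg\n",
                g, gi$n, gi$mean_decrease))
  }
  if (!is.na(x$decrease_difference)) {
    cat(sprintf("  adult - juvenile decrease: %.2f deg (%.0f%% bootstrap CI %.2f to %.2f)\n",
                x$decrease_difference, 100 * x$conf,
                x$decrease_ci[1L], x$decrease_ci[2L]))
  }
  invisible(x)
}

#' Plot an AY-angle profile
#'
#' Layer labels on the x axis, AY angle on the y axis; the calibration layer
#' and the thirds boundaries are marked.
#'
#' @param x an [ay_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.ay_profile <- function(x, ...) {
  graphics::plot(x$layer, x$ay_deg, type = "b", pch = 16,
                 xlab = "layer (ventral to dorsal)", ylab = "AY angle (deg)",
                 ylim = c(0, 90), ...)
  graphics::abline(v = 6, col = "red", lty = 2)
  graphics::abline(v = c(4.5, 8.5), col = "grey70", lty = 3)
  invisible(x)
}
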