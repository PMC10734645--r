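#' Body reference frame from pelvic landmarks
#'
#' The vertical body axis is the line through the center of the sacral
#' vertebrae and the center of the anus; the horizontal axis is its
#' orthogonal within the frontal plane. Frames are orthonormal right-handed
#' triads: `horizontal_axis` (lateral, x-like), `ventral_axis` (y-like) and
#' `vertical_axis` (cranial, z-like).
#'
#' The frontal-plane orientation is fixed by convention: the horizontal axis
#' is the projection of the scanner lateral axis `c(1, 0, 0)` onto the plane
#' orthogonal to the vertical axis. Landmarks that tilt the vertical axis
#' within the frontal plane therefore tilt all downstream AY angles by the
#' same amount.
#'
#' @param sacral_center,anus_center 3-D landmark points in mm.
#' @return An object of class `body_frame` with fields `vertical_axis`,
#'   `horizontal_axis`, `ventral_axis` (unit 3-vectors) and `origin`.
#' @examples
#' build_body_frame(c(0, 0, 100), c(0, 0, 0))
#' @export
build_body_frame <- function(sacral_center, anus_center) {
  s <- .check_point(sacral_center, "sacral_center")
  a <- .check_point(anus_center, "anus_center")
  if (vnorm(s - a) < 1e-9) {
    stop("sacral and anus landmarks coincide; cannot define the vertical axis",
         call. = FALSE)
  }
  v <- unitize(s - a, "vertical axis")
  lat <- c(1, 0, 0)
  h <- lat - sum(lat * v) * v
  if (vnorm(h) < 1e-9) {
    stop("vertical axis is parallel to the lateral direction; ",
         "horizontal axis undefined", call. = FALSE)
  }
  h <- unitize(h, "horizontal axis")
  structure(
    list(vertical_axis = v,
         horizontal_axis = h,
         ventral_axis = .cross3(v, h),
         origin = a),
    class = "body_frame"
  )
}

#' Canonical body frame
#'
#' The identity frame of the phantom/scanner coordinates: x lateral toward
#' the measured hip, y ventral, z cranial, origin at the hip center.
#'
#' @return A `body_frame`.
#' @export
default_body_frame <- function() {
  structure(
    list(vertical_axis = c(0, 0, 1),
         horizontal_axis = c(1, 0, 0),
         ventral_axis = c(0, 1, 0),
         origin = c(0, 0, 0)),
    class = "body_frame"
  )
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.check_frame <- function(frame) {
  if (!inherits(frame, "body_frame")) {
    stop("'frame' must be a body_frame (see build_body_frame())", call. = FALSE)
  }
  frame
}

#' @export
print.body_frame <- function(x, ...) {
  cat("Body frame (mm):\n")
  cat("  vertical  :", sprintf("% .6f", x$vertical_axis), "\n")
  cat("  horizontal:", sprintf("% .6f", x$horizontal_axis), "\n")
  cat("  ventral   :", sprintf("% .6f", x$ventral_axis), "\n")
  cat("  origin    :", sprintf("% .2f", x$origin), "\n")
  invisible(x)
}
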