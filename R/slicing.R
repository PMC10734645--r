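# Slice-stack emulation of the MRI acquisition: frontal stacks intersect the
# plate surface, axial stacks the trochanter outline. Stacks are cut along
# the scanner (phantom) axes; body-frame tilts enter only when angles are
# measured.

#' Cut a phantom into a slice stack
#'
#' Frontal stacks partition the plate's ventro-dorsal extent into slabs of
#' the given thickness (ventral to dorsal) and collect the plate-trace points
#' falling in each slab; axial stacks partition the trochanter's
#' cranio-caudal extent (cranial to caudal) and collect trochanter-outline
#' points. Empty slabs are dropped. Default thicknesses give the standard 12
#' frontal plate traces and 9 axial trochanter outlines. The calibration
#' slice is selected by [find_calibration_slice()] and layer labels are
#' assigned around it (label 6 frontal, label 5 axial).
#'
#' @param phantom a [generate_phantom()] phantom.
#' @param orientation `"frontal"` or `"axial"`.
#' @param thickness_mm slice thickness; default plate extent / 12 (frontal)
#'   or trochanter extent / 9 (axial).
#' @return An object of class `slice_stack`: fields `orientation`,
#'   `thickness_mm`, `slices` (list of point matrices, in stack order),
#'   `slice_centers` (slab center coordinate), `calibration_index` (position
#'   of the calibration slice in `slices`) and `labels` (layer labels).
#' @export
slice_phantom <- function(phantom,
                          orientation = c("frontal", "axial"),
                          thickness_mm = NULL) {
  if (!inherits(phantom, "phantom")) stop("'phantom' must be a phantom", call. = FALSE)
  orientation <- match.arg(orientation)

  if (orientation == "frontal") {
    pts <- do.call(rbind, phantom$plate_patches)
    coord <- pts[, "y"]
    start <- phantom$plate_ventral_edge_y
    extent <- phantom$plate_extent_mm
  } else {
    pts <- phantom$trochanter_points
    coord <- pts[, "z"]
    start <- phantom$trochanter_z_range[2L]
    extent <- diff(phantom$trochanter_z_range)
  }
  thickness_mm <- thickness_mm %||% (extent / if (orientation == "frontal") 12 else 9)
  if (!is.numeric(thickness_mm) || thickness_mm <= 0) {
    stop("thickness_mm must be positive", call. = FALSE)
  }
  n <- ceiling(extent / thickness_mm - 1e-9)
  # slab j spans (start - j*t, start - (j-1)*t]; stacks run ventral->dorsal
  # (frontal) or cranial->caudal (axial), i.e. decreasing coordinate
  idx <- ceiling((start - coord) / thickness_mm - 1e-9)
  idx[idx < 1L] <- 1L
  slices <- lapply(seq_len(n), function(j) pts[idx == j, , drop = FALSE])
  keep <- vapply(slices, nrow, integer(1L)) > 0L
  if (!any(keep)) {
    stop("slice stack is empty: the ", orientation,
         " slabs do not intersect the target structure", call. = FALSE)
  }
  slices <- slices[keep]
  centers <- (start - (seq_len(n) - 0.5) * thickness_mm)[keep]
  stack <- structure(
    list(orientation = orientation, thickness_mm = thickness_mm,
         slices = slices, slice_centers = centers,
         calibration_index = NA_integer_, labels = integer(length(slices))),
    class = "slice_stack"
  )
  cal <- find_calibration_slice(stack)
  stack$calibration_index <- cal
  ref <- if (orientation == "frontal") 6L else 5L
  stack$labels <- ref + (seq_along(slices) - cal)
  stack
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("%s slice stack: %d slices of %.3f mm, calibration slice %d (label %d)\n",
              x$orientation, length(x$slices), x$thickness_mm,
              x$calibration_index,
              x$labels[x$calibration_index]))
  invisible(x)
}

.polyline_length <- function(m) {
  if (nrow(m) < 2L) return(0)
  sum(sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

.max_diameter <- function(m) {
  if (nrow(m) < 2L) return(0)
  max(stats::dist(m))
}

#' Select the calibration slice
#'
#' Frontal stacks: the slice with the maximal plate-trace arc length (the
#' slice of maximum longitudinal plate extent). Axial stacks: the slice with
#' the largest trochanter diameter (maximal pairwise point distance). Ties
#' are broken toward the more ventral (frontal) or cranial (axial) slice.
#' Both metrics are invariant to translation, and the argmax to isotropic
#' scaling.
#'
#' @param stack a [slice_phantom()] stack.
#' @return Integer position of the calibration slice within `stack$slices`.
#' @export
find_calibration_slice <- function(stack) {
  if (!inherits(stack, "slice_stack")) {
    stop("'stack' must be a slice_stack", call. = FALSE)
  }
  if (!length(stack$slices)) stop("empty slice stack", call. = FALSE)
  metric <- if (stack$orientation == "frontal") .polyline_length else .max_diameter
  scores <- vapply(stack$slices, metric, numeric(1L))
  which.max(scores)  # which.max returns the first (most ventral/cranial) tie
}

#' Layer label from a signed offset to the reference layer
#'
#' Axial stacks use reference label 5: a slice `x` layers cranial to the
#' reference gets label `5 - x` and a slice `y` layers caudal gets `5 + y`.
#' Frontal stacks use the analogous scheme around label 6 (`6 - v` ventral,
#' `6 + d` dorsal). Offsets are signed: positive toward dorsal/caudal.
#'
#' @param offset_from_reference signed integer offset (dorsal/caudal > 0).
#' @param orientation `"frontal"` or `"axial"`.
#' @return Integer layer label.
#' @seealso [layer_offset()] for the inverse map.
#' @examples
#' layer_index(-2, "axial")  # 3
#' layer_index(3, "frontal") # 9
#' @export
layer_index <- function(offset_from_reference,
                        orientation = c("frontal", "axial")) {
  orientation <- match.arg(orientation)
  off <- offset_from_reference
  if (!is.numeric(off) || length(off) != 1L || off != round(off)) {
    stop("offset must be a single integer", call. = FALSE)
  }
  ref <- if (orientation == "frontal") 6L else 5L
  nmax <- if (orientation == "frontal") 12L else 9L
  label <- ref + as.integer(off)
  if (label < 1L || label > nmax) {
    stop("offset ", off, " falls outside the ", orientation,
         " stack bounds (labels 1..", nmax, ")", call. = FALSE)
  }
  label
}

#' Signed offset from a layer label
#'
#' Inverse of [layer_index()].
#'
#' @param label integer layer label (1..12 frontal, 1..9 axial).
#' @param orientation `"frontal"` or `"axial"`.
#' @return Signed integer offset from the reference layer.
#' @export
layer_offset <- function(label, orientation = c("frontal", "axial")) {
  orientation <- match.arg(orientation)
  ref <- if (orientation == "frontal") 6L else 5L
  nmax <- if (orientation == "frontal") 12L else 9L
  if (!is.numeric(label) || length(label) != 1L || label != round(label) ||
      label < 1 || label > nmax) {
    stop("label must be an integer in 1..", nmax, call. = FALSE)
  }
  as.integer(label) - ref
}
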