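# Plain-text serialization of phantoms and stacks. One directory per
# phantom: delimited tables for landmarks, attachments, plate traces and
# trochanter points, plus a YAML spec document. All numeric columns are
# written with fixed precision so identical inputs give identical bytes.

.PHANTOM_PRECISION <- 6L  # decimal places; 1e-6 mm, below any tolerance used

#' Write a phantom to a directory
#'
#' @param phantom a phantom.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_phantom()]
#' @export
write_phantom <- function(phantom, dir) {
  if (!inherits(phantom, "phantom")) stop("'phantom' must be a phantom", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lm <- phantom$landmarks
  landmarks <- data.frame(
    structure = names(lm), point_role = "landmark",
    x_mm = vapply(lm, `[`, numeric(1L), 1L),
    y_mm = vapply(lm, `[`, numeric(1L), 2L),
    z_mm = vapply(lm, `[`, numeric(1L), 3L)
  )
  write_tsv(landmarks, file.path(dir, "landmarks.tsv"), .PHANTOM_PRECISION)

  att <- phantom$attachments
  attachments <- rbind(
    data.frame(structure = att$muscle, plane = att$plane, region = att$region,
               group = att$group, point_role = "femoral",
               x_mm = att$fx, y_mm = att$fy, z_mm = att$fz),
    data.frame(structure = att$muscle, plane = att$plane, region = att$region,
               group = att$group, point_role = "pelvic",
               x_mm = att$px, y_mm = att$py, z_mm = att$pz)
  )
  write_tsv(attachments, file.path(dir, "attachments.tsv"), .PHANTOM_PRECISION)

  patches <- do.call(rbind, lapply(seq_along(phantom$plate_patches), function(k) {
    p <- phantom$plate_patches[[k]]
    data.frame(layer = k, point_index = seq_len(nrow(p)),
               x_mm = p[, 1L], y_mm = p[, 2L], z_mm = p[, 3L])
  }))
  write_tsv(patches, file.path(dir, "plate_patches.tsv"), .PHANTOM_PRECISION)

  tp <- phantom$trochanter_points
  write_tsv(data.frame(point_index = seq_len(nrow(tp)),
                       x_mm = tp[, 1L], y_mm = tp[, 2L], z_mm = tp[, 3L]),
            file.path(dir, "trochanter_points.tsv"), .PHANTOM_PRECISION)

  spec <- phantom$meta$spec
  yaml::write_yaml(
    list(ccd_angle = spec$ccd_angle,
         anteversion = spec$anteversion,
         scale_mm = spec$scale_mm,
         plate_extent_mm = spec$plate_extent_mm,
         age_group = spec$age_group,
         warp_deg = as.numeric(spec$warp),
         attachment_group = spec$attachment_map$group[1L],
         seed = phantom$meta$seed,
         noise_sd_mm = phantom$meta$noise_sd_mm,
         patient_id = phantom$meta$patient_id,
         plate_ventral_edge_y = phantom$plate_ventral_edge_y,
         trochanter_z_range = phantom$trochanter_z_range),
    file.path(dir, "spec.yaml")
  )
  invisible(dir)
}

#' Read a phantom directory
#'
#' Reconstructs a phantom written by [write_phantom()]. Coordinates round-trip
#' at the serialization precision (1e-6 mm).
#'
#' @param dir directory written by [write_phantom()].
#' @return A `phantom`.
#' @export
read_phantom <- function(dir) {
  need <- c("landmarks.tsv", "attachments.tsv", "plate_patches.tsv",
            "trochanter_points.tsv", "spec.yaml")
  if (!all(file.exists(file.path(dir, need)))) {
    stop("'", dir, "' is not a phantom directory (missing ",
         paste(setdiff(need, list.files(dir)), collapse = ", "), ")",
         call. = FALSE)
  }
  meta <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  lms <- utils::read.delim(file.path(dir, "landmarks.tsv"))
  landmarks <- lapply(seq_len(nrow(lms)), function(i) {
    c(lms$x_mm[i], lms$y_mm[i], lms$z_mm[i])
  })
  names(landmarks) <- lms$structure

  at <- utils::read.delim(file.path(dir, "attachments.tsv"))
  fem <- at[at$point_role == "femoral", ]
  pel <- at[at$point_role == "pelvic", ]
  key <- function(d) paste(d$structure, d$plane, d$region, d$group)
  pel <- pel[match(key(fem), key(pel)), ]
  attachments <- data.frame(
    muscle = fem$structure, plane = fem$plane, region = fem$region,
    group = fem$group,
    fx = fem$x_mm, fy = fem$y_mm, fz = fem$z_mm,
    px = pel$x_mm, py = pel$y_mm, pz = pel$z_mm,
    stringsAsFactors = FALSE
  )

  pp <- utils::read.delim(file.path(dir, "plate_patches.tsv"))
  patches <- lapply(sort(unique(pp$layer)), function(k) {
    rows <- pp[pp$layer == k, ]
    rows <- rows[order(rows$point_index), ]
    m <- as.matrix(rows[, c("x_mm", "y_mm", "z_mm")])
    colnames(m) <- c("x", "y", "z")
    m
  })

  tp <- utils::read.delim(file.path(dir, "trochanter_points.tsv"))
  troch <- as.matrix(tp[order(tp$point_index), c("x_mm", "y_mm", "z_mm")])
  colnames(troch) <- c("x", "y", "z")

  spec <- phantom_spec(
    ccd_angle = meta$ccd_angle, anteversion = meta$anteversion,
    scale_mm = meta$scale_mm, warp = warp_profile(meta$warp_deg),
    plate_extent_mm = meta$plate_extent_mm,
    age_group = meta$age_group,
    attachment_map = default_attachment_map(meta$attachment_group)
  )
  structure(
    list(plate_patches = patches,
         plate_extent_mm = meta$plate_extent_mm,
         plate_ventral_edge_y = meta$plate_ventral_edge_y,
         trochanter_points = troch,
         trochanter_z_range = as.numeric(meta$trochanter_z_range),
         landmarks = landmarks,
         attachments = attachments,
         meta = list(spec = spec, seed = meta$seed,
                     noise_sd_mm = meta$noise_sd_mm,
                     patient_id = meta$patient_id)),
    class = "phantom"
  )
}

#' Write a slice stack as delimited text
#'
#' One row per trace point (`slice_label`, `point_index`, `x_mm`, `y_mm`,
#' `z_mm`) plus a YAML metadata document.
#'
#' @param stack a [slice_phantom()] stack.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_slice_stack <- function(stack, dir) {
  if (!inherits(stack, "slice_stack")) stop("'stack' must be a slice_stack", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(seq_along(stack$slices), function(i) {
    s <- stack$slices[[i]]
    data.frame(slice_label = stack$labels[i], point_index = seq_len(nrow(s)),
               x_mm = s[, 1L], y_mm = s[, 2L], z_mm = s[, 3L])
  }))
  write_tsv(rows, file.path(dir, "slices.tsv"), .PHANTOM_PRECISION)
  yaml::write_yaml(
    list(orientation = stack$orientation,
         thickness_mm = stack$thickness_mm,
         n_slices = length(stack$slices),
         calibration_index = stack$calibration_index,
         calibration_label = stack$labels[stack$calibration_index]),
    file.path(dir, "stack.yaml")
  )
  invisible(dir)
}
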