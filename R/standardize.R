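#' Two-point synapse annotation
#'
#' The manual annotation that defines a cell couple's geometry: the frame
#' of tight coupling, the interface centre, and the cell rear pole. The
#' rear-to-centre axis is the cell's symmetry axis; reorientation maps it
#' onto the template's vertical axis with the interface facing up.
#'
#' @param coupling_frame frame index of tight cell coupling (1-based).
#' @param interface_center,cell_rear length-3 um coordinates; must differ.
#' @return object of class `synapse_annotation`.
#' @export
synapse_annotation <- function(coupling_frame, interface_center, cell_rear) {
  interface_center <- as.numeric(interface_center)
  cell_rear <- as.numeric(cell_rear)
  stopifnot(length(interface_center) == 3, length(cell_rear) == 3,
            coupling_frame >= 1)
  if (sqrt(sum((interface_center - cell_rear)^2)) < 1e-9) {
    stop("annotation points coincide; synapse axis is degenerate")
  }
  structure(
    list(coupling_frame = as.integer(coupling_frame),
         interface_center = interface_center, cell_rear = cell_rear),
    class = "synapse_annotation"
  )
}

#' Detect the frame of tight cell coupling
#'
#' Time zero of every couple is the frame where the T cell:APC interface
#' first reaches its full width or the cells have been in contact for
#' 40 s, whichever comes first. "Full width" is operationalized as 90% of
#' the steady-state width, itself the median width over the final quarter
#' of the movie; the 40 s clause is `contact_frames_40s` frames after first
#' contact at the default 20 s frame interval.
#'
#' @param contact_widths numeric vector of per-frame interface widths (um);
#'   0 (or NA) means no contact.
#' @param full_width_fraction fraction of steady-state width counting as
#'   full (default 0.9).
#' @param contact_frames_40s number of frames corresponding to 40 s of
#'   contact (default 2 at a 20 s interval).
#' @return integer frame index (1-based).
#' @examples
#' detect_tight_coupling(c(0, 0, 3, 3, 3, 3, 3, 3))
#' @export
detect_tight_coupling <- function(contact_widths,
                                  full_width_fraction = 0.9,
                                  contact_frames_40s = 2L) {
  w <- as.numeric(contact_widths)
  w[is.na(w)] <- 0
  if (!any(w > 0)) stop("no cell couple: no contact in any frame")
  first_contact <- which(w > 0)[1]
  n <- length(w)
  steady <- median(w[seq(max(1, ceiling(0.75 * n + 1e-9)), n)])
  full <- which(w >= full_width_fraction * steady)[1]
  if (is.na(full)) full <- n
  as.integer(min(full, first_contact + contact_frames_40s))
}

#' Segment the T cell around a seed point
#'
#' Thresholds the volume at an Otsu level computed on the neighbourhood of
#' the seed (a box of twice the expected cell radius) and keeps the
#' connected component containing the seed.
#'
#' @param volume 3D intensity array.
#' @param axes voxel-centre axes in um (list with `x`, `y`, `z`).
#' @param seed_point length-3 um coordinate inside the cell.
#' @param radius_hint expected cell radius in um (sets the Otsu
#'   neighbourhood).
#' @return list with `mask` (logical array), `threshold`, and `truncated`
#'   (TRUE when more than a quarter of the mask surface touches the volume
#'   border, flagging a clipped cell; a warning is also raised).
#' @export
segment_t_cell <- function(volume, axes, seed_point, radius_hint = 5) {
  stopifnot(length(seed_point) == 3)
  dm <- dim(volume)
  si <- round(c(
    (seed_point[1] - axes$x[1]) / (axes$x[2] - axes$x[1]),
    (seed_point[2] - axes$y[1]) / (axes$y[2] - axes$y[1]),
    if (length(axes$z) > 1) (seed_point[3] - axes$z[1]) / (axes$z[2] - axes$z[1]) else 0
  )) + 1
  if (any(si < 1) || any(si > dm)) stop("seed point outside the volume")

  # Otsu on the neighbourhood of the seed
  spacing <- c(axes$x[2] - axes$x[1], axes$y[2] - axes$y[1],
               if (length(axes$z) > 1) axes$z[2] - axes$z[1] else 1)
  half <- pmax(1, round(2 * radius_hint / spacing))
  rng <- lapply(1:3, function(d) {
    seq(max(1, si[d] - half[d]), min(dm[d], si[d] + half[d]))
  })
  nb <- volume[rng[[1]], rng[[2]], rng[[3]]]
  thr <- otsu_threshold(nb)
  fg <- volume > thr
  if (!fg[si[1], si[2], si[3]]) {
    stop("seed point lies below the segmentation threshold (background?)")
  }
  seed_idx <- si[1] + dm[1] * (si[2] - 1 + dm[2] * (si[3] - 1))
  mask <- flood_from_seed(fg, seed_idx, connectivity = 6L)

  # truncation check: surface voxels on the array border
  border <- array(FALSE, dm)
  border[c(1, dm[1]), , ] <- TRUE
  border[, c(1, dm[2]), ] <- TRUE
  border[, , c(1, dm[3])] <- TRUE
  surf <- mask & !erode_once(mask)
  truncated <- sum(surf & border) > 0.25 * sum(surf)
  if (truncated) warning("segmented cell touches the volume border (truncated)")
  list(mask = mask, threshold = thr, truncated = truncated)
}

# One step of 6-connected erosion.
erode_once <- function(mask) {
  out <- mask
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    out <- out & shift3d(mask, off, fill = FALSE)
  }
  out
}

#' Reorient a cell with the interface facing up
#'
#' Rigidly rotates volume and mask so the annotated rear-to-interface axis
#' points along +z (interface up). Rotation is about the midpoint of the
#' two annotation points; intensities are resampled by trilinear
#' interpolation (total masked intensity is conserved to within about 1%).
#' When the axis already points up the input is returned unchanged.
#'
#' @param volume 3D intensity array.
#' @param mask logical cell mask of the same dimensions.
#' @param axes voxel-centre axes in um.
#' @param annotation a [synapse_annotation()].
#' @return list with rotated `volume`, `mask`, the same `axes`, the updated
#'   `annotation`, and `angle` (rotation angle in radians).
#' @export
reorient_interface_up <- function(volume, mask, axes, annotation) {
  stopifnot(inherits(annotation, "synapse_annotation"))
  axis_vec <- annotation$interface_center - annotation$cell_rear
  len <- sqrt(sum(axis_vec^2))
  if (len < 1e-9) stop("degenerate synapse axis")
  u <- axis_vec / len
  ang <- acos(pmin(1, pmax(-1, u[3])))
  if (ang < 1e-6) {
    return(list(volume = volume, mask = mask, axes = axes,
                annotation = annotation, angle = 0))
  }
  Rm <- rotation_between(u, c(0, 0, 1))
  centre <- (annotation$interface_center + annotation$cell_rear) / 2
  co <- axes_coords(axes)
  # inverse mapping: source point for each output voxel
  src <- sweep(sweep(co, 2, centre) %*% Rm, 2, centre, "+")
  dm <- dim(volume)
  vol_rot <- array(interp_trilinear(volume, axes, src), dm)
  mask_rot <- array(interp_trilinear(mask + 0, axes, src) > 0.5, dm)
  # a rigid rotation conserves photons; undo the slight interpolation loss
  # across the coarse axial axis by rescaling the masked intensity
  before <- sum(volume[mask])
  after <- sum(vol_rot[mask_rot])
  if (after > 0) vol_rot <- vol_rot * (before / after)
  rot_pt <- function(p) as.numeric(Rm %*% (p - centre) + centre)
  ann2 <- synapse_annotation(annotation$coupling_frame,
                             rot_pt(annotation$interface_center),
                             rot_pt(annotation$cell_rear))
  list(volume = vol_rot, mask = mask_rot, axes = axes,
       annotation = ann2, angle = ang)
}

#' Map a reoriented cell onto the half-spheroid template
#'
#' Resamples the masked fluorescence of an interface-up cell onto the
#' template by radial shape mapping: for every template voxel, the ray from
#' the template centroid through that voxel is matched to the same-direction
#' ray from the cell centroid, the cell's radial extent along the ray is
#' linearly rescaled to the template's, and intensity is sampled by
#' trilinear interpolation. The resulting vector is normalized to sum 1, so
#' entries are probabilities (fractions of total intensity).
#'
#' @param volume 3D intensity array, interface up.
#' @param mask logical cell mask.
#' @param axes voxel-centre axes in um.
#' @param template a [build_template()] result.
#' @param ray_step ray-marching step in um used to find the cell boundary.
#' @return object of class `standardized_cell`: numeric `vector` of length
#'   `template$n_voxels` summing to 1, plus the template reference.
#' @export
standardize_shape <- function(volume, mask, axes, template, ray_step = 0.1) {
  stopifnot(inherits(template, "half_spheroid_template"))
  if (!any(mask)) stop("empty cell mask")
  co_mask <- axes_coords(axes)[which(mask), , drop = FALSE]
  cen_cell <- colMeans(co_mask)
  max_r <- sqrt(max(rowSums(sweep(co_mask, 2, cen_cell)^2))) + 1

  a <- template$semi_axes[["lateral"]]
  c_ax <- template$semi_axes[["axial"]]
  # template coordinates: flat face at z = 0, dome at negative z
  tp <- cbind(template$voxels$x, template$voxels$y, -template$voxels$depth)
  cen_tpl <- colMeans(tp)
  dirs <- sweep(tp, 2, cen_tpl)
  d_t <- sqrt(rowSums(dirs^2))
  d_t[d_t < 1e-12] <- 1e-12
  u <- dirs / d_t

  # template boundary along each ray: nearest hit on the ellipsoid dome
  # (z <= 0) or the flat face z = 0
  inv <- c(1 / a^2, 1 / a^2, 1 / c_ax^2)
  A <- (u^2) %*% inv
  Bq <- 2 * (u %*% (cen_tpl * inv))
  Cq <- sum(cen_tpl^2 * inv) - 1
  disc <- pmax(0, Bq^2 - 4 * A * Cq)
  t_ell <- as.numeric((-Bq + sqrt(disc)) / (2 * A))
  z_hit <- cen_tpl[3] + t_ell * u[, 3]
  t_face <- ifelse(u[, 3] > 1e-12, -cen_tpl[3] / u[, 3], Inf)
  R_t <- ifelse(z_hit <= 1e-9, t_ell, t_face)
  R_t <- pmax(R_t, 1e-9)

  # cell boundary along the same directions by ray marching in the mask
  steps <- seq(0, max_r, by = ray_step)
  inside_prev <- rep(TRUE, nrow(u))
  R_c <- rep(NA_real_, nrow(u))
  for (s in steps[-1]) {
    pts <- sweep(u * s, 2, cen_cell, "+")
    inside <- interp_trilinear(mask + 0, axes, pts) > 0.5
    newly_out <- inside_prev & !inside
    R_c[newly_out] <- s - ray_step
    inside_prev <- inside & inside_prev
  }
  R_c[is.na(R_c)] <- max_r
  R_c <- pmax(R_c, ray_step)

  q <- u * (d_t / R_t * R_c)
  q <- sweep(q, 2, cen_cell, "+")
  # mask-weighted sampling removes partial-volume attenuation at the cell
  # boundary (a constant cell maps to a constant vector)
  w <- interp_trilinear(mask + 0, axes, q)
  vals <- interp_trilinear(volume * (mask + 0), axes, q)
  vals <- ifelse(w > 0.25, vals / w, 0)
  vals[vals < 0] <- 0
  tot <- sum(vals)
  if (tot <= 0) stop("no intensity inside the mask to standardize")
  structure(
    list(vector = vals / tot, n_voxels = template$n_voxels,
         semi_axes = template$semi_axes),
    class = "standardized_cell"
  )
}

#' @export
print.standardized_cell <- function(x, ...) {
  cat(sprintf("standardized_cell: %d probabilities (sum %.6f)\n",
              x$n_voxels, sum(x$vector)))
  invisible(x)
}
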