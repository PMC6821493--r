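#' Simulation configuration for synthetic cell-couple movies
#'
#' Bundles the acquisition and cell-geometry constants used by the
#' synthetic-data generator. Defaults mirror a spinning-disk time-lapse
#' acquisition: voxels of 0.34 um laterally and 1 um axially, one 3D stack
#' every 20 s for 46 frames.
#'
#' @param voxel_spacing numeric length-3, voxel size in um (x, y, z).
#' @param frame_interval frame interval in seconds.
#' @param n_frames number of frames in a movie.
#' @param t_cell_radius T-cell radius in um.
#' @param interface_radius radius of the planar contact disc in um; must be
#'   smaller than `t_cell_radius`.
#' @param apc_radius radius of the (unlabelled, dark) APC in um.
#' @param background_intensity cellular background fluorescence in
#'   arbitrary units.
#' @param accumulation_contrast intensity of the accumulation region as a
#'   multiple of background; must exceed 1 for a detectable region.
#' @param noise_model list with `poisson_scale` (expected photons per voxel
#'   at background intensity; shot noise) and `gaussian_sd` (additive read
#'   noise, as a fraction of background). Set `poisson_scale = Inf` and
#'   `gaussian_sd = 0` for noise-free volumes.
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical output.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_frames = 5, seed = 1)
#' cfg
#' @export
sim_config <- function(voxel_spacing = c(0.34, 0.34, 1),
                       frame_interval = 20,
                       n_frames = 46,
                       t_cell_radius = 5,
                       interface_radius = 3,
                       apc_radius = 5,
                       background_intensity = 100,
                       accumulation_contrast = 2,
                       noise_model = list(poisson_scale = 50, gaussian_sd = 0.02),
                       seed = 1L) {
  stopifnot(
    length(voxel_spacing) == 3, all(voxel_spacing > 0),
    frame_interval > 0, n_frames >= 1,
    t_cell_radius > 0, interface_radius > 0,
    interface_radius < t_cell_radius,
    apc_radius > 0, background_intensity > 0,
    accumulation_contrast >= 1
  )
  if (!is.list(noise_model) ||
      !all(c("poisson_scale", "gaussian_sd") %in% names(noise_model))) {
    stop("noise_model must list poisson_scale and gaussian_sd")
  }
  structure(
    list(
      voxel_spacing = as.numeric(voxel_spacing),
      frame_interval = frame_interval,
      n_frames = as.integer(n_frames),
      t_cell_radius = t_cell_radius,
      interface_radius = interface_radius,
      apc_radius = apc_radius,
      background_intensity = background_intensity,
      accumulation_contrast = accumulation_contrast,
      noise_model = noise_model,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic couple configuration\n")
  cat(sprintf(
    "  voxels %.2f x %.2f x %.2f um, %d frames every %g s\n",
    x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3],
    x$n_frames, x$frame_interval
  ))
  cat(sprintf(
    "  T cell radius %g um, interface radius %g um, contrast %gx background\n",
    x$t_cell_radius, x$interface_radius, x$accumulation_contrast
  ))
  cat(sprintf(
    "  noise: %s photons at background, read sd %g x background, seed %d\n",
    format(x$noise_model$poisson_scale), x$noise_model$gaussian_sd, x$seed
  ))
  invisible(x)
}

#' Pattern labels recognised by the classifier
#'
#' The six mutually exclusive interface patterns plus `"none"`.
#' @return Character vector of the seven labels.
#' @export
pattern_labels <- function() {
  c("none", "central", "invagination", "diffuse", "lamellal",
    "peripheral", "asymmetric")
}

#' Per-frame pattern script for a synthetic cell couple
#'
#' Describes the intended interface pattern for each frame of a synthetic
#' movie together with the geometry used to render it. Geometry arguments
#' are recycled along the script.
#'
#' @param labels character vector of per-frame labels from
#'   [pattern_labels()].
#' @param patch_fraction for `central`: patch radius as a fraction of the
#'   interface radius.
#' @param radial_fraction for rim patterns: centre of the annulus/arc as a
#'   fraction of the interface radius.
#' @param angular_width for `asymmetric`: azimuthal width of the rim patch
#'   in degrees.
#' @param depth for `invagination`: depth of the intrusion below the
#'   interface plane in um (>= 1 um by definition of the pattern).
#'
#' @return An object of class `pattern_script` (data frame, one row per
#'   frame).
#' @examples
#' pattern_script(c("none", "central", "central"))
#' @export
pattern_script <- function(labels,
                           patch_fraction = 0.45,
                           radial_fraction = 0.85,
                           angular_width = 75,
                           depth = 2) {
  labels <- as.character(labels)
  bad <- setdiff(labels, pattern_labels())
  if (length(bad)) {
    stop("unknown pattern label(s): ", paste(unique(bad), collapse = ", "))
  }
  if (any(labels == "invagination") && any(depth < 1)) {
    stop("invagination depth must be >= 1 um")
  }
  n <- length(labels)
  structure(
    data.frame(
      label = labels,
      patch_fraction = rep_len(patch_fraction, n),
      radial_fraction = rep_len(radial_fraction, n),
      angular_width = rep_len(angular_width, n),
      depth = rep_len(depth, n),
      stringsAsFactors = FALSE
    ),
    class = c("pattern_script", "data.frame")
  )
}
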