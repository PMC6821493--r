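#' Simulate a 4D movie of a T cell:APC couple
#'
#' Renders a T cell as a sphere truncated by a planar contact disc
#' (interface facing up, +z), with a scripted micrometre-scale accumulation
#' region at a defined contrast over the cellular background, imaged on an
#' anisotropic voxel grid with Poisson shot noise and Gaussian read noise.
#' The APC above the interface is unlabelled and therefore dark. Ground
#' truth (per-frame label, region voxels, cell mask, synapse geometry) is
#' returned alongside and is never consumed by the analysis operations.
#'
#' @param config a [sim_config()].
#' @param script a [pattern_script()]; frames beyond the script length are
#'   rendered without accumulation (`"none"`).
#' @param coupling_frame frame at which tight coupling occurs (used to
#'   time-align cohort tabulations; rendering is identical across frames).
#'
#' @return A list with elements `series` (class `volume_series`: 4D array
#'   `data` indexed \[x, y, z, t\], voxel-centre `axes` in um, `spacing`,
#'   `frame_interval`) and `truth` (class `ground_truth`).
#' @examples
#' cfg <- sim_config(n_frames = 1, noise_model = list(poisson_scale = Inf,
#'                                                    gaussian_sd = 0))
#' cc <- make_cell_couple(cfg, pattern_script("central"))
#' dim(cc$series$data)
#' @export
make_cell_couple <- function(config, script = pattern_script("none"),
                             coupling_frame = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(script, "pattern_script")) {
    script <- pattern_script(script)
  }
  if (nrow(script) > config$n_frames) {
    stop("script length exceeds config$n_frames")
  }
  R <- config$t_cell_radius
  ri <- config$interface_radius
  if (any(script$depth[script$label == "invagination"] > 2 * R)) {
    stop("scripted invagination depth exceeds the cell diameter")
  }
  if (any(script$patch_fraction <= 0 | script$patch_fraction > 1)) {
    stop("patch_fraction must lie in (0, 1]")
  }
  set.seed(config$seed)

  sp <- config$voxel_spacing
  d_int <- sqrt(R^2 - ri^2) # z of the contact plane (cell centred at origin)
  # z grid aligned so voxel centres sit at d_int - dz/2, d_int - 3dz/2, ...
  dz <- sp[3]
  n_below <- ceiling((d_int + R + 1.5) / dz)
  zs <- d_int - dz / 2 - dz * (n_below - 1):0
  zs <- c(zs, d_int + dz / 2, d_int + 3 * dz / 2) # head room above interface
  nx <- floor((R + 1.5) / sp[1])
  axes <- list(x = seq(-nx, nx) * sp[1], y = seq(-nx, nx) * sp[2], z = zs)
  co <- axes_coords(axes)
  dm <- c(length(axes$x), length(axes$y), length(axes$z))

  r2 <- co[, 1]^2 + co[, 2]^2 + co[, 3]^2
  cell <- r2 <= R^2 & co[, 3] <= d_int
  cell_mask <- array(cell, dm)

  # pad script with "none" to the full movie length
  full <- pattern_script(rep("none", config$n_frames))
  if (nrow(script) > 0) full[seq_len(nrow(script)), ] <- script
  # without contrast there is no accumulation: the realized label is "none"
  if (config$accumulation_contrast <= 1) full$label[] <- "none"

  B <- config$background_intensity
  data <- array(0, c(dm, config$n_frames))
  region_idx <- vector("list", config$n_frames)
  for (t in seq_len(config$n_frames)) {
    idx <- scripted_region_indices(full[t, ], co, cell, config, d_int)
    region_idx[[t]] <- idx
    expect <- numeric(prod(dm))
    expect[cell] <- B
    expect[idx] <- B * config$accumulation_contrast
    data[, , , t] <- array(apply_noise(expect, config), dm)
  }

  series <- structure(
    list(
      data = data, axes = axes, spacing = sp,
      frame_interval = config$frame_interval,
      coupling_frame = as.integer(coupling_frame)
    ),
    class = "volume_series"
  )
  truth <- structure(
    list(
      labels = full$label,
      region_indices = region_idx,
      cell_mask = cell_mask,
      cell_center = c(0, 0, 0),
      interface_center = c(0, 0, d_int),
      cell_rear = c(0, 0, -R),
      interface_radius = ri,
      coupling_frame = as.integer(coupling_frame)
    ),
    class = "ground_truth"
  )
  list(series = series, truth = truth)
}

# Voxel indices of the scripted accumulation region for one frame.
# Geometry conventions (all in um, depth measured below the contact plane):
#   central       patch disc of radius patch_fraction * r_i, <= 1 um deep
#   invagination  cylinder of radius 0.6 into the cell body, `depth` um deep
#   diffuse       interface shell plus a cortical band (<= 0.8 um from the
#                 cell surface) reaching 2.5 um beyond the interface rim
#   lamellal      thin (< 1 um) slab across the whole interface
#   peripheral    full annulus at the interface rim
#   asymmetric    single rim arc of `angular_width` degrees
scripted_region_indices <- function(row, co, cell, config, d_int) {
  if (row$label == "none") return(integer(0))
  R <- config$t_cell_radius
  ri <- config$interface_radius
  depth_v <- d_int - co[, 3]
  rho <- sqrt(co[, 1]^2 + co[, 2]^2)
  sel <- switch(row$label,
    central = rho <= row$patch_fraction * ri & depth_v <= 1.0,
    invagination = rho <= 0.6 & depth_v <= row$depth,
    diffuse = {
      r <- sqrt(rho^2 + co[, 3]^2)
      depth_v <= 1.0 | (R - r <= 0.8 & depth_v <= 2.5)
    },
    lamellal = depth_v <= 0.9,
    peripheral = rho >= (row$radial_fraction - 0.15) * ri & rho <= ri &
      depth_v <= 1.0,
    asymmetric = {
      ang <- atan2(co[, 2], co[, 1]) * 180 / pi
      rho >= (row$radial_fraction - 0.15) * ri & rho <= ri &
        depth_v <= 1.0 & abs(ang) <= row$angular_width / 2
    },
    stop("unhandled label ", row$label)
  )
  which(sel & cell & depth_v >= 0)
}

# Poisson shot noise (scaled to `poisson_scale` expected photons at
# background) plus additive Gaussian read noise.
apply_noise <- function(expected, config) {
  B <- config$background_intensity
  ps <- config$noise_model$poisson_scale
  gs <- config$noise_model$gaussian_sd
  out <- expected
  if (is.finite(ps)) {
    out <- rpois(length(expected), expected / B * ps) * B / ps
  }
  if (gs > 0) {
    out <- out + rnorm(length(expected), 0, gs * B)
  }
  out
}

#' @export
print.volume_series <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf(
    "volume_series: %d x %d x %d voxels, %d frame(s), %g s interval\n",
    dm[1], dm[2], dm[3], dm[4], x$frame_interval
  ))
  cat(sprintf(
    "  spacing %.2f x %.2f x %.2f um, coupling frame %d\n",
    x$spacing[1], x$spacing[2], x$spacing[3], x$coupling_frame
  ))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$labels), "frame(s); labels:",
      paste(unique(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one frame of a volume series as a 3D array
#'
#' @param series a `volume_series`.
#' @param frame frame index (1-based).
#' @return 3D numeric array indexed \[x, y, z\].
#' @export
get_frame <- function(series, frame) {
  stopifnot(frame >= 1, frame <= dim(series$data)[4])
  series$data[, , , frame]
}

#' Simulate a cohort of cell couples from a pattern-frequency schedule
#'
#' Draws each cell's per-frame pattern label independently from a
#' per-time-point probability schedule (a multinomial draw per cell and
#' frame) and renders each cell with [make_cell_couple()]. The cohort is
#' reproducible from `config$seed`; per-cell seeds are derived from it.
#'
#' @param n_cells number of cell couples (0 gives an empty cohort).
#' @param frequency_schedule numeric matrix of label probabilities with one
#'   row per frame (a single row is recycled) and columns named after
#'   labels from [pattern_labels()]. Each row must sum to 1 (tolerance
#'   1e-9).
#' @param config a [sim_config()].
#' @param coupling_frame frame of tight coupling used for time alignment.
#'
#' @return An object of class `couple_cohort`: a list with `couples` (list
#'   of `make_cell_couple()` results), `schedule`, and `labels` (cells x
#'   frames character matrix of realized ground-truth labels).
#' @examples
#' sched <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("none", "central")))
#' coh <- make_cohort(2, sched, sim_config(n_frames = 2, seed = 7))
#' coh$labels
#' @export
make_cohort <- function(n_cells, frequency_schedule, config,
                        coupling_frame = 3L) {
  stopifnot(inherits(config, "sim_config"), n_cells >= 0)
  sched <- as.matrix(frequency_schedule)
  if (is.null(colnames(sched)) ||
      !all(colnames(sched) %in% pattern_labels())) {
    stop("frequency_schedule columns must be named after pattern labels")
  }
  if (any(sched < 0 | sched > 1)) {
    stop("schedule probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(sched) - 1) > 1e-9)) {
    stop("schedule rows must sum to 1 (tolerance 1e-9)")
  }
  if (nrow(sched) == 1) {
    sched <- sched[rep(1, config$n_frames), , drop = FALSE]
  }
  if (nrow(sched) != config$n_frames) {
    stop("frequency_schedule must have 1 or n_frames rows")
  }

  if (n_cells == 0) {
    return(structure(
      list(couples = list(), schedule = sched,
           labels = matrix(character(), 0, config$n_frames)),
      class = "couple_cohort"
    ))
  }

  set.seed(config$seed)
  labs <- matrix("", n_cells, config$n_frames)
  for (t in seq_len(config$n_frames)) {
    labs[, t] <- sample(colnames(sched), n_cells, replace = TRUE,
                        prob = sched[t, ])
  }
  couples <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    couples[[i]] <- make_cell_couple(cfg_i, pattern_script(labs[i, ]),
                                     coupling_frame = coupling_frame)
  }
  structure(
    list(couples = couples, schedule = sched, labels = labs),
    class = "couple_cohort"
  )
}

#' @export
print.couple_cohort <- function(x, ...) {
  cat(sprintf("couple_cohort: %d cell couple(s), %d frame(s)\n",
              length(x$couples), ncol(x$labels)))
  invisible(x)
}
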