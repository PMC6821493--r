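#' Classifier thresholds for the six interface patterns
#'
#' All numeric criteria of the pattern decision rule, exposed as a single
#' configuration object. Defaults: a detected region must exceed 1.4x the
#' cellular background (strictly more than 40% above background) and cover
#' at least `min_region_volume`; the interface shell reaches
#' `interface_shell` um below the contact plane; an invagination extends at
#' least `invagination_depth` um into the cell with its deep voxels central;
#' full-coverage regions (> `coverage_full`) split into diffuse (cortical
#' extension at least `lamella_depth` um deep) versus lamellal; remaining
#' regions are central when the radial centroid fraction is at most
#' `central_radial`, otherwise peripheral (annular or >= 2 rim components)
#' or asymmetric (single rim component).
#'
#' @param background_factor detection factor over cellular background.
#' @param min_region_volume noise floor for a detected region, um^3.
#' @param interface_shell depth of the interface shell, um.
#' @param invagination_depth minimum invagination depth, um.
#' @param central_radial maximum radial centroid fraction for central.
#' @param coverage_full interface-coverage fraction above which a region
#'   counts as covering the whole interface.
#' @param lamella_depth depth separating a thin interface lamella from
#'   cortex-following diffuse accumulation, um.
#' @param rim_fraction radial fraction beyond which voxels count as
#'   rim-contacting.
#' @param annular_span azimuthal span (degrees) of rim voxels above which a
#'   region counts as annular.
#' @return named list of thresholds.
#' @export
pattern_thresholds <- function(background_factor = 1.4,
                               min_region_volume = 0.2,
                               interface_shell = 1.5,
                               invagination_depth = 1.5,
                               central_radial = 0.5,
                               coverage_full = 0.6,
                               lamella_depth = 1.0,
                               rim_fraction = 0.75,
                               annular_span = 180) {
  list(
    background_factor = background_factor,
    min_region_volume = min_region_volume,
    interface_shell = interface_shell,
    invagination_depth = invagination_depth,
    central_radial = central_radial,
    coverage_full = coverage_full,
    lamella_depth = lamella_depth,
    rim_fraction = rim_fraction,
    annular_span = annular_span
  )
}

#' Cellular background fluorescence
#'
#' The median intensity over the masked cell voxels; robust to the bright
#' accumulation region, which covers only a minority of the cell.
#'
#' @param volume 3D intensity array.
#' @param mask logical cell mask.
#' @return background intensity (arbitrary units).
#' @export
cellular_background <- function(volume, mask) {
  if (!any(mask)) stop("empty cell mask")
  median(volume[mask])
}

#' Detect the micrometre-scale accumulation region
#'
#' Voxels strictly brighter than `background_factor` times the cellular
#' background (default: more than 40% above background), restricted to the
#' cell mask. The largest 26-connected component is the accumulation
#' region; it is discarded as noise when smaller than the minimum region
#' volume. The number of supra-threshold components at the interface rim is
#' recorded across all components, so split rim accumulations still count.
#'
#' @param volume 3D intensity array.
#' @param mask logical cell mask.
#' @param axes voxel-centre axes in um.
#' @param background from [cellular_background()]; must be positive.
#' @param thresholds a [pattern_thresholds()] list.
#' @param smooth apply an in-plane 3x3 box mean before thresholding
#'   (default TRUE). Accumulation regions are micrometre-scale, several
#'   lateral voxels across, so detection at that scale suppresses
#'   uncorrelated single-voxel shot noise while leaving the interior of a
#'   genuine (or noise-free) region untouched.
#' @return `NULL` when nothing exceeds the criterion, else a list with
#'   `indices` (linear voxel indices of the region), `all_labels` (integer
#'   array labelling every supra-threshold component), `volume_um3`,
#'   `peak`, `mean`.
#' @export
find_accumulation <- function(volume, mask, axes, background,
                              thresholds = pattern_thresholds(),
                              smooth = TRUE) {
  stopifnot(background > 0)
  spacing <- axes_spacing(axes)
  voxvol <- prod(spacing)
  detect <- if (smooth) smooth_inplane(volume) else volume
  above <- detect > thresholds$background_factor * background & mask
  if (!any(above)) return(NULL)
  labs <- label_components_3d(above, connectivity = 26L)
  sizes <- tabulate(labs[labs > 0])
  keep <- which(sizes * voxvol >= thresholds$min_region_volume)
  if (length(keep) == 0) return(NULL)
  main <- keep[which.max(sizes[keep])]
  idx <- which(labs == main)
  list(
    indices = idx,
    all_labels = labs,
    kept_components = keep,
    volume_um3 = sizes[main] * voxvol,
    peak = max(volume[idx]),
    mean = mean(volume[idx])
  )
}

# In-plane 3x3 box mean per z slice (the axial spacing is comparable to the
# feature scale, so z is left untouched); borders normalize by the number of
# in-array neighbours.
smooth_inplane <- function(volume) {
  acc <- array(0, dim(volume))
  cnt <- array(0, dim(volume))
  ones <- array(1, dim(volume))
  for (dx in -1:1) {
    for (dy in -1:1) {
      acc <- acc + shift3d(volume, c(dx, dy, 0), fill = 0)
      cnt <- cnt + shift3d(ones, c(dx, dy, 0), fill = 0)
    }
  }
  acc / cnt
}

axes_spacing <- function(axes) {
  c(axes$x[2] - axes$x[1], axes$y[2] - axes$y[1],
    if (length(axes$z) > 1) axes$z[2] - axes$z[1] else 1)
}

#' Geometric features of an accumulation region
#'
#' Quantifies a detected region against the interface disc: the fraction of
#' the disc covered by the region's projection, the radial position of the
#' region centroid (0 = synapse axis, 1 = rim), the maximum extension away
#' from the interface into the cell, the radial position of the deep
#' (below-shell) voxels, and the rim-contact structure (component count and
#' azimuthal span) evaluated over all supra-threshold components.
#'
#' @param region a [find_accumulation()] result.
#' @param interface list with `center` (um, on the contact plane), `radius`
#'   (um) and implicitly +z normal (interface-up frame).
#' @param axes voxel-centre axes in um.
#' @param thresholds a [pattern_thresholds()] list.
#' @return data frame with one row of features.
#' @export
extract_geometry <- function(region, interface, axes,
                             thresholds = pattern_thresholds()) {
  if (is.null(region) || length(region$indices) == 0) {
    stop("no region to measure; classify as 'none' upstream")
  }
  spacing <- axes_spacing(axes)
  co <- axes_coords(axes)
  pts <- co[region$indices, , drop = FALSE]
  cen <- interface$center
  rad <- interface$radius
  depth <- cen[3] - pts[, 3]
  rho <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)

  # coverage: projected footprint of the region within the disc
  lat <- unique(cbind(
    round((pts[, 1] - axes$x[1]) / spacing[1]),
    round((pts[, 2] - axes$y[1]) / spacing[2])
  )[rho <= rad, , drop = FALSE])
  coverage <- nrow(lat) * spacing[1] * spacing[2] / (pi * rad^2)
  coverage <- min(coverage, 1)

  # radial location as the mean in-plane radial distance of region voxels
  # (robust for annular regions, whose centroid would sit on the axis)
  radial <- mean(rho) / rad
  voxvol <- prod(spacing)
  deep <- depth >= thresholds$interface_shell - 1e-9
  deep_radial <- if (any(deep)) mean(rho[deep]) / rad else NA_real_
  deep_volume <- sum(deep) * voxvol
  ext_volume <- sum(depth >= thresholds$lamella_depth - 1e-9) * voxvol

  rim_info <- rim_structure(region, co, cen, rad, thresholds)

  data.frame(
    coverage = coverage,
    radial_fraction = radial,
    depth = max(depth),
    deep_volume = deep_volume,
    deep_radial = deep_radial,
    ext_volume = ext_volume,
    n_rim_components = rim_info$n_components,
    annular = rim_info$annular,
    volume_um3 = region$volume_um3
  )
}

# Rim-contact structure: which kept components reach the rim band, and the
# azimuthal span covered by rim voxels (gap analysis on the circle).
rim_structure <- function(region, co, cen, rad, thresholds) {
  labs <- region$all_labels
  keep <- region$kept_components
  idx_all <- which(labs > 0)
  idx_all <- idx_all[labs[idx_all] %in% keep]
  pts <- co[idx_all, , drop = FALSE]
  rho <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)
  depth <- cen[3] - pts[, 3]
  rim <- rho >= thresholds$rim_fraction * rad & rho <= 1.1 * rad &
    depth <= thresholds$interface_shell & depth >= 0
  if (!any(rim)) return(list(n_components = 0L, annular = FALSE))
  n_comp <- length(unique(labs[idx_all][rim]))
  ang <- sort(atan2(pts[rim, 2] - cen[2], pts[rim, 1] - cen[1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  span <- (2 * pi - max(gaps)) * 180 / pi
  list(n_components = n_comp, annular = span >= thresholds$annular_span)
}

#' Assign one of the six mutually exclusive interface patterns
#'
#' Decision order: invagination (deep and central) first, then the
#' full-coverage patterns (diffuse versus lamellal by depth of cortical
#' extension), then central, then the rim patterns (peripheral when annular
#' or split into several rim components, asymmetric for a single rim
#' protrusion). Exactly one label results for any feature record; a missing
#' region is `"none"`.
#'
#' @param features one-row data frame from [extract_geometry()], or `NULL`.
#' @param thresholds a [pattern_thresholds()] list.
#' @return a single label from [pattern_labels()].
#' @export
classify_pattern <- function(features, thresholds = pattern_thresholds()) {
  if (is.null(features) || nrow(features) == 0) return("none")
  f <- features[1, ]
  # deep/cortical extension must itself clear the noise floor so that a
  # single stray supra-threshold voxel cannot fake micrometre-deep structure
  deep <- !is.null(f$deep_volume) && isTRUE(f$deep_volume >=
                                              thresholds$min_region_volume)
  ext <- !is.null(f$ext_volume) && isTRUE(f$ext_volume >=
                                            thresholds$min_region_volume)
  if (deep && !is.na(f$deep_radial) &&
      f$deep_radial <= thresholds$central_radial) {
    return("invagination")
  }
  if (f$coverage > thresholds$coverage_full) {
    if (ext) return("diffuse")
    return("lamellal")
  }
  if (f$radial_fraction <= thresholds$central_radial) return("central")
  if (f$n_rim_components >= 2 || isTRUE(f$annular)) return("peripheral")
  "asymmetric"
}

#' Classify every frame of a cell couple
#'
#' Runs the per-frame pipeline (segmentation, background estimation,
#' accumulation detection, geometric feature extraction, pattern
#' assignment) over a volume series and returns one pattern call per frame
#' with time expressed relative to tight cell coupling.
#'
#' @param series a `volume_series`.
#' @param annotation a [synapse_annotation()]; when the synapse axis is not
#'   already vertical, each frame is reoriented first.
#' @param cell_id identifier carried into the calls.
#' @param thresholds a [pattern_thresholds()] list.
#' @param radius_hint expected cell radius in um for segmentation.
#' @return data frame of pattern calls: `cell_id`, `frame`, `time_s`,
#'   `label`, and the geometric features (NA for `"none"` frames).
#' @export
classify_couple <- function(series, annotation, cell_id = "cell",
                            thresholds = pattern_thresholds(),
                            radius_hint = 5) {
  stopifnot(inherits(series, "volume_series"),
            inherits(annotation, "synapse_annotation"))
  nt <- dim(series$data)[4]
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    vol <- series$data[, , , t]
    axes <- series$axes
    ann <- annotation
    axis_vec <- ann$interface_center - ann$cell_rear
    u <- axis_vec / sqrt(sum(axis_vec^2))
    seg <- segment_t_cell(vol, axes, seed_point = (ann$interface_center +
                                                     ann$cell_rear) / 2,
                          radius_hint = radius_hint)
    mask <- seg$mask
    if (acos(pmin(1, pmax(-1, u[3]))) >= 1e-6) {
      ro <- reorient_interface_up(vol, mask, axes, ann)
      vol <- ro$volume; mask <- ro$mask; ann <- ro$annotation
    }
    bg <- cellular_background(vol, mask)
    region <- find_accumulation(vol, mask, axes, bg, thresholds)
    if (is.null(region)) {
      feats <- data.frame(coverage = NA_real_, radial_fraction = NA_real_,
                          depth = NA_real_, deep_volume = NA_real_,
                          deep_radial = NA_real_, ext_volume = NA_real_,
                          n_rim_components = NA_integer_, annular = NA,
                          volume_um3 = NA_real_)
      label <- "none"
    } else {
      interface <- interface_disc(mask, axes, ann)
      feats <- extract_geometry(region, interface, axes, thresholds)
      label <- classify_pattern(feats, thresholds)
    }
    out[[t]] <- cbind(
      data.frame(
        cell_id = cell_id, frame = t,
        time_s = (t - annotation$coupling_frame) * series$frame_interval,
        label = label, stringsAsFactors = FALSE
      ),
      feats
    )
  }
  do.call(rbind, out)
}

# Interface disc in the reoriented (interface-up) frame: plane through the
# annotated interface centre, radius from the lateral extent of the top
# mask layer.
interface_disc <- function(mask, axes, annotation) {
  co <- axes_coords(axes)[which(mask), , drop = FALSE]
  ztop <- max(co[, 3])
  top <- co[, 3] > ztop - axes_spacing(axes)[3]
  cen <- annotation$interface_center
  rad <- max(sqrt((co[top, 1] - cen[1])^2 + (co[top, 2] - cen[2])^2))
  list(center = c(cen[1], cen[2], ztop + axes_spacing(axes)[3] / 2),
       radius = rad)
}

#' Tabulate pattern frequencies over the coupling time course
#'
#' Per condition, time point and label: the number of cells called with
#' that label, the number of cells observed at that time, and the
#' proportion. Cells not observed at a time point (e.g. coupled at movie
#' start, so no -40 s frame exists) are excluded from that time's
#' denominator. Optionally adds `"periphery"` rows, the sum of asymmetric
#' and peripheral.
#'
#' @param calls data frame of pattern calls (from [classify_couple()],
#'   possibly row-bound over cells) with columns `cell_id`, `time_s`,
#'   `label`, and optionally `condition`.
#' @param time_range keep time points within this range in seconds
#'   (default -40 to 420).
#' @param collapse_periphery add `"periphery"` = asymmetric + peripheral.
#' @return data frame of class `frequency_table`: `condition`, `time_s`,
#'   `label`, `count`, `total`, `proportion`.
#' @export
tabulate_frequencies <- function(calls, time_range = c(-40, 420),
                                 collapse_periphery = TRUE) {
  stopifnot(all(c("cell_id", "time_s", "label") %in% names(calls)))
  if (is.null(calls$condition)) calls$condition <- "all"
  calls <- calls[calls$time_s >= time_range[1] & calls$time_s <= time_range[2], ]
  labels <- pattern_labels()
  out <- list()
  for (cond in unique(calls$condition)) {
    cc <- calls[calls$condition == cond, ]
    for (tt in sort(unique(cc$time_s))) {
      ct <- cc[cc$time_s == tt, ]
      total <- length(unique(ct$cell_id))
      counts <- vapply(labels, function(l) sum(ct$label == l), integer(1))
      rows <- data.frame(
        condition = cond, time_s = tt, label = labels,
        count = as.integer(counts), total = total,
        proportion = counts / total, stringsAsFactors = FALSE
      )
      if (collapse_periphery) {
        per <- sum(counts[c("asymmetric", "peripheral")])
        rows <- rbind(rows, data.frame(
          condition = cond, time_s = tt, label = "periphery",
          count = as.integer(per), total = total,
          proportion = per / total, stringsAsFactors = FALSE
        ))
      }
      out[[length(out) + 1]] <- rows
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("frequency_table", "data.frame")
  res
}
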