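#' Otsu threshold of a 3D volume
#'
#' The between-class-variance-maximizing threshold computed on a 256-bin
#' histogram of the whole volume.
#'
#' @param volume numeric array with at least two distinct intensities.
#' @param levels number of histogram bins.
#' @return threshold intensity: voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(volume, levels = 256L) {
  v <- as.numeric(volume)
  rng <- range(v)
  if (diff(rng) <= 0) stop("constant volume: Otsu threshold undefined")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(
    pmin(levels, pmax(1L, findInterval(v, breaks, rightmost.closed = TRUE))),
    nbins = levels
  )
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  h <- as.numeric(h)
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  breaks[which.max(between) + 1L]
}

#' Puncta segmentation parameters
#'
#' @param otsu_multiplier final threshold = Otsu threshold x multiplier.
#' @param control_percentile percentile of the control (APC) puncta size
#'   distribution used as the detection size cutoff.
#' @param min_seed_separation minimum separation between watershed seeds in
#'   um (adjacent puncta closer than this merge).
#' @param voxel_spacing voxel size in um.
#' @return named list of parameters.
#' @export
puncta_params <- function(otsu_multiplier = 3.5,
                          control_percentile = 95,
                          min_seed_separation = 0.1,
                          voxel_spacing = c(0.05, 0.05, 0.1)) {
  stopifnot(otsu_multiplier > 0,
            control_percentile > 0, control_percentile < 100,
            min_seed_separation >= 0, all(voxel_spacing > 0))
  list(
    otsu_multiplier = otsu_multiplier,
    control_percentile = control_percentile,
    min_seed_separation = min_seed_separation,
    voxel_spacing = as.numeric(voxel_spacing)
  )
}

#' Segment 3D puncta
#'
#' Binarizes the volume at the Otsu threshold times the multiplier, then
#' splits touching particles: seeds are the maxima of the 3D Euclidean
#' distance transform of the foreground (deduplicated so that no seed lies
#' inside another's inscribed sphere, and merged below the minimum seed
#' separation), and labels grow from the seeds through the foreground.
#' Punctum volume is voxel count times voxel volume.
#'
#' @param volume 3D intensity array.
#' @param params a [puncta_params()] list.
#' @param seeds optional n x 3 matrix of seed coordinates in um (overrides
#'   distance-transform seeding, e.g. for seeding from known centres).
#' @param axes optional voxel-centre axes (um); defaults to a grid starting
#'   at half a voxel with `params$voxel_spacing`.
#' @return object of class `puncta_set`: data frame `puncta` (id,
#'   volume_um3, centroid, mean intensity, `retained` flag — all TRUE until
#'   [filter_puncta()] is applied), `labels` array, `threshold`.
#' @export
segment_puncta <- function(volume, params = puncta_params(), seeds = NULL,
                           axes = NULL) {
  sp <- params$voxel_spacing
  dm <- dim(volume)
  if (is.null(axes)) {
    axes <- list(
      x = (seq_len(dm[1]) - 0.5) * sp[1],
      y = (seq_len(dm[2]) - 0.5) * sp[2],
      z = (seq_len(dm[3]) - 0.5) * sp[3]
    )
  }
  thr <- otsu_threshold(volume) * params$otsu_multiplier
  fg <- volume > thr
  if (!any(fg)) {
    return(empty_puncta_set(array(0L, dm), thr))
  }
  co <- axes_coords(axes)

  if (is.null(seeds)) {
    # distance transform and seeding on the foreground bounding box only
    cr <- crop_to_mask(fg, margin = 2L)
    dt <- array(0, dm)
    dt[cr$ranges[[1]], cr$ranges[[2]], cr$ranges[[3]]] <- edt_3d(cr$mask, sp)
    cand <- local_maxima_3d(dt)
    # order by decreasing distance value; drop candidates inside an
    # accepted seed's inscribed sphere or closer than the minimum
    # separation
    # order by decreasing distance value; two candidates belong to the
    # same particle when their inscribed spheres overlap substantially
    # (d < 0.8 * (dt_i + dt_j); touching equal spheres sit at d = dt_i +
    # dt_j and must stay separate) or when closer than the minimum seed
    # separation
    cand <- cand[order(-dt[cand])]
    acc <- integer(0)
    for (ci in cand) {
      if (length(acc) == 0) { acc <- ci; next }
      d <- sqrt(colSums((t(co[acc, , drop = FALSE]) - co[ci, ])^2))
      if (all(d >= pmax(params$min_seed_separation,
                        0.8 * (dt[acc] + dt[ci])))) {
        acc <- c(acc, ci)
      }
    }
    seed_idx <- acc
  } else {
    seeds <- matrix(as.numeric(seeds), ncol = 3)
    seed_idx <- apply(seeds, 1, function(p) {
      i <- round((p[1] - axes$x[1]) / sp[1]) + 1
      j <- round((p[2] - axes$y[1]) / sp[2]) + 1
      k <- round((p[3] - axes$z[1]) / sp[3]) + 1
      i + dm[1] * (j - 1 + dm[2] * (k - 1))
    })
  }

  # label growth on the foreground bounding box for speed
  cr2 <- crop_to_mask(fg, margin = 1L)
  seed_lab <- array(0L, dm)
  seed_lab[seed_idx] <- seq_along(seed_idx)
  sub <- function(a) a[cr2$ranges[[1]], cr2$ranges[[2]], cr2$ranges[[3]],
                       drop = FALSE]
  lab_sub <- grow_labels(cr2$mask, sub(seed_lab), connectivity = 6L)
  # any foreground not reached from a seed (separate component with no
  # seed, only possible with user-supplied seeds) becomes its own punctum
  left <- cr2$mask & lab_sub == 0
  if (any(left)) {
    extra <- label_components_3d(left, connectivity = 26L)
    extra[extra > 0] <- extra[extra > 0] + max(lab_sub)
    lab_sub <- lab_sub + extra
  }
  labels <- array(0L, dm)
  labels[cr2$ranges[[1]], cr2$ranges[[2]], cr2$ranges[[3]]] <- lab_sub

  voxvol <- prod(sp)
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(id) {
    idx <- which(labels == id)
    cen <- colMeans(co[idx, , drop = FALSE])
    data.frame(
      id = id, volume_um3 = length(idx) * voxvol,
      x = cen[1], y = cen[2], z = cen[3],
      mean_intensity = mean(volume[idx]), retained = TRUE
    )
  })
  structure(
    list(puncta = do.call(rbind, rows), labels = labels, threshold = thr,
         voxel_spacing = sp),
    class = "puncta_set"
  )
}

empty_puncta_set <- function(labels, thr) {
  structure(
    list(
      puncta = data.frame(
        id = integer(), volume_um3 = numeric(), x = numeric(),
        y = numeric(), z = numeric(), mean_intensity = numeric(),
        retained = logical()
      ),
      labels = labels, threshold = thr, voxel_spacing = NULL
    ),
    class = "puncta_set"
  )
}

#' @export
print.puncta_set <- function(x, ...) {
  p <- x$puncta
  cat(sprintf("puncta_set: %d puncta (%d retained), threshold %.3g\n",
              nrow(p), sum(p$retained), x$threshold))
  if (nrow(p)) {
    cat(sprintf("  volumes %.3g-%.3g um^3 (mean %.3g)\n",
                min(p$volume_um3), max(p$volume_um3), mean(p$volume_um3)))
  }
  invisible(x)
}

#' Calibrate the minimum punctum size from control puncta
#'
#' Small puncta detected in cells that do not express the stained protein
#' set the detection floor: the cutoff is the given percentile of the
#' control size distribution, with linear interpolation between the
#' closest order statistics.
#'
#' @param control_volumes punctum volumes (um^3) from the control cells.
#' @param percentile percentile in (0, 100), default 95.
#' @return cutoff volume in um^3.
#' @examples
#' calibrate_size_threshold(seq(0.001, 0.1, by = 0.001))
#' @export
calibrate_size_threshold <- function(control_volumes, percentile = 95) {
  v <- as.numeric(control_volumes)
  if (length(v) == 0) stop("empty control set")
  stopifnot(percentile > 0, percentile < 100)
  unname(quantile(v, percentile / 100, type = 7))
}

#' Apply the calibrated size filter
#'
#' Marks puncta smaller than the cutoff as excluded; retained puncta are
#' exactly those with volume at or above the cutoff.
#'
#' @param set a [segment_puncta()] result, or a data frame with a
#'   `volume_um3` column.
#' @param cutoff volume cutoff in um^3 (from [calibrate_size_threshold()]).
#' @return the input with its `retained` flags updated.
#' @export
filter_puncta <- function(set, cutoff) {
  if (inherits(set, "puncta_set")) {
    set$puncta$retained <- set$puncta$volume_um3 >= cutoff
    set$cutoff <- cutoff
    return(set)
  }
  set$retained <- set$volume_um3 >= cutoff
  set
}

#' Summarize puncta by cSMAC status
#'
#' Per group (e.g. cells with versus without a cSMAC): mean retained
#' punctum volume with its standard error, the mean number of retained
#' puncta per cell, and a two-sample Student's t test between the two
#' groups' punctum volumes.
#'
#' @param puncta data frame with columns `volume_um3`, `cell_id`, `group`,
#'   and optionally `retained` (only retained puncta are summarized).
#' @return list with `summary` (one row per group) and `t_test` (the
#'   `htest` comparing the first two groups, or NULL with fewer groups).
#' @export
summarize_puncta <- function(puncta) {
  stopifnot(all(c("volume_um3", "cell_id", "group") %in% names(puncta)))
  if (!is.null(puncta$retained)) puncta <- puncta[puncta$retained, ]
  groups <- unique(puncta$group)
  rows <- lapply(groups, function(g) {
    pg <- puncta[puncta$group == g, ]
    if (nrow(pg) == 0) {
      warning("group with zero retained puncta excluded: ", g)
      return(NULL)
    }
    per_cell <- table(pg$cell_id)
    data.frame(
      group = g, n_cells = length(per_cell), n_puncta = nrow(pg),
      mean_volume = mean(pg$volume_um3),
      sem_volume = sd(pg$volume_um3) / sqrt(nrow(pg)),
      mean_count_per_cell = mean(as.numeric(per_cell))
    )
  })
  summary <- do.call(rbind, rows)
  tt <- NULL
  if (!is.null(summary) && nrow(summary) >= 2) {
    g1 <- puncta$volume_um3[puncta$group == summary$group[1]]
    g2 <- puncta$volume_um3[puncta$group == summary$group[2]]
    if (length(g1) > 1 && length(g2) > 1) {
      tt <- t.test(g1, g2, var.equal = TRUE)
    }
  }
  list(summary = summary, t_test = tt)
}
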