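#' Build the standardized half-spheroid template
#'
#' Constructs the half-spheroid voxel template onto which every segmented
#' cell is mapped for voxel-by-voxel comparison. The template lives on the
#' native anisotropic acquisition grid and contains exactly `n_target`
#' interior voxels at the default spacing of 0.34 um laterally and 1 um
#' axially. Because only the voxel count is fixed, the semi-axes are found
#' by a calibration search: the lateral semi-axis is scanned over
#' `lateral_range` in steps of `lateral_step`; for each value the axial
#' semi-axis achieving the target interior count (a monotone step function)
#' is bisected for within `axial_range`; among all exact solutions the pair
#' whose lateral/axial aspect ratio is closest to `target_aspect` (a
#' moderately flattened cell) is kept.
#'
#' The flat face of the spheroid is the interface plane; voxel depth is
#' measured below it, with voxel centres at depth spacing/2, 3*spacing/2,
#' and so on. Voxels are ordered by depth layer (interface first), then y,
#' then x; this order is fixed and used for all tie-breaks.
#'
#' @param spacing voxel spacing in um (x, y, z); all positive.
#' @param n_target required interior voxel count.
#' @param lateral_range,axial_range search bounds for the semi-axes in um.
#' @param lateral_step lateral scan step in um.
#' @param target_aspect preferred lateral/axial semi-axis ratio.
#'
#' @return Object of class `half_spheroid_template`: `voxels` (data frame
#'   with um coordinates `x`, `y`, `depth` and the fixed `index`),
#'   `semi_axes` (lateral, axial in um), `spacing`, `n_voxels`.
#' @examples
#' \donttest{
#' tpl <- build_template()
#' tpl$n_voxels
#' }
#' @export
build_template <- function(spacing = c(0.34, 0.34, 1),
                           n_target = 6628L,
                           lateral_range = c(2, 8),
                           axial_range = c(2, 8),
                           lateral_step = 0.01,
                           target_aspect = 1.5) {
  stopifnot(length(spacing) == 3, all(spacing > 0), n_target >= 1)

  # lateral voxel grid big enough for the largest admissible semi-axis
  nmax <- floor(lateral_range[2] / min(spacing[1:2]))
  xs <- seq(-nmax, nmax) * spacing[1]
  ys <- seq(-nmax, nmax) * spacing[2]
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  rr <- gx^2 + gy^2

  # interior count: per lateral column, z centres at (k - 1/2) * dz lie
  # inside for k <= c * s / dz + 1/2 with s = sqrt(1 - (x^2+y^2)/a^2)
  count_for <- function(s, c_ax) sum(floor(c_ax * s / spacing[3] + 0.5))

  best <- NULL
  nearest <- c(below = -Inf, above = Inf) # closest achievable counts
  for (a in seq(lateral_range[1], lateral_range[2], by = lateral_step)) {
    s <- sqrt(pmax(0, 1 - rr / a^2))
    s <- s[s > 0]
    c_hi <- count_for(s, axial_range[2])
    c_lo <- count_for(s, axial_range[1])
    for (cc in c(c_lo, c_hi)) {
      if (cc <= n_target) nearest["below"] <- max(nearest["below"], cc)
      if (cc >= n_target) nearest["above"] <- min(nearest["above"], cc)
    }
    if (c_hi < n_target || c_lo > n_target) next
    lo <- axial_range[1]; hi <- axial_range[2]
    for (it in 1:48) {
      mid <- (lo + hi) / 2
      if (count_for(s, mid) < n_target) lo <- mid else hi <- mid
    }
    if (count_for(s, hi) == n_target) {
      if (is.null(best) || abs(a / hi - target_aspect) <
          abs(best[1] / best[2] - target_aspect)) {
        best <- c(a, hi)
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "no semi-axis pair reaches %d voxels in the search bounds (nearest achievable counts: %s / %s)",
      n_target, format(nearest["below"]), format(nearest["above"])
    ))
  }

  a <- best[1]; c_ax <- best[2]
  nlat <- floor(a / spacing[1:2])
  xs <- seq(-nlat[1], nlat[1]) * spacing[1]
  ys <- seq(-nlat[2], nlat[2]) * spacing[2]
  nz <- floor(c_ax / spacing[3] + 0.5)
  depths <- (seq_len(nz) - 0.5) * spacing[3]
  # fixed voxel order: depth layer (interface first), then y, then x
  g <- expand.grid(x = xs, y = ys, depth = depths,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$depth, g$y, g$x), ]
  inside <- (g$x / a)^2 + (g$y / a)^2 + (g$depth / c_ax)^2 <= 1
  vox <- g[inside, , drop = FALSE]
  vox$index <- seq_len(nrow(vox))
  rownames(vox) <- NULL
  if (nrow(vox) != n_target) {
    stop("internal error: calibrated template count drifted from target")
  }
  structure(
    list(
      voxels = vox,
      semi_axes = c(lateral = a, axial = c_ax),
      spacing = as.numeric(spacing),
      n_voxels = nrow(vox)
    ),
    class = "half_spheroid_template"
  )
}

#' Interior voxel count of a half spheroid on a given grid
#'
#' Counts voxel centres inside a half spheroid of the given semi-axes on an
#' anisotropic grid, using the same conventions as [build_template()]
#' (flat face at depth 0, centres at half-integer depth multiples). Useful
#' for inspecting the calibration search.
#'
#' @param spacing voxel spacing in um (x, y, z).
#' @param lateral,axial semi-axes in um.
#' @return integer voxel count.
#' @export
template_voxel_count <- function(spacing, lateral, axial) {
  stopifnot(all(spacing > 0), lateral > 0, axial > 0)
  nlat <- floor(lateral / spacing[1:2])
  xs <- seq(-nlat[1], nlat[1]) * spacing[1]
  ys <- seq(-nlat[2], nlat[2]) * spacing[2]
  rr <- outer(xs^2, ys^2, "+")
  s <- sqrt(pmax(0, 1 - rr / lateral^2))
  sum(floor(axial * s / spacing[3] + 0.5))
}

#' @export
print.half_spheroid_template <- function(x, ...) {
  cat(sprintf(
    "half_spheroid_template: %d voxels, semi-axes %.2f (lateral) x %.2f (axial) um\n",
    x$n_voxels, x$semi_axes[1], x$semi_axes[2]
  ))
  cat(sprintf("  spacing %.2f x %.2f x %.2f um, flat face = interface plane\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}
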