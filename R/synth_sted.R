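#' Simulate a deconvolved STED-like 3D puncta field
#'
#' Renders ellipsoidal puncta of known true volumes in an intensity regime
#' emulating deconvolved STED stacks: a dark camera floor, a dim smooth
#' cytoplasmic haze, and bright sharp-edged puncta. Each punctum has an
#' error-function edge profile whose half-maximum isosurface encloses
#' exactly the requested volume, so the noise-free above-half-max voxel
#' count recovers the truth up to voxelization error. Punctum elongation
#' follows the per-axis PSF sigmas.
#'
#' The default amplitude ratios (puncta 15x floor, haze 4x floor) give the
#' histogram shape on which Otsu-based detection with a fixed threshold
#' multiplier operates sensibly: the Otsu level falls at the haze, and a
#' few-fold multiplier lands between the haze and the punctum half-max.
#'
#' @param true_volumes numeric vector of punctum volumes in um^3 (may be
#'   empty, giving a pure floor-plus-haze image).
#' @param psf_sigma per-axis PSF sigma in um (length 3 or scalar); sets
#'   both the edge width and the axis ratio of the rendered ellipsoids.
#' @param config a [sim_config()]; supplies voxel spacing (use a fine,
#'   near-isotropic spacing for STED-like data), the floor intensity
#'   (`background_intensity`) and the noise model.
#' @param centers optional n x 3 matrix of punctum centres in um; by
#'   default puncta are laid out on a grid with generous separation.
#'   Centres must be pairwise separated by at least `min_separation`.
#' @param min_separation minimum allowed centre-to-centre distance in um.
#' @param amplitude punctum amplitude above its local base, in intensity
#'   units (default 15x the floor).
#' @param haze_amplitude peak of the cytoplasmic haze (default 4x floor);
#'   set to 0 for a clean two-level image.
#' @param haze_sigma haze Gaussian sigma in um.
#' @param margin dark margin around the puncta in um (gives the histogram
#'   its floor mode).
#'
#' @return list with `volume` (3D array), `axes` (um voxel-centre axes) and
#'   `truth` (class `ground_truth_sted`: true volumes, centres, the
#'   haze-free `half_max` level, per-punctum core voxel indices).
#' @examples
#' cfg <- sim_config(voxel_spacing = c(0.05, 0.05, 0.1),
#'                   noise_model = list(poisson_scale = Inf, gaussian_sd = 0))
#' f <- make_sted_field(0.23, config = cfg, haze_amplitude = 0)
#' sum(f$volume > f$truth$half_max) * prod(cfg$voxel_spacing)
#' @export
make_sted_field <- function(true_volumes, psf_sigma = c(0.01, 0.01, 0.02),
                            config, centers = NULL, min_separation = 0.1,
                            amplitude = 12 * config$background_intensity,
                            haze_amplitude = 6 * config$background_intensity,
                            haze_sigma = 1, margin = 2.5) {
  stopifnot(inherits(config, "sim_config"))
  true_volumes <- as.numeric(true_volumes)
  if (any(true_volumes <= 0)) stop("punctum volumes must be positive")
  sp <- config$voxel_spacing
  voxvol <- prod(sp)
  if (any(true_volumes < voxvol)) {
    stop(sprintf(
      "requested punctum volume below one voxel (%.3g um^3)", voxvol
    ))
  }
  psf_sigma <- rep_len(as.numeric(psf_sigma), 3)
  stopifnot(all(psf_sigma > 0))
  set.seed(config$seed)

  n <- length(true_volumes)
  # ellipsoid semi-axes: volume-matched, elongated like the PSF
  gm <- prod(psf_sigma)^(1 / 3)
  shape <- psf_sigma / gm
  r0 <- (3 * true_volumes / (4 * pi))^(1 / 3)
  semi <- outer(r0, shape) # n x 3

  if (is.null(centers) && n > 0) {
    pitch <- max(4 * max(semi), 1)
    k <- ceiling(sqrt(n))
    centers <- cbind(
      pitch * ((seq_len(n) - 1) %% k),
      pitch * ((seq_len(n) - 1) %/% k),
      0
    )
  }
  if (n > 0) {
    centers <- matrix(as.numeric(centers), ncol = 3)
    if (nrow(centers) != n) stop("need one centre per punctum")
    if (n > 1) {
      dmin <- min(dist(centers))
      if (dmin < min_separation - 1e-12) {
        stop(sprintf("punctum centres closer than %g um", min_separation))
      }
    }
  }

  pad <- if (n > 0) max(semi) + margin else margin
  lo <- if (n > 0) apply(centers, 2, min) - pad else rep(-pad, 3)
  hi <- if (n > 0) apply(centers, 2, max) + pad else rep(pad, 3)
  axes <- lapply(1:3, function(d) seq(lo[d], hi[d] + sp[d], by = sp[d]))
  names(axes) <- c("x", "y", "z")
  co <- axes_coords(axes)
  dm <- lengths(axes)

  B <- config$background_intensity
  expect <- rep(B, nrow(co))
  if (haze_amplitude > 0) {
    hc <- if (n > 0) colMeans(centers) else rep(0, 3)
    # the cytoplasm surrounds all puncta: widen the haze to the puncta
    # cloud when it is larger than the nominal sigma
    hs <- haze_sigma
    if (n > 1) {
      spread <- max(sqrt(rowSums(sweep(centers, 2, hc)^2)))
      hs <- max(haze_sigma, 0.8 * spread)
    }
    hr2 <- (co[, 1] - hc[1])^2 + (co[, 2] - hc[2])^2 + (co[, 3] - hc[3])^2
    expect <- expect + haze_amplitude * exp(-hr2 / (2 * hs^2))
  }
  core_masks <- vector("list", n)
  for (i in seq_len(n)) {
    rho <- sqrt(
      ((co[, 1] - centers[i, 1]) / semi[i, 1])^2 +
        ((co[, 2] - centers[i, 2]) / semi[i, 2])^2 +
        ((co[, 3] - centers[i, 3]) / semi[i, 3])^2
    )
    # erf-profile edge: half max exactly at rho = 1 (the true surface);
    # the relative edge width gm / r0 is identical along every axis
    expect <- expect + amplitude * pnorm((1 - rho) * r0[i] / gm)
    core_masks[[i]] <- which(rho <= 1)
  }
  vol <- array(apply_noise(expect, config), dm)

  truth <- structure(
    list(
      volumes = true_volumes,
      centers = if (n > 0) centers else matrix(numeric(), 0, 3),
      half_max = B + amplitude / 2, core_masks = core_masks
    ),
    class = "ground_truth_sted"
  )
  list(volume = vol, axes = axes, truth = truth)
}
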