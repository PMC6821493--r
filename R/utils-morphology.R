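# Internal 3D morphology primitives. The installed image packages only
# operate slice-wise on 3D stacks, so connected components, the Euclidean
# distance transform and seeded label growth are implemented here as
# vectorized whole-array operations.

# Offsets of the 6- or 26-neighbourhood as an integer matrix (one row per
# neighbour).
neighbour_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  as.matrix(g)
}

# Shift a 3D array by an integer offset, padding with `fill`.
shift3d <- function(a, off, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (d in 1:3) {
    o <- off[d]
    if (o >= 0) {
      src[[d]] <- seq_len(dm[d] - o)
      dst[[d]] <- seq_len(dm[d] - o) + o
    } else {
      src[[d]] <- seq_len(dm[d] + o) - o
      dst[[d]] <- seq_len(dm[d] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Crop a logical mask to its bounding box (with 1-voxel margin); returns the
# cropped mask and index ranges, or NULL for an empty mask.
crop_to_mask <- function(mask, margin = 1L) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  dm <- dim(mask)
  rng <- lapply(1:3, function(d) {
    seq(max(1L, min(w[, d]) - margin), min(dm[d], max(w[, d]) + margin))
  })
  list(mask = mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE], ranges = rng)
}

# Connected-component labelling of a logical 3D mask by iterative label
# propagation (each voxel takes the max label among its in-mask neighbours
# until stable). Returns an integer array, 0 = background.
label_components_3d <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  labels <- array(0, dm)
  cr <- crop_to_mask(mask)
  if (is.null(cr)) return(labels)
  m <- cr$mask
  lab <- array(0, dim(m))
  lab[m] <- seq_len(sum(m))
  offs <- neighbour_offsets(connectivity)
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      new <- pmax(new, shift3d(lab, offs[r, ], fill = 0) * m)
    }
    new[!m] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  # compact label ids to 1..k in order of first occurrence
  ids <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], ids)
  labels[cr$ranges[[1]], cr$ranges[[2]], cr$ranges[[3]]] <- lab
  storage.mode(labels) <- "integer"
  labels
}

# Flood fill: the connected component of `mask` containing the voxel with
# linear index `seed_idx`.
flood_from_seed <- function(mask, seed_idx, connectivity = 6L) {
  dm <- dim(mask)
  reached <- array(FALSE, dm)
  reached[seed_idx] <- TRUE
  offs <- neighbour_offsets(connectivity)
  repeat {
    new <- reached
    for (r in seq_len(nrow(offs))) {
      new <- new | (shift3d(reached, offs[r, ], fill = FALSE) & mask)
    }
    if (identical(new, reached)) break
    reached <- new
  }
  reached
}

# Exact Euclidean distance transform of a foreground mask (distance in
# micrometres from each foreground voxel to the nearest background voxel),
# computed as three separable 1D squared-distance passes, each a vectorized
# min over shifted copies. Positions outside the array count as background
# (fill = 0 in the shifted copies).
edt_3d <- function(mask, spacing) {
  dm <- dim(mask)
  inf <- sum((dm * spacing)^2) * 4
  d2 <- array(0, dm)
  d2[mask] <- inf
  for (ax in 1:3) {
    w <- spacing[ax]
    n <- dm[ax]
    res <- d2
    for (k in seq_len(n - 1)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- k
      res <- pmin(res, shift3d(d2, off, fill = 0) + (k * w)^2)
      off[ax] <- -k
      res <- pmin(res, shift3d(d2, off, fill = 0) + (k * w)^2)
      # all later shifts add larger squared distances than anything left
      if ((k * w)^2 > max(res)) break
    }
    d2 <- res
  }
  d <- sqrt(d2)
  d[!mask] <- 0
  d
}

# Local maxima of a non-negative array restricted to a mask: voxels whose
# value is >= all 26 neighbours and > 0. Returns linear indices.
local_maxima_3d <- function(a, mask = NULL) {
  if (!is.null(mask)) a <- a * mask
  offs <- neighbour_offsets(26L)
  is_max <- a > 0
  for (r in seq_len(nrow(offs))) {
    is_max <- is_max & (a >= shift3d(a, offs[r, ], fill = 0))
  }
  which(is_max)
}

# Seeded label growth restricted to a foreground mask: breadth-first
# 6-connected dilation of seed labels until the mask is covered. Ties at
# equidistant voxels resolve by neighbour order (deterministic).
grow_labels <- function(mask, seed_labels, connectivity = 6L) {
  offs <- neighbour_offsets(connectivity)
  lab <- seed_labels
  lab[!mask] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      cand <- shift3d(lab, offs[r, ], fill = 0)
      take <- mask & lab == 0 & cand > 0
      if (any(take)) {
        lab[take] <- cand[take]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}
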