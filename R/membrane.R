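#' Polyline arc length
#'
#' Sum of consecutive Euclidean segment lengths. Duplicate consecutive
#' points contribute zero.
#'
#' @param points two-column matrix or data frame of 2D um coordinates
#'   (>= 2 points).
#' @return arc length in um.
#' @examples
#' arc_length(rbind(c(0, 0), c(3, 0)))
#' @export
arc_length <- function(points) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2, nrow(p) >= 2)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Partition a membrane trace into interface quarters
#'
#' Divides the interface diameter (the chord between the two annotated
#' endpoints) into four equal sections; polyline points are assigned to
#' sections by orthogonal projection onto the chord, with the polyline cut
#' by linear interpolation exactly where the projection crosses a quarter
#' boundary. The central two sections are the cSMAC (a conservative
#' convention: cSMACs are commonly smaller than half the interface
#' diameter); the outer sections are the left and right pSMAC. Projections
#' beyond the chord (membrane overhang) are clamped to the nearest end and
#' flagged.
#'
#' @param trace a [membrane_trace()] (or its `points` plus `endpoints`).
#' @param endpoints optional 2 x 2 matrix overriding the trace endpoints.
#' @return list with `sections` (list of four point matrices, left to
#'   right), `boundaries` (chord positions of the cuts), `chord` (full
#'   diameter, um) and `clamped` (TRUE when overhang was clamped).
#' @export
partition_interface <- function(trace, endpoints = NULL) {
  pts <- if (inherits(trace, "membrane_trace")) as.matrix(trace$points) else as.matrix(trace)
  if (is.null(endpoints)) {
    stopifnot(inherits(trace, "membrane_trace"))
    endpoints <- trace$endpoints
  }
  e1 <- endpoints[1, ]
  e2 <- endpoints[2, ]
  L <- sqrt(sum((e2 - e1)^2))
  if (L <= 0) stop("interface endpoints coincide")
  u <- (e2 - e1) / L
  tpos <- as.numeric((sweep(pts, 2, e1)) %*% u)
  clamped <- any(tpos < -1e-9 | tpos > L + 1e-9)
  tpos_cl <- pmin(pmax(tpos, 0), L)

  cuts <- L * c(1, 2, 3) / 4
  sections <- vector("list", 4)
  lo_bounds <- c(0, cuts)
  hi_bounds <- c(cuts, L)
  for (s in 1:4) {
    lo <- lo_bounds[s]; hi <- hi_bounds[s]
    keep <- which(tpos_cl >= lo - 1e-12 & tpos_cl <= hi + 1e-12)
    sec <- pts[keep, , drop = FALSE]
    # interpolate entry/exit points where segments straddle a boundary
    for (b in c(lo, hi)) {
      crossing <- which((tpos[-length(tpos)] - b) * (tpos[-1] - b) < 0)
      for (ci in crossing) {
        w <- (b - tpos[ci]) / (tpos[ci + 1] - tpos[ci])
        cut_pt <- pts[ci, ] + w * (pts[ci + 1, ] - pts[ci, ])
        sec <- rbind(sec, cut_pt)
      }
    }
    # keep polyline order along the original trace
    ord <- order(apply(sec, 1, function(q) {
      # position along the trace: nearest original vertex index plus
      # chord position as tie-break
      sum((q - e1) * u)
    }))
    sections[[s]] <- sec[ord, , drop = FALSE]
  }
  list(sections = sections, boundaries = cuts, chord = L, clamped = clamped)
}

#' Undulation ratio of a membrane section
#'
#' Arc length of the section divided by its chord portion ("diameter" of
#' the same region). A flat membrane scores 1.
#'
#' @param points section polyline (2D um coordinates).
#' @param chord chord length of the region in um (> 0).
#' @return dimensionless ratio.
#' @export
undulation_ratio <- function(points, chord) {
  stopifnot(chord > 0)
  arc_length(points) / chord
}

#' Membrane-undulation report for a traced interface
#'
#' Quantifies membrane undulations per interface region as the ratio of
#' plasma-membrane length to the straight-line diameter of the same
#' region. In `"quartered"` mode the interface is split by
#' [partition_interface()]: the central two quarters form the cSMAC (chord
#' = half the diameter) and the outer quarters the left and right pSMAC
#' (chord = a quarter each), mirroring measuring the periphery twice per
#' cell. `"whole"` mode returns a single ratio over the full chord, as
#' used for control couples without a cSMAC.
#'
#' @param trace a [membrane_trace()].
#' @param mode `"quartered"` or `"whole"`.
#' @param cell_id identifier carried into the report.
#' @return data frame of class `undulation_report`: `cell_id`, `region`,
#'   `length_um`, `diameter_um`, `ratio`.
#' @export
undulation_report <- function(trace, mode = c("quartered", "whole"),
                              cell_id = "cell") {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "membrane_trace"))
  if (mode == "whole") {
    L <- sqrt(sum((trace$endpoints[2, ] - trace$endpoints[1, ])^2))
    res <- data.frame(
      cell_id = cell_id, region = "whole",
      length_um = arc_length(trace$points), diameter_um = L,
      ratio = undulation_ratio(trace$points, L)
    )
  } else {
    part <- partition_interface(trace)
    L <- part$chord
    res <- rbind(
      data.frame(
        cell_id = cell_id, region = "cSMAC",
        length_um = arc_length(part$sections[[2]]) +
          arc_length(part$sections[[3]]),
        diameter_um = L / 2,
        ratio = (arc_length(part$sections[[2]]) +
                   arc_length(part$sections[[3]])) / (L / 2)
      ),
      data.frame(
        cell_id = cell_id, region = "pSMAC_left",
        length_um = arc_length(part$sections[[1]]), diameter_um = L / 4,
        ratio = undulation_ratio(part$sections[[1]], L / 4)
      ),
      data.frame(
        cell_id = cell_id, region = "pSMAC_right",
        length_um = arc_length(part$sections[[4]]), diameter_um = L / 4,
        ratio = undulation_ratio(part$sections[[4]], L / 4)
      )
    )
  }
  class(res) <- c("undulation_report", "data.frame")
  res
}
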