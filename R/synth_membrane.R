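#' Simulate a traced membrane polyline with sinusoidal undulations
#'
#' Generates a 2D membrane trace \eqn{y = A \sin(2\pi x / \lambda)} sampled
#' over an interface chord of length `span`, as produced by tracing the
#' T-cell plasma membrane in single EM-section images. The true arc length
#' is computed by adaptive numerical quadrature and stored as ground truth.
#'
#' @param amplitude undulation amplitude A in um (0 gives a flat membrane).
#' @param wavelength undulation wavelength in um; snapped to an integer
#'   number of periods over the undulating stretch so the trace starts and
#'   ends on the interface chord.
#' @param span chord length (interface diameter) in um.
#' @param sampling number of polyline points (>= 2).
#' @param region `"whole"` undulates the full span; `"central"` restricts
#'   undulation to the central half of the chord (the cSMAC under the
#'   quartering convention) and leaves the peripheral quarters flat. With
#'   `"central"` the wavelength is snapped to an integer number of periods
#'   over the central half so the trace stays continuous.
#'
#' @return list with `trace` (class `membrane_trace`: data frame of
#'   `x`/`y` um coordinates plus `endpoints`) and `truth` (true arc length
#'   in um from quadrature, and the flat-chord length).
#' @examples
#' mt <- make_membrane_trace(0.5, 1, 4, sampling = 2000)
#' mt$truth$arc_length
#' @export
make_membrane_trace <- function(amplitude, wavelength = 1, span = 4,
                                sampling = 1000,
                                region = c("whole", "central")) {
  stopifnot(span > 0, sampling >= 2, wavelength > 0, amplitude >= 0)
  region <- match.arg(region)
  x <- seq(0, span, length.out = sampling)
  if (region == "whole") {
    # snap to an integer number of periods so the trace ends on the chord
    periods <- max(1, round(span / wavelength))
    k <- 2 * pi * periods / span
    y <- amplitude * sin(k * x)
    integrand <- function(t) sqrt(1 + (amplitude * k * cos(k * t))^2)
    arc <- integrate(integrand, 0, span, subdivisions = 2000L,
                     rel.tol = 1e-10)$value
  } else {
    a <- span / 4
    b <- 3 * span / 4
    periods <- max(1, round((b - a) / wavelength))
    k <- 2 * pi * periods / (b - a)
    y <- ifelse(x >= a & x <= b, amplitude * sin(k * (x - a)), 0)
    integrand <- function(t) sqrt(1 + (amplitude * k * cos(k * (t - a)))^2)
    arc <- (span / 2) +
      integrate(integrand, a, b, subdivisions = 2000L, rel.tol = 1e-10)$value
  }
  trace <- membrane_trace(x, y, endpoints = rbind(c(0, 0), c(span, 0)))
  truth <- list(arc_length = arc, chord = span)
  list(trace = trace, truth = truth)
}

#' Construct a membrane trace object
#'
#' An ordered 2D polyline (um coordinates) with the two interface-diameter
#' endpoints. Endpoints default to the first and last polyline points and
#' must lie within 0.1 um of them.
#'
#' @param x,y numeric coordinates in um (>= 2 points).
#' @param endpoints 2 x 2 matrix of interface-diameter endpoints (um).
#' @return object of class `membrane_trace`.
#' @export
membrane_trace <- function(x, y, endpoints = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  pts <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (is.null(endpoints)) {
    endpoints <- rbind(unlist(pts[1, ]), unlist(pts[nrow(pts), ]))
  }
  endpoints <- matrix(as.numeric(endpoints), 2, 2)
  ends <- rbind(unlist(pts[1, ]), unlist(pts[nrow(pts), ]))
  gap <- sqrt(rowSums((endpoints - ends)^2))
  if (any(gap > 0.1)) {
    warning("interface endpoints lie > 0.1 um from the polyline ends")
  }
  structure(list(points = pts, endpoints = endpoints),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf(
    "membrane_trace: %d points, chord %.2f um, arc length %.2f um\n",
    nrow(x$points),
    sqrt(sum((x$endpoints[2, ] - x$endpoints[1, ])^2)),
    arc_length(x$points)
  ))
  invisible(x)
}
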