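#' Plot pattern-frequency time courses
#'
#' Draws the percentage of cell couples showing each interface pattern
#' against time relative to tight cell coupling, one line per pattern,
#' optionally restricted to one condition.
#'
#' @param x a `frequency_table` from [tabulate_frequencies()].
#' @param condition condition to plot (default: the first).
#' @param labels pattern labels to draw.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.frequency_table <- function(x, condition = NULL,
                                 labels = c("central", "invagination",
                                            "diffuse", "lamellal",
                                            "periphery"),
                                 ...) {
  if (is.null(condition)) condition <- x$condition[1]
  d <- x[x$condition == condition & x$label %in% labels, ]
  if (nrow(d) == 0) stop("nothing to plot for condition ", condition)
  labels <- intersect(labels, unique(d$label))
  cols <- grDevices::hcl.colors(max(3, length(labels)), "Dark 2")
  plot(range(d$time_s), c(0, 100), type = "n",
       xlab = "time relative to tight coupling (s)",
       ylab = "% of cell couples", main = condition, ...)
  for (i in seq_along(labels)) {
    di <- d[d$label == labels[i], ]
    di <- di[order(di$time_s), ]
    lines(di$time_s, 100 * di$proportion, col = cols[i], lwd = 2)
  }
  abline(v = 0, lty = 3)
  legend("topright", legend = labels, col = cols[seq_along(labels)],
         lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot an undulation report
#'
#' Strip chart of undulation ratios by interface region, the usual display
#' for cSMAC versus pSMAC membrane topology comparisons.
#'
#' @param x an `undulation_report` (possibly row-bound over cells).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.undulation_report <- function(x, ...) {
  regions <- unique(x$region)
  at <- match(x$region, regions)
  plot(at + runif(length(at), -0.08, 0.08), x$ratio, xaxt = "n",
       xlab = "", ylab = "membrane length / region diameter",
       xlim = c(0.5, length(regions) + 0.5), pch = 19, ...)
  axis(1, at = seq_along(regions), labels = regions)
  abline(h = 1, lty = 3)
  invisible(x)
}
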