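#' Plot a lag-effect curve with its 95% confidence band
#'
#' Effect estimate as a bold line over lag days, the pointwise 95% CI as a
#' grey band, and a dashed zero reference line -- the conventional display
#' of single-day and cumulative temperature effects.
#'
#' @param x a [effect_curve()] result.
#' @param main optional title (default built from the contrast).
#' @param ylab y-axis label.
#' @param ... further par arguments to `plot`.
#' @export
plot.yll_effect_curve <- function(x, main = NULL,
                                  ylab = "YLL difference (years)", ...) {
  lag <- x$lag
  if (is.null(main)) {
    kind <- if (isTRUE(attr(x, "cumulative"))) "Cumulative" else "Single-day"
    main <- sprintf("%s %s effect (%.1f vs %.1f \u00b0C)", kind,
                    attr(x, "contrast"), attr(x, "target"), attr(x, "ref"))
  }
  ylim <- range(x$ci_low, x$ci_high, 0)
  graphics::plot(lag, x$estimate, type = "n", ylim = ylim,
                 xlab = "Lag (days)", ylab = ylab, main = main, ...)
  graphics::polygon(c(lag, rev(lag)), c(x$ci_low, rev(x$ci_high)),
                    col = "grey85", border = NA)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::lines(lag, x$estimate, lwd = 2)
  invisible(x)
}

#' Plot the four standard effect curves of a fitted model
#'
#' 2 x 2 panel: single-day and cumulative curves for the cold (25th to 1st
#' percentile) and heat (75th to 99th) contrasts.
#'
#' @param x a fitted [yll_dlnm()] model.
#' @param ... passed to [plot.yll_effect_curve()].
#' @export
plot.yll_dlnm <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op))
  for (cum in c(FALSE, TRUE))
    for (ct in c("cold", "heat"))
      plot(effect_curve(x, ct, cumulative = cum), ...)
  invisible(x)
}
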