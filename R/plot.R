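# Static plot of a trace with its selected (countable) extreme points.

#' Plot a glucose trace with the selected excursion points
#'
#' Draws the CGM curve and overlays the selected valid extreme points joined
#' by straight lines, with a subtitle reporting SDBG and the MAGE
#' statistics.
#'
#' @param trace a [glucose_trace()].
#' @param result the matching `mage_result` from [calculate_mage()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_mage <- function(trace, result, ...) {
  stopifnot(inherits(trace, "glucose_trace"),
            inherits(result, "mage_result"))
  th <- trace$times / 3600
  graphics::plot(th, trace$values, type = "l", col = "grey40",
                 xlab = "time (h)", ylab = "glucose (mmol/L)",
                 main = result$trace_id, ...)
  if (length(result$selected_times)) {
    graphics::lines(result$selected_times / 3600, result$selected_values,
                    col = "red3", lwd = 2)
    graphics::points(result$selected_times / 3600, result$selected_values,
                     col = "red3", pch = 19)
  }
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.2f", v)
  graphics::mtext(sprintf(
    "SDBG %s | MAGE+ %s | MAGE- %s | MAGE %s (%s) | MAGEa %s mmol/L",
    fmt(result$sdbg), fmt(result$mage_plus), fmt(result$mage_minus),
    fmt(result$mage), result$direction, fmt(result$mage_a)),
    side = 3, line = 0.2, cex = 0.8)
  invisible(NULL)
}
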