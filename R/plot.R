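## Base-graphics plot methods.

#' @export
plot.time_trace_1d <- function(x, ..., xlab = "T (ns)",
                               ylab = "echo amplitude") {
  graphics::plot(x$t_ns, x$values, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
plot.spectrum_1d <- function(x, ..., xlim = NULL, xlab = "frequency (MHz)",
                             ylab = "magnitude") {
  if (is.null(xlim)) xlim <- c(0, min(8, max(x$freq_MHz)))
  graphics::plot(x$freq_MHz, x$magnitude, type = "l", xlim = xlim,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
plot.spectrum_2d <- function(x, ..., max_MHz = 8, nlevels = 12,
                             xlab = expression(nu[1] ~ "(MHz)"),
                             ylab = expression(nu[2] ~ "(MHz)")) {
  i1 <- x$f1_MHz <= max_MHz; i2 <- x$f2_MHz <= max_MHz
  graphics::contour(x$f1_MHz[i1], x$f2_MHz[i2], x$magnitude[i1, i2],
                    nlevels = nlevels, xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
plot.time_trace_2d <- function(x, ...) {
  graphics::image(x$t1_ns, x$t2_ns, x$values,
                  xlab = "t1 (ns)", ylab = "t2 (ns)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
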