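# Two-panel figure in the conventional presentation: ROC curves on the
# left (panel a), CU curves on the right (panel b). First curve solid,
# second dashed; at most two curves per figure so the overlay stays
# readable.

#' Render ROC and CU curves to image files
#'
#' Draws a two-panel figure — panel (a) the ROC curve(s), panel (b) the CU
#' curve(s) with sensitivity as a percentage against NNCOC — and writes it
#' as PNG and SVG. The first curve is drawn solid, the second dashed. The
#' NNCOC axis can be linear, log-transformed, or truncated; log or
#' truncation help when a low positive predictive value pushes NNCOC into
#' the tens or hundreds.
#'
#' @param cu_curves List of one or two `cu_curve` objects.
#' @param roc_curves List of matching `roc_curve` objects, same length.
#' @param labels Character labels, one per curve.
#' @param path_base Output path without extension; `<path_base>.png` and
#'   `<path_base>.svg` are written.
#' @param x_scale `"linear"` (default) or `"log"` for the NNCOC axis.
#' @param x_max Optional truncation limit for the NNCOC axis.
#' @return Character vector of the two file paths, invisibly.
#' @export
render_curves <- function(cu_curves, roc_curves, labels = NULL, path_base,
                          x_scale = c("linear", "log"), x_max = NULL) {
  if (inherits(cu_curves, "cu_curve")) cu_curves <- list(cu_curves)
  if (inherits(roc_curves, "roc_curve")) roc_curves <- list(roc_curves)
  k <- length(cu_curves)
  if (k < 1 || k > 2) {
    stop("render_curves overlays one or two curves, not more", call. = FALSE)
  }
  if (length(roc_curves) != k) {
    stop("need one ROC curve per CU curve", call. = FALSE)
  }
  x_scale <- match.arg(x_scale)
  if (is.null(labels)) labels <- paste("model", seq_len(k))

  paths <- paste0(path_base, c(".png", ".svg"))
  devices <- list(
    function(f) grDevices::png(f, width = 1400, height = 700, res = 120),
    function(f) grDevices::svg(f, width = 11, height = 5.5)
  )
  for (i in seq_along(paths)) {
    devices[[i]](paths[i])
    draw_two_panel(cu_curves, roc_curves, labels, x_scale, x_max)
    grDevices::dev.off()
  }
  invisible(paths)
}

draw_two_panel <- function(cu_curves, roc_curves, labels, x_scale, x_max) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2.5, 1))
  on.exit(graphics::par(old), add = TRUE)
  ltys <- c(1, 2)

  # panel a: ROC
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity", main = "a")
  graphics::abline(0, 1, col = "grey80")
  for (i in seq_along(roc_curves)) {
    graphics::lines(roc_curves[[i]]$fpr, roc_curves[[i]]$sensitivity, lty = ltys[i])
  }

  # panel b: CU — sensitivity (%) vs NNCOC, zigzag drawn as-is
  xs <- unlist(lapply(cu_curves, function(cv) cv$points$nncoc))
  xlim <- c(1, if (!is.null(x_max)) x_max else max(xs))
  graphics::plot(NA, xlim = xlim, ylim = c(0, 100),
                 log = if (x_scale == "log") "x" else "",
                 xlab = "NNCOC", ylab = "Sensitivity (%)", main = "b")
  for (i in seq_along(cu_curves)) {
    pts <- cu_curves[[i]]$points
    keep <- if (!is.null(x_max)) pts$nncoc <= x_max else rep(TRUE, nrow(pts))
    graphics::lines(pts$nncoc[keep], 100 * pts$sensitivity[keep], lty = ltys[i])
  }
  graphics::legend("bottomright", legend = labels, lty = ltys[seq_along(cu_curves)],
                   bty = "n")
}

#' Plot method for CU curves
#'
#' Single-curve convenience plot on the current device: sensitivity (%)
#' against NNCOC, zigzag preserved.
#'
#' @param x A `cu_curve`.
#' @param x_scale `"linear"` or `"log"` NNCOC axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cu_curve <- function(x, x_scale = c("linear", "log"), ...) {
  x_scale <- match.arg(x_scale)
  pts <- x$points
  graphics::plot(pts$nncoc, 100 * pts$sensitivity, type = "l",
                 log = if (x_scale == "log") "x" else "",
                 xlab = "NNCOC", ylab = "Sensitivity (%)", ...)
  invisible(x)
}
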