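#' Plot a tissue snapshot
#'
#' Draws the cell polygons coloured by a per-cell field (auxin in greens,
#' CUC1 in blues, noise in greys) with optional PIN allocation marks drawn as
#' inward ticks on each wall side, scaled by the allocation.
#'
#' @param x a `tissue_mesh`
#' @param what per-cell field to colour by: `"aux"`, `"cuc"` or `"delta"`
#' @param pin draw PIN allocation marks
#' @param zlim colour scale range (defaults to the data range)
#' @param main plot title
#' @param ... passed to [graphics::plot.default()]
#' @return `x`, invisibly
#' @export
plot.tissue_mesh <- function(x, what = c("aux", "cuc", "delta"), pin = FALSE,
                             zlim = NULL, main = NULL, ...) {
  what <- match.arg(what)
  vals <- x[[what]]
  if (is.null(zlim)) zlim <- range(vals, 0)
  if (diff(zlim) == 0) zlim <- zlim + c(0, 1)
  ramp <- switch(what,
                 aux = grDevices::colorRampPalette(c("white", "#1a9641"))(64L),
                 cuc = grDevices::colorRampPalette(c("white", "#2c7bb6"))(64L),
                 delta = grDevices::colorRampPalette(c("white", "grey25"))(64L))
  idx <- pmin(64L, pmax(1L, 1L + floor(63 * (vals - zlim[1L]) / diff(zlim))))
  if (is.null(main))
    main <- sprintf("%s (iteration %d, %d cells)", what, x$iteration, n_cells(x))
  graphics::plot(NA, xlim = range(x$pos[, 1L]), ylim = range(x$pos[, 2L]),
                 asp = 1, xlab = "x (um)", ylab = "y (um)", main = main, ...)
  for (i in seq_len(n_cells(x))) {
    xy <- x$pos[x$loops[[i]], , drop = FALSE]
    graphics::polygon(xy[, 1L], xy[, 2L], col = ramp[idx[i]], border = "grey40",
                      lwd = 0.4)
  }
  if (pin) {
    ctr <- cell_centroids(x)
    for (side in 1:2) {
      cc <- if (side == 1L) x$walls$c1 else x$walls$c2
      pv <- if (side == 1L) x$walls$pin1 else x$walls$pin2
      sel <- which(!is.na(cc) & pv > 1e-4)
      if (!length(sel)) next
      p1 <- x$pos[x$walls$v1[sel], , drop = FALSE]
      p2 <- x$pos[x$walls$v2[sel], , drop = FALSE]
      mid <- (p1 + p2) / 2
      inward <- ctr[cc[sel], , drop = FALSE] - mid
      inward <- inward / sqrt(rowSums(inward^2))
      tick <- mid + inward * pmin(0.8, 4 * pv[sel])
      graphics::segments(mid[, 1L], mid[, 2L], tick[, 1L], tick[, 2L],
                         col = "#d7191c", lwd = 1.2)
    }
  }
  invisible(x)
}

#' Render a snapshot to an SVG file
#'
#' @param mesh a `tissue_mesh`
#' @param path output `.svg` path
#' @param ... passed to [plot.tissue_mesh()]
#' @return `path`, invisibly
#' @export
render_svg <- function(mesh, path, ...) {
  grDevices::svg(path, width = 7, height = 7)
  on.exit(grDevices::dev.off())
  plot(mesh, ...)
  invisible(path)
}
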