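#' Grayscale image of one concentration field
#'
#' Renders a field as a grayscale lattice image, normalised to the min-max
#' range of the non-PV cells (so the extreme clamped Delta of a PV cell does
#' not flatten the rest of the field); PV cells are overdrawn with a cross.
#'
#' @param state A [grid_state()].
#' @param which `"D"`, `"N"` or `"R"`.
#' @param main Plot title; defaults to the field name.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the normalised matrix that was drawn.
#' @export
plot_field <- function(state, which = c("R", "D", "N"), main = NULL, ...) {
  which <- match.arg(which)
  f <- state[[which]]
  keep <- !state$pv_mask
  rng <- range(f[keep])
  z <- if (diff(rng) > 0) (f - rng[1L]) / diff(rng) else f * 0 + 0.5
  z[z < 0] <- 0; z[z > 1] <- 1
  nr <- nrow(f); ncl <- ncol(f)
  # x = column, y = row with row 1 at the top
  graphics::image(x = seq_len(ncl), y = seq_len(nr),
                  z = t(z[nr:1, , drop = FALSE]),
                  col = gray.colors(256L, start = 0, end = 1),
                  xlab = "column", ylab = "row", axes = FALSE,
                  main = if (is.null(main)) which else main, ...)
  graphics::box()
  pv <- which(state$pv_mask, arr.ind = TRUE)
  if (nrow(pv) > 0L) {
    graphics::points(pv[, 2L], nr + 1L - pv[, 1L], pch = 4L, cex = 2L,
                     lwd = 2L, col = "red")
  }
  invisible(z)
}

#' @importFrom grDevices gray.colors colorRampPalette
NULL

#' Heatmap of a 2-D production-rate sweep
#'
#' Log2 averaged diff values on a blue-red diverging scale centred at the
#' cholangiocyte cutoff (log2 diff = 1): red above the cutoff
#' (differentiation), blue below. Sentinel cells (infinite, negative,
#' non-converged, failed) are marked with crosses.
#'
#' @param x A `sweep_grid` from [sweep_2d()].
#' @param center Colour-scale centre on the log2 scale (default 1).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly `x`.
#' @export
plot.sweep_grid <- function(x, center = 1, ...) {
  v <- x$log2
  pal <- colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255L)
  if (any(is.finite(v))) {
    hw <- max(abs(range(v, na.rm = TRUE) - center), 1e-9)
  } else {
    v[] <- center
    hw <- 1
  }
  graphics::image(x = seq_along(x$beta_D_values),
                  y = seq_along(x$beta_N_values),
                  z = t(v), col = pal,
                  zlim = c(center - hw, center + hw),
                  xlab = "beta_D", ylab = "beta_N", axes = FALSE,
                  main = sprintf("log2(diff), m = %g, n = %g",
                                 x$panel_params["m"], x$panel_params["n"]),
                  ...)
  graphics::axis(1L, at = seq_along(x$beta_D_values),
                 labels = signif(x$beta_D_values, 3L), las = 2L)
  graphics::axis(2L, at = seq_along(x$beta_N_values),
                 labels = signif(x$beta_N_values, 3L), las = 1L)
  graphics::box()
  sent <- which(is.na(x$log2), arr.ind = TRUE)
  if (nrow(sent) > 0L) {
    graphics::points(sent[, 2L], sent[, 1L], pch = 4L, cex = 1.5, lwd = 2L)
  }
  invisible(x)
}
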