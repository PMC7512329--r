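#' Plot a (ranked) incidence matrix with its isocline
#'
#' Draws the matrix in the unit square, generalist corner top-left, with
#' filled cells dark and, when the fill permits, the calibrated line of
#' perfect nestedness overlaid in red.
#'
#' @param x an [incidence_matrix()].
#' @param r optional [ranking()] applied before plotting (default: input
#'   order).
#' @param isocline draw the isocline if the matrix fill allows one
#'   (default `TRUE`).
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.incidence_matrix <- function(x, r = identity_ranking(x),
                                  isocline = TRUE, main = NULL, ...) {
  stopifnot_incidence(x)
  ranked <- reorder(x, r)
  N <- nrow(ranked); M <- ncol(ranked)
  # image() draws x[i, j] at (i, j); transpose + flip so row rank 1 is top
  z <- t(unclass(ranked)[N:1, , drop = FALSE])
  graphics::image(x = (seq_len(M) - 0.5) / M, y = (seq_len(N) - 0.5) / N,
                  z = z, zlim = c(0, 1), col = c("white", "grey20"),
                  xlab = "column rank (rescaled)", ylab = "row rank (rescaled)",
                  main = main %||% sprintf("%d x %d, fill %.2f", N, M,
                                           fill_density(x)),
                  useRaster = TRUE, ...)
  phi <- fill_density(x)
  if (isocline && phi > 0 && phi < 1 && N >= 2 && M >= 2) {
    iso <- tryCatch(solve_isocline(N, M, phi), error = function(e) NULL)
    if (!is.null(iso)) {
      xs <- seq(0, 1, length.out = 512)
      graphics::lines(xs, isocline_value(iso, xs), col = "red", lwd = 2)
    }
  }
  invisible(x)
}
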