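#' Render a SpheriCell map as a half-disc wedge plot
#'
#' Draws the 6 x 3 shell-by-sector grid as a half disc: shells are radial
#' rings and the three latitude sectors are mirrored about the equator
#' (division plane), giving the longitudinal-cut view of the spherical ROI
#' system.  Values are color-coded; \code{NA} wedges (masked or
#' non-significant ROIs) are hatched grey.
#'
#' @param values 6 x 3 matrix (shells x sectors, sectors ordered polar,
#'   diagonal, equatorial), e.g. from [project_map()] or
#'   [roi_comparisons()].
#' @param file output PNG path; \code{NULL} draws on the current device.
#' @param style \code{"sequential"} (single-hue, for intensities) or
#'   \code{"diverging"} (blue-white-red centered at 0, for effect maps).
#' @param main plot title.
#' @param zlim value range for the color scale (default data range).
#' @return Invisibly, the color matrix used.
#' @export
render_map <- function(values, file = NULL,
                       style = c("sequential", "diverging"), main = "",
                       zlim = NULL) {
  style <- match.arg(style)
  stopifnot(all(dim(values) == c(6, 3)))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  finite <- values[is.finite(values)]
  if (is.null(zlim))
    zlim <- if (length(finite)) range(finite) else c(0, 1)
  if (diff(zlim) == 0) zlim <- zlim + c(-0.5, 0.5)
  pal <- if (style == "sequential") {
    grDevices::colorRampPalette(c("#FFFFD9", "#41B6C4", "#081D58"))(256)
  } else {
    m <- max(abs(zlim)); zlim <- c(-m, m)
    grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(256)
  }
  col_of <- function(v) {
    if (!is.finite(v)) return(NA_character_)
    pal[pmax(1, pmin(256, 1 + floor((v - zlim[1]) / diff(zlim) * 255)))]
  }
  cols <- apply(values, c(1, 2), col_of)

  graphics::par(mar = c(1, 1, 3, 6))
  graphics::plot(NA, xlim = c(-0.05, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  # latitude bands (degrees from the equator), mirrored above/below
  bands <- rbind(polar = c(60, 90), diagonal = c(30, 60), equatorial = c(0, 30))
  for (mu in 1:6) for (nu in 1:3) {
    r0 <- (mu - 1) / 6; r1 <- mu / 6
    for (sgn in c(1, -1)) {
      th <- seq(bands[nu, 1], bands[nu, 2], length.out = 20) * pi / 180 * sgn
      xs <- c(r0 * cos(th), rev(r1 * cos(th)))
      ys <- c(r0 * sin(th), rev(r1 * sin(th)))
      cc <- cols[mu, nu]
      graphics::polygon(xs, ys, col = if (is.na(cc)) "grey85" else cc,
                        border = "grey40", lwd = 0.5,
                        density = if (is.na(cc)) 12 else NULL)
    }
  }
  # color scale
  ticks <- seq(zlim[1], zlim[2], length.out = 5)
  ys <- seq(-0.8, 0.8, length.out = 257)
  for (k in 1:256)
    graphics::rect(1.02, ys[k], 1.08, ys[k + 1], col = pal[k], border = NA)
  graphics::text(1.09, seq(-0.8, 0.8, length.out = 5),
                 labels = format(ticks, digits = 2), adj = 0, cex = 0.7)
  invisible(cols)
}
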