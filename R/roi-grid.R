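#' Spherical ROI grid of the standardized mitotic cell
#'
#' The standardized cell ("SpheriCell") divides the registered cell sphere
#' into 6 concentric shells of equal radial width and 3 latitude sectors
#' relative to the division plane, giving 18 regions of interest (ROIs).
#' Sectors are defined on the absolute latitude \eqn{|\lambda|} measured from
#' the equatorial (division) plane: equatorial \eqn{[0, 30)} degrees, diagonal
#' \eqn{[30, 60)}, polar \eqn{[60, 90]}.  Each shell carries a dimensionless
#' eccentricity value \eqn{r_\mu = (\mu - 1/2)/6} (shell mid-radius relative
#' to the sphere radius) and each sector an orientation value \eqn{\phi_\nu},
#' the angle of its mid-latitude direction from the mitotic axis: polar 15,
#' diagonal 45, equatorial 75 degrees.  These enter the per-cell center of
#' eccentricity and center of orientation measures.
#'
#' @return An object of class \code{roi_grid}: a list with elements
#'   \code{n_shells}, \code{n_sectors}, \code{sectors} (names, from the pole
#'   to the equator), \code{shell_edges} (relative radii 0..1 in steps of
#'   1/6), \code{sector_bands} (latitude intervals in degrees, rows named by
#'   sector), \code{r_mu} and \code{phi_nu}.
#' @examples
#' g <- roi_grid()
#' g$n_shells * g$n_sectors  # 18 ROIs
#' @export
roi_grid <- function() {
  sectors <- c("polar", "diagonal", "equatorial")
  bands <- rbind(polar = c(60, 90), diagonal = c(30, 60), equatorial = c(0, 30))
  colnames(bands) <- c("lat_lo", "lat_hi")
  g <- list(
    n_shells  = 6L,
    n_sectors = 3L,
    sectors   = sectors,
    shell_edges = (0:6) / 6,
    sector_bands = bands,
    r_mu    = (1:6 - 0.5) / 6,
    phi_nu  = c(polar = 15, diagonal = 45, equatorial = 75)
  )
  class(g) <- "roi_grid"
  g
}

#' @export
print.roi_grid <- function(x, ...) {
  cat("SpheriCell ROI grid: ", x$n_shells, " shells x ", x$n_sectors,
      " sectors = ", x$n_shells * x$n_sectors, " ROIs\n", sep = "")
  cat("  shell eccentricities r_mu:", format(x$r_mu, digits = 3), "\n")
  cat("  sector orientations phi_nu (deg):",
      paste(names(x$phi_nu), x$phi_nu, sep = "="), "\n")
  invisible(x)
}

# ROI flattening order used throughout: shell fastest within sector, sectors
# ordered polar, diagonal, equatorial; l = (nu - 1) * 6 + mu.
roi_labels <- function(grid = roi_grid()) {
  as.vector(outer(seq_len(grid$n_shells), grid$sectors,
                  function(mu, s) paste0("s", mu, ".", s)))
}

# relative ROI volume fractions of the unit ball (shell x sector), summing to 1
roi_volume_fractions <- function(grid = roi_grid()) {
  shell_frac <- diff(grid$shell_edges^3)                # (mu^3-(mu-1)^3)/216
  lat <- grid$sector_bands * pi / 180
  sector_frac <- sin(lat[, "lat_hi"]) - sin(lat[, "lat_lo"])  # radial cones
  v <- outer(shell_frac, sector_frac)
  dimnames(v) <- list(shell = 1:6, sector = grid$sectors)
  v
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error level (default 0.05).
#' @param m number of comparisons in the family (default 52, the number of
#'   per-species comparisons used for the concentration/abundance/
#'   eccentricity/orientation panels).
#' @return The per-comparison threshold \code{alpha / m}.
#' @examples
#' bonferroni_threshold(m = 52)  # approx 9.62e-4
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 52) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}
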