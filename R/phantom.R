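#' Configuration for a synthetic mitotic-cell phantom
#'
#' Defines the geometry and staining patterns of a seeded image phantom with
#' known ground truth, used to exercise the registration and binning pipeline
#' without microscope data.  Metaphase chromatin is a solid oblate ellipsoid
#' whose shortest half-axis is parallel to the mitotic axis (the metaphase
#' plate); during segregation two congruent daughter ellipsoids sit
#' symmetrically on the axis, their centroids \code{centroid_distance} apart.
#'
#' @param phase \code{"metaphase"} or \code{"segregation"}.
#' @param stack_shape integer length-3, stack size in voxels (z, y, x).
#' @param voxel_spacing numeric length-3, micrometer per voxel (z, y, x).
#' @param axis_direction unit 3-vector (z, y, x), the true mitotic axis.
#' @param chromatin_half_axes numeric length-3 in micrometer, descending
#'   (a >= b >= c); the shortest half-axis is aligned with the mitotic axis.
#' @param centroid_distance micrometer between daughter centroids
#'   (segregation only; must be > 0 exactly when \code{phase} is
#'   \code{"segregation"}).
#' @param center optional true center in micrometer (z, y, x); defaults to
#'   the stack center.
#' @param channel_patterns list of channel specifications, each a list with
#'   \code{channel_name}, \code{pattern} (one of \code{"chromatin"},
#'   \code{"spindle"}, \code{"centrosome"}, \code{"uniform"},
#'   \code{"cytoplasmic-shell"}) and \code{amplitude}.  The DAPI channel
#'   should use the \code{"chromatin"} pattern.
#' @param noise list with \code{gaussian_sd} (additive read noise, intensity
#'   units) and \code{poisson_scale} (photon shot noise; 0 disables).
#' @param background scalar background intensity added to every voxel.
#' @return An object of class \code{phantom_config}.
#' @seealso [make_phantom()]
#' @export
phantom_config <- function(phase = c("metaphase", "segregation"),
                           stack_shape = c(40L, 72L, 72L),
                           voxel_spacing = c(1, 0.5, 0.5),
                           axis_direction = c(1, 0, 0),
                           chromatin_half_axes = c(8, 8, 4),
                           centroid_distance = if (match.arg(phase) == "segregation") 10 else 0,
                           center = NULL,
                           channel_patterns = list(
                             list(channel_name = "DAPI", pattern = "chromatin", amplitude = 100),
                             list(channel_name = "b-tubulin", pattern = "spindle", amplitude = 80),
                             list(channel_name = "g-tubulin", pattern = "centrosome", amplitude = 120)
                           ),
                           noise = list(gaussian_sd = 2, poisson_scale = 0),
                           background = 10) {
  phase <- match.arg(phase)
  stopifnot(length(stack_shape) == 3L, all(stack_shape >= 4))
  stopifnot(length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  ax <- chromatin_half_axes
  if (length(ax) != 3L || any(ax <= 0))
    stop("'chromatin_half_axes' must be 3 positive half-axes in um", call. = FALSE)
  if (is.unsorted(rev(ax)))
    stop("'chromatin_half_axes' must be ordered descending (a >= b >= c)", call. = FALSE)
  if (!is_unit3(axis_direction))
    stop("'axis_direction' must have unit norm (tol 1e-9)", call. = FALSE)
  if (phase == "segregation" && !(centroid_distance > 0))
    stop("'centroid_distance' must be > 0 for segregation phantoms", call. = FALSE)
  if (phase == "metaphase" && centroid_distance != 0)
    stop("'centroid_distance' applies to segregation phantoms only", call. = FALSE)
  patterns <- c("chromatin", "spindle", "centrosome", "uniform", "cytoplasmic-shell")
  nm <- vapply(channel_patterns, function(p) p$channel_name, character(1))
  if (anyDuplicated(nm)) stop("duplicate channel names", call. = FALSE)
  for (p in channel_patterns) {
    if (!p$pattern %in% patterns)
      stop("unknown pattern '", p$pattern, "'", call. = FALSE)
    if (!is.numeric(p$amplitude) || p$amplitude < 0)
      stop("pattern amplitude must be nonnegative", call. = FALSE)
  }
  if (!"DAPI" %in% nm) stop("a 'DAPI' channel pattern is required", call. = FALSE)
  if (is.null(center))
    center <- (stack_shape - 1) * voxel_spacing / 2
  structure(list(phase = phase, stack_shape = as.integer(stack_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 axis_direction = as.numeric(axis_direction),
                 chromatin_half_axes = as.numeric(ax),
                 centroid_distance = centroid_distance,
                 center = as.numeric(center),
                 channel_patterns = channel_patterns,
                 noise = noise, background = background),
            class = "phantom_config")
}

# squared normalized ellipsoid coordinate of points P (n x 3, um) for an
# ellipsoid at `center` with frame (e1, e2, u) and half-axes (a, b, c),
# c along u; inside iff value <= 1
ellipsoid_q <- function(P, center, basis, half_axes) {
  D <- sweep(P, 2, center)
  (D %*% basis[, 1])^2 / half_axes[1]^2 +
    (D %*% basis[, 2])^2 / half_axes[2]^2 +
    (D %*% basis[, 3])^2 / half_axes[3]^2
}

# check the axis-aligned extent of an ellipsoid against the stack bounds
check_ellipsoid_bounds <- function(center, basis, half_axes, extent_um) {
  for (k in 1:3) {
    half_extent <- sqrt(sum((half_axes * basis[k, ])^2))
    if (center[k] - half_extent < 0 || center[k] + half_extent > extent_um[k])
      stop("chromatin ellipsoid exceeds stack bounds along the ",
           c("z", "y", "x")[k], " axis", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a seeded mitotic-cell image phantom
#'
#' Synthesizes a multi-channel 3D stack with known mitotic geometry: chromatin
#' ellipsoid(s) in the DAPI channel and, per configuration, a spindle pattern
#' along the axis between the two spindle poles, centrosome blobs at the
#' poles, a uniform stain, or a cytoplasmic shell.  Gaussian read noise and
#' optional Poisson shot noise are added after pattern synthesis and the
#' result is clipped at zero.  The same \code{(config, seed)} pair always
#' yields a bit-identical stack.
#'
#' @param config a [phantom_config()].
#' @param seed integer RNG seed.
#' @return A list with elements \code{stack} (an [image_stack()]) and
#'   \code{truth}, the ground-truth geometry: \code{true_center},
#'   \code{true_axis} (unit, sign-normalized), \code{true_sphere_radius}
#'   (1.5 x longest chromatin half-axis for metaphase; 1.5 x half the
#'   centroid distance for segregation) and \code{true_phase}.
#' @examples
#' ph <- make_phantom(phantom_config(noise = list(gaussian_sd = 0, poisson_scale = 0)), seed = 1)
#' ph$truth$true_sphere_radius  # 1.5 * 8 = 12 um
#' @export
make_phantom <- function(config, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  u <- unit3(config$axis_direction)
  basis <- cbind(orthonormal_complement(u), u)  # (e1, e2, u); c-axis along u
  shp <- config$stack_shape
  sp <- config$voxel_spacing
  extent_um <- (shp - 1) * sp
  ha <- config$chromatin_half_axes
  ctr <- config$center

  if (config$phase == "metaphase") {
    chrom_centers <- list(ctr)
    R <- 1.5 * ha[1]
  } else {
    off <- config$centroid_distance / 2
    chrom_centers <- list(ctr - off * u, ctr + off * u)
    R <- 1.5 * off
  }
  for (cc in chrom_centers) check_ellipsoid_bounds(cc, basis, ha, extent_um)

  ax <- stack_axis_coords(list(voxels = array(0, c(shp, 1)), spacing = sp))
  P <- as.matrix(expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  n_vox <- nrow(P)

  chromatin_mask <- rep(FALSE, n_vox)
  for (cc in chrom_centers)
    chromatin_mask <- chromatin_mask | (ellipsoid_q(P, cc, basis, ha) <= 1)

  D <- sweep(P, 2, ctr)
  t_ax <- as.vector(D %*% u)            # signed coordinate along the axis
  rho2 <- rowSums(D^2)
  radial2 <- pmax(rho2 - t_ax^2, 0)     # squared distance from the axis line
  pole_offset <- 0.75 * R
  sigma_pole <- 1.0                     # um, centrosome blob width
  spindle_w <- 0.15 * R                 # um, spindle half-width

  pattern_values <- function(pattern, amplitude) {
    switch(pattern,
      chromatin = amplitude * chromatin_mask,
      uniform = rep(amplitude, n_vox),
      spindle = {
        along <- abs(t_ax) <= pole_offset
        amplitude * along * (0.3 + 0.7 * abs(t_ax) / pole_offset) *
          exp(-radial2 / (2 * spindle_w^2))
      },
      centrosome = {
        d1 <- rho2 - 2 * pole_offset * t_ax + pole_offset^2
        d2 <- rho2 + 2 * pole_offset * t_ax + pole_offset^2
        amplitude * (exp(-d1 / (2 * sigma_pole^2)) + exp(-d2 / (2 * sigma_pole^2)))
      },
      `cytoplasmic-shell` = amplitude * (rho2 > (0.5 * R)^2 & rho2 <= R^2),
      stop("unknown pattern '", pattern, "'", call. = FALSE))
  }

  n_chan <- length(config$channel_patterns)
  vox <- array(0, dim = c(shp, n_chan))
  nm <- character(n_chan)
  for (ci in seq_len(n_chan)) {
    pat <- config$channel_patterns[[ci]]
    nm[ci] <- pat$channel_name
    vox[, , , ci] <- config$background + pattern_values(pat$pattern, pat$amplitude)
  }

  vox <- with_seed(seed, {
    v <- vox
    if ((config$noise$poisson_scale %||% 0) > 0) {
      s <- config$noise$poisson_scale
      v[] <- stats::rpois(length(v), lambda = as.vector(v) * s) / s
    }
    if ((config$noise$gaussian_sd %||% 0) > 0)
      v[] <- v + stats::rnorm(length(v), sd = config$noise$gaussian_sd)
    pmax(v, 0)
  })

  truth <- list(true_center = ctr, true_axis = canonical_axis_sign(u),
                true_sphere_radius = R, true_phase = config$phase)
  list(stack = image_stack(vox, sp, nm), truth = truth)
}
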