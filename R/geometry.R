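#' Segment chromatin regions in the DAPI channel
#'
#' Applies a global Otsu threshold to the DAPI channel and extracts
#' 26-connected foreground components, discarding components smaller than
#' \code{min_volume}.  Metaphase cells yield one chromatin region, cells in
#' segregation two.
#'
#' @param stack an [image_stack()] with a DAPI channel.
#' @param min_volume minimum component volume in cubic micrometer
#'   (default 20).
#' @return A list of class \code{chromatin_components}; each component has
#'   \code{indices} (linear voxel indices into the (z, y, x) array),
#'   \code{n_voxels} and \code{volume_um3}.  Components are sorted by volume,
#'   descending.  The Otsu threshold used is stored as attribute
#'   \code{threshold}.
#' @export
segment_chromatin <- function(stack, min_volume = 20) {
  stopifnot(inherits(stack, "image_stack"))
  dapi <- stack_channel(stack, "DAPI")
  rng <- range(dapi)
  if (diff(rng) <= 0) stop("no chromatin found: constant DAPI channel", call. = FALSE)
  # global 3D Otsu: treat the flattened volume as a single frame
  norm <- (as.vector(dapi) - rng[1]) / diff(rng)
  thr_norm <- EBImage::otsu(EBImage::Image(matrix(norm, nrow = length(norm))),
                            range = c(0, 1))
  threshold <- rng[1] + thr_norm * diff(rng)
  mask <- dapi > threshold

  comps <- connected_components_26(mask)
  vox_vol <- prod(stack$spacing)
  comps <- lapply(comps, function(idx)
    list(indices = idx, n_voxels = length(idx), volume_um3 = length(idx) * vox_vol))
  comps <- comps[vapply(comps, `[[`, numeric(1), "volume_um3") >= min_volume]
  if (length(comps) == 0L)
    stop("no chromatin found: no component above min_volume = ", min_volume,
         " um^3", call. = FALSE)
  ord <- order(vapply(comps, `[[`, numeric(1), "volume_um3"), decreasing = TRUE)
  structure(comps[ord], class = "chromatin_components",
            threshold = threshold, dim = NULL, stack_dim = dim(dapi),
            spacing = stack$spacing)
}

# 26-connected components of a 3D logical array, via the undirected voxel
# adjacency graph (igraph); returns a list of linear-index vectors
connected_components_26 <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  coords <- arrayInd(fg, d)
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # keep one of each +/- pair (undirected edges)
  offsets <- offsets[offsets[, 1] > 0 |
                     (offsets[, 1] == 0 & offsets[, 2] > 0) |
                     (offsets[, 1] == 0 & offsets[, 2] == 0 & offsets[, 3] > 0),
                     , drop = FALSE]
  edges_from <- integer(0); edges_to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- coords + matrix(offsets[r, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- mask[lin]
    edges_from <- c(edges_from, fg[ok][hit])
    edges_to <- c(edges_to, lin[hit])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges_from), to = as.character(edges_to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(fg)))
  memb <- igraph::components(g)$membership
  split(as.integer(names(memb)), memb)
}

#' Fit an ellipsoid to a binary voxel component by second moments
#'
#' The component's voxel centers (in physical micrometers) define a centroid
#' and a covariance matrix; the ellipsoid axes are the covariance
#' eigenvectors and the half-axes are \eqn{\sqrt{5\lambda}} of the
#' eigenvalues, the exact relation for a uniform solid ellipsoid.
#'
#' @param component one element of [segment_chromatin()] output (a list with
#'   \code{indices}), or a plain vector of linear voxel indices.
#' @param dim integer length-3 array dimension (z, y, x); taken from the
#'   component's attributes when available.
#' @param spacing voxel spacing in micrometer (z, y, x).
#' @return A list of class \code{ellipsoid_fit} with \code{centroid} (um),
#'   \code{half_axes} (um, descending) and \code{axes} (3 orthonormal
#'   columns paired with the half-axes).
#' @export
fit_ellipsoid <- function(component, dim, spacing) {
  idx <- if (is.list(component)) component$indices else component
  if (length(idx) < 4L)
    stop("degenerate component: need at least 4 voxels for an ellipsoid fit",
         call. = FALSE)
  coords <- arrayInd(idx, dim)
  P <- sweep(coords - 1, 2, spacing, `*`)
  centroid <- colMeans(P)
  Pc <- sweep(P, 2, centroid)
  V <- crossprod(Pc) / nrow(Pc)
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values))
    stop("degenerate covariance: voxels are (nearly) coplanar", call. = FALSE)
  structure(list(centroid = centroid,
                 half_axes = sqrt(5 * ev$values),
                 axes = ev$vectors),
            class = "ellipsoid_fit")
}

#' Build the mitotic reference frame from chromatin ellipsoid fit(s)
#'
#' Metaphase: the mitotic axis is the eigenvector of the shortest half-axis
#' of the single chromatin ellipsoid (the spindle axis, perpendicular to the
#' metaphase plate); the center is the ellipsoid centroid and the sphere
#' radius is \eqn{R = 1.5 a_1}, placing the outer edge of the fourth of six
#' shells at the longest half-axis \eqn{a_1}.  Segregation: the axis is the
#' normalized centroid-to-centroid vector of the two daughter fits, the
#' center their midpoint, and \eqn{R = 1.5 \cdot d/2} so that the fourth
#' shell boundary passes through both centroids.  The axis sign is
#' normalized to a nonnegative z-component (ties broken on y, then x);
#' downstream binning is insensitive to the sign.
#'
#' @param phase \code{"metaphase"} (one fit) or \code{"segregation"} (two).
#' @param fits a single [fit_ellipsoid()] result or a list of one or two.
#' @return A list of class \code{mitotic_frame} with \code{phase},
#'   \code{center}, \code{axis} and \code{sphere_radius}, all in physical
#'   micrometer coordinates.
#' @export
build_frame <- function(phase = c("metaphase", "segregation"), fits) {
  phase <- match.arg(phase)
  if (inherits(fits, "ellipsoid_fit")) fits <- list(fits)
  if (phase == "metaphase") {
    if (length(fits) != 1L)
      stop("metaphase requires exactly 1 ellipsoid fit", call. = FALSE)
    f <- fits[[1]]
    axis <- canonical_axis_sign(f$axes[, which.min(f$half_axes)])
    frame <- list(phase = phase, center = f$centroid, axis = axis,
                  sphere_radius = 1.5 * max(f$half_axes))
  } else {
    if (length(fits) != 2L)
      stop("segregation requires exactly 2 ellipsoid fits", call. = FALSE)
    dvec <- fits[[2]]$centroid - fits[[1]]$centroid
    dist <- sqrt(sum(dvec^2))
    if (dist < 1e-9)
      stop("coincident daughter centroids: mitotic axis undefined", call. = FALSE)
    frame <- list(phase = phase,
                  center = (fits[[1]]$centroid + fits[[2]]$centroid) / 2,
                  axis = canonical_axis_sign(dvec / dist),
                  sphere_radius = 1.5 * dist / 2)
  }
  class(frame) <- "mitotic_frame"
  frame
}

#' @export
print.mitotic_frame <- function(x, ...) {
  cat("mitotic_frame [", x$phase, "]\n",
      "  center (z,y,x um): ", paste(format(x$center, digits = 4), collapse = ", "), "\n",
      "  axis   (z,y,x):    ", paste(format(x$axis, digits = 4), collapse = ", "), "\n",
      "  sphere radius:     ", format(x$sphere_radius, digits = 4), " um\n", sep = "")
  invisible(x)
}

#' Assign points to spherical ROIs
#'
#' Maps physical points to (shell, sector) ROI indices of a mitotic frame.
#' The shell index is \code{min(6, floor(6 rho / R) + 1)} of the radial
#' distance \code{rho} (the center falls in shell 1, \code{rho = R} in shell
#' 6); points with \code{rho > R} are outside.  The sector follows the
#' absolute latitude from the division plane with lower-inclusive bands, so
#' the assignment is a total, deterministic function that is invariant under
#' flipping the axis sign.
#'
#' @param points numeric 3-vector or n x 3 matrix of (z, y, x) positions, um.
#' @param frame a [build_frame()] result.
#' @param grid a [roi_grid()].
#' @return A data frame with integer column \code{shell} and factor column
#'   \code{sector}; both are \code{NA} for points outside the sphere.
#' @export
assign_roi <- function(points, frame, grid = roi_grid()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  D <- sweep(points, 2, frame$center)
  rho <- sqrt(rowSums(D^2))
  R <- frame$sphere_radius
  inside <- rho <= R

  shell <- rep(NA_integer_, nrow(points))
  shell[inside] <- pmin(6L, floor(6 * rho[inside] / R) + 1L)

  # |latitude| from the equatorial plane = 90 - angle(point - center, axis)
  cosang <- abs(as.vector(D %*% frame$axis)) / pmax(rho, .Machine$double.eps)
  cosang[rho == 0] <- 0                  # center: latitude 0, shell 1
  lat <- 90 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi

  sector <- rep(NA_character_, nrow(points))
  bands <- grid$sector_bands
  for (s in rownames(bands)) {
    hi_ok <- if (bands[s, "lat_hi"] >= 90) lat <= 90 else lat < bands[s, "lat_hi"]
    sector[inside & lat >= bands[s, "lat_lo"] & hi_ok] <- s
  }
  data.frame(shell = shell,
             sector = factor(sector, levels = grid$sectors))
}
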