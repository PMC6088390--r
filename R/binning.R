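#' Bin a registered stack into the 18 spherical ROIs
#'
#' Resamples the stack to isotropic voxels (linear interpolation along z to
#' match the in-plane spacing, which must be equal in y and x), assigns every
#' voxel center inside the cell sphere to its (shell, sector) ROI and
#' averages the fluorescence of member voxels per channel.  Every in-sphere
#' voxel is counted in exactly one ROI.
#'
#' @param stack an [image_stack()].
#' @param frame a [build_frame()] result whose sphere intersects the stack.
#' @param grid a [roi_grid()].
#' @return An object of class \code{sphericell_map}: a list with
#'   \code{intensities} (6 x 3 x channel array of ROI mean intensities;
#'   \code{NA} where an ROI holds no voxel), \code{volumes} and
#'   \code{voxel_counts} (6 x 3), \code{frame}, \code{grid} and
#'   \code{channel_names}.  A warning reports the clipped volume when the
#'   sphere extends beyond the stack.
#' @export
bin_stack <- function(stack, frame, grid = roi_grid()) {
  stopifnot(inherits(stack, "image_stack"), inherits(frame, "mitotic_frame"))
  sp <- stack$spacing
  if (abs(sp[2] - sp[3]) > 1e-9 * sp[2])
    stop("in-plane spacing must be isotropic (y and x equal)", call. = FALSE)
  iso <- sp[2]

  d <- dim(stack$voxels)
  z_max <- (d[1] - 1) * sp[1]
  zq <- seq(0, z_max, by = iso)
  # linear interpolation weights along z
  i0 <- pmin(floor(zq / sp[1]) + 1, d[1] - 1L)
  w <- zq / sp[1] - (i0 - 1)

  nzq <- length(zq)
  R <- frame$sphere_radius
  ctr <- frame$center
  coords <- list(zq, (seq_len(d[2]) - 1) * iso, (seq_len(d[3]) - 1) * iso)
  # restrict to the sphere's bounding box to keep memory flat
  win <- lapply(1:3, function(k) which(coords[[k]] >= ctr[k] - R &
                                       coords[[k]] <= ctr[k] + R))
  if (any(vapply(win, length, integer(1)) == 0L))
    stop("cell sphere lies fully outside the stack", call. = FALSE)

  P <- as.matrix(expand.grid(z = coords[[1]][win[[1]]],
                             y = coords[[2]][win[[2]]],
                             x = coords[[3]][win[[3]]],
                             KEEP.OUT.ATTRS = FALSE))
  roi <- assign_roi(P, frame, grid)
  inside <- !is.na(roi$shell)
  l_idx <- (as.integer(roi$sector[inside]) - 1L) * grid$n_shells +
    roi$shell[inside]

  counts_flat <- tabulate(l_idx, nbins = 18L)
  vox_vol <- iso^3
  sphere_vol <- 4 / 3 * pi * R^3
  covered <- sum(counts_flat) * vox_vol
  clipped <- any(ctr - R < 0) || any(ctr + R > vapply(coords, max, numeric(1)))
  if (clipped)
    warning(sprintf("cell sphere clipped by the stack: ~%.1f um^3 of %.1f um^3 not covered",
                    max(sphere_vol - covered, 0), sphere_vol), call. = FALSE)

  n_chan <- d[4]
  intens <- matrix(NA_real_, 18L, n_chan)
  i0w <- i0[win[[1]]]
  ww <- w[win[[1]]]
  for (ci in seq_len(n_chan)) {
    ch <- stack$voxels[, , , ci]
    # resample along z (weights recycle down the z-major first dimension)
    iso_ch <- ch[i0w, win[[2]], win[[3]], drop = FALSE] * (1 - ww) +
      ch[i0w + 1L, win[[2]], win[[3]], drop = FALSE] * ww
    vals <- as.vector(iso_ch)[inside]
    sums <- rep(0, 18L)
    agg <- rowsum(vals, l_idx)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    intens[, ci] <- ifelse(counts_flat > 0, sums / counts_flat, NA_real_)
  }

  dim(intens) <- c(grid$n_shells, grid$n_sectors, n_chan)
  dimnames(intens) <- list(shell = 1:6, sector = grid$sectors,
                           channel = stack$channel_names)
  counts <- matrix(counts_flat, grid$n_shells, grid$n_sectors,
                   dimnames = list(shell = 1:6, sector = grid$sectors))
  structure(list(intensities = intens,
                 volumes = counts * vox_vol,
                 voxel_counts = counts,
                 frame = frame, grid = grid,
                 channel_names = stack$channel_names),
            class = "sphericell_map")
}

#' @export
print.sphericell_map <- function(x, ...) {
  cat("sphericell_map: 6 shells x 3 sectors, channels: ",
      paste(x$channel_names, collapse = ", "), "\n",
      "  phase ", x$frame$phase, ", R = ",
      format(x$frame$sphere_radius, digits = 4), " um, ",
      sum(x$voxel_counts), " voxels binned\n", sep = "")
  invisible(x)
}

#' Project SpheriCell maps to 2D polar-grid values
#'
#' Extracts the 6 x 3 shell-by-sector value grid of one channel for plotting
#' as a half-disc of wedges.  ROIs whose DAPI mean is below \code{dapi_floor}
#' are masked (\code{NA}) to suppress antibody background outside chromatin-
#' bearing regions.  With \code{normalize = TRUE} values are min-max scaled
#' to \[0, 1\] jointly over all supplied maps; a constant collection maps to
#' 0 by convention.
#'
#' @param maps a single \code{sphericell_map} or a list of them (the
#'   normalization collection).
#' @param channel channel name to project.
#' @param normalize logical; min-max scale over the collection.
#' @param dapi_floor optional DAPI mean threshold for masking.
#' @return A 6 x 3 matrix for a single map, else a list of matrices.
#' @export
project_map <- function(maps, channel, normalize = FALSE, dapi_floor = NULL) {
  single <- inherits(maps, "sphericell_map")
  if (single) maps <- list(maps)
  vals <- lapply(maps, function(m) {
    v <- m$intensities[, , channel]
    if (!is.null(dapi_floor)) {
      dapi <- m$intensities[, , "DAPI"]
      v[!is.na(dapi) & dapi < dapi_floor] <- NA
    }
    if (all(is.na(v))) stop("all ROIs masked in a map", call. = FALSE)
    v
  })
  if (normalize) {
    rng <- range(unlist(vals), na.rm = TRUE)
    vals <- lapply(vals, function(v)
      if (diff(rng) <= 0) v * 0 else (v - rng[1]) / diff(rng))
  }
  if (single) vals[[1]] else vals
}
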