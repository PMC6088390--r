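#' Multi-channel 3D image stack
#'
#' Container for one registered multi-channel 3D fluorescence stack with
#' physical voxel spacing.  Voxels are stored as a 4D array with dimensions
#' (z, y, x, channel); all geometry downstream works in physical micrometers
#' with the center of voxel (1, 1, 1) at the origin, so results are
#' independent of the (possibly anisotropic) voxel spacing.
#'
#' @param voxels numeric array, either (z, y, x) for a single channel or
#'   (z, y, x, channel); intensities must be nonnegative.
#' @param spacing numeric length-3 vector, micrometer per voxel along
#'   (z, y, x); all entries positive.
#' @param channel_names character vector naming the channels; exactly one
#'   must be \code{"DAPI"}.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(voxels, spacing, channel_names) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("'voxels' must be a (z, y, x[, channel]) array", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (z, y, x) in um", call. = FALSE)
  if (length(channel_names) != dim(voxels)[4L])
    stop("channel count mismatch: ", length(channel_names), " names for ",
         dim(voxels)[4L], " channels", call. = FALSE)
  if (sum(channel_names == "DAPI") != 1L)
    stop("exactly one channel must be named 'DAPI'", call. = FALSE)
  if (any(voxels < 0)) stop("voxel intensities must be nonnegative", call. = FALSE)
  dimnames(voxels) <- list(NULL, NULL, NULL, channel_names)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 channel_names = as.character(channel_names)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("image_stack: ", d[1], " x ", d[2], " x ", d[3], " voxels (z,y,x), ",
      d[4], " channel(s): ", paste(x$channel_names, collapse = ", "), "\n",
      "  spacing (um): ", paste(format(x$spacing), collapse = " x "), "\n",
      sep = "")
  invisible(x)
}

# physical coordinates (um) of voxel centers along each axis
stack_axis_coords <- function(stack) {
  d <- dim(stack$voxels)
  lapply(1:3, function(k) (seq_len(d[k]) - 1) * stack$spacing[k])
}

stack_channel <- function(stack, name) {
  if (!name %in% stack$channel_names)
    stop("no channel named '", name, "'", call. = FALSE)
  stack$voxels[, , , match(name, stack$channel_names)]
}
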