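#' Write an image stack as multi-page TIFF with a JSON side-car
#'
#' Pages are ordered channel-major (all z slices of channel 1, then channel
#' 2, ...).  Voxel values are stored as 32-bit samples after division by a
#' power-of-two scale recorded in the side-car, which the reader multiplies
#' back; values are therefore reproduced to ~1e-9 relative precision.  The
#' side-car records channel names, voxel spacing and stack shape exactly.
#'
#' @param stack an [image_stack()].
#' @param path TIFF output path; the side-car defaults to
#'   \code{paste0(path, ".json")}.
#' @param sidecar optional explicit side-car path.
#' @return Invisibly, the side-car path.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  mx <- max(stack$voxels)
  scale <- if (mx <= 1) 1 else 2^ceiling(log2(mx))
  pages <- list()
  for (ci in seq_len(d[4])) for (zi in seq_len(d[1]))
    pages[[length(pages) + 1L]] <- stack$voxels[zi, , , ci] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(channel_names = stack$channel_names,
               spacing = stack$spacing,
               stack_shape = d[1:3],
               scale = scale,
               page_order = "channel-major")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param sidecar side-car JSON path (default \code{paste0(path, ".json")}).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) stop("side-car not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$stack_shape)
  n_chan <- length(meta$channel_names)
  if (length(pages) != d[1] * n_chan)
    stop("channel count mismatch: side-car declares ", n_chan, " channels x ",
         d[1], " slices but TIFF has ", length(pages), " pages", call. = FALSE)
  vox <- array(0, dim = c(d, n_chan))
  k <- 1L
  for (ci in seq_len(n_chan)) for (zi in seq_len(d[1])) {
    vox[zi, , , ci] <- pages[[k]] * meta$scale
    k <- k + 1L
  }
  image_stack(vox, meta$spacing, meta$channel_names)
}

#' Write SpheriCell maps to CSV
#'
#' One row per cell, channel and ROI with stable column order:
#' \code{cell_id, channel, shell, sector, mean_intensity, voxel_count,
#' volume_um3} plus the frame columns (\code{phase}, center, axis, radius)
#' so a map can be reconstructed field by field.
#'
#' @param maps a named list of \code{sphericell_map} (names become cell ids)
#'   or a single map.
#' @param path CSV output path.
#' @return Invisibly, \code{path}.
#' @export
write_map_csv <- function(maps, path) {
  if (inherits(maps, "sphericell_map")) maps <- list(cell_1 = maps)
  if (is.null(names(maps)) || any(names(maps) == ""))
    names(maps) <- paste0("cell_", seq_along(maps))
  rows <- lapply(names(maps), function(id) {
    m <- maps[[id]]
    g <- m$grid
    base <- expand.grid(shell = seq_len(g$n_shells), sector = g$sectors,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    per_chan <- lapply(m$channel_names, function(ch)
      data.frame(cell_id = id, channel = ch, base,
                 mean_intensity = as.vector(m$intensities[, , ch]),
                 voxel_count = as.vector(m$voxel_counts),
                 volume_um3 = as.vector(m$volumes)))
    out <- do.call(rbind, per_chan)
    if (!is.null(m$frame)) {
      out$phase <- m$frame$phase
      out$center_z <- m$frame$center[1]; out$center_y <- m$frame$center[2]
      out$center_x <- m$frame$center[3]
      out$axis_z <- m$frame$axis[1]; out$axis_y <- m$frame$axis[2]
      out$axis_x <- m$frame$axis[3]
      out$sphere_radius <- m$frame$sphere_radius
    }
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read SpheriCell maps written by [write_map_csv()]
#'
#' @param path CSV path.
#' @return A named list of \code{sphericell_map}.
#' @export
read_map_csv <- function(path) {
  tab <- utils::read.csv(path, fileEncoding = "UTF-8")
  grid <- roi_grid()
  maps <- lapply(split(tab, tab$cell_id), function(d) {
    channels <- unique(d$channel)
    intens <- array(NA_real_, dim = c(6, 3, length(channels)),
                    dimnames = list(shell = 1:6, sector = grid$sectors,
                                    channel = channels))
    counts <- vols <- matrix(0, 6, 3, dimnames = list(shell = 1:6,
                                                      sector = grid$sectors))
    for (r in seq_len(nrow(d))) {
      mu <- d$shell[r]; nu <- d$sector[r]
      intens[mu, nu, d$channel[r]] <- d$mean_intensity[r]
      counts[mu, nu] <- d$voxel_count[r]
      vols[mu, nu] <- d$volume_um3[r]
    }
    frame <- NULL
    if ("phase" %in% names(d)) {
      frame <- structure(list(phase = d$phase[1],
                              center = c(d$center_z[1], d$center_y[1], d$center_x[1]),
                              axis = c(d$axis_z[1], d$axis_y[1], d$axis_x[1]),
                              sphere_radius = d$sphere_radius[1]),
                         class = "mitotic_frame")
    }
    structure(list(intensities = intens, volumes = vols, voxel_counts = counts,
                   frame = frame, grid = grid, channel_names = channels),
              class = "sphericell_map")
  })
  maps[unique(tab$cell_id)]
}

#' Write / read a normalized ROI dataset as CSV
#'
#' The main table has columns \code{cell_id, phase, species, shell, sector,
#' intensity, volume}; the companion totals table has \code{cell_id, phase,
#' species, total, median}.
#'
#' @param data a [roi_dataset()].
#' @param path main CSV path.
#' @param totals_path companion CSV path (default derived from \code{path}).
#' @return Invisibly, \code{path}.
#' @export
write_dataset_csv <- function(data, path,
                              totals_path = sub("\\.csv$", "_totals.csv", path)) {
  stopifnot(inherits(data, "roi_dataset"))
  n <- dim(data$intensities)[1]
  grid <- roi_grid()
  roi <- expand.grid(shell = 1:6, sector = grid$sectors,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(n), function(ci)
    do.call(rbind, lapply(seq_along(data$species), function(si)
      data.frame(cell_id = paste0("cell_", ci),
                 phase = as.character(data$phase[ci]),
                 species = data$species[si], roi,
                 intensity = data$intensities[ci, si, ],
                 volume = data$volumes)))))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  tot <- do.call(rbind, lapply(seq_len(n), function(ci)
    data.frame(cell_id = paste0("cell_", ci),
               phase = as.character(data$phase[ci]),
               species = data$species,
               total = data$totals[ci, ],
               median = data$medians)))
  utils::write.csv(tot, totals_path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path,
                             totals_path = sub("\\.csv$", "_totals.csv", path)) {
  tab <- utils::read.csv(path, fileEncoding = "UTF-8")
  tot <- utils::read.csv(totals_path, fileEncoding = "UTF-8")
  cells <- unique(tab$cell_id)
  species <- unique(tab$species)
  labels <- roi_labels()
  n <- length(cells); S <- length(species)
  intens <- array(NA_real_, dim = c(n, S, 18))
  totals <- matrix(NA_real_, n, S, dimnames = list(NULL, species))
  phase <- character(n)
  vols <- numeric(18)
  for (ci in seq_len(n)) {
    d <- tab[tab$cell_id == cells[ci], ]
    phase[ci] <- d$phase[1]
    for (si in seq_len(S)) {
      ds <- d[d$species == species[si], ]
      l <- match(paste0("s", ds$shell, ".", ds$sector), labels)
      intens[ci, si, l] <- ds$intensity
      if (ci == 1 && si == 1) vols[l] <- ds$volume
    }
    dt <- tot[tot$cell_id == cells[ci], ]
    totals[ci, ] <- dt$total[match(species, dt$species)]
  }
  med <- tot$median[match(species, tot$species)]
  roi_dataset(intens, totals, phase, species, vols, med)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path configuration file (\code{.json}, \code{.yaml} or
#'   \code{.yml}).
#' @return A named list with validated basic fields (when present):
#'   \code{seed} (nonnegative integer), \code{species}, thresholds and
#'   statistics/fit settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$seed) && (cfg$seed < 0 || cfg$seed != round(cfg$seed)))
    stop("config seed must be a nonnegative integer", call. = FALSE)
  if (!is.null(cfg$bounds)) {
    for (b in cfg$bounds)
      if (length(b) == 2 && b[1] >= b[2])
        stop("config bounds must satisfy lower < upper", call. = FALSE)
  }
  cfg
}
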