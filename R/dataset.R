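#' Normalized per-cell ROI intensity dataset
#'
#' Container for the model-facing data: per-cell, per-species intensities in
#' the 18 spherical ROIs, expressed as fold changes relative to the
#' population median of the volume-weighted average cellular intensity, plus
#' the normalized cell averages themselves, the phase label of every cell,
#' the ROI volumes used for averaging and the medians used for
#' normalization.  Usually built by [normalize_dataset()] from raw tables or
#' by [simulate_roi_dataset()] from ground truth.
#'
#' @param intensities n_cells x S x 18 array of normalized ROI intensities.
#' @param totals n_cells x S matrix of normalized cell-average intensities.
#' @param phase factor of length n_cells with levels metaphase, segregation.
#' @param species character vector of S species names.
#' @param volumes length-18 ROI volumes (any common unit; used as weights).
#' @param medians length-S normalization medians (raw-intensity units).
#' @return An object of class \code{roi_dataset}.
#' @export
roi_dataset <- function(intensities, totals, phase, species, volumes,
                        medians) {
  dims <- dim(intensities)
  stopifnot(length(dims) == 3L, dims[3] == 18L,
            nrow(totals) == dims[1], ncol(totals) == dims[2],
            length(phase) == dims[1], length(species) == dims[2],
            length(volumes) == 18L, length(medians) == dims[2])
  phase <- factor(as.character(phase), levels = c("metaphase", "segregation"))
  if (anyNA(phase)) stop("phase must be metaphase or segregation", call. = FALSE)
  dimnames(intensities) <- list(NULL, species, roi_labels())
  colnames(totals) <- species
  structure(list(intensities = intensities, totals = totals, phase = phase,
                 species = species, volumes = as.numeric(volumes),
                 medians = stats::setNames(as.numeric(medians), species)),
            class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat("roi_dataset: ", dim(x$intensities)[1], " cells (",
      sum(x$phase == "metaphase"), " metaphase, ",
      sum(x$phase == "segregation"), " segregation), ",
      length(x$species), " species, 18 ROIs\n", sep = "")
  invisible(x)
}

#' Normalize raw ROI intensities to population fold changes
#'
#' Computes the volume-weighted average cellular intensity of every species
#' in every cell, \eqn{I_{i,t} = \sum_l I_{il} V_l / \sum_l V_l}, divides
#' ROI intensities and cell averages by the per-species population median
#' \eqn{\hat I_{i,t}}, and stores the medians for round-tripping.  After
#' normalization the median cell average equals 1 for every species.
#'
#' @param raw n_cells x S x 18 array of raw ROI mean intensities.
#' @param volumes length-18 ROI volumes.
#' @param phase factor of cell phases.
#' @param species species names.
#' @return A [roi_dataset()].
#' @export
normalize_dataset <- function(raw, volumes, phase, species) {
  stopifnot(length(dim(raw)) == 3L, dim(raw)[3] == 18L,
            dim(raw)[2] == length(species))
  w <- volumes / sum(volumes)
  n <- dim(raw)[1]
  # I_{i,t}: volume-weighted mean over ROIs, per cell and species
  avg <- apply(raw, c(1, 2), function(v) sum(v * w))
  med <- apply(matrix(avg, nrow = n), 2, stats::median)
  if (any(med <= 0))
    stop("population median is zero for species: ",
         paste(species[med <= 0], collapse = ", "), call. = FALSE)
  norm_int <- sweep(raw, 2, med, `/`)
  norm_avg <- sweep(matrix(avg, nrow = n), 2, med, `/`)
  roi_dataset(norm_int, norm_avg, phase, species, volumes, med)
}

#' Dataset size bookkeeping
#'
#' Number of data points entering a model fit: one value per cell, species
#' and ROI, plus one cell-average value per cell and species (the averages
#' enter as normalization inputs).
#'
#' @param n_cells,n_species,n_rois problem dimensions (\code{n_rois}
#'   defaults to 18).
#' @return A list with \code{roi_values}, \code{cell_averages} and
#'   \code{total}.
#' @examples
#' n_dataset_points(205, 13)  # 47970 + 2665 = 50635
#' @export
n_dataset_points <- function(n_cells, n_species, n_rois = 18L) {
  roi_values <- n_cells * n_species * n_rois
  cell_averages <- n_cells * n_species
  list(roi_values = roi_values, cell_averages = cell_averages,
       total = roi_values + cell_averages)
}

#' Number of free parameters of the affinity model
#'
#' One scaling factor and 18 compartment affinities per species and phase,
#' plus one pairwise affinity per interaction.
#'
#' @param n_species,n_rois,n_phases,n_interactions problem dimensions.
#' @return Integer parameter count.
#' @examples
#' n_model_params(13, n_interactions = 19)  # 513
#' n_model_params(13, n_interactions = 35)  # 529
#' @export
n_model_params <- function(n_species, n_rois = 18L, n_phases = 2L,
                           n_interactions = 0L) {
  n_phases * n_species + n_phases * n_species * n_rois + n_interactions
}
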