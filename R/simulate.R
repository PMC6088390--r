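#' Ground-truth parameters for the steady-state affinity model
#'
#' Bundles the generative parameters of the ROI intensity model: per-species,
#' per-phase scaling factors \code{d}, per-species x per-ROI compartment
#' affinities \code{alpha} (both phases), the symmetric pairwise affinity
#' matrix \code{beta}, and the log-normal parameters of per-cell species
#' totals.
#'
#' @param species character vector of species names (DAPI included), length
#'   S >= 2, unique.
#' @param d_meta,d_segr positive length-S vectors.
#' @param alpha_meta,alpha_segr positive S x 18 matrices.
#' @param beta S x S symmetric nonnegative matrix (zeros for absent pairs),
#'   or \code{NULL} for no interactions.
#' @param lognormal_mu,lognormal_sigma length-S parameters of the log-normal
#'   cell-total distribution (sigma >= 0; sigma = 0 is the degenerate
#'   point mass at \code{exp(mu)}).
#' @return An object of class \code{affinity_truth}.
#' @export
affinity_truth <- function(species, d_meta, d_segr, alpha_meta, alpha_segr,
                           beta = NULL, lognormal_mu = rep(0, length(species)),
                           lognormal_sigma = rep(0.5, length(species))) {
  S <- length(species)
  stopifnot(S >= 2, !anyDuplicated(species))
  chk_pos <- function(x, nm, lo = 1e-3, hi = 1e2) {
    if (any(x <= 0)) stop("'", nm, "' must be positive", call. = FALSE)
    if (any(x < lo | x > hi))
      stop("'", nm, "' must lie within [", lo, ", ", hi, "]", call. = FALSE)
  }
  stopifnot(length(d_meta) == S, length(d_segr) == S,
            all(dim(alpha_meta) == c(S, 18)), all(dim(alpha_segr) == c(S, 18)))
  chk_pos(d_meta, "d_meta"); chk_pos(d_segr, "d_segr")
  chk_pos(alpha_meta, "alpha_meta"); chk_pos(alpha_segr, "alpha_segr")
  if (is.null(beta)) beta <- matrix(0, S, S)
  stopifnot(all(dim(beta) == c(S, S)))
  if (max(abs(beta - t(beta))) > 0)
    stop("'beta' must be exactly symmetric", call. = FALSE)
  if (any(beta < 0)) stop("'beta' must be nonnegative", call. = FALSE)
  nz <- beta[beta > 0]
  if (length(nz) && any(nz < 1e-7 | nz > 1e2))
    stop("nonzero 'beta' must lie within [1e-7, 1e2]", call. = FALSE)
  if (any(lognormal_sigma < 0)) stop("'lognormal_sigma' must be >= 0", call. = FALSE)
  dimnames(alpha_meta) <- dimnames(alpha_segr) <- list(species, roi_labels())
  dimnames(beta) <- list(species, species)
  structure(list(species = species,
                 d_meta = stats::setNames(d_meta, species),
                 d_segr = stats::setNames(d_segr, species),
                 alpha_meta = alpha_meta, alpha_segr = alpha_segr,
                 beta = beta,
                 lognormal_mu = stats::setNames(lognormal_mu, species),
                 lognormal_sigma = stats::setNames(lognormal_sigma, species)),
            class = "affinity_truth")
}

#' Draw a random ground truth for recovery experiments
#'
#' Compartment affinities are sampled log-uniformly over one decade centered
#' at 1 (\code{[10^-0.5, 10^0.5]}): median-normalized intensity data are of
#' order 1, and one decade keeps every ROI intensity within the dynamic
#' range where the 5-percent-of-maximum error floor still corresponds to
#' quantifiable signal.  Scaling factors default to 1 (the first species
#' acts as scale reference) and the requested interaction pairs are planted
#' with affinity \code{beta_value}.
#'
#' @param species species names.
#' @param interactions list of length-2 integer/character vectors (unordered
#'   pairs, homodimers allowed) to plant in \code{beta}.
#' @param beta_value affinity assigned to planted pairs (default 1).
#' @param sigma log-normal sigma of cell totals (default 0.5).
#' @param seed RNG seed.
#' @return An [affinity_truth()].
#' @export
random_affinity_truth <- function(species, interactions = list(),
                                  beta_value = 1, sigma = 0.5, seed = 1L) {
  S <- length(species)
  with_seed(seed, {
    alpha_m <- matrix(10^stats::runif(S * 18, -0.5, 0.5), S, 18)
    alpha_s <- matrix(10^stats::runif(S * 18, -0.5, 0.5), S, 18)
    beta <- matrix(0, S, S)
    for (p in interactions) {
      i <- if (is.character(p)) match(p, species) else as.integer(p)
      beta[i[1], i[2]] <- beta[i[2], i[1]] <- beta_value
    }
    affinity_truth(species, d_meta = rep(1, S), d_segr = rep(1, S),
                   alpha_meta = alpha_m, alpha_segr = alpha_s, beta = beta,
                   lognormal_sigma = rep(sigma, S))
  })
}

#' Simulate per-cell species totals
#'
#' Cellular total intensities are log-normally distributed across cells;
#' each cell is labeled metaphase or segregation.  Totals are expressed as
#' fold changes relative to the population median, so \code{mu = 0} gives a
#' population median of ~1.
#'
#' @param truth an [affinity_truth()].
#' @param n_cells number of cells (>= 1).
#' @param phase_fractions length-2 nonnegative weights (metaphase,
#'   segregation) summing to a positive value.
#' @param seed RNG seed.
#' @return A list with \code{totals} (n_cells x S matrix) and \code{phase}
#'   (factor with levels metaphase, segregation).
#' @export
simulate_cell_totals <- function(truth, n_cells, phase_fractions = c(0.5, 0.5),
                                 seed = 1L) {
  stopifnot(inherits(truth, "affinity_truth"), n_cells >= 1)
  if (length(phase_fractions) != 2L || any(phase_fractions < 0) ||
      sum(phase_fractions) <= 0)
    stop("'phase_fractions' must be 2 nonnegative weights", call. = FALSE)
  S <- length(truth$species)
  with_seed(seed, {
    totals <- vapply(seq_len(S), function(i)
      stats::rlnorm(n_cells, meanlog = truth$lognormal_mu[i],
                    sdlog = truth$lognormal_sigma[i]),
      numeric(n_cells))
    totals <- matrix(totals, nrow = n_cells,
                     dimnames = list(NULL, truth$species))
    phase <- factor(sample(c("metaphase", "segregation"), n_cells,
                           replace = TRUE,
                           prob = phase_fractions / sum(phase_fractions)),
                    levels = c("metaphase", "segregation"))
    list(totals = totals, phase = phase)
  })
}

#' Simulate a normalized ROI intensity dataset from ground truth
#'
#' Evaluates the steady-state model exactly for every cell: ROI intensities
#' are \eqn{d_i \tilde\alpha_{il} \tilde I_{i,t} (1 + \sum_j
#' \tilde\alpha_{jl} \beta_{ij} \tilde I_{j,t})} with the phase-specific
#' \code{d} and \code{alpha}.  With \code{with_noise}, additive Gaussian
#' noise with standard deviation \code{0.05 * value + 0.05 * max} (maximum
#' per species over the whole generated population) is applied and the
#' result truncated at zero -- the same heteroscedastic error model used as
#' weights during fitting.
#'
#' @param truth an [affinity_truth()].
#' @param totals result of [simulate_cell_totals()] (or a compatible list
#'   with \code{totals} and \code{phase}); species must match the truth.
#' @param with_noise logical.
#' @param seed RNG seed (noise only).
#' @return A [roi_dataset()].
#' @export
simulate_roi_dataset <- function(truth, totals, with_noise = TRUE, seed = 1L) {
  stopifnot(inherits(truth, "affinity_truth"))
  T_mat <- totals$totals
  if (!identical(colnames(T_mat), truth$species))
    stop("species mismatch between totals and ground truth", call. = FALSE)
  pred <- predict_roi_intensities(
    list(d_meta = truth$d_meta, d_segr = truth$d_segr,
         alpha_meta = truth$alpha_meta, alpha_segr = truth$alpha_segr,
         beta = truth$beta),
    T_mat, totals$phase)
  if (with_noise) {
    max_i <- apply(pred, 2, max)  # per species over all cells and ROIs
    eps <- sweep(0.05 * pred, 2, 0.05 * max_i, `+`)
    pred <- with_seed(seed, {
      pmax(pred + array(stats::rnorm(length(pred), sd = as.vector(eps)),
                        dim = dim(pred)), 0)
    })
  }
  roi_dataset(intensities = pred, totals = T_mat, phase = totals$phase,
              species = truth$species,
              volumes = as.vector(roi_volume_fractions()),
              medians = stats::setNames(rep(1, length(truth$species)),
                                        truth$species))
}

#' Paired groups of SpheriCell maps with a planted effect
#'
#' Builds two groups of per-cell 6 x 3 intensity maps from a common template:
#' group A is template plus log-normal cell-to-cell variation and
#' multiplicative ROI noise; group B additionally carries a declared effect
#' -- a fold change on the whole map and/or a shift of intensity mass from
#' one shell to another (same sector).  Used to calibrate the group
#' comparison statistics against known effects.
#'
#' @param template 6 x 3 nonnegative matrix of mean ROI intensities.
#' @param n_cells cells per group (>= 2).
#' @param effect list with \code{fold} (multiplicative change for group B,
#'   default 1) and optionally \code{shift = list(from, to, fraction)}
#'   moving the given fraction of every sector's intensity from shell
#'   \code{from} to shell \code{to} in group B.
#' @param cell_sd log-normal sd of per-cell scale (default 0.3).
#' @param roi_sd log-normal sd of per-ROI noise (default 0.1).
#' @param seed RNG seed.
#' @return A list with \code{group_a}, \code{group_b} (lists of
#'   \code{sphericell_map}-like objects with \code{intensities}, single
#'   channel \code{"probe"}, plus equal \code{volumes}) and \code{effect}.
#' @export
make_roi_fixture_population <- function(template, n_cells, effect = list(fold = 1),
                                        cell_sd = 0.3, roi_sd = 0.1, seed = 1L) {
  stopifnot(all(dim(template) == c(6, 3)), all(template >= 0))
  if (n_cells < 2) stop("need at least 2 cells per group", call. = FALSE)
  grid <- roi_grid()
  vol <- roi_volume_fractions(grid) * (4 / 3 * pi * 12^3)  # R = 12 um reference
  fold <- effect$fold %||% 1
  tmpl_b <- template * fold
  if (!is.null(effect$shift)) {
    sh <- effect$shift
    moved <- tmpl_b[sh$from, ] * sh$fraction
    tmpl_b[sh$from, ] <- tmpl_b[sh$from, ] - moved
    tmpl_b[sh$to, ] <- tmpl_b[sh$to, ] + moved
  }
  wrap <- function(m) {
    intens <- array(m, dim = c(6, 3, 1),
                    dimnames = list(shell = 1:6, sector = grid$sectors,
                                    channel = "probe"))
    structure(list(intensities = intens, volumes = vol,
                   voxel_counts = vol / prod(c(0.5, 0.5, 0.5)),
                   frame = NULL, grid = grid, channel_names = "probe"),
              class = "sphericell_map")
  }
  with_seed(seed, {
    draw <- function(tmpl) lapply(seq_len(n_cells), function(i) {
      scale_i <- stats::rlnorm(1, sdlog = cell_sd)
      noise <- matrix(stats::rlnorm(18, sdlog = roi_sd), 6, 3)
      wrap(tmpl * scale_i * noise)
    })
    list(group_a = draw(template), group_b = draw(tmpl_b),
         effect = list(fold = fold, shift = effect$shift))
  })
}
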