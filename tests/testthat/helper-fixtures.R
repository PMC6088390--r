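# shared fixtures: small phantoms and affinity ground truths, built in code

quiet_phantom_config <- function(phase = "metaphase", ...) {
  phantom_config(phase = phase,
                 noise = list(gaussian_sd = 0, poisson_scale = 0), ...)
}

noisy_phantom_config <- function(phase = "metaphase", ...) {
  phantom_config(phase = phase,
                 noise = list(gaussian_sd = 1.5, poisson_scale = 0), ...)
}

# S = 4 ground truth with one known pair and defaults frozen at the
# generator's study conditions
toy_truth <- function(interactions = list(c(1, 2)), beta_value = 0.5,
                      seed = 11L) {
  random_affinity_truth(c("DAPI", "A", "B", "C"), interactions = interactions,
                        beta_value = beta_value, sigma = 0.4, seed = seed)
}

toy_dataset <- function(truth, n_cells = 60, with_noise = TRUE, seed = 5L) {
  totals <- simulate_cell_totals(truth, n_cells, seed = seed)
  simulate_roi_dataset(truth, totals, with_noise = with_noise, seed = seed + 1L)
}

truth_params <- function(truth)
  truth[c("d_meta", "d_segr", "alpha_meta", "alpha_segr", "beta")]

# uniform-intensity sphericell map with analytic ROI volumes (R in um)
constant_map <- function(value = 5, radius = 12, channel = "probe") {
  grid <- roi_grid()
  intens <- array(value, dim = c(6, 3, 1),
                  dimnames = list(shell = 1:6, sector = grid$sectors,
                                  channel = channel))
  vol <- roi_volume_fractions(grid) * (4 / 3 * pi * radius^3)
  structure(list(intensities = intens, volumes = vol,
                 voxel_counts = round(vol / 0.125), frame = NULL,
                 grid = grid, channel_names = channel),
            class = "sphericell_map")
}

# deterministic tilted unit axes for phantom sweeps
unit_vec <- function(k) {
  v <- rbind(c(1, 0, 0), c(2, 1, 0), c(3, 1, 1), c(1, -1, 0.5),
             c(2, 0.5, -1), c(1, 1, 1))[(k - 1) %% 6 + 1, ]
  unname(v / sqrt(sum(v^2)))
}

roi_volume_fractions <- sphericell:::roi_volume_fractions
roi_labels <- sphericell:::roi_labels
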