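test_that("the error model follows the 5% + 5%-of-max rule", {
  x <- array(0.5, c(1, 2, 3))
  x[1, 1, 1] <- 2; x[1, 1, 2] <- 4
  eps <- error_model(x)
  expect_equal(eps[1, 1, 1], 0.05 * 2 + 0.05 * 4)  # value 2, species max 4
  expect_equal(eps[1, 1, 3], 0.05 * 0.5 + 0.05 * 4)
  expect_equal(eps[1, 2, 1], 0.05 * 0.5 + 0.05 * 0.5)
  expect_error(error_model(array(0, c(1, 2, 3))), "zero")
})

test_that("the objective vanishes at the generating parameters (no noise)", {
  tr <- toy_truth(interactions = list(c(1, 2), c(2, 3)))
  ds <- toy_dataset(tr, n_cells = 15, with_noise = FALSE)
  obj <- model_objective(truth_params(tr), ds)
  expect_lt(obj$rss, 1e-18)
  # rss equals an explicit loop over residuals
  ds_n <- toy_dataset(tr, n_cells = 10, with_noise = TRUE, seed = 9)
  obj_n <- model_objective(truth_params(tr), ds_n)
  pred <- predict_roi_intensities(truth_params(tr), ds_n$totals, ds_n$phase)
  eps <- error_model(ds_n$intensities)
  acc <- 0
  for (ci in 1:10) for (si in 1:4) for (l in 1:18)
    acc <- acc + ((ds_n$intensities[ci, si, l] - pred[ci, si, l]) / eps[ci, si, l])^2
  expect_equal(obj_n$rss, acc, tolerance = 1e-12)
})

test_that("predictions are invariant under swapping pair labels", {
  sp <- c("P", "Q", "R")
  a <- matrix(2, 3, 18)
  b <- matrix(0, 3, 3); b[1, 3] <- b[3, 1] <- 0.7
  tr <- affinity_truth(sp, rep(1, 3), rep(1, 3), a, a, b)
  tot <- matrix(rlnorm(6, sdlog = 0.2), 2, 3, dimnames = list(NULL, sp))
  phase <- factor(c("metaphase", "segregation"),
                  levels = c("metaphase", "segregation"))
  p1 <- predict_roi_intensities(truth_params(tr), tot, phase)
  # relabel species (1, 3) -> (3, 1) everywhere
  perm <- c(3, 2, 1)
  tr2 <- tr
  tr2$beta <- tr$beta[perm, perm]
  p2 <- predict_roi_intensities(list(d_meta = tr$d_meta[perm],
                                     d_segr = tr$d_segr[perm],
                                     alpha_meta = tr$alpha_meta[perm, ],
                                     alpha_segr = tr$alpha_segr[perm, ],
                                     beta = tr2$beta),
                                tot[, perm], phase)
  expect_equal(unname(p1), unname(p2[, perm, ]))
})

test_that("the interaction-free fit matches the closed-form weighted regression", {
  tr <- toy_truth(interactions = list())
  ds <- toy_dataset(tr, n_cells = 40, with_noise = TRUE, seed = 12)
  fit <- fit_affinity_model(ds, interactions = list(), n_starts = 2, seed = 3,
                            gauge = "reference")
  eps <- error_model(ds$intensities)
  # per (species, ROI, phase) the model is data ~ P * T: weighted LS in P
  for (si in c(1, 3)) for (l in c(2, 11)) for (ph in c("metaphase", "segregation")) {
    cells <- which(ds$phase == ph)
    Tv <- ds$totals[cells, si]
    y <- ds$intensities[cells, si, l]
    w <- 1 / eps[cells, si, l]^2
    P_hat <- sum(w * Tv * y) / sum(w * Tv^2)
    d_fit <- if (ph == "metaphase") fit$params$d_meta[si] else fit$params$d_segr[si]
    a_fit <- if (ph == "metaphase") fit$params$alpha_meta[si, l] else fit$params$alpha_segr[si, l]
    expect_equal(unname(d_fit * a_fit), P_hat, tolerance = 1e-6)
  }
})

test_that("parameter counting and the fitted-object surface are consistent", {
  tr <- toy_truth(interactions = list(c(1, 2)))
  ds <- toy_dataset(tr, n_cells = 12, with_noise = TRUE, seed = 13)
  fit <- fit_affinity_model(ds, list(c(1, 2)), n_starts = 1, seed = 1,
                            gauge = "free")
  expect_s3_class(fit, "affinity_fit")
  expect_equal(fit$n_par, n_model_params(4, n_interactions = 1))
  expect_equal(fit$n_obs, 12 * 4 * 18)
  expect_length(coef(fit), 2 * 4 + 2 * 4 * 18 + 1)
  expect_equal(dim(predict(fit)), c(12, 4, 18))
  expect_equal(deviance(fit), sum(residuals(fit)^2), tolerance = 1e-10)
  expect_output(print(fit), "affinity model")
  s <- summary(fit)
  expect_output(print(s), "pairwise affinities")
  expect_equal(nrow(s$beta), 1)
  # reference gauge removes one d per interaction component + isolated species
  fit_ref <- fit_affinity_model(ds, list(c(1, 2)), n_starts = 1, seed = 1,
                                gauge = "reference")
  expect_equal(fit_ref$n_par, fit$n_par - 3)  # components {1,2}, {3}, {4}
  expect_equal(fit_ref$gauge_species, c("DAPI", "B", "C"))
})

test_that("a warm start at the truth converges to the noise floor", {
  tr <- toy_truth(interactions = list(c(1, 2)))
  ds <- toy_dataset(tr, n_cells = 30, with_noise = TRUE, seed = 14)
  fit <- fit_affinity_model(ds, list(c(1, 2)), n_starts = 0, seed = 2,
                            gauge = "reference", start = truth_params(tr))
  # weighted rss should be of the order of the number of residuals
  expect_lt(fit$rss, fit$n_obs)
  expect_gt(fit$rss, fit$n_obs / 10)
})

test_that("rescaled compartment affinities are the d * alpha products", {
  tr <- toy_truth()
  ds <- toy_dataset(tr, n_cells = 10, with_noise = TRUE, seed = 15)
  fit <- fit_affinity_model(ds, list(c(1, 2)), n_starts = 1, seed = 4)
  sc <- rescale_roi_affinities(fit)
  for (si in 1:4)
    expect_equal(sc$alpha_meta_scaled[si, ],
                 fit$params$alpha_meta[si, ] * fit$params$d_meta[si])
  fit1 <- fit
  fit1$params$d_meta[] <- 1
  sc1 <- rescale_roi_affinities(fit1)
  expect_equal(sc1$alpha_meta_scaled, fit1$params$alpha_meta)
})

test_that("invalid interaction specifications are rejected", {
  tr <- toy_truth()
  ds <- toy_dataset(tr, n_cells = 5, seed = 16)
  expect_error(fit_affinity_model(ds, list(c(1, 9)), n_starts = 1), "invalid")
  expect_error(fit_affinity_model(ds, list(c(1, 2), c(2, 1)), n_starts = 1),
               "duplicate")
})
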