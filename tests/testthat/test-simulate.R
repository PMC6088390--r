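test_that("cell totals follow the configured log-normal population", {
  tr <- toy_truth()
  # degenerate sigma: every cell sits exactly at exp(mu)
  tr0 <- tr; tr0$lognormal_sigma[] <- 0
  tot0 <- simulate_cell_totals(tr0, 25, seed = 1)
  expect_true(all(tot0$totals == 1))
  # Monte-Carlo median of a log-normal with mu = 0 is ~1
  tr5 <- tr; tr5$lognormal_sigma[] <- 0.5
  tot <- simulate_cell_totals(tr5, 10000, seed = 2)
  med <- apply(tot$totals, 2, median)
  expect_true(all(med > 0.95 & med < 1.05))
  # extreme phase fractions
  tot_m <- simulate_cell_totals(tr, 50, phase_fractions = c(1, 0), seed = 3)
  expect_true(all(tot_m$phase == "metaphase"))
  expect_error(affinity_truth(tr$species, tr$d_meta, tr$d_segr, tr$alpha_meta,
                              tr$alpha_segr, tr$beta,
                              lognormal_sigma = rep(-1, 4)), ">= 0")
})

test_that("ground-truth containers enforce their invariants", {
  expect_error(random_affinity_truth(c("only"), seed = 1))
  tr <- toy_truth()
  b <- tr$beta; b[1, 2] <- b[1, 2] + 1e-9  # break symmetry
  expect_error(affinity_truth(tr$species, tr$d_meta, tr$d_segr, tr$alpha_meta,
                              tr$alpha_segr, b), "symmetric")
  expect_error(affinity_truth(tr$species, rep(1e-4, 4), tr$d_segr,
                              tr$alpha_meta, tr$alpha_segr), "within")
})

test_that("the simulated table evaluates the steady-state model exactly", {
  sp <- c("X", "Y")
  # beta = 0, d = 1, alpha = 1, totals 2 -> every ROI reads 2
  tr <- affinity_truth(sp, c(1, 1), c(1, 1), matrix(1, 2, 18), matrix(1, 2, 18))
  tot <- list(totals = matrix(2, 3, 2, dimnames = list(NULL, sp)),
              phase = factor(rep(c("metaphase", "segregation"), c(2, 1)),
                             levels = c("metaphase", "segregation")))
  ds <- simulate_roi_dataset(tr, tot, with_noise = FALSE)
  expect_equal(unname(ds$intensities), array(2, c(3, 2, 18)))
  # heterodimer: beta_12 = 1, totals (1, 1) -> 1 * 1 * (1 + 1) = 2
  b <- matrix(c(0, 1, 1, 0), 2, 2)
  tr2 <- affinity_truth(sp, c(1, 1), c(1, 1), matrix(1, 2, 18),
                        matrix(1, 2, 18), b)
  tot1 <- list(totals = matrix(1, 2, 2, dimnames = list(NULL, sp)),
               phase = factor(c("metaphase", "segregation"),
                              levels = c("metaphase", "segregation")))
  ds2 <- simulate_roi_dataset(tr2, tot1, with_noise = FALSE)
  expect_equal(unname(ds2$intensities), array(2, c(2, 2, 18)))
  # homodimer: beta_11 = 1, total 2 -> 1 * 1 * 2 * (1 + 1 * 1 * 2) = 6
  bh <- matrix(c(1, 0, 0, 0), 2, 2)
  tr3 <- affinity_truth(sp, c(1, 1), c(1, 1), matrix(1, 2, 18),
                        matrix(1, 2, 18), bh)
  tot2 <- list(totals = matrix(2, 2, 2, dimnames = list(NULL, sp)),
               phase = factor(c("metaphase", "metaphase"),
                              levels = c("metaphase", "segregation")))
  ds3 <- simulate_roi_dataset(tr3, tot2, with_noise = FALSE)
  expect_equal(unname(ds3$intensities[, 1, ]), matrix(6, 2, 18))
  expect_equal(unname(ds3$intensities[, 2, ]), matrix(2, 2, 18))
})

test_that("noiseless tables round-trip through the model predictor", {
  tr <- toy_truth(interactions = list(c(1, 2), c(3, 3)))
  tot <- simulate_cell_totals(tr, 30, seed = 4)
  ds <- simulate_roi_dataset(tr, tot, with_noise = FALSE)
  pred <- predict_roi_intensities(truth_params(tr), tot$totals, tot$phase)
  expect_lt(max(abs(ds$intensities - pred)), 1e-12)
})

test_that("noisy tables are reproducible and species-checked", {
  tr <- toy_truth()
  tot <- simulate_cell_totals(tr, 20, seed = 5)
  d1 <- simulate_roi_dataset(tr, tot, with_noise = TRUE, seed = 6)
  d2 <- simulate_roi_dataset(tr, tot, with_noise = TRUE, seed = 6)
  expect_identical(d1$intensities, d2$intensities)
  expect_true(all(d1$intensities >= 0))
  bad <- tot; colnames(bad$totals) <- c("DAPI", "A", "B", "Z")
  expect_error(simulate_roi_dataset(tr, bad), "mismatch")
})

test_that("fixture populations require enough cells and store their effect", {
  expect_error(make_roi_fixture_population(matrix(1, 6, 3), n_cells = 1),
               "at least 2")
  pop <- make_roi_fixture_population(matrix(1, 6, 3), n_cells = 5,
                                    effect = list(fold = 3), seed = 1)
  expect_equal(pop$effect$fold, 3)
  expect_length(pop$group_a, 5)
})
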