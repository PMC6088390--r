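test_that("comparing a group with itself gives a null effect", {
  set.seed(1)
  a <- rlnorm(30)
  r <- compare_groups(a, a, "c", seed = 1)
  expect_equal(r$effect, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  expect_true(r$ci_low <= 0 && 0 <= r$ci_high)
})

test_that("a planted two-fold change is detected on the log2 scale", {
  pop <- make_roi_fixture_population(matrix(10, 6, 3), n_cells = 50,
                                    effect = list(fold = 2), cell_sd = 0.15,
                                    roi_sd = 0.05, seed = 2)
  ca <- vapply(pop$group_a, function(m) cell_measures(m)$c, numeric(1))
  cb <- vapply(pop$group_b, function(m) cell_measures(m)$c, numeric(1))
  r <- compare_groups(ca, cb, "c", m = 52, seed = 3)
  expect_gt(r$effect, 0.9)
  expect_lt(r$effect, 1.1)
  expect_true(r$significant)
  expect_true(r$ci_low <= r$effect && r$effect <= r$ci_high)
})

test_that("a shell shift moves the eccentricity center outward", {
  pop <- make_roi_fixture_population(matrix(10, 6, 3), n_cells = 30,
                                    effect = list(fold = 1,
                                                  shift = list(from = 2, to = 5,
                                                               fraction = 0.5)),
                                    seed = 4)
  ra <- vapply(pop$group_a, function(m) cell_measures(m)$r, numeric(1))
  rb <- vapply(pop$group_b, function(m) cell_measures(m)$r, numeric(1))
  r <- compare_groups(ra, rb, "r", seed = 5)
  expect_gt(r$effect, 0)
  expect_true(all(rb > min(ra)))  # strict construction-level shift
})

test_that("null fixtures give approximately uniform Welch p-values", {
  set.seed(6)
  p <- replicate(400, {
    pop <- make_roi_fixture_population(matrix(10, 6, 3), n_cells = 10,
                                      effect = list(fold = 1),
                                      seed = sample.int(1e6, 1))
    ca <- vapply(pop$group_a, function(m) cell_measures(m)$c, numeric(1))
    cb <- vapply(pop$group_b, function(m) cell_measures(m)$c, numeric(1))
    stats::t.test(log(cb), log(ca), var.equal = FALSE)$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
  # essentially nothing survives the Bonferroni cut under the null
  expect_lte(mean(p < 0.05 / 52), 0.005)
})

test_that("the percentile bootstrap is seeded, degenerate-safe and warned", {
  expect_equal(unname(bootstrap_ci(rep(3, 10), seed = 1)), c(3, 3))
  x <- rnorm(50)
  expect_identical(bootstrap_ci(x, seed = 9), bootstrap_ci(x, seed = 9))
  expect_false(identical(bootstrap_ci(x, seed = 9), bootstrap_ci(x, seed = 10)))
  expect_warning(bootstrap_ci(x, n_boot = 50, seed = 1), "unstable")
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("per-ROI comparisons recover exact and planted differences", {
  maps_a <- replicate(10, {
    m <- constant_map(0)
    m$intensities[, , 1] <- matrix(rlnorm(18, meanlog = 2, sdlog = 0.05), 6, 3)
    m
  }, simplify = FALSE)
  maps_b2 <- lapply(maps_a, function(m) { m$intensities <- m$intensities * 2; m })
  expect_equal(unname(roi_comparisons(maps_a, maps_a, "probe")),
               matrix(0, 6, 3))
  expect_equal(unname(roi_comparisons(maps_a, maps_b2, "probe")),
               matrix(1, 6, 3))
  # effect planted only in polar ROIs of shells 1-3
  maps_bp <- lapply(maps_a, function(m) {
    m$intensities[1:3, 1, 1] <- m$intensities[1:3, 1, 1] * 3; m })
  ft <- roi_comparisons(rep(maps_a, 4), rep(maps_bp, 4), "probe",
                        mode = "fold_test")
  sig <- which(ft$significant, arr.ind = TRUE)
  expect_true(all(sig[, "sector"] == 1))
  expect_true(all(sig[, "shell"] %in% 1:3))
  expect_true(all(is.na(ft$effect[!ft$significant])))
})
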