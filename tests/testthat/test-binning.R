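frame_at <- function(center, axis, R)
  structure(list(phase = "metaphase", center = center, axis = axis,
                 sphere_radius = R), class = "mitotic_frame")

test_that("binning a uniform channel yields that constant in all 18 ROIs", {
  cfg <- quiet_phantom_config(channel_patterns = list(
    list(channel_name = "DAPI", pattern = "chromatin", amplitude = 100),
    list(channel_name = "flat", pattern = "uniform", amplitude = 7)))
  ph <- make_phantom(cfg, seed = 1)
  m <- bin_stack(ph$stack, frame_at(cfg$center, c(1, 0, 0), 10))
  expect_equal(unname(m$intensities[, , "flat"]), matrix(17, 6, 3))
  expect_identical(m$intensities,
                   bin_stack(ph$stack, frame_at(cfg$center, c(1, 0, 0), 10))$intensities)
})

test_that("voxel counts partition the sphere and shell volumes scale as mu^3", {
  cfg <- quiet_phantom_config()
  ph <- make_phantom(cfg, seed = 1)
  R <- 10
  m <- bin_stack(ph$stack, frame_at(cfg$center, c(1, 0, 0), R))
  # independent in-sphere count on the isotropic grid
  iso <- 0.5
  ax <- lapply(dim(ph$stack$voxels)[1:3], function(n) NULL)
  zq <- seq(0, (dim(ph$stack$voxels)[1] - 1) * ph$stack$spacing[1], by = iso)
  yx <- (seq_len(72) - 1) * iso
  P <- as.matrix(expand.grid(zq, yx, yx))
  inside <- rowSums(sweep(P, 2, cfg$center)^2) <= R^2
  expect_equal(sum(m$voxel_counts), sum(inside))
  # shell-volume ratio approaches (6^3 - 5^3) / 1 = 91
  expect_lt(abs(sum(m$volumes[6, ]) / sum(m$volumes[1, ]) - 91) / 91, 0.1)
  # total volume close to the analytic sphere volume
  expect_lt(abs(sum(m$volumes) / (4 / 3 * pi * R^3) - 1), 0.05)
})

test_that("binning is equivariant under a joint 90-degree rotation", {
  cfg <- quiet_phantom_config(axis_direction = unname(c(0, 1, 1) / sqrt(2)),
                              voxel_spacing = c(0.5, 0.5, 0.5),
                              stack_shape = c(72L, 72L, 72L))
  ph <- make_phantom(cfg, seed = 2)
  fr <- frame_at(cfg$center, cfg$axis_direction, 11)
  m1 <- bin_stack(ph$stack, fr)
  # rotate stack and axis by 90 degrees about z: (y, x) -> (x, -y)
  vox_rot <- aperm(ph$stack$voxels, c(1, 3, 2, 4))[, , rev(seq_len(72)), , drop = FALSE]
  stack_rot <- image_stack(vox_rot, ph$stack$spacing, ph$stack$channel_names)
  ctr_rot <- c(cfg$center[1], cfg$center[3], (72 - 1) * 0.5 - cfg$center[2])
  axis_rot <- c(cfg$axis_direction[1], cfg$axis_direction[3], -cfg$axis_direction[2])
  m2 <- bin_stack(stack_rot, frame_at(ctr_rot, axis_rot, 11))
  rel <- abs(m2$intensities / m1$intensities - 1)
  expect_lt(max(rel, na.rm = TRUE), 0.02)
})

test_that("degenerate geometries error or warn as appropriate", {
  cfg <- quiet_phantom_config()
  ph <- make_phantom(cfg, seed = 1)
  expect_error(bin_stack(ph$stack, frame_at(c(500, 500, 500), c(1, 0, 0), 5)),
               "outside")
  expect_warning(bin_stack(ph$stack, frame_at(c(2, 17.75, 17.75), c(1, 0, 0), 10)),
                 "clipped")
  stack_aniso <- image_stack(ph$stack$voxels, c(1, 0.5, 0.7),
                             ph$stack$channel_names)
  expect_error(bin_stack(stack_aniso, frame_at(cfg$center, c(1, 0, 0), 10)),
               "isotropic")
})

test_that("projection masks, normalizes and handles constant maps", {
  m <- constant_map(4)
  expect_equal(unname(project_map(m, "probe")), matrix(4, 6, 3))
  # constant collection min-max normalizes to 0 by convention
  expect_equal(unname(project_map(m, "probe", normalize = TRUE)),
               matrix(0, 6, 3))
  m2 <- constant_map(4)
  m2$intensities[6, 3, 1] <- 8
  vals <- project_map(list(m, m2), "probe", normalize = TRUE)
  expect_equal(max(vals[[2]]), 1)
  expect_equal(min(vals[[1]]), 0)
})

test_that("DAPI floor masks background ROIs before display", {
  cfg <- quiet_phantom_config()
  ph <- make_phantom(cfg, seed = 1)
  m <- bin_stack(ph$stack, frame_at(cfg$center, c(1, 0, 0), 12))
  v <- project_map(m, "b-tubulin", dapi_floor = 20)
  dapi <- m$intensities[, , "DAPI"]
  expect_true(all(is.na(v[dapi < 20])))
  expect_error(project_map(m, "b-tubulin", dapi_floor = 1e9), "masked")
})

test_that("the spindle pattern concentrates in polar sectors of mid shells", {
  cfg <- quiet_phantom_config()
  ph <- make_phantom(cfg, seed = 1)
  m <- bin_stack(ph$stack, frame_at(cfg$center, c(1, 0, 0), 12))
  tub <- m$intensities[, , "b-tubulin"]
  expect_gt(mean(tub[3:5, "polar"]), mean(tub[3:5, "equatorial"]))
  expect_gt(mean(tub[3:5, "polar"]), mean(tub[6, "polar"]))
})
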