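test_that("Otsu segmentation finds the expected chromatin bodies", {
  ph_m <- make_phantom(quiet_phantom_config(), seed = 1)
  comps <- segment_chromatin(ph_m$stack)
  expect_length(comps, 1L)
  # volume close to the analytic ellipsoid volume (4/3) pi a b c
  expect_lt(abs(comps[[1]]$volume_um3 / (4 / 3 * pi * 8 * 8 * 4) - 1), 0.1)

  ph_s <- make_phantom(quiet_phantom_config("segregation",
                                            chromatin_half_axes = c(5, 4, 3),
                                            centroid_distance = 12), seed = 1)
  expect_length(segment_chromatin(ph_s$stack), 2L)
})

test_that("second-moment ellipsoid fit recovers digital solids", {
  # solid digital ball of radius 10 um at 0.5 um spacing
  sp <- c(0.5, 0.5, 0.5)
  n <- 48L
  ax <- (seq_len(n) - 1) * 0.5
  ctr <- rep(ax[n %/% 2], 3)
  P <- as.matrix(expand.grid(ax, ax, ax))
  mask <- array(rowSums(sweep(P, 2, ctr)^2) <= 100, dim = c(n, n, n))
  fit <- fit_ellipsoid(which(mask), dim = c(n, n, n), spacing = sp)
  expect_true(all(fit$half_axes > 9.5 & fit$half_axes < 10.5))
  expect_equal(fit$centroid, ctr, tolerance = 0.01)

  # oblate phantom: axes within 5%, short-axis direction within 2 degrees
  ph <- make_phantom(quiet_phantom_config(), seed = 2)
  comp <- segment_chromatin(ph$stack)[[1]]
  f <- fit_ellipsoid(comp, dim(ph$stack$voxels)[1:3], ph$stack$spacing)
  expect_equal(f$half_axes, c(8, 8, 4), tolerance = 0.05)
  ang <- acos(min(abs(sum(f$axes[, 3] * ph$truth$true_axis)), 1)) * 180 / pi
  expect_lt(ang, 2)
})

test_that("degenerate components are rejected", {
  expect_error(fit_ellipsoid(1:2, dim = c(4, 4, 4), spacing = c(1, 1, 1)),
               "degenerate")
  # coplanar voxels: a single z-slice
  idx <- which(array(slice.index(array(0, c(4, 4, 4)), 1) == 2, c(4, 4, 4)))
  expect_error(fit_ellipsoid(idx, dim = c(4, 4, 4), spacing = c(1, 1, 1)),
               "coplanar")
})

test_that("frame construction follows the shell-anchoring rules", {
  f <- structure(list(centroid = c(0, 0, 0), half_axes = c(8, 8, 4),
                      axes = diag(3)[, c(2, 3, 1)]), class = "ellipsoid_fit")
  fr <- build_frame("metaphase", f)
  expect_equal(fr$sphere_radius, 12)           # 1.5 * a1
  expect_equal(fr$axis, c(1, 0, 0))            # shortest-axis eigenvector
  f1 <- structure(list(centroid = c(0, 0, 0)), class = "ellipsoid_fit")
  f2 <- structure(list(centroid = c(0, 10, 0)), class = "ellipsoid_fit")
  fr2 <- build_frame("segregation", list(f1, f2))
  expect_equal(fr2$sphere_radius, 7.5)         # 1.5 * (10 / 2)
  expect_equal(fr2$center, c(0, 5, 0))
  expect_equal(fr2$axis, c(0, 1, 0))
  expect_error(build_frame("segregation", list(f1, f1)), "coincident")
  expect_error(build_frame("metaphase", list(f1, f2)), "exactly 1")
})

test_that("axis sign is canonicalized to nonnegative z, ties on y then x", {
  f1 <- structure(list(centroid = c(0, 0, 0)), class = "ellipsoid_fit")
  f2 <- structure(list(centroid = c(-4, 0, 3)), class = "ellipsoid_fit")
  fr <- build_frame("segregation", list(f1, f2))
  expect_gt(fr$axis[1], 0)
  f3 <- structure(list(centroid = c(0, -5, 0)), class = "ellipsoid_fit")
  fr2 <- build_frame("segregation", list(f1, f3))
  expect_equal(fr2$axis, c(0, 1, 0))
})

test_that("ROI assignment matches its definition on landmark points", {
  fr <- structure(list(phase = "metaphase", center = c(0, 0, 0),
                       axis = c(1, 0, 0), sphere_radius = 10),
                  class = "mitotic_frame")
  r <- assign_roi(rbind(c(0.5, 0, 0),     # on-axis, innermost
                        c(0, 9.5, 0),     # equatorial plane, outermost
                        c(0, 0, 10.5)),   # outside
                  fr)
  expect_equal(r$shell, c(1L, 6L, NA))
  expect_equal(as.character(r$sector), c("polar", "equatorial", NA))
  # boundary rules: rho = R falls in shell 6; the center in shell 1
  rb <- assign_roi(rbind(c(10, 0, 0), c(0, 0, 0)), fr)
  expect_equal(rb$shell, c(6L, 1L))
})

test_that("ROI assignment agrees with a brute-force trigonometry oracle", {
  fr <- structure(list(phase = "metaphase", center = c(3, -2, 5),
                       axis = unname(c(1, 2, -2) / 3), sphere_radius = 8),
                  class = "mitotic_frame")
  set.seed(42)
  P <- matrix(rnorm(3e4, sd = 5), ncol = 3)
  P <- sweep(P, 2, fr$center, `+`)
  got <- assign_roi(P, fr)
  # oracle: plain per-point trigonometry with explicit branching
  for (i in sample(nrow(P), 2000)) {
    d <- P[i, ] - fr$center
    rho <- sqrt(sum(d^2))
    if (rho > fr$sphere_radius) {
      expect_true(is.na(got$shell[i]))
      next
    }
    mu <- if (rho == 0) 1L else min(6L, floor(6 * rho / fr$sphere_radius) + 1L)
    lat <- 90 - acos(abs(sum(d * fr$axis)) / rho) * 180 / pi
    nu <- if (lat < 30) "equatorial" else if (lat < 60) "diagonal" else "polar"
    expect_equal(got$shell[i], mu)
    expect_equal(as.character(got$sector[i]), nu)
  }
})

test_that("ROI assignment is invariant under axis sign flip", {
  fr <- structure(list(phase = "metaphase", center = c(0, 0, 0),
                       axis = unname(c(2, -1, 2) / 3), sphere_radius = 6),
                  class = "mitotic_frame")
  fr_flip <- fr; fr_flip$axis <- -fr$axis
  set.seed(1)
  P <- matrix(rnorm(3000, sd = 3), ncol = 3)
  expect_identical(assign_roi(P, fr), assign_roi(P, fr_flip))
})

test_that("frames recovered from phantoms match the ground truth", {
  # a handful of seeded phantoms per phase; median errors well inside spec
  angs <- c(); rels <- c()
  for (s in 1:4) {
    for (phase in c("metaphase", "segregation")) {
      cfg <- if (phase == "metaphase") {
        noisy_phantom_config(axis_direction = unit_vec(s))
      } else {
        noisy_phantom_config("segregation", axis_direction = unit_vec(s),
                             chromatin_half_axes = c(5, 4, 3),
                             centroid_distance = 12)
      }
      ph <- make_phantom(cfg, seed = s)
      comps <- segment_chromatin(ph$stack)
      n_fit <- if (phase == "metaphase") 1L else 2L
      fits <- lapply(comps[seq_len(n_fit)], fit_ellipsoid,
                     dim = dim(ph$stack$voxels)[1:3],
                     spacing = ph$stack$spacing)
      fr <- build_frame(phase, fits)
      angs <- c(angs, acos(min(abs(sum(fr$axis * ph$truth$true_axis)), 1)) * 180 / pi)
      rels <- c(rels, abs(fr$sphere_radius / ph$truth$true_sphere_radius - 1))
    }
  }
  expect_lt(median(angs), 3)
  expect_lt(median(rels), 0.05)
})
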