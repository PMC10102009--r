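aligned_phantom <- function(mean_axis = c(1, 0, 0), seed = 2,
                            shape = c(16, 64, 64)) {
  generate_fiber_stack(fiber_spec(
    volume_shape = shape, voxel_size = c(1, 0.75, 0.75), n_fibers = 6,
    fiber_radius = 0.75, mean_axis = mean_axis, kappa = Inf,
    poisson = FALSE, seed = seed))
}

test_that("single-orientation cylinders recover theta/phi on core voxels", {
  g <- aligned_phantom(c(1, 0, 0))
  of <- local_orientation(g$shg, mask = g$truth$valid)
  core <- g$truth$core & of$valid
  expect_gt(sum(core), 50)
  d0 <- pmin(of$theta[core], 180 - of$theta[core])
  expect_lt(median(d0), 3)
  expect_lt(median(abs(of$phi[core] - 90)), 3)
  # 90-degree in-plane rotation equivariance: +y cylinders give theta = 90
  gy <- aligned_phantom(c(0, 1, 0), seed = 3)
  ofy <- local_orientation(gy$shg, mask = gy$truth$valid)
  cy <- gy$truth$core & ofy$valid
  expect_lt(median(abs(ofy$theta[cy] - 90)), 3)
})

test_that("orientation agrees with the structure-tensor oracle", {
  g <- aligned_phantom(c(1, 0, 0))
  of <- local_orientation(g$shg, mask = g$truth$valid)
  core <- which(g$truth$core & of$valid)
  est <- cbind(of$ax[core], of$ay[core], of$az[core])
  ora <- st_orientation_axes(g$shg$intensities, g$shg$voxel_size, core)
  expect_gte(mean(axis_angle_deg(est, ora) <= 5), 0.95)
})

test_that("window-size guidance holds: 2-3x diameter windows, MAE <= 5 deg", {
  # tilted fibers, diameter 1.5 um, default 5.3 um window is ~2.8 diameters
  g <- generate_fiber_stack(fiber_spec(
    volume_shape = c(24, 64, 64), voxel_size = c(1, 0.75, 0.75),
    n_fibers = 6, fiber_radius = 0.75, mean_axis = c(1, 1, 0.5),
    kappa = Inf, poisson = FALSE, seed = 11))
  of <- local_orientation(g$shg, mask = g$truth$valid)
  core <- g$truth$core & of$valid
  est <- cbind(of$ax[core], of$ay[core], of$az[core])
  tru <- cbind(g$truth$ax[core], g$truth$ay[core], g$truth$az[core])
  expect_lte(mean(axis_angle_deg(est, tru)), 5)
})

test_that("white-noise stacks yield finite angles, no NaN among valid", {
  set.seed(12)
  img <- volumetric_image(array(runif(16 * 32 * 32, 1, 10), c(16, 32, 32)),
                          c(1, 0.75, 0.75), "SHG")
  of <- local_orientation(img)
  expect_true(any(of$valid))
  expect_false(anyNA(of$theta[of$valid]))
  expect_false(anyNA(of$phi[of$valid]))
})

test_that("directional variance endpoints and the orthogonal-pair value", {
  # all orientations identical -> V = 0
  ax <- matrix(rep(c(1, 0, 0), 100), ncol = 3, byrow = TRUE)
  expect_equal(directional_variance_axes(ax), 0)
  # uniform axes, N = 1e5 -> V = 1 +- 0.01
  set.seed(13)
  expect_equal(directional_variance_axes(sample_axes(1e5, kappa = 0)), 1,
               tolerance = 0.01)
  # two equal orthogonal in-plane populations -> V = 0.75, and the mean
  # dyadic eigenvalues match a direct eigen-solve of diag(1/2, 1/2, 0)
  two <- rbind(matrix(rep(c(1, 0, 0), 50), ncol = 3, byrow = TRUE),
               matrix(rep(c(0, 1, 0), 50), ncol = 3, byrow = TRUE))
  expect_equal(directional_variance_axes(two), 0.75)
  lmax <- max(eigen(crossprod(two) / nrow(two), symmetric = TRUE)$values)
  expect_equal(1.5 * (1 - lmax), 0.75)
})

test_that("variance map: windowed V near 0 for parallel fibers, invariances", {
  g <- aligned_phantom(c(1, 0, 0))
  of <- local_orientation(g$shg, mask = g$truth$valid)
  vm <- directional_variance(of)
  expect_true(all(vm$V[vm$valid] >= 0 & vm$V[vm$valid] <= 1))
  core <- g$truth$core & vm$valid
  expect_lt(mean(vm$V[core]), 0.02)
  # V invariant under global intensity scaling
  img10 <- g$shg; img10$intensities <- img10$intensities * 10
  of10 <- local_orientation(img10, mask = g$truth$valid)
  vm10 <- directional_variance(of10)
  expect_equal(vm10$V[vm10$valid], vm$V[vm$valid], tolerance = 1e-12)
  # 90-degree in-plane rotation leaves V unchanged (permuted axes)
  rot <- aperm(g$shg$intensities, c(1, 3, 2))[, , dim(g$shg$intensities)[2]:1]
  # (rotating a (z,y,x) stack by 90 deg in-plane swaps y/x)
  imgr <- volumetric_image(array(rot, dim(g$shg$intensities)[c(1, 3, 2)]),
                           g$shg$voxel_size[c(1, 3, 2)], "SHG")
  ofr <- local_orientation(imgr, mask = imgr$intensities > 0)
  vmr <- directional_variance(ofr)
  expect_lt(abs(mean(vmr$V[vmr$valid]) - mean({
    ofa <- local_orientation(g$shg, mask = g$shg$intensities > 0)
    vma <- directional_variance(ofa)
    vma$V[vma$valid]
  })), 0.01)
})

test_that("windows below the minimum size are rejected", {
  g <- aligned_phantom(c(1, 0, 0))
  expect_error(local_orientation(g$shg, window_um = c(1, 1, 1)), "window")
  of <- local_orientation(g$shg, mask = g$truth$valid)
  expect_error(directional_variance(of, window_um = c(1.5, 1.5, 1.5)),
               "window")
})

test_that("zone mean variance averages per zone and flags empty zones", {
  d <- c(4, 20, 10)
  V <- array(0.4, d)
  zones <- array(0L, d)
  zones[, 1:10, ] <- 1L
  zones[, 11:20, ] <- 3L
  vmap <- structure(list(V = V, valid = array(TRUE, d),
                         window_um = c(5, 5.3, 5.3)),
                    class = "variance_map")
  zm <- zone_mean_variance(vmap, structure(zones, levels = c(
    "background", "superficial", "transitional", "radial", "calcified")))
  expect_equal(zm$mean_variance, c(0.4, 0.4))
  expect_false(any(zm$missing))
  # zone with no valid voxels flagged missing
  vmap$valid[zones == 3L] <- FALSE
  zm2 <- zone_mean_variance(vmap, structure(zones, levels = c(
    "background", "superficial", "transitional", "radial", "calcified")))
  expect_true(zm2$missing[zm2$zone == "radial"])
})

test_that("mean variance rises with phantom dispersion (two-point check)", {
  vs <- sapply(c(32, 0), function(k) {
    g <- generate_fiber_stack(fiber_spec(
      volume_shape = c(16, 48, 48), voxel_size = c(1, 0.75, 0.75),
      n_fibers = 60, fiber_radius = 0.75, kappa = k, poisson = FALSE,
      seed = 21))
    of <- local_orientation(g$shg, mask = g$truth$valid)
    directional_variance_axes(field_axes(of))
  })
  expect_lt(vs[1], vs[2])
})
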