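# Gaussian kernel fields: voxelization, splatting, initialization, and
# adaptive density control, each against an independent oracle.

test_that("voxelize evaluates the kernel sum exactly at voxel centers", {
  g <- volume_grid(c(9, 9, 9), 2)
  gs <- gaussian_set(matrix(0, 1, 3), 1, matrix(2, 1, 3))
  v <- voxelize(gs, g)
  expect_equal(v$values[5, 5, 5], 1.0)
  expect_equal(v$values[6, 5, 5], exp(-0.5))  # 2 mm = one sigma away
  # superposition: duplicated kernel doubles every voxel
  gs2 <- gaussian_set(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1),
                      matrix(2, 2, 3))
  expect_equal(voxelize(gs2, g)$values, 2 * v$values)
  # empty set gives zeros
  gs0 <- gaussian_set(matrix(0, 0, 3), numeric(0), matrix(0, 0, 3) + 1)
  expect_equal(max(abs(voxelize(gs0, g)$values)), 0)
})

test_that("voxelize matches direct summation within the truncation bound", {
  g <- volume_grid(c(9, 9, 9), 2)
  for (seed in 1:3) {
    gs <- random_gaussians(1, seed = seed, extent = 6)
    v <- voxelize(gs, g, allow_negative = TRUE)
    oracle <- voxelize_oracle(gs, g)
    expect_lt(max(abs(v$values - oracle)), 1e-3 * abs(gs$densities[1]))
  }
})

test_that("negative-permitting flag controls clamping", {
  g <- volume_grid(c(5, 5, 5), 2)
  gs <- gaussian_set(matrix(0, 1, 3), -1, matrix(2, 1, 3))
  expect_equal(voxelize(gs, g, allow_negative = TRUE)$values[3, 3, 3], -1)
  expect_equal(max(abs(voxelize(gs, g, allow_negative = FALSE)$values)), 0)
})

test_that("total integral is conserved by voxelization", {
  g <- volume_grid(c(25, 25, 25), 2)
  gs <- random_gaussians(6, seed = 11, extent = 6, rho_range = c(0.5, 2),
                         scale_range = c(1.5, 3))
  v <- voxelize(gs, g, allow_negative = TRUE)
  expect_equal(sum(v$values) * prod(g$spacing), gaussian_total_integral(gs),
               tolerance = 0.02)
})

test_that("rotating an isotropic kernel changes nothing", {
  g <- volume_grid(c(9, 9, 9), 2)
  geom <- tiny_geometry(n_proj = 1, n_u = 16, n_v = 16, pixel = 2)
  base <- gaussian_set(matrix(c(1, 2, -1), 1, 3), 1.3, matrix(2.5, 1, 3))
  v0 <- voxelize(base, g)
  s0 <- splat_project(base, geom, 1)$image
  set.seed(3)
  for (i in 1:3) {
    rot <- base
    rot$quaternions <- matrix(rnorm(4), 1, 4)
    expect_lt(max(abs(voxelize(rot, g)$values - v0$values)), 1e-9)
    expect_lt(max(abs(splat_project(rot, geom, 1)$image - s0)), 1e-9)
  }
})

test_that("splatting matches numeric ray integration at cone-beam geometry", {
  # kernels with sigma >= 1 detector pixel, sad = 1000 mm
  geom <- tiny_geometry(n_proj = 2, n_u = 24, n_v = 20, pixel = 5)
  gs <- random_gaussians(4, seed = 21, extent = 15, rho_range = c(0.5, 2),
                         scale_range = c(4, 8))
  sf <- splat_project(gs, geom, 2)
  ax <- gaussCBCT:::detector_axes(geom)
  # all pixels with non-negligible signal
  idx <- which(sf$image > 0.05 * max(sf$image), arr.ind = TRUE)
  set.seed(2)
  idx <- idx[sample(nrow(idx), min(40, nrow(idx))), , drop = FALSE]
  rel <- apply(idx, 1, function(ij) {
    oracle <- ray_integral_oracle(gs, geom, 2, ij[2], ij[1], step = 0.2,
                                  t_range = c(geom$sad - 120, geom$sad + 120))
    abs(sf$image[ij[1], ij[2]] - oracle) / oracle
  })
  # local-affine approximation: within 2% at 90% of sampled pixels
  expect_gte(mean(rel <= 0.02), 0.9)
})

test_that("splat amplitude reduces to sqrt(2*pi) in the near-parallel limit", {
  geom <- scan_geometry(1e6, 1.5e6, 33, 33, 1.5, 1.5, c(0, 90), c(0, 1))
  gs <- gaussian_set(matrix(0, 1, 3), 1, matrix(1, 1, 3))
  sf <- splat_project(gs, geom, 1)
  expect_equal(sf$image[17, 17], sqrt(2 * pi), tolerance = 0.01 * sqrt(2 * pi))
  # one sigma off-axis: previous value x exp(-1/2)
  expect_equal(sf$image[17, 18], sqrt(2 * pi) * exp(-0.5),
               tolerance = 0.01 * sqrt(2 * pi))
  # zero density renders nothing
  gs0 <- gaussian_set(matrix(0, 1, 3), 0, matrix(1, 1, 3))
  expect_equal(max(abs(splat_project(gs0, geom, 1)$image)), 0)
})

test_that("kernels behind the source are skipped with a warning", {
  geom <- tiny_geometry(n_proj = 1, n_u = 8, n_v = 8)
  gs <- gaussian_set(matrix(c(0, -2000, 0), 1, 3), 1, matrix(2, 1, 3))
  expect_warning(sf <- splat_project(gs, geom, 1), "skipped")
  expect_false(sf$valid[1])
})

test_that("analytic gradients match finite differences (voxelize and splat)", {
  g <- volume_grid(c(10, 10, 10), 2.5)
  geom <- tiny_geometry(n_proj = 3, n_u = 24, n_v = 20, pixel = 3, arc = 270)
  gs <- random_gaussians(3, seed = 31, extent = 10, rho_range = c(0.4, 1.5),
                         scale_range = c(2, 5))
  set.seed(32)
  upv <- array(rnorm(1000), c(10, 10, 10))
  ups <- matrix(rnorm(20 * 24), 20, 24)
  grv <- gaussCBCT:::voxelize_backward(gs, g, upv, allow_negative = TRUE)
  grs <- gaussCBCT:::splat_backward(gs, geom, 2, ups)
  lossv <- function(gg) sum(upv * voxelize(gg, g, allow_negative = TRUE)$values)
  losss <- function(gg) sum(ups * splat_project(gg, geom, 2)$image)
  h <- 1e-5
  fields <- list(positions = 3, scales = 3, quaternions = 4)
  worst <- 0
  for (i in 1:3) {
    for (f in names(fields)) {
      for (j in seq_len(fields[[f]])) {
        for (op in c("vox", "splat")) {
          g1 <- gs; g1[[f]][i, j] <- g1[[f]][i, j] + h
          g2 <- gs; g2[[f]][i, j] <- g2[[f]][i, j] - h
          fn <- if (op == "vox") lossv else losss
          fd <- (fn(g1) - fn(g2)) / (2 * h)
          an <- switch(f, positions = , scales = , quaternions = {
            gmat <- if (op == "vox") grv else grs
            switch(f, positions = gmat$d_pos, scales = gmat$d_scales,
                   quaternions = gmat$d_quats)[i, j]
          })
          worst <- max(worst, abs(fd - an) / max(abs(fd), 1e-6))
        }
      }
    }
    g1 <- gs; g1$densities[i] <- g1$densities[i] + h
    g2 <- gs; g2$densities[i] <- g2$densities[i] - h
    worst <- max(worst,
                 abs((lossv(g1) - lossv(g2)) / (2 * h) - grv$d_rho[i]) /
                   max(abs(grv$d_rho[i]), 1e-6),
                 abs((losss(g1) - losss(g2)) / (2 * h) - grs$d_rho[i]) /
                   max(abs(grs$d_rho[i]), 1e-6))
  }
  expect_lt(worst, 1e-3)
})

test_that("init_from_volume lattice schemes behave as specified", {
  vol <- ball_volume(dim = c(20, 20, 20), spacing = 4, radius = 35)
  u <- init_from_volume(vol, 8000, scheme = "uniform")
  expect_equal(u$count, 8000)  # 20^3 lattice over a cubic grid
  expect_true(all(u$densities == 0))
  z <- init_from_volume(volume(vol$values * 0, vol$grid), 1000,
                        scheme = "grid", density_floor = 1e-4)
  expect_equal(z$count, 0)
  expect_error(init_from_volume(vol, 1e6, "grid"), "exceeds voxel count")
  # voxelized init correlates with a smooth seed volume
  g <- vol$grid
  pts <- gaussCBCT:::grid_points(g)
  smooth <- volume(array(0.02 * exp(-rowSums(pts^2) / 1500), g$dim), g)
  gi <- init_from_volume(smooth, 4000, scheme = "grid", density_floor = 1e-4)
  vv <- voxelize(gi, g)
  expect_gt(cor(as.numeric(vv$values), as.numeric(smooth$values)), 0.8)
})

test_that("adaptive control prunes, clones and splits as contracted", {
  cfg <- adaptive_control_config(prune_eps = 1e-3, grad_thresh = 1,
                                 size_thresh = 5)
  gs <- gaussian_set(rbind(c(0, 0, 0), c(10, 0, 0), c(-10, 0, 0)),
                     c(0.5, 1e-5, 0.8),
                     rbind(c(2, 2, 2), c(2, 2, 2), c(8, 6, 6)))
  # no gradients, no tiny densities -> unchanged
  keep <- adaptive_control(gaussian_set(gs$positions[c(1, 3), ],
                                        gs$densities[c(1, 3)],
                                        gs$scales[c(1, 3), ]),
                           c(0, 0), cfg)
  expect_equal(keep$count, 2)
  # tiny-density kernel pruned
  pruned <- adaptive_control(gs, c(0, 0, 0), cfg)
  expect_equal(pruned$count, 2)
  # small kernel with large gradient cloned; density halved, total conserved
  cl <- adaptive_control(gaussian_set(matrix(0, 1, 3), 0.5, matrix(2, 1, 3)),
                         2, cfg, grad_dir = matrix(c(1, 0, 0), 1, 3))
  expect_equal(cl$count, 2)
  expect_equal(sum(cl$densities), 0.5)
  # voxelized mass approximately conserved by the clone
  g <- volume_grid(c(15, 15, 15), 2)
  before <- sum(voxelize(gaussian_set(matrix(0, 1, 3), 0.5,
                                      matrix(2, 1, 3)), g)$values)
  after <- sum(voxelize(cl, g)$values)
  expect_equal(after, before, tolerance = 0.05)
  # large kernel split: two children, scales / 1.6, +-0.5 sigma apart on the
  # largest principal axis
  spl <- adaptive_control(gaussian_set(matrix(0, 1, 3), 0.8,
                                       matrix(c(8, 6, 6), 1, 3)),
                          2, cfg)
  expect_equal(spl$count, 2)
  expect_equal(spl$scales[1, ], c(8, 6, 6) / 1.6)
  expect_equal(sum(spl$densities), 0.8)
  expect_equal(abs(spl$positions[1, 1] - spl$positions[2, 1]), 8)
  expect_equal(spl$positions[1, 2], spl$positions[2, 2])
})
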