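# Losses, optimizer plumbing, stage determinism and convergence smoke tests.

test_that("D-SSIM loss identities and bounds", {
  set.seed(30)
  a <- matrix(runif(30 * 24), 30, 24)
  expect_equal(dssim_loss(a, a), 0)
  shifted <- dssim_loss(a + 0.3, a)
  expect_gt(shifted, 0)
  expect_lte(shifted, 0.5)
  expect_lte(dssim_loss(-a, a), 1)
  expect_error(dssim_loss(a, t(a)), "shape mismatch")
})

test_that("D-SSIM gradient matches finite differences", {
  set.seed(31)
  a <- matrix(runif(20 * 16), 20, 16)
  b <- matrix(runif(20 * 16), 20, 16)
  gr <- gaussCBCT:::dssim_grad(a, b)
  expect_equal(gr$loss, dssim_loss(a, b))
  h <- 1e-6
  set.seed(32)
  for (j in sample(length(a), 6)) {
    a1 <- a; a1[j] <- a1[j] + h
    a2 <- a; a2[j] <- a2[j] - h
    fd <- (dssim_loss(a1, b) - dssim_loss(a2, b)) / (2 * h)
    expect_equal(gr$grad[j], fd, tolerance = 1e-3 * max(abs(fd), 1e-4))
  }
})

test_that("TV loss matches hand values and is homogeneous", {
  expect_equal(tv_loss(array(3.7, c(6, 6, 6))), 0)
  # linear in x with slope s per voxel: mean |dx| = s, others 0 -> s / 3
  s <- 0.25
  ramp <- array(rep(s * (1:8), 64), c(8, 8, 8))
  expect_equal(tv_loss(ramp), s / 3)
  set.seed(33)
  v <- array(runif(6^3), c(6, 6, 6))
  expect_equal(tv_loss(5 * v), 5 * tv_loss(v))
  # gradient check
  g <- gaussCBCT:::tv_grad(v)
  h <- 1e-7
  for (j in sample(length(v), 5)) {
    v1 <- v; v1[j] <- v1[j] + h
    v2 <- v; v2[j] <- v2[j] - h
    expect_equal(g[j], (tv_loss(v1) - tv_loss(v2)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("loss weights and schedules validate inputs", {
  expect_error(loss_weights(lambda_ssim = -1))
  expect_error(stage_schedule(stage1_epochs = 0))
  w <- loss_weights()
  expect_equal(w$lambda_ssim, 0.25)
  expect_equal(w$lambda_tv, 0.05)
  expect_equal(w$lambda_mbc, 1)
  expect_equal(w$tv_D, 32)
  s <- stage_schedule()
  expect_equal(c(s$stage1_epochs, s$stage2_epochs, s$stage3_epochs),
               c(5000, 1000, 1000))
  expect_equal(c(s$batch2, s$batch3), c(32, 8))
})

make_static_fixture <- function(n_proj = 12) {
  vol <- ball_volume(dim = c(20, 20, 12), spacing = 6, radius = 40,
                     flatten_z = 1)
  traj <- make_circular_trajectory(0, 360, 60, n_proj / 60)
  geom <- scan_geometry(1000, 1500, 32, 24, 8, 8, traj$angles, traj$times)
  frames <- vapply(seq_len(n_proj), function(k) forward_project(vol, geom, k),
                   matrix(0, 24, 32))
  list(vol = vol, pset = projection_set(frames, geom))
}

test_that("stage 1 halves the projection misfit on a static scan", {
  fx <- make_static_fixture()
  g <- fx$vol$grid
  gs0 <- init_from_volume(fdk_reconstruct(fx$pset, g), 600, "grid",
                          density_floor = 1e-3)
  init_l1 <- mean(vapply(1:4, function(k) {
    mean(abs(suppressWarnings(splat_project(gs0, fx$pset$geometry, k))$image -
               fx$pset$frames[, , k]))
  }, 0))
  s1 <- stage1_fit(fx$pset, gs0, epochs = 200, seed = 0, tv_grid = g,
                   acfg = NULL)
  final_l1 <- mean(vapply(1:4, function(k) {
    mean(abs(suppressWarnings(splat_project(s1$gset, fx$pset$geometry,
                                            k))$image -
               fx$pset$frames[, , k]))
  }, 0))
  expect_lt(final_l1, 0.5 * init_l1)
  # smoothed loss decreases over the stage
  expect_lt(mean(tail(s1$log$loss, 50)), mean(head(s1$log$loss, 50)))
})

test_that("stage 1 is deterministic under a fixed seed", {
  fx <- make_static_fixture(n_proj = 6)
  g <- fx$vol$grid
  gs0 <- init_from_volume(fdk_reconstruct(fx$pset, g), 300, "grid",
                          density_floor = 1e-3)
  a <- stage1_fit(fx$pset, gs0, epochs = 30, seed = 5, tv_grid = g, acfg = NULL)
  b <- stage1_fit(fx$pset, gs0, epochs = 30, seed = 5, tv_grid = g, acfg = NULL)
  expect_identical(a$gset$densities, b$gset$densities)
  expect_identical(a$gset$positions, b$gset$positions)
  # zero TV weight: loss equals the projection term
  c0 <- stage1_fit(fx$pset, gs0, weights = loss_weights(lambda_tv = 0),
                   epochs = 5, seed = 1, tv_grid = g, acfg = NULL)
  expect_equal(c0$log$loss, c0$log$l1 + 0.25 * c0$log$dssim)
})

test_that("stage 2/3 joint fit is deterministic and validates batches", {
  fx <- make_static_fixture(n_proj = 10)
  g <- fx$vol$grid
  gs0 <- init_from_volume(fdk_reconstruct(fx$pset, g), 300, "grid",
                          density_floor = 1e-3)
  mbc <- mbc_model(g, c(2, 3, 4))
  spec <- motion_encoder_spec(c(24, 32))
  enc <- list(spec = spec, weights = encoder_init(spec, 1))
  expect_error(stage23_fit(fx$pset, gs0, mbc, enc, epochs = 1, batch = 99,
                           out_grid = g), "exceeds projection count")
  a <- stage23_fit(fx$pset, gs0, mbc, enc, epochs = 8, batch = 4, stage = 2,
                   out_grid = g, seed = 3)
  b <- stage23_fit(fx$pset, gs0, mbc, enc, epochs = 8, batch = 4, stage = 2,
                   out_grid = g, seed = 3)
  expect_identical(encode(fx$pset$frames, spec, a$enc$weights),
                   encode(fx$pset$frames, spec, b$enc$weights))
  expect_identical(a$mbc$levels[[2]]$densities, b$mbc$levels[[2]]$densities)
})

test_that("scaling gauge: (c*e, head/c) leaves composed DVFs unchanged", {
  g <- volume_grid(c(12, 12, 8), 5)
  mbc <- mbc_model(g, c(2, 3, 4))
  set.seed(40)
  for (i in 1:3) {
    mbc$levels[[i]]$densities <- matrix(rnorm(3 * mbc$levels[[i]]$count),
                                        ncol = 3)
  }
  spec <- motion_encoder_spec(c(24, 32))
  enc_w <- encoder_init(spec, 2, head_sd = 0.1)
  frame <- matrix(runif(24 * 32), 24, 32)
  w1 <- encode(frame, spec, enc_w)
  cval <- 2.5
  mbc2 <- mbc
  for (i in 1:3) mbc2$levels[[i]]$densities <- cval * mbc$levels[[i]]$densities
  enc_w2 <- enc_w
  L <- length(spec$channels)
  enc_w2$params[[4 * L + 1]] <- enc_w2$params[[4 * L + 1]] / cval
  enc_w2$params[[4 * L + 2]] <- enc_w2$params[[4 * L + 2]] / cval
  w2 <- encode(frame, spec, enc_w2)
  d1 <- compose_dvf(voxelize_mbcs(mbc), w1, g)
  d2 <- compose_dvf(voxelize_mbcs(mbc2), w2, g)
  expect_equal(d1$vectors, d2$vectors, tolerance = 1e-10)
})

test_that("known per-frame displacements are recovered on a 1-level toy problem", {
  # ball moving along SI by a known trace through a known smooth basis
  # field; per-frame scalars recovered by 1D optimization of the projection
  # misfit through the same compose -> warp -> project chain
  g <- volume_grid(c(20, 20, 14), 5)
  pts <- gaussCBCT:::grid_points(g)
  ref <- volume(array(0.02 * exp(-((pts[, 1] + 10)^2 + pts[, 2]^2 +
                                     (pts[, 3] + 5)^2) / 500), g$dim), g)
  basis_field <- array(exp(-rowSums(pts^2) / 4000), g$dim)  # ~1 at center
  traj <- make_circular_trajectory(0, 360, 60, 0.2)
  geom <- scan_geometry(1000, 1500, 40, 30, 5, 5, traj$angles, traj$times)
  alpha_true <- c(0, 3, 8, 12, 6, 1, -4, 10, 2, 7, 11, 5)
  zero <- array(0, g$dim)
  mk_dvf <- function(a) {
    displacement_field(array(c(zero, zero, a * basis_field), c(g$dim, 3)), g)
  }
  frames <- vapply(seq_along(alpha_true), function(k) {
    forward_project(warp_volume(ref, mk_dvf(alpha_true[k])), geom, k)
  }, matrix(0, 30, 40))
  alpha_hat <- vapply(seq_along(alpha_true), function(k) {
    stats::optimize(function(a) {
      drr <- forward_project(warp_volume(ref, mk_dvf(a)), geom, k)
      sum((drr - frames[, , k])^2)
    }, c(-15, 15), tol = 1e-4)$minimum
  }, 0)
  # recovered SI displacement at the ball center within 0.5 mm RMS
  ctr_val <- exp(-sum(c(-10, 0, -5)^2) / 4000)
  rms <- sqrt(mean(((alpha_hat - alpha_true) * ctr_val)^2))
  expect_lt(rms, 0.5)
})

test_that("adam descends a quadratic", {
  st <- gaussCBCT:::adam_new()
  params <- list(x = c(5, -3))
  for (i in 1:300) {
    g <- list(x = 2 * params$x)
    up <- gaussCBCT:::adam_step(st, params, g, list(x = 0.1))
    st <- up$state
    params <- up$params
  }
  expect_lt(max(abs(params$x)), 0.2)
})

test_that("full reconstruction materializes one frame per projection and exports artifacts", {
  st <- tiny_phantom_setup("S1", n_proj = 16, dim = c(24, 24, 12), spacing = 8,
                           detector = c(32, 24), pixel = 10,
                           keep = character(0))
  cfg <- recon_config("desk", M = 600, mbc_levels = c(2, 3, 4),
                      schedule = stage_schedule(50, 15, 10, 8, 4),
                      densify_from = 20, densify_until = 40,
                      densify_every = 10, encoder_input = c(24, 32), seed = 2)
  rec <- reconstruct(st$sim$projections, st$grid, cfg)
  expect_s3_class(rec, "dynamic_reconstruction")
  expect_identical(nrow(rec$coefficients), 16L)   # one frame per projection
  f <- materialize_frame(rec, 5)
  expect_true(all(is.finite(f$values)))
  expect_identical(dim(f$values), st$grid$dim)
  d <- frame_dvf(rec, 5)
  expect_s3_class(d, "displacement_field")
  out <- file.path(tempdir(), "recon_export_test")
  export_reconstruction(rec, out, frames = 3)
  files <- list.files(out)
  expect_true(all(c("reference.mha", "coefficients.csv", "log.jsonl",
                    "mbc_1_x.mha", "mbc_3_z.mha", "frame_0003.mha") %in% files))
  # coefficients round-trip through the CSV
  df <- read.csv(file.path(out, "coefficients.csv"))
  expect_equal(as.matrix(df[, -1]), rec$coefficients, tolerance = 1e-12,
               ignore_attr = TRUE)
  # per-epoch log lines parse as JSON
  lines <- readLines(file.path(out, "log.jsonl"))
  expect_identical(length(lines), 50L + 15L + 10L)
  expect_silent(jsonlite::fromJSON(lines[1]))
  unlink(out, recursive = TRUE)
})
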