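# Motion model: basis voxelization, DVF composition, warping, the
# normality regularizer, and the convolutional encoder.

test_that("voxelize_mbcs produces nine signed basis fields", {
  g <- volume_grid(c(20, 20, 12), 4)
  m <- mbc_model(g, c(3, 4, 5))
  expect_equal(vapply(m$levels, `[[`, 0L, "count"), c(27L, 64L, 125L))
  basis <- voxelize_mbcs(m)
  expect_length(basis, 9)
  expect_true(all(vapply(basis, function(b) max(abs(b$values)), 0) == 0))
  # single kernel with x-channel density 2 at a voxel center
  m$levels[[1]] <- gaussian_set(matrix(m$mbc_grid$origin, 1, 3),
                                matrix(c(2, 0, 0), 1, 3),
                                matrix(6, 1, 3))
  basis <- voxelize_mbcs(m)
  expect_equal(basis[[1]]$values[1, 1, 1], 2)
  expect_equal(basis[[2]]$values[1, 1, 1], 0)
  expect_equal(basis[[3]]$values[1, 1, 1], 0)
  # negative densities survive the negative-permitting voxelizer
  m$levels[[1]]$densities[1, 1] <- -1
  expect_equal(voxelize_mbcs(m)[[1]]$values[1, 1, 1], -1)
})

test_that("compose_dvf is exactly linear and selects bases", {
  g <- volume_grid(c(12, 12, 8), 5)
  m <- mbc_model(g, c(3, 4, 5))
  for (i in 1:3) {
    m$levels[[i]]$densities <- matrix(rnorm(3 * m$levels[[i]]$count),
                                      ncol = 3)
  }
  basis <- voxelize_mbcs(m)
  expect_equal(max(abs(compose_dvf(basis, rep(0, 9), g)$vectors)), 0)
  d1 <- compose_dvf(basis, c(1, rep(0, 8)), g)
  # w = e_1 selects basis 1 into the x component only
  up <- gaussCBCT:::cpp_resample(as.numeric(basis[[1]]$values),
                                 m$mbc_grid$dim, m$mbc_grid$spacing,
                                 m$mbc_grid$origin, g$dim, g$spacing,
                                 g$origin)
  expect_equal(as.numeric(d1$vectors[, , , 1]), as.numeric(up))
  expect_equal(max(abs(d1$vectors[, , , 2:3])), 0)
  set.seed(9)
  w <- rnorm(9)
  d <- compose_dvf(basis, w, g)
  d2 <- compose_dvf(basis, 2 * w, g)
  expect_equal(d2$vectors, 2 * d$vectors, tolerance = 1e-14)
  # mismatched grids among bases are rejected
  basis2 <- basis
  basis2[[5]] <- volume(basis[[5]]$values, volume_grid(m$mbc_grid$dim,
                                                       m$mbc_grid$spacing * 2))
  expect_error(compose_dvf(basis2, w, g), "share one grid")
})

test_that("warp with zero displacement is the identity", {
  g <- volume_grid(c(10, 12, 8), 3)
  set.seed(10)
  v <- volume(array(runif(960), c(10, 12, 8)), g)
  d0 <- displacement_field(array(0, c(10, 12, 8, 3)), g)
  expect_equal(warp_volume(v, d0)$values, v$values, tolerance = 1e-14)
})

test_that("constant displacement shifts a linear ramp by the displacement", {
  g <- volume_grid(c(16, 8, 8), 2)
  ax <- grid_axis(g, 1)
  ramp <- volume(array(rep(ax, 64), c(16, 8, 8)), g)
  d <- displacement_field(array(rep(c(2, 0, 0), each = 1024),
                                c(16, 8, 8, 3)), g)
  w <- warp_volume(ramp, d)
  interior <- 2:14
  expect_equal(w$values[interior, , ], ramp$values[interior, , ] + 2,
               tolerance = 1e-12)
})

test_that("warping the reference with the ground-truth field reproduces the rendered frame", {
  grid <- volume_grid(c(50, 50, 26), 4)
  sp <- phantom_spec(grid)
  ref <- render_frame(sp, 0)
  for (tv in c(10, 15)) {
    fr <- render_frame(sp, tv)
    w <- warp_volume(ref$volume, fr$gt_dvf)
    re <- sqrt(sum((w$values - fr$volume$values)^2)) /
      sqrt(sum(fr$volume$values^2))
    expect_lt(re, 0.05)
  }
})

test_that("warp of a smooth field under a smooth DVF is accurate", {
  g <- volume_grid(c(20, 20, 16), 4)
  pts <- gaussCBCT:::grid_points(g)
  f <- function(p) exp(-((p[, 1] + 8)^2 + p[, 2]^2 + p[, 3]^2) / 800)
  v <- volume(array(f(pts), g$dim), g)
  # smooth displacement, max 10 mm
  dvec <- cbind(10 * exp(-(pts[, 1]^2 + pts[, 2]^2) / 3000), 0,
                5 * exp(-pts[, 3]^2 / 2000))
  d <- displacement_field(array(dvec, c(g$dim, 3)), g)
  w <- warp_volume(v, d)
  truth <- f(pts + dvec)
  rms <- sqrt(mean((as.numeric(w$values) - truth)^2)) / max(abs(truth))
  expect_lt(rms, 0.01)
})

test_that("normality loss matches hand-computed values", {
  g <- volume_grid(c(4, 4, 4), 1)
  mk <- function(val) volume(array(val, c(4, 4, 4)), g)
  # all bases with mean square exactly 1
  ones <- replicate(9, mk(1), simplify = FALSE)
  expect_equal(normality_loss(ones), 0)
  # all zero
  zeros <- replicate(9, mk(0), simplify = FALSE)
  expect_equal(normality_loss(zeros), 1)
  # one basis mean-square 2, rest 1
  mixed <- ones
  mixed[[4]] <- mk(sqrt(2))
  expect_equal(normality_loss(mixed), 1 / 9)
})

test_that("the (w, e) sign gauge leaves composed DVFs unchanged", {
  g <- volume_grid(c(10, 10, 8), 5)
  m <- mbc_model(g, c(3, 4, 5))
  for (i in 1:3) {
    m$levels[[i]]$densities <- matrix(rnorm(3 * m$levels[[i]]$count), ncol = 3)
  }
  basis <- voxelize_mbcs(m)
  neg_basis <- lapply(basis, function(b) volume(-b$values, b$grid))
  set.seed(12)
  w <- rnorm(9)
  expect_equal(compose_dvf(basis, w, g)$vectors,
               compose_dvf(neg_basis, -w, g)$vectors, tolerance = 1e-14)
})

test_that("encoder output is 9-dimensional, deterministic, zero for zero head", {
  spec <- motion_encoder_spec(c(48, 64))
  init <- encoder_init(spec, seed = 1)
  set.seed(5)
  frame <- matrix(runif(48 * 96), 48, 96)
  w1 <- encode(frame, spec, init)
  expect_length(w1, 9)
  expect_true(all(is.finite(w1)))
  expect_identical(w1, encode(frame, spec, init))
  # zero final layer -> zero output for any input
  L <- length(spec$channels)
  init0 <- init
  init0$params[[4 * L + 1]] <- init0$params[[4 * L + 1]] * 0
  init0$params[[4 * L + 2]] <- init0$params[[4 * L + 2]] * 0
  expect_equal(encode(frame, spec, init0), rep(0, 9))
  expect_error(encode(frame * NaN, spec, init), "non-finite")
})

test_that("encoder gradients match finite differences", {
  spec <- motion_encoder_spec(c(12, 16))
  init <- encoder_init(spec, seed = 2, head_sd = 0.05)
  set.seed(6)
  inp <- array(rnorm(12 * 16 * 3), c(12, 16, 3))
  up <- matrix(rnorm(27), 3, 9)
  bw <- gaussCBCT:::cpp_encoder_fwdbwd(as.numeric(inp), c(12L, 16L), 3L,
                                       init$params, spec$channels, up)
  lossf <- function(params) {
    r <- gaussCBCT:::cpp_encoder_forward(as.numeric(inp), c(12L, 16L), 3L,
                                         params, spec$channels, TRUE,
                                         init$running)
    sum(up * r$coeffs)
  }
  h <- 1e-5
  worst <- 0
  set.seed(7)
  for (pi in seq_along(init$params)) {
    n_el <- length(init$params[[pi]])
    for (j in sample(n_el, min(4, n_el))) {
      p1 <- init$params; p1[[pi]][j] <- p1[[pi]][j] + h
      p2 <- init$params; p2[[pi]][j] <- p2[[pi]][j] - h
      fd <- (lossf(p1) - lossf(p2)) / (2 * h)
      an <- bw$grads[[pi]][j]
      if (abs(fd) > 1e-8 || abs(an) > 1e-8) {
        worst <- max(worst, abs(fd - an) / max(abs(fd), 1e-4))
      }
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("warp gradients match finite differences", {
  g <- volume_grid(c(8, 8, 6), 3)
  set.seed(13)
  ref <- array(runif(8 * 8 * 6), c(8, 8, 6))
  dvf <- array(rnorm(8 * 8 * 6 * 3, sd = 1.3), c(8, 8, 6, 3))
  up <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  bw <- gaussCBCT:::cpp_warp_backward(as.numeric(ref), g$dim, g$spacing,
                                      g$origin, as.numeric(dvf),
                                      as.numeric(up))
  lossf <- function(r, d) {
    sum(up * gaussCBCT:::cpp_warp(as.numeric(r), g$dim, g$spacing, g$origin,
                                  as.numeric(d)))
  }
  h <- 1e-6
  set.seed(14)
  worst_ref <- 0
  for (j in sample(length(ref), 8)) {
    r1 <- ref; r1[j] <- r1[j] + h
    r2 <- ref; r2[j] <- r2[j] - h
    fd <- (lossf(r1, dvf) - lossf(r2, dvf)) / (2 * h)
    worst_ref <- max(worst_ref, abs(fd - bw$d_ref[j]))
  }
  expect_lt(worst_ref, 1e-4)
  worst_d <- 0
  for (j in sample(length(dvf), 8)) {
    d1 <- dvf; d1[j] <- d1[j] + h
    d2 <- dvf; d2[j] <- d2[j] - h
    fd <- (lossf(ref, d1) - lossf(ref, d2)) / (2 * h)
    an <- array(bw$d_dvf, dim(dvf))[j]
    worst_d <- max(worst_d, abs(fd - an) / max(abs(fd), 1e-3))
  }
  # trilinear interpolation is piecewise linear in the displacement; away
  # from lattice breakpoints the analytic slope is exact
  expect_lt(worst_d, 1e-3)
})
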