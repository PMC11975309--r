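# Evaluation metrics and the Amsterdam-Shroud trace pipeline.

mk_vol <- function(vals, g) volume(array(vals, g$dim), g)

test_that("relative error matches hand-computed values", {
  g <- volume_grid(c(4, 4, 4), 2)
  a <- mk_vol(runif(64), g)
  expect_equal(as.numeric(relative_error(list(a), list(a))), 0)
  b <- mk_vol(rep(1, 64), g)
  expect_equal(as.numeric(relative_error(list(mk_vol(rep(2, 64), g)), list(b))), 1)
  # per-frame ratios 0.1 and 0.3 average to 0.2
  f1 <- mk_vol(rep(1.1, 64), g); f2 <- mk_vol(rep(1.3, 64), g)
  expect_equal(as.numeric(relative_error(list(f1, f2), list(b, b))), 0.2,
               tolerance = 1e-12)
  expect_error(relative_error(list(a), list(mk_vol(rep(0, 64), g))),
               "all-zero")
  expect_error(relative_error(list(a), list(a, a)), "frame counts")
})

test_that("volumetric SSIM is 1 on identity and degrades under noise", {
  g <- volume_grid(c(12, 12, 12), 2)
  set.seed(20)
  b <- mk_vol(runif(12^3), g)
  expect_equal(ssim_volume(b, b), 1)
  noisy <- mk_vol(b$values + rnorm(12^3, sd = 0.5), g)
  expect_lt(ssim_volume(noisy, b), 0.9)
  expect_error(ssim_volume(b, mk_vol(b$values, volume_grid(c(12, 12, 12), 3))),
               "grid mismatch")
})

test_that("center-of-mass error equals analytic shifts of a sphere", {
  g <- volume_grid(c(20, 20, 20), 2)
  pts <- gaussCBCT:::grid_points(g)
  sph <- function(c0) array(rowSums(sweep(pts, 2, c0)^2) < 10^2, g$dim)
  a <- sph(c(0, 0, 0))
  expect_equal(come(a, a, g), 0)
  expect_equal(come(a, sph(c(0, 0, 2)), g), 2, tolerance = 1e-9)
  expect_equal(come(a, sph(c(4, 0, 0)), g), 4, tolerance = 1e-9)
  # translation equivariance
  expect_equal(come(sph(c(2, 2, 0)), sph(c(2, 2, 2)), g), 2, tolerance = 0.2)
  expect_error(come(a, a & FALSE, g), "empty mask")
})

test_that("dice matches hand counts", {
  g <- volume_grid(c(10, 10, 10), 1)
  a <- array(FALSE, c(10, 10, 10)); a[1:4, 1:4, 1:4] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, c(10, 10, 10)); b[1:4, 1:4, 3:6] <- TRUE  # half overlap
  expect_equal(dice(a, b), 0.5)
  c2 <- array(FALSE, c(10, 10, 10)); c2[7:9, 7:9, 7:9] <- TRUE
  expect_equal(dice(a, c2), 0)
  expect_warning(d0 <- dice(a & FALSE, a & FALSE), "empty")
  expect_equal(d0, 1)
})

test_that("contour propagation shifts a sphere with the field", {
  g <- volume_grid(c(20, 20, 20), 2)
  pts <- gaussCBCT:::grid_points(g)
  mask <- array(rowSums(pts^2) < 10^2, g$dim)
  d0 <- displacement_field(array(0, c(g$dim, 3)), g)
  expect_equal(propagate_contour(mask, d0), mask)
  # constant 4 mm SI shift: pull warp by +4 moves the object inferiorly
  dz <- displacement_field(array(rep(c(0, 0, 4), each = prod(g$dim)),
                                 c(g$dim, 3)), g)
  moved <- propagate_contour(mask, dz)
  expect_equal(gaussCBCT:::mask_com(moved, g) - gaussCBCT:::mask_com(mask, g),
               c(0, 0, -4), tolerance = 1)
  # volume approximately preserved under the (rigid) field
  expect_equal(sum(moved), sum(mask), tolerance = 0.1 * sum(mask))
})

test_that("AS image captures a moving horizontal edge", {
  # synthetic frames: intensity step at row r(t)
  n_v <- 40; n_u <- 24; np <- 30
  geom <- scan_geometry(1000, 1500, n_u, n_v, 2, 2,
                        (0:(np - 1)) * 12, (0:(np - 1)) * 0.5)
  r_t <- 20 + 6 * sin(2 * pi * (0:(np - 1)) / 15)
  frames <- array(0, c(n_v, n_u, np))
  for (k in 1:np) {
    frames[, , k] <- matrix(rep(pmin(pmax(seq_len(n_v) - r_t[k], 0), 1),
                                n_u), n_v, n_u)
  }
  pset <- projection_set(frames, geom)
  # constant frames give an all-zero AS image
  p0 <- projection_set(frames * 0 + 1, geom)
  expect_equal(max(abs(as_image(p0, 1:n_u))), 0)
  img <- as_image(pset)
  expect_equal(dim(img), c(n_v - 1, np))
  # column extrema follow the edge
  peaks <- apply(abs(img), 2, which.max)
  expect_lt(max(abs(peaks - floor(r_t))), 1.5)
  # a band of width 1 equals the single-column gradient profile
  img1 <- as_image(pset, 5)
  expect_equal(as.numeric(img1),
               as.numeric(frames[-1, 5, ] - frames[-n_v, 5, ]))
  expect_error(as_image(pset, 100:110), "outside")
  # trace extraction: subpixel recovery and isocenter scaling
  tr <- extract_trace(img, geom)
  amp_rows <- (max(attr(tr, "rows")) - min(attr(tr, "rows")))
  expect_equal(amp_rows, 12, tolerance = 0.5)
  amp_iso <- max(tr) - min(tr)
  expect_equal(amp_iso, 12 * 2 * 1000 / 1500, tolerance = 1)
})

test_that("localization error and Pearson handle the sign gauge", {
  t <- seq(0, 10, by = 0.5)
  ref <- 5 * sin(t)
  tp <- trace_pair(t, ref, ref)
  le <- localization_error(tp)
  expect_equal(le$mean, 0)
  expect_equal(le$sd, 0)
  expect_equal(trace_pearson(tp), 1)
  # constant offset: LE mean 1, r = 1
  tp2 <- trace_pair(t, ref + 1, ref)
  le2 <- localization_error(tp2)
  expect_equal(le2$mean, 1)
  expect_equal(trace_pearson(tp2), 1)
  # inverted trace: gauge flip recovers r = 1 and reports the flip
  tp3 <- trace_pair(t, -ref, ref)
  expect_equal(trace_pearson(tp3), 1)
  expect_message(le3 <- localization_error(tp3), "flip")
  expect_true(le3$flipped)
  expect_error(trace_pair(t, ref[-1], ref), "length mismatch")
})

test_that("AS round trip on a simulated scan recovers the breathing trace", {
  st <- tiny_phantom_setup("S1", n_proj = 44, dim = c(40, 40, 20), spacing = 5,
                           detector = c(48, 40), pixel = 6,
                           keep = character(0))
  img <- as_image(st$sim$projections)
  tr <- extract_trace(img, st$geom)
  tp <- trace_pair(st$trace$times, tr - mean(tr),
                   st$trace$values - mean(st$trace$values))
  expect_gt(abs(trace_pearson(tp)), 0.9)
  # amplitude recovered at isocenter scale within ~1 voxel equivalent
  le <- localization_error(tp)
  expect_lt(le$mean, 5)
})
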