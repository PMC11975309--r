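# Containers, geometry validation, trajectory sampling, and file round trips.

test_that("scan_geometry enforces its invariants", {
  expect_error(scan_geometry(1500, 1000, 4, 4, 1, 1, 0, 0), "sdd > sad")
  expect_error(scan_geometry(1000, 1500, 4, 4, 1, 1, c(0, 1), 0), "equal length")
  expect_error(scan_geometry(1000, 1500, 4, 4, 1, 1, c(0, 1), c(1, 0)),
               "strictly increasing")
  expect_error(scan_geometry(1000, 1500, 4, 4, 1, 1, 0, 0,
                             detector_offset_u = 10), "full-fan")
  g <- scan_geometry(1000, 1500, 4, 4, 1, 1, 0, 0)
  expect_s3_class(g, "scan_geometry")
  gh <- scan_geometry(1000, 1500, 4, 4, 1, 1, 0, 0, fan_mode = "half",
                      detector_offset_u = 100)
  expect_equal(gh$detector_offset_u, 100)
})

test_that("volume and displacement containers validate shape and finiteness", {
  g <- volume_grid(c(2, 3, 4), c(1, 1, 3))
  expect_error(volume(array(0, c(2, 3, 5)), g), "do not match")
  expect_error(volume(array(NaN, c(2, 3, 4)), g), "finite")
  v <- volume(array(1, c(2, 3, 4)), g)
  expect_equal(sum(v$values), 24)
  expect_error(displacement_field(array(0, c(2, 3, 4, 2)), g), "nx x ny x nz x 3")
  d <- displacement_field(array(0, c(2, 3, 4, 3)), g)
  expect_s3_class(d, "displacement_field")
  # voxel-center mapping: default origin centers the grid on the isocenter
  expect_equal(grid_axis(volume_grid(c(5, 5, 5), 2), 1), c(-4, -2, 0, 2, 4))
})

test_that("projection_set validates frame/angle agreement", {
  g <- tiny_geometry(n_proj = 5, n_u = 6, n_v = 4)
  expect_error(projection_set(array(0, c(4, 6, 4)), g), "frame count")
  expect_error(projection_set(array(0, c(6, 4, 5)), g), "frame size")
  p <- projection_set(array(0, c(4, 6, 5)), g)
  expect_s3_class(p, "projection_set")
})

test_that("make_circular_trajectory samples uniformly in time", {
  tj <- make_circular_trajectory(0, 360, 60, 11)
  expect_length(tj$angles, 660)
  expect_lt(max(tj$angles), 360)
  expect_equal(diff(tj$times), rep(1 / 11, 659))
  expect_equal(make_circular_trajectory(0, 360, 1, 1)$angles, 0)
  tj2 <- make_circular_trajectory(0, 200, 300, 5.5)
  expect_length(tj2$angles, 1650)
  expect_equal(max(tj2$angles) - min(tj2$angles), 200 * (1649 / 1650))
  expect_error(make_circular_trajectory(0, -10, 60, 11), "must be > 0")
})

test_that("volume round trips are lossless (.mha and .nii.gz)", {
  g <- volume_grid(c(5, 4, 3), c(1, 1, 3), origin = c(-2, 0, 1.5))
  set.seed(7)
  v <- volume(array(round(runif(60) * 100), c(5, 4, 3)), g)
  for (ext in c(".mha", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_volume(v, path)
    v2 <- read_volume(path)
    expect_identical(v2$values, v$values)
    expect_equal(v2$grid$spacing, g$spacing)
    expect_equal(v2$grid$origin, g$origin)
    unlink(path)
  }
  # 2x2x2 of ones with 2 mm spacing
  path <- tempfile(fileext = ".mha")
  write_volume(volume(array(1, c(2, 2, 2)), volume_grid(c(2, 2, 2), 2)), path)
  v3 <- read_volume(path)
  expect_equal(sum(v3$values), 8)
  expect_equal(v3$grid$spacing, c(2, 2, 2))
  unlink(path)
})

test_that("volume I/O rejects bad input", {
  expect_error(read_volume(tempfile(fileext = ".mha")), "not found")
  empty <- tempfile(fileext = ".mha")
  file.create(empty)
  expect_error(read_volume(empty), "empty file|corrupt")
  unlink(empty)
  bad <- tempfile(fileext = ".xyz")
  file.create(bad)
  expect_error(read_volume(bad), "unsupported.*xyz|unsupported")
  unlink(bad)
  g <- volume_grid(c(2, 2, 2), 1)
  v <- volume(array(1, c(2, 2, 2)), g)
  v$values[1] <- NaN  # bypass constructor validation
  expect_error(write_volume(v, tempfile(fileext = ".mha")), "non-finite")
  expect_error(write_volume(volume(array(1, c(2, 2, 2)), g), "out.xyz"),
               "unsupported")
})

test_that("projection round trip preserves frames, angles and times", {
  g <- tiny_geometry(n_proj = 3, n_u = 8, n_v = 6)
  set.seed(1)
  frames <- array(runif(8 * 6 * 3) * 7 - 1, c(6, 8, 3))
  p <- projection_set(frames, g)
  path <- tempfile(fileext = ".tif")
  write_projections(p, path)
  p2 <- read_projections(path)
  expect_lt(max(abs(p2$frames - frames)), 1e-8)
  expect_equal(p2$geometry$angles, g$angles)
  expect_equal(p2$geometry$times, g$times)
  expect_equal(p2$geometry$sad, g$sad)
  unlink(c(path, paste0(path, ".json")))
})

test_that("projection reads cross-check the sidecar geometry", {
  g <- tiny_geometry(n_proj = 3, n_u = 8, n_v = 6)
  p <- projection_set(array(0.5, c(6, 8, 3)), g)
  path <- tempfile(fileext = ".tif")
  write_projections(p, path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sc$angles <- c(sc$angles, 99)  # 4 angles, 3 frames
  sc$times <- c(sc$times, 99)
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_projections(path), "frame count")
  sc$angles <- sc$angles[1:3]
  sc$times <- c(0, 0, 1)  # not strictly increasing
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_projections(path), "strictly increasing")
  unlink(c(path, paste0(path, ".json")))
})

test_that("gaussian set and trace serialization round-trip", {
  gs <- random_gaussians(5)
  path <- tempfile(fileext = ".rds")
  write_gaussian_set(gs, path)
  gs2 <- read_gaussian_set(path)
  expect_equal(gs2$positions, gs$positions)
  expect_equal(gs2$densities, gs$densities)
  unlink(path)
  tr <- make_trace("S1", 10, 5, seed = 3)
  pcsv <- tempfile(fileext = ".csv")
  write_trace(tr, pcsv)
  tr2 <- read_trace(pcsv, "S1")
  expect_equal(tr2$values, tr$values, tolerance = 1e-12)
  unlink(pcsv)
})

test_that("all modules agree on world coordinates of a point object", {
  # a bright point at a known world position must be located identically by
  # the voxelizer, the projector and the phantom machinery
  pos <- c(6, -4, 2)
  g <- volume_grid(c(13, 13, 9), 2)
  gs <- gaussian_set(matrix(pos, 1, 3), 1, matrix(0.8, 1, 3))
  v <- voxelize(gs, g)
  peak <- which(v$values == max(v$values), arr.ind = TRUE)[1, ]
  ax <- lapply(1:3, function(a) grid_axis(g, a))
  expect_equal(c(ax[[1]][peak[1]], ax[[2]][peak[2]], ax[[3]][peak[3]]), pos)
  # projector: central column of the point's projection at angle 0 must be
  # at detector u = pos_x * sdd / (sad + pos_y)
  geom <- tiny_geometry(n_proj = 1, n_u = 41, n_v = 41, pixel = 1)
  fr <- forward_project(v, geom, 1)
  idx <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  axd <- gaussCBCT:::detector_axes(geom)
  expect_equal(axd$u[idx[2]], pos[1] * geom$sdd / (geom$sad + pos[2]),
               tolerance = 0.7)
  expect_equal(axd$v[idx[1]], pos[3] * geom$sdd / (geom$sad + pos[2]),
               tolerance = 0.7)
})
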