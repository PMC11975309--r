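# Shared fixtures, built in code.

# small full-fan geometry; detector pixels 5 mm (3.33 mm at isocenter)
tiny_geometry <- function(n_proj = 8, n_u = 24, n_v = 20, arc = 360,
                          sad = 1000, sdd = 1500, pixel = 5) {
  angles <- (seq_len(n_proj) - 1) * arc / n_proj
  scan_geometry(sad, sdd, n_u, n_v, pixel, pixel, angles,
                times = (seq_len(n_proj) - 1) * 0.5)
}

# random anisotropic rotated kernels inside a box
random_gaussians <- function(M, seed = 1, extent = 12, rho_range = c(-1, 2),
                             scale_range = c(1.5, 4)) {
  set.seed(seed)
  gaussian_set(matrix(runif(M * 3, -extent, extent), M, 3),
               runif(M, rho_range[1], rho_range[2]),
               matrix(runif(M * 3, scale_range[1], scale_range[2]), M, 3),
               matrix(rnorm(M * 4), M, 4))
}

# reference rotation matrix from quaternion (independent of the C++ path)
rot_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# brute-force evaluation of the kernel sum at every voxel center (no
# truncation): the independent oracle for the voxelizer
voxelize_oracle <- function(gset, grid, allow_negative = TRUE) {
  out <- array(0, grid$dim)
  ax <- lapply(1:3, function(a) grid_axis(grid, a))
  for (i in seq_len(gset$count)) {
    R <- rot_from_quat(gset$quaternions[i, ])
    S <- R %*% diag(gset$scales[i, ]^2) %*% t(R)
    Q <- solve(S)
    for (iz in seq_len(grid$dim[3])) for (iy in seq_len(grid$dim[2])) {
      d2 <- c(ax[[2]][iy], ax[[3]][iz]) - gset$positions[i, 2:3]
      for (ix in seq_len(grid$dim[1])) {
        d <- c(ax[[1]][ix] - gset$positions[i, 1], d2)
        out[ix, iy, iz] <- out[ix, iy, iz] +
          gset$densities[i] * exp(-0.5 * sum(d * (Q %*% d)))
      }
    }
  }
  if (!allow_negative) out[out < 0] <- 0
  out
}

# fine-step numeric integral of the kernel-sum density along the ray to one
# detector pixel: the independent oracle for the splatting rasterizer
ray_integral_oracle <- function(gset, geometry, angle_index, iu, iv,
                                step = 0.05, t_range = NULL) {
  vf <- gaussCBCT:::view_frame(geometry, angle_index)
  ax <- gaussCBCT:::detector_axes(geometry)
  pix <- vf$o + geometry$sdd * vf$ew + ax$u[iu] * vf$eu + ax$v[iv] * vf$ev
  dir <- (pix - vf$o) / sqrt(sum((pix - vf$o)^2))
  if (is.null(t_range)) t_range <- c(geometry$sad - 80, geometry$sad + 80)
  ts <- seq(t_range[1], t_range[2], by = step)
  total <- 0
  for (i in seq_len(gset$count)) {
    R <- rot_from_quat(gset$quaternions[i, ])
    S <- R %*% diag(gset$scales[i, ]^2) %*% t(R)
    Q <- solve(S)
    pdiff <- sweep(outer(ts, dir), 2, vf$o - gset$positions[i, ], "+")
    m2 <- rowSums((pdiff %*% Q) * pdiff)
    total <- total + gset$densities[i] * sum(exp(-0.5 * m2)) * step
  }
  total
}

# small ball-in-box attenuation volume
ball_volume <- function(dim = c(24, 24, 16), spacing = 4, radius = 30,
                        mu = 0.02, flatten_z = 0.7) {
  g <- volume_grid(dim, spacing)
  ax <- lapply(1:3, function(a) grid_axis(g, a))
  vals <- array(0, dim)
  for (iz in seq_len(dim[3])) for (iy in seq_len(dim[2])) {
    r2yz <- ax[[2]][iy]^2 + (ax[[3]][iz] / flatten_z)^2
    vals[, iy, iz] <- mu * (ax[[1]]^2 + r2yz < radius^2)
  }
  volume(vals, g)
}

# tiny phantom + scan used by the heavier end-to-end tests
tiny_phantom_setup <- function(scenario = "S5", n_proj = 60, seed = 0,
                               dim = c(40, 40, 20), spacing = 5,
                               detector = c(64, 48), pixel = 5,
                               keep = c("volume", "mask")) {
  grid <- volume_grid(dim, spacing)
  sp <- phantom_spec(grid)
  traj <- make_circular_trajectory(0, 360, 60, n_proj / 60)
  geom <- scan_geometry(1000, 1500, detector[1], detector[2], pixel, pixel,
                        traj$angles, traj$times)
  tr <- make_trace(scenario, 60, n_proj / 60, seed)
  sim <- simulate_scan(sp, tr, geom, keep = keep)
  list(spec = sp, grid = grid, geom = geom, trace = tr, sim = sim)
}
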