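# The radiative Gaussian representation: kernel sets, voxelization,
# splatting-based x-ray rasterization, initialization from a seed volume,
# and adaptive density control (prune / clone / split).

#' Set of 3D Gaussian kernels
#'
#' Each kernel contributes `rho * exp(-1/2 (x-p)' Sigma^-1 (x-p))` to the
#' represented scalar field, with `Sigma = R(q) diag(s^2) R(q)'` guaranteed
#' symmetric positive definite by the scale/quaternion parameterization.
#'
#' @param positions M x 3 matrix of kernel centers (mm).
#' @param densities Length-M vector of central densities (per-mm attenuation
#'   amplitude). Signed values are allowed; non-negativity for physical
#'   attenuation fields is enforced by the optimizer, not the container.
#'   For motion-basis sets an M x 3 matrix (one channel per Cartesian
#'   direction) is accepted.
#' @param scales M x 3 matrix of axis standard deviations (mm, > 0).
#' @param quaternions M x 4 matrix of (not necessarily unit) quaternions
#'   `(w, x, y, z)`; normalized internally.
#' @return An object of class `gaussian_set`.
#' @export
gaussian_set <- function(positions, densities, scales, quaternions = NULL) {
  positions <- as.matrix(positions)
  M <- nrow(positions)
  if (ncol(positions) != 3) stop("gaussian_set: positions must be M x 3")
  densities <- if (is.matrix(densities)) densities else as.numeric(densities)
  nd <- if (is.matrix(densities)) nrow(densities) else length(densities)
  if (nd != M) stop("gaussian_set: densities length must match positions")
  scales <- as.matrix(scales)
  if (!all(dim(scales) == c(M, 3))) stop("gaussian_set: scales must be M x 3")
  if (M > 0 && any(scales <= 0)) stop("gaussian_set: scales must be > 0")
  if (is.null(quaternions)) {
    quaternions <- cbind(rep(1, M), matrix(0, M, 3))
  }
  quaternions <- as.matrix(quaternions)
  if (!all(dim(quaternions) == c(M, 4))) stop("gaussian_set: quaternions must be M x 4")
  structure(list(positions = positions, densities = densities,
                 scales = scales, quaternions = quaternions,
                 count = M),
            class = "gaussian_set")
}

#' @export
print.gaussian_set <- function(x, ...) {
  cat(sprintf("gaussian_set: %d kernels, density range [%.4g, %.4g], scales [%.3g, %.3g] mm\n",
              x$count, if (x$count) min(x$densities) else NA,
              if (x$count) max(x$densities) else NA,
              if (x$count) min(x$scales) else NA,
              if (x$count) max(x$scales) else NA))
  invisible(x)
}

# scale bounds shared by optimizer projections and adaptive control
SCALE_MIN <- 0.1
SCALE_MAX <- 100

# Pointwise truncation of each kernel at this Mahalanobis radius keeps the
# dropped tail below 1e-3 of the central density (exp(-3.8^2/2) = 7.3e-4).
TRUNC_RADIUS <- 3.8

#' Voxelize a Gaussian set onto a regular grid
#'
#' Evaluates the kernel-sum field at every voxel center. Kernels are truncated
#' at Mahalanobis radius 3.8 (pointwise error below `1e-3 * |rho|`).
#'
#' @param gset A [gaussian_set()] (single-channel densities).
#' @param grid A [volume_grid()].
#' @param allow_negative If `FALSE` (the physical-attenuation default),
#'   negative voxel sums are clamped to 0. Motion-basis fields use the
#'   negative-permitting variant (`TRUE`).
#' @return A [volume()].
#' @export
voxelize <- function(gset, grid, allow_negative = FALSE) {
  stopifnot(inherits(gset, "gaussian_set"), inherits(grid, "volume_grid"))
  if (is.matrix(gset$densities)) {
    stop("voxelize: multi-channel densities; voxelize each channel separately")
  }
  if (gset$count == 0) {
    return(volume(array(0, grid$dim), grid))
  }
  vals <- cpp_voxelize(gset$positions, gset$densities, gset$scales,
                       gset$quaternions, grid$dim, grid$spacing, grid$origin,
                       allow_negative, TRUNC_RADIUS)
  volume(vals, grid)
}

# Gradient of sum(upstream * voxelize(gset)) w.r.t. kernel parameters.
voxelize_backward <- function(gset, grid, upstream, allow_negative = FALSE) {
  cpp_voxelize_backward(gset$positions, gset$densities, gset$scales,
                        gset$quaternions, grid$dim, grid$spacing, grid$origin,
                        allow_negative, TRUNC_RADIUS, as.numeric(upstream))
}

#' Rasterize a Gaussian set into an x-ray projection by splatting
#'
#' Each 3D kernel is mapped to ray space by the view transform and a local
#' affine approximation of the perspective mapping, marginalized along the
#' ray coordinate to a 2D Gaussian on the detector with amplitude
#' `rho * sqrt(2*pi*det(Sigma_tilde)/det(Sigma_hat))`, and accumulated at
#' detector pixel centers within its truncation footprint.
#'
#' @param gset A [gaussian_set()].
#' @param geometry A [scan_geometry()].
#' @param angle_index Which projection (1-based) to render.
#' @return A `splat_frame`: list with `image` (n_v x n_u), per-kernel
#'   projected means `phat` (detector mm), projected covariances `shat`
#'   (columns s_uu, s_uv, s_vv), amplitudes `amp`, and `valid` flags
#'   (kernels behind the source or with degenerate projected covariance are
#'   skipped).
#' @export
splat_project <- function(gset, geometry, angle_index) {
  vf <- view_frame(geometry, angle_index)
  ax <- detector_axes(geometry)
  res <- cpp_splat_project(gset$positions, gset$densities, gset$scales,
                           gset$quaternions, vf$o, vf$eu, vf$ev, vf$ew,
                           geometry$sdd, ax$u, ax$v, TRUNC_RADIUS)
  if (res$skipped > 0) {
    warning("splat_project: skipped ", res$skipped,
            " kernel(s) behind the source or with degenerate projected covariance")
  }
  structure(res, class = "splat_frame")
}

splat_backward <- function(gset, geometry, angle_index, upstream) {
  vf <- view_frame(geometry, angle_index)
  ax <- detector_axes(geometry)
  cpp_splat_backward(gset$positions, gset$densities, gset$scales,
                     gset$quaternions, vf$o, vf$eu, vf$ev, vf$ew,
                     geometry$sdd, ax$u, ax$v, TRUNC_RADIUS, upstream)
}

#' Initialize a Gaussian set from a seed volume
#'
#' `scheme = "grid"` samples about `M` points on a regular lattice covering
#' the grid, keeps those whose sampled intensity reaches `density_floor`
#' (dropping air), and assigns the sampled intensity as the kernel density.
#' `scheme = "uniform"` keeps the full lattice with zero densities (used for
#' motion-basis sets). Initial scales are isotropic at the lattice pitch;
#' rotations start at identity.
#'
#' @param vol A [volume()] (e.g. a motion-averaged FDK reconstruction).
#' @param M Target number of lattice points (>= 1, at most the voxel count).
#' @param scheme `"grid"` or `"uniform"`.
#' @param density_floor Minimum sampled intensity for `"grid"` sampling.
#' @param scale_factor Initial scale as a multiple of the lattice pitch.
#' @return A [gaussian_set()].
#' @export
init_from_volume <- function(vol, M, scheme = c("grid", "uniform"),
                             density_floor = 1e-4, scale_factor = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(vol, "volume"))
  if (M < 1) stop("init_from_volume: M must be >= 1")
  if (M > prod(vol$grid$dim)) {
    stop("init_from_volume: M (", M, ") exceeds voxel count (",
         prod(vol$grid$dim), ")")
  }
  g <- vol$grid
  extent <- g$dim * g$spacing
  # lattice with approximately M points, pitch proportional per axis
  pitch <- (prod(extent) / M)^(1 / 3)
  n_ax <- pmax(1L, as.integer(round(extent / pitch)))
  axes <- lapply(1:3, function(a) {
    k <- n_ax[a]
    g$origin[a] - g$spacing[a] / 2 + (seq_len(k) - 0.5) * extent[a] / k
  })
  pts <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  dimnames(pts) <- NULL
  vals <- apply_dvf_sample(vol, pts)
  mean_pitch <- mean(extent / n_ax)
  if (scheme == "grid") {
    keep <- vals >= density_floor
    pts <- pts[keep, , drop = FALSE]
    vals <- vals[keep]
    # overlap gain of a dense lattice of isotropic kernels: the voxelized
    # field sums to ~ (2*pi)^{3/2} sigma^3 / cell_volume times the density,
    # so divide to make the voxelized set match the seed volume intensity
    gain <- (2 * pi)^1.5 * (scale_factor * mean_pitch)^3 / prod(extent / n_ax)
    vals <- vals / gain
  } else {
    vals <- rep(0, nrow(pts))
  }
  Mk <- nrow(pts)
  gaussian_set(pts, vals,
               matrix(scale_factor * mean_pitch, Mk, 3),
               cbind(rep(1, Mk), matrix(0, Mk, 3)))
}

# trilinear point sampling of a volume at world coordinates (n x 3)
apply_dvf_sample <- function(vol, pts) {
  g <- vol$grid
  f <- sweep(sweep(pts, 2, g$origin, "-"), 2, g$spacing, "/")
  f <- pmin(pmax(f, 0), matrix(rep(g$dim - 1, each = nrow(pts)), ncol = 3))
  i0 <- pmin(floor(f), matrix(rep(pmax(g$dim - 2, 0), each = nrow(pts)), ncol = 3))
  w <- f - i0
  acc <- numeric(nrow(pts))
  for (c in 0:7) {
    dx <- bitwAnd(c, 1L); dy <- bitwAnd(bitwShiftR(c, 1L), 1L)
    dz <- bitwAnd(bitwShiftR(c, 2L), 1L)
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ix <- pmin(i0[, 1] + dx, g$dim[1] - 1)
    iy <- pmin(i0[, 2] + dy, g$dim[2] - 1)
    iz <- pmin(i0[, 3] + dz, g$dim[3] - 1)
    acc <- acc + wt * vol$values[cbind(ix + 1, iy + 1, iz + 1)]
  }
  acc
}

#' Adaptive density control: prune, clone, split
#'
#' Kernels with `|rho| < prune_eps` are removed. Kernels whose accumulated
#' positional gradient exceeds `grad_thresh` are densified: small kernels
#' (max scale below `size_thresh`) are cloned with the copy offset by one
#' gradient step; large kernels are split into two kernels with scales
#' divided by 1.6 placed at +-0.5 sigma along the largest principal axis.
#' In both cases the densities of parent and child are halved, preserving the
#' summed amplitude. Gradient statistics are reset by the caller.
#'
#' @param gset A [gaussian_set()] (single-channel densities).
#' @param grad_accum Length-M vector: mean positional-gradient norm per kernel.
#' @param cfg List with `prune_eps`, `grad_thresh`, `size_thresh` (mm) and
#'   `clone_step` (mm offset applied along the accumulated gradient
#'   direction); see [adaptive_control_config()].
#' @param grad_dir Optional M x 3 matrix of mean positional gradients (used
#'   for the clone offset direction; zero rows fall back to no offset).
#' @return A new [gaussian_set()].
#' @export
adaptive_control <- function(gset, grad_accum, cfg = adaptive_control_config(),
                             grad_dir = NULL) {
  stopifnot(length(grad_accum) == gset$count)
  keep <- abs(gset$densities) >= cfg$prune_eps
  dens <- grad_accum > cfg$grad_thresh & keep
  pos <- gset$positions; rho <- gset$densities
  sc <- gset$scales; qu <- gset$quaternions
  new_pos <- NULL; new_rho <- NULL; new_sc <- NULL; new_qu <- NULL
  if (any(dens)) {
    for (i in which(dens)) {
      if (max(sc[i, ]) < cfg$size_thresh) {
        # clone: copy offset by one gradient step
        off <- c(0, 0, 0)
        if (!is.null(grad_dir)) {
          gnorm <- sqrt(sum(grad_dir[i, ]^2))
          if (gnorm > 0) off <- -cfg$clone_step * grad_dir[i, ] / gnorm
        }
        rho[i] <- rho[i] / 2
        new_pos <- rbind(new_pos, pos[i, ] + off)
        new_rho <- c(new_rho, rho[i])
        new_sc <- rbind(new_sc, sc[i, ])
        new_qu <- rbind(new_qu, qu[i, ])
      } else {
        # split along the largest principal axis of Sigma
        k <- which.max(sc[i, ])  # ties: lowest axis index (which.max contract)
        R <- quat_rotation(qu[i, ])
        axis <- R[, k]
        offset <- 0.5 * sc[i, k] * axis
        rho[i] <- rho[i] / 2
        sc_new <- pmax(sc[i, ] / 1.6, SCALE_MIN)
        sc[i, ] <- sc_new
        old <- pos[i, ]
        pos[i, ] <- old + offset
        new_pos <- rbind(new_pos, old - offset)
        new_rho <- c(new_rho, rho[i])
        new_sc <- rbind(new_sc, sc_new)
        new_qu <- rbind(new_qu, qu[i, ])
      }
    }
  }
  pos <- rbind(pos[keep, , drop = FALSE], new_pos)
  rho <- c(rho[keep], new_rho)
  sc <- rbind(sc[keep, , drop = FALSE], new_sc)
  qu <- rbind(qu[keep, , drop = FALSE], new_qu)
  gaussian_set(pos, rho, sc, qu)
}

#' Defaults for adaptive density control
#'
#' @param prune_eps Kernels with smaller `|rho|` are removed.
#' @param grad_thresh Accumulated positional-gradient norm triggering
#'   densification.
#' @param size_thresh Max-scale boundary (mm) between cloning and splitting.
#' @param clone_step Offset (mm) of the cloned copy along the gradient.
#' @return A named list.
#' @export
adaptive_control_config <- function(prune_eps = 1e-4, grad_thresh = 2e-5,
                                    size_thresh = 8, clone_step = 0.5) {
  list(prune_eps = prune_eps, grad_thresh = grad_thresh,
       size_thresh = size_thresh, clone_step = clone_step)
}

# rotation matrix from quaternion (w,x,y,z), R columns = principal axes
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Analytic total integral of a Gaussian set
#'
#' `sum_i rho_i (2*pi)^{3/2} sqrt(det Sigma_i)`; useful as a conservation
#' check against the voxelized field.
#'
#' @param gset A [gaussian_set()].
#' @return Scalar integral (value units x mm^3).
#' @export
gaussian_total_integral <- function(gset) {
  if (gset$count == 0) return(0)
  sum(gset$densities * (2 * pi)^1.5 * apply(gset$scales, 1, prod))
}
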