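# Three-stage optimization. Stage 1 fits the reference-frame Gaussians to
# all projections through the splatting rasterizer (motion ignored). Stages
# 2 and 3 jointly fit the reference Gaussians, the MBC Gaussians and the
# convolutional motion encoder through the voxelize -> warp -> project
# pipeline, coarse (half-resolution) then fine. All parameters are updated
# with Adam; every random choice flows from the stage seed.

#' Loss weights
#'
#' @param lambda_ssim D-SSIM weight in the projection loss (default 0.25).
#' @param lambda_tv Total-variation weight (default 0.05).
#' @param lambda_mbc Normality-loss weight (default 1).
#' @param tv_D Edge length of the random TV subvolume (default 32 voxels).
#' @return A named list.
#' @export
loss_weights <- function(lambda_ssim = 0.25, lambda_tv = 0.05,
                         lambda_mbc = 1, tv_D = 32) {
  stopifnot(lambda_ssim >= 0, lambda_tv >= 0, lambda_mbc >= 0, tv_D >= 2)
  list(lambda_ssim = lambda_ssim, lambda_tv = lambda_tv,
       lambda_mbc = lambda_mbc, tv_D = tv_D)
}

#' Stage schedule
#'
#' @param stage1_epochs,stage2_epochs,stage3_epochs Optimizer steps per
#'   stage (defaults 5000 / 1000 / 1000; half-fan scans get 2000 in
#'   stage 2).
#' @param batch2,batch3 Projections per step in stages 2 and 3 (32 / 8).
#' @return A named list. Stage 1 uses batch size 1 (the rasterizer renders
#'   one projection per step); stage 2 voxelizes at half the output
#'   resolution, stages 1 and 3 at full resolution.
#' @export
stage_schedule <- function(stage1_epochs = 5000, stage2_epochs = 1000,
                           stage3_epochs = 1000, batch2 = 32, batch3 = 8) {
  stopifnot(stage1_epochs > 0, stage2_epochs > 0, stage3_epochs > 0,
            batch2 >= 1, batch3 >= 1)
  list(stage1_epochs = stage1_epochs, stage2_epochs = stage2_epochs,
       stage3_epochs = stage3_epochs, batch2 = batch2, batch3 = batch3)
}

#' Training learning rates
#'
#' Position steps scale with the scene extent, density steps with the
#' initialization intensity, and scale steps with the initial kernel pitch,
#' so the defaults transfer across problem sizes.
#'
#' @param positions,densities,scales,rotations Reference-kernel rates
#'   (relative; see Details).
#' @param mbc Rate for MBC channel densities (absolute, bases are
#'   order-one after normality regularization).
#' @param mbc_geometry Rate multiplier for MBC kernel positions/scales
#'   (fraction of the reference rates); 0 freezes MBC kernel geometry.
#' @param encoder Encoder rate.
#' @return A named list.
#' @export
learning_rates <- function(positions = 2e-4, densities = 5e-2, scales = 5e-3,
                           rotations = 1e-3, mbc = 1e-2, mbc_geometry = 0.1,
                           encoder = 1e-3) {
  list(positions = positions, densities = densities, scales = scales,
       rotations = rotations, mbc = mbc, mbc_geometry = mbc_geometry,
       encoder = encoder)
}

#' D-SSIM loss between two images
#'
#' `(1 - SSIM(a, b)) / 2` with an 11 x 11 Gaussian window (sigma 1.5) and
#' the dynamic range taken from the observed range of `b`.
#'
#' @param a,b Matrices of equal shape.
#' @return Scalar in `[0, 1]`; 0 iff the images are identical.
#' @export
dssim_loss <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dssim_loss: shape mismatch")
  drange <- diff(range(b))
  if (drange <= 0) drange <- 1
  (1 - cpp_ssim2d(a, b, drange, FALSE)$mssim) / 2
}

# D-SSIM value and gradient w.r.t. a
dssim_grad <- function(a, b) {
  drange <- diff(range(b))
  if (drange <= 0) drange <- 1
  r <- cpp_ssim2d(a, b, drange, TRUE)
  list(loss = (1 - r$mssim) / 2, grad = -r$grad_mssim_a / 2)
}

#' Mean anisotropic total variation of a subvolume
#'
#' Mean absolute forward difference per axis, averaged over the three axes;
#' 0 for constant volumes, homogeneous of degree 1.
#'
#' @param subvol 3D array (typically a random cubic subvolume of the
#'   voxelized reference).
#' @return Non-negative scalar.
#' @export
tv_loss <- function(subvol) {
  d <- dim(subvol)
  dx <- subvol[-1, , , drop = FALSE] - subvol[-d[1], , , drop = FALSE]
  dy <- subvol[, -1, , drop = FALSE] - subvol[, -d[2], , drop = FALSE]
  dz <- subvol[, , -1, drop = FALSE] - subvol[, , -d[3], drop = FALSE]
  (mean(abs(dx)) + mean(abs(dy)) + mean(abs(dz))) / 3
}

tv_grad <- function(subvol) {
  d <- dim(subvol)
  g <- array(0, d)
  s <- sign(subvol[-1, , , drop = FALSE] - subvol[-d[1], , , drop = FALSE])
  g[-1, , ] <- g[-1, , ] + s / length(s)
  g[-d[1], , ] <- g[-d[1], , ] - s / length(s)
  s <- sign(subvol[, -1, , drop = FALSE] - subvol[, -d[2], , drop = FALSE])
  g[, -1, ] <- g[, -1, ] + s / length(s)
  g[, -d[2], ] <- g[, -d[2], ] - s / length(s)
  s <- sign(subvol[, , -1, drop = FALSE] - subvol[, , -d[3], drop = FALSE])
  g[, , -1] <- g[, , -1] + s / length(s)
  g[, , -d[3]] <- g[, , -d[3]] - s / length(s)
  g / 3
}

# ---- Adam ----------------------------------------------------------------

adam_new <- function() list(t = 0, m = list(), v = list())

adam_step <- function(state, params, grads, lrs, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, lr_scale = 1) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] -
      lr_scale * lrs[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# Cosine learning-rate decay over a stage (to 5% of the initial rate):
# stochastic-gradient noise scales with the step size, so annealing it
# settles the fine alignment that fixed-rate Adam leaves oscillating.
cosine_lr <- function(ep, epochs, floor = 0.05) {
  floor + (1 - floor) * 0.5 * (1 + cos(pi * (ep - 1) / max(epochs - 1, 1)))
}

# random D^3 subgrid of `grid` (uniform corner), clipped to the grid
tv_subgrid <- function(grid, D) {
  D <- pmin(D, grid$dim)
  corner <- vapply(1:3, function(a) sample.int(grid$dim[a] - D[if (length(D) > 1) a else 1] + 1, 1) - 1L,
                   0L)
  Dv <- rep_len(D, 3)
  volume_grid(Dv, grid$spacing, grid$origin + corner * grid$spacing)
}

# half-resolution companion of a grid covering the same physical extent
half_grid <- function(grid) {
  dim2 <- pmax(2L, as.integer(ceiling(grid$dim / 2)))
  volume_grid(dim2, grid$spacing * 2, grid$origin + grid$spacing / 2)
}

# ---- Stage 1 --------------------------------------------------------------

#' Stage 1: fit the reference Gaussians by splatting
#'
#' One optimizer step per epoch: render one random projection through the
#' splatting rasterizer, compare with the measured projection (L1 +
#' `lambda_ssim` D-SSIM), add `lambda_tv` times the TV of a random
#' voxelized subvolume, and update density, position, scale and rotation of
#' every kernel with Adam (densities projected to be non-negative after
#' each step). Adaptive density control runs on its cadence.
#'
#' @param pset A [projection_set()].
#' @param gset Initial [gaussian_set()] (from [init_from_volume()]).
#' @param weights A [loss_weights()].
#' @param epochs Number of optimizer steps.
#' @param seed Integer seed (projection sampling, TV subvolume placement).
#' @param lr A [learning_rates()].
#' @param tv_grid Grid on which TV subvolumes are voxelized (the output
#'   grid).
#' @param acfg [adaptive_control_config()] or `NULL` to disable
#'   densification/pruning.
#' @param densify_from,densify_until,densify_every Adaptive-control cadence
#'   in epochs.
#' @param verbose Print running loss every 200 epochs.
#' @return List with `gset` (fitted set) and `log` (per-epoch data frame).
#' @export
stage1_fit <- function(pset, gset, weights = loss_weights(), epochs = 5000,
                       seed = 0, lr = learning_rates(), tv_grid = NULL,
                       acfg = adaptive_control_config(),
                       densify_from = 500, densify_until = 4000,
                       densify_every = 100, verbose = FALSE) {
  if (dim(pset$frames)[3] < 1) stop("stage1_fit: empty projection set")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- pset$geometry
  n_proj <- dim(pset$frames)[3]
  if (is.null(tv_grid)) {
    stop("stage1_fit: tv_grid (the output grid) is required")
  }
  extent <- max(tv_grid$dim * tv_grid$spacing)
  pitch <- stats::median(gset$scales)
  rho_ref <- max(stats::quantile(abs(gset$densities), 0.95), 1e-6)
  lrs <- list(densities = lr$densities * rho_ref,
              positions = lr$positions * extent,
              scales = lr$scales * pitch,
              quaternions = lr$rotations)
  opt <- adam_new()
  grad_norm_acc <- numeric(gset$count)
  grad_dir_acc <- matrix(0, gset$count, 3)
  acc_n <- 0
  log <- data.frame(epoch = integer(), loss = numeric(), l1 = numeric(),
                    dssim = numeric(), tv = numeric(), kernels = integer())
  for (ep in seq_len(epochs)) {
    k <- sample.int(n_proj, 1)
    target <- pset$frames[, , k]
    sf <- suppressWarnings(splat_project(gset, g, k))
    resid <- sf$image - target
    l1 <- mean(abs(resid))
    ds <- if (weights$lambda_ssim > 0) dssim_grad(sf$image, target) else
      list(loss = 0, grad = 0)
    upstream <- sign(resid) / length(resid) + weights$lambda_ssim * ds$grad
    gr <- splat_backward(gset, g, k, upstream)
    tvv <- 0
    if (weights$lambda_tv > 0) {
      sg <- tv_subgrid(tv_grid, weights$tv_D)
      sub <- voxelize(gset, sg)
      tvv <- tv_loss(sub$values)
      gtv <- voxelize_backward(gset, sg, weights$lambda_tv * tv_grad(sub$values))
      gr$d_rho <- gr$d_rho + gtv$d_rho
      gr$d_pos <- gr$d_pos + gtv$d_pos
      gr$d_scales <- gr$d_scales + gtv$d_scales
      gr$d_quats <- gr$d_quats + gtv$d_quats
    }
    grads <- list(densities = gr$d_rho, positions = gr$d_pos,
                  scales = gr$d_scales, quaternions = gr$d_quats)
    params <- gset[c("densities", "positions", "scales", "quaternions")]
    st <- adam_step(opt, params, grads, lrs,
                    lr_scale = cosine_lr(ep, epochs))
    opt <- st$state
    gset$densities <- pmax(st$params$densities, 0)
    gset$positions <- st$params$positions
    gset$scales <- pmin(pmax(st$params$scales, SCALE_MIN), SCALE_MAX)
    gset$quaternions <- st$params$quaternions
    pn <- sqrt(rowSums(gr$d_pos^2))
    grad_norm_acc <- grad_norm_acc + pn
    grad_dir_acc <- grad_dir_acc + gr$d_pos
    acc_n <- acc_n + 1
    loss <- l1 + weights$lambda_ssim * ds$loss + weights$lambda_tv * tvv
    log <- rbind(log, data.frame(epoch = ep, loss = loss, l1 = l1,
                                 dssim = ds$loss, tv = tvv,
                                 kernels = gset$count))
    if (!is.null(acfg) && ep >= densify_from && ep <= densify_until &&
        ep %% densify_every == 0) {
      gset <- adaptive_control(gset, grad_norm_acc / acc_n, acfg,
                               grad_dir_acc / acc_n)
      grad_norm_acc <- numeric(gset$count)
      grad_dir_acc <- matrix(0, gset$count, 3)
      acc_n <- 0
      opt <- adam_new()  # kernel count changed; restart moments
    }
    if (verbose && ep %% 200 == 0) {
      message(sprintf("stage1 %d/%d loss %.5f (%d kernels)", ep, epochs,
                      mean(tail(log$loss, 50)), gset$count))
    }
  }
  list(gset = gset, log = log)
}

# ---- Stages 2 and 3 --------------------------------------------------------

# update running batch-norm statistics (momentum 0.9)
update_running <- function(running, stats) {
  for (l in seq_along(running)) {
    running[[l]]$mean <- 0.9 * running[[l]]$mean + 0.1 * stats[[l]]$mean
    running[[l]]$var <- 0.9 * running[[l]]$var + 0.1 * stats[[l]]$var
  }
  running
}

#' Stages 2/3: joint fit of reference, motion bases and encoder
#'
#' Each step samples a batch of projections (uniformly, without replacement
#' within a shuffle cycle), voxelizes the reference Gaussians at the stage
#' resolution (half for stage 2, full for stage 3), derives per-projection
#' coefficients from the encoder, composes DVFs from the voxelized motion
#' bases, warps the reference, forward-projects each dynamic volume at its
#' gantry angle, and descends the mean projection loss (L1 + D-SSIM) plus
#' the normality and TV regularizers. Gradients flow to all three
#' components.
#'
#' @param pset A [projection_set()].
#' @param gset Reference [gaussian_set()] from stage 1.
#' @param mbc An [mbc_model()].
#' @param enc Encoder state (`spec`, `weights`) — see
#'   [motion_encoder_spec()], [encoder_init()].
#' @param weights A [loss_weights()].
#' @param epochs Optimizer steps.
#' @param batch Projections per step.
#' @param stage 2 (half resolution) or 3 (full resolution).
#' @param out_grid Output [volume_grid()].
#' @param seed Integer seed.
#' @param lr A [learning_rates()].
#' @param opt_states Optional optimizer states carried over from a previous
#'   stage (continuous optimization across stages).
#' @param acfg [adaptive_control_config()] to keep densifying/pruning the
#'   reference set during this stage (`NULL`, the default, disables it; the
#'   motion sets always keep fixed counts). Densification continues on a
#'   100-step cadence over the first 80% of the stage.
#' @param verbose Print running loss every 50 steps.
#' @return List with updated `gset`, `mbc`, `enc`, per-step `log`, and
#'   `opt_states` for hand-off to the next stage.
#' @export
stage23_fit <- function(pset, gset, mbc, enc, weights = loss_weights(),
                        epochs = 1000, batch = 32, stage = 2,
                        out_grid = NULL, seed = 0, lr = learning_rates(),
                        opt_states = NULL, acfg = NULL, verbose = FALSE) {
  g <- pset$geometry
  n_proj <- dim(pset$frames)[3]
  if (batch > n_proj) {
    stop("stage23_fit: batch (", batch, ") exceeds projection count (",
         n_proj, ")")
  }
  if (is.null(out_grid)) stop("stage23_fit: out_grid is required")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + stage)
  grid_s <- if (stage == 2) half_grid(out_grid) else out_grid
  extent <- max(out_grid$dim * out_grid$spacing)
  pitch <- stats::median(gset$scales)
  rho_ref <- max(stats::quantile(abs(gset$densities), 0.95), 1e-6)
  lrs_ref <- list(densities = lr$densities * rho_ref,
                  positions = lr$positions * extent,
                  scales = lr$scales * pitch,
                  quaternions = lr$rotations)
  mg <- lr$mbc_geometry
  lrs_mbc <- list(densities = lr$mbc,
                  positions = mg * lr$positions * extent,
                  scales = mg * lr$scales * stats::median(mbc$levels[[1]]$scales),
                  quaternions = mg * lr$rotations)
  if (is.null(opt_states)) {
    opt_states <- list(ref = adam_new(),
                       mbc = lapply(1:3, function(i) adam_new()),
                       enc = adam_new())
  }
  lr_enc <- lapply(seq_along(enc$weights$params), function(i) lr$encoder)
  names(lr_enc) <- paste0("p", seq_along(enc$weights$params))
  queue <- integer(0)
  log <- data.frame(epoch = integer(), loss = numeric(), proj = numeric(),
                    mbcreg = numeric(), tv = numeric())
  mbc_grid <- mbc$mbc_grid
  # With frozen MBC geometry the per-level unit-density footprints are
  # constant, so voxelization and its density gradient reduce to matrix
  # products with cached basis matrices.
  Bcache <- NULL
  n_mvox <- prod(mbc_grid$dim)
  if (mg == 0 && sum(vapply(mbc$levels, `[[`, 0L, "count")) * n_mvox < 5e7) {
    Bcache <- lapply(mbc$levels, function(set) {
      cpp_gauss_basis(set$positions, set$scales, set$quaternions,
                      mbc_grid$dim, mbc_grid$spacing, mbc_grid$origin,
                      TRUNC_RADIUS)
    })
  }
  grad_norm_acc <- numeric(gset$count)
  grad_dir_acc <- matrix(0, gset$count, 3)
  acc_n <- 0
  mbc_basis_fields <- function() {
    if (is.null(Bcache)) return(voxelize_mbcs(mbc))
    out <- vector("list", 9)
    for (i in 1:3) {
      vals <- Bcache[[i]] %*% mbc$levels[[i]]$densities  # n_mvox x 3
      for (k in 1:3) {
        out[[3 * (i - 1) + k]] <- volume(array(vals[, k], mbc_grid$dim),
                                         mbc_grid)
      }
    }
    out
  }
  for (ep in seq_len(epochs)) {
    if (length(queue) < batch) queue <- c(queue, sample.int(n_proj))
    ks <- queue[seq_len(batch)]
    queue <- queue[-seq_len(batch)]
    # forward shared pieces
    basis <- mbc_basis_fields()
    Vref <- voxelize(gset, grid_s)
    inp <- encoder_prepare(pset$frames[, , ks, drop = FALSE], enc$spec)
    fwd <- cpp_encoder_forward(as.numeric(inp), dim(inp)[1:2], length(ks),
                               enc$weights$params, enc$spec$channels, TRUE,
                               enc$weights$running)
    W <- fwd$coeffs  # batch x 9
    dV_acc <- array(0, grid_s$dim)
    dbasis_acc <- lapply(1:9, function(i) array(0, mbc_grid$dim))
    dW <- matrix(0, length(ks), 9)
    proj_loss <- 0
    same_grid <- grids_equal(mbc_grid, grid_s)
    for (bi in seq_along(ks)) {
      k <- ks[bi]
      w9 <- W[bi, ]
      dvf <- compose_dvf(basis, w9, grid_s)
      warped <- warp_volume(Vref, dvf)
      drr <- forward_project(warped, g, k)
      target <- pset$frames[, , k]
      resid <- drr - target
      l1 <- mean(abs(resid))
      ds <- if (weights$lambda_ssim > 0) dssim_grad(drr, target) else
        list(loss = 0, grad = 0)
      proj_loss <- proj_loss + (l1 + weights$lambda_ssim * ds$loss) / length(ks)
      upstream <- (sign(resid) / length(resid) +
                     weights$lambda_ssim * ds$grad) / length(ks)
      dwarped <- back_project(upstream, grid_s, g, k)
      wb <- cpp_warp_backward(as.numeric(Vref$values), grid_s$dim,
                              grid_s$spacing, grid_s$origin,
                              as.numeric(dvf$vectors),
                              as.numeric(dwarped$values))
      dV_acc <- dV_acc + array(wb$d_ref, grid_s$dim)
      nvox <- prod(grid_s$dim)
      for (kc in 1:3) {
        dcomp <- wb$d_dvf[seq((kc - 1) * nvox + 1, kc * nvox)]
        dcoarse <- if (same_grid) dcomp else
          cpp_resample_adjoint(dcomp, mbc_grid$dim, mbc_grid$spacing,
                               mbc_grid$origin, grid_s$dim, grid_s$spacing,
                               grid_s$origin)
        for (i in 1:3) {
          j <- 3 * (i - 1) + kc
          dW[bi, j] <- sum(dcoarse * basis[[j]]$values)
          dbasis_acc[[j]] <- dbasis_acc[[j]] + w9[j] * dcoarse
        }
      }
    }
    # normality regularizer on the bases
    mbcreg <- normality_loss(basis)
    if (weights$lambda_mbc > 0) {
      ng <- normality_loss_backward(basis)
      for (j in 1:9) {
        dbasis_acc[[j]] <- dbasis_acc[[j]] + weights$lambda_mbc * ng[[j]]
      }
    }
    # TV on a random subvolume of the reference
    tvv <- 0
    gr_tv <- NULL
    if (weights$lambda_tv > 0) {
      sg <- tv_subgrid(grid_s, min(weights$tv_D, min(grid_s$dim)))
      sub <- voxelize(gset, sg)
      tvv <- tv_loss(sub$values)
      gr_tv <- voxelize_backward(gset, sg, weights$lambda_tv * tv_grad(sub$values))
    }
    # backprop into reference kernels
    gr_ref <- voxelize_backward(gset, grid_s, dV_acc)
    if (!is.null(gr_tv)) {
      gr_ref$d_rho <- gr_ref$d_rho + gr_tv$d_rho
      gr_ref$d_pos <- gr_ref$d_pos + gr_tv$d_pos
      gr_ref$d_scales <- gr_ref$d_scales + gr_tv$d_scales
      gr_ref$d_quats <- gr_ref$d_quats + gr_tv$d_quats
    }
    st <- adam_step(opt_states$ref,
                    gset[c("densities", "positions", "scales", "quaternions")],
                    list(densities = gr_ref$d_rho, positions = gr_ref$d_pos,
                         scales = gr_ref$d_scales,
                         quaternions = gr_ref$d_quats),
                    lrs_ref, lr_scale = cosine_lr(ep, epochs))
    opt_states$ref <- st$state
    gset$densities <- pmax(st$params$densities, 0)
    gset$positions <- st$params$positions
    gset$scales <- pmin(pmax(st$params$scales, SCALE_MIN), SCALE_MAX)
    gset$quaternions <- st$params$quaternions
    grad_norm_acc <- grad_norm_acc + sqrt(rowSums(gr_ref$d_pos^2))
    grad_dir_acc <- grad_dir_acc + gr_ref$d_pos
    acc_n <- acc_n + 1
    if (!is.null(acfg) && ep %% 100 == 0 && ep <= 0.8 * epochs) {
      gset <- adaptive_control(gset, grad_norm_acc / acc_n, acfg,
                               grad_dir_acc / acc_n)
      grad_norm_acc <- numeric(gset$count)
      grad_dir_acc <- matrix(0, gset$count, 3)
      acc_n <- 0
      opt_states$ref <- adam_new()
    }
    # backprop into MBC kernels (3 channels share position/shape)
    for (i in 1:3) {
      set <- mbc$levels[[i]]
      d_rho <- matrix(0, set$count, 3)
      d_pos <- matrix(0, set$count, 3)
      d_sc <- matrix(0, set$count, 3)
      d_qu <- matrix(0, set$count, 4)
      for (kc in 1:3) {
        j <- 3 * (i - 1) + kc
        if (!is.null(Bcache)) {
          d_rho[, kc] <- crossprod(Bcache[[i]], as.numeric(dbasis_acc[[j]]))
          next
        }
        gk <- gaussian_set(set$positions, set$densities[, kc], set$scales,
                           set$quaternions)
        gb <- voxelize_backward(gk, mbc_grid, dbasis_acc[[j]],
                                allow_negative = TRUE)
        d_rho[, kc] <- gb$d_rho
        d_pos <- d_pos + gb$d_pos
        d_sc <- d_sc + gb$d_scales
        d_qu <- d_qu + gb$d_quats
      }
      grads_i <- list(densities = d_rho)
      params_i <- list(densities = set$densities)
      if (mg > 0) {
        grads_i <- c(grads_i, list(positions = d_pos, scales = d_sc,
                                   quaternions = d_qu))
        params_i <- c(params_i, set[c("positions", "scales", "quaternions")])
      }
      st <- adam_step(opt_states$mbc[[i]], params_i, grads_i, lrs_mbc,
                      lr_scale = cosine_lr(ep, epochs))
      opt_states$mbc[[i]] <- st$state
      set$densities <- st$params$densities
      if (mg > 0) {
        set$positions <- st$params$positions
        set$scales <- pmin(pmax(st$params$scales, SCALE_MIN), SCALE_MAX)
        set$quaternions <- st$params$quaternions
      }
      mbc$levels[[i]] <- set
    }
    # backprop into the encoder
    bw <- cpp_encoder_fwdbwd(as.numeric(inp), dim(inp)[1:2], length(ks),
                             enc$weights$params, enc$spec$channels, dW)
    enc$weights$running <- update_running(enc$weights$running, bw$batch_stats)
    pe <- enc$weights$params
    names(pe) <- paste0("p", seq_along(pe))
    ge <- bw$grads
    names(ge) <- paste0("p", seq_along(ge))
    st <- adam_step(opt_states$enc, pe, ge, lr_enc,
                    lr_scale = cosine_lr(ep, epochs))
    opt_states$enc <- st$state
    enc$weights$params <- unname(st$params)
    loss <- proj_loss + weights$lambda_mbc * mbcreg + weights$lambda_tv * tvv
    log <- rbind(log, data.frame(epoch = ep, loss = loss, proj = proj_loss,
                                 mbcreg = mbcreg, tv = tvv))
    if (verbose && ep %% 50 == 0) {
      message(sprintf("stage%d %d/%d loss %.5f (proj %.5f, mbc %.4f)", stage,
                      ep, epochs, mean(tail(log$loss, 50)),
                      mean(tail(log$proj, 50)), mbcreg))
    }
  }
  list(gset = gset, mbc = mbc, enc = enc, log = log,
       opt_states = opt_states)
}

# ---- Full reconstruction ---------------------------------------------------

#' Reconstruction configuration
#'
#' Defaults reproduce the full-size protocol (50,000 reference kernels,
#' 20^3/22^3/24^3 motion lattices, 5000/1000/1000 epochs). The `"desk"`
#' profile scales everything down for single-CPU runs (8,000 kernels,
#' 6^3/8^3/10^3 lattices, 1500/400/400 epochs) and expects a roughly
#' 100 x 100 x 50 output grid.
#'
#' @param profile `"paper_scale"` or `"desk"`.
#' @param ... Overrides for any field of the returned list.
#' @return Named list of hyperparameters.
#' @export
recon_config <- function(profile = c("paper_scale", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    M = 50000, mbc_levels = c(20, 22, 24),
    schedule = stage_schedule(5000, 1000, 1000, 32, 8),
    weights = loss_weights(), lr = learning_rates(),
    density_floor = 1e-3, encoder_input = c(96, 128),
    encoder_head_sd = 1e-2,
    mbc_grid_fraction = 0.25, mbc_scale_factor = 2,
    fdk_filter = "ramlak", fdk_mask_floor = 2e-3, seed = 0,
    densify_from = 500, densify_until = 4000, densify_every = 100,
    acfg = adaptive_control_config(), acfg_stage23 = NULL)
  if (profile == "desk") {
    # Small problems need faster motion learning (fewer samples per state)
    # and benefit from continued reference densification during the joint
    # stages; both are measurably required for sub-voxel motion recovery
    # at desk sizes.
    cfg$M <- 8000
    cfg$mbc_levels <- c(6, 8, 10)
    cfg$schedule <- stage_schedule(1500, 400, 400, 32, 8)
    cfg$densify_from <- 300
    cfg$densify_until <- 1200
    cfg$encoder_input <- c(48, 64)
    cfg$encoder_head_sd <- 0.03
    cfg$lr <- learning_rates(mbc = 5e-2, encoder = 5e-3)
    cfg$acfg_stage23 <- adaptive_control_config()
  }
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Full three-stage dynamic reconstruction
#'
#' FDK initialization, reference-kernel sampling, MBC lattice and encoder
#' initialization, then stages 1-3 as one continuous optimization (no
#' reinitialization between stages).
#'
#' @param pset A [projection_set()] of a single scan.
#' @param out_grid Output [volume_grid()].
#' @param config From [recon_config()].
#' @param verbose Progress messages.
#' @return A `dynamic_reconstruction`: reference Gaussians and voxelized
#'   reference volume, the MBC model and its voxelized bases, encoder
#'   weights, the `n x 9` per-projection coefficient matrix, and training
#'   logs. Materialize single frames with [materialize_frame()].
#' @export
reconstruct <- function(pset, out_grid, config = recon_config(),
                        verbose = FALSE) {
  g <- pset$geometry
  if (verbose) message("FDK initialization ...")
  avg <- fdk_reconstruct(pset, out_grid, filter = config$fdk_filter)
  if (!is.null(config$fdk_mask_floor)) {
    avg <- mask_air(avg, floor = config$fdk_mask_floor)
  }
  gset <- init_from_volume(avg, config$M, scheme = "grid",
                           density_floor = config$density_floor)
  if (verbose) message("reference init: ", gset$count, " kernels")
  s1 <- stage1_fit(pset, gset, config$weights,
                   epochs = config$schedule$stage1_epochs,
                   seed = config$seed, lr = config$lr, tv_grid = out_grid,
                   acfg = config$acfg, densify_from = config$densify_from,
                   densify_until = config$densify_until,
                   densify_every = config$densify_every, verbose = verbose)
  gset <- s1$gset
  mbc <- mbc_model(out_grid, config$mbc_levels,
                   grid_fraction = config$mbc_grid_fraction,
                   scale_factor = config$mbc_scale_factor)
  spec_enc <- motion_encoder_spec(config$encoder_input)
  enc <- list(spec = spec_enc,
              weights = encoder_init(spec_enc, seed = config$seed,
                                     head_sd = config$encoder_head_sd))
  half_fan <- g$fan_mode == "half"
  ep2 <- config$schedule$stage2_epochs * if (half_fan) 2 else 1
  s2 <- stage23_fit(pset, gset, mbc, enc, config$weights, epochs = ep2,
                    batch = min(config$schedule$batch2, dim(pset$frames)[3]),
                    stage = 2, out_grid = out_grid, seed = config$seed,
                    lr = config$lr, acfg = config$acfg_stage23,
                    verbose = verbose)
  s3 <- stage23_fit(pset, s2$gset, s2$mbc, s2$enc, config$weights,
                    epochs = config$schedule$stage3_epochs,
                    batch = min(config$schedule$batch3, dim(pset$frames)[3]),
                    stage = 3, out_grid = out_grid, seed = config$seed,
                    lr = config$lr, opt_states = s2$opt_states,
                    acfg = config$acfg_stage23, verbose = verbose)
  gset <- s3$gset; mbc <- s3$mbc; enc <- s3$enc
  basis <- voxelize_mbcs(mbc)
  coeffs <- encode(pset$frames, enc$spec, enc$weights)
  reference <- voxelize(gset, out_grid)
  structure(list(
    reference_gaussians = gset, reference = reference,
    mbc = mbc, basis = basis, encoder = enc, coefficients = coeffs,
    geometry = g, out_grid = out_grid, fdk = avg,
    logs = list(stage1 = s1$log, stage2 = s2$log, stage3 = s3$log),
    config = config
  ), class = "dynamic_reconstruction")
}

#' @export
print.dynamic_reconstruction <- function(x, ...) {
  cat(sprintf(
    "dynamic_reconstruction: %d frames, %d reference kernels, grid %dx%dx%d\n",
    nrow(x$coefficients), x$reference_gaussians$count, x$out_grid$dim[1],
    x$out_grid$dim[2], x$out_grid$dim[3]))
  invisible(x)
}

#' Displacement field of one reconstructed frame
#'
#' @param recon A `dynamic_reconstruction`.
#' @param k Frame (projection) index.
#' @return A [displacement_field()] on the output grid.
#' @export
frame_dvf <- function(recon, k) {
  compose_dvf(recon$basis, recon$coefficients[k, ], recon$out_grid)
}

#' Materialize one dynamic frame
#'
#' Deforms the voxelized reference with the frame's DVF.
#'
#' @inheritParams frame_dvf
#' @return A [volume()].
#' @export
materialize_frame <- function(recon, k) {
  warp_volume(recon$reference, frame_dvf(recon, k))
}

#' Write reconstruction artifacts to a directory
#'
#' `reference.mha`, the nine basis fields `mbc_<level>_<xyz>.mha`,
#' `coefficients.csv` (time_s, w1..w9) and optionally selected dynamic
#' frames.
#'
#' @param recon A `dynamic_reconstruction`.
#' @param dir Output directory (created if missing).
#' @param frames Integer indices of dynamic frames to materialize, or NULL.
#' @return Invisibly, `dir`.
#' @export
export_reconstruction <- function(recon, dir, frames = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(recon$reference, file.path(dir, "reference.mha"))
  dirs <- c("x", "y", "z")
  for (i in 1:3) for (k in 1:3) {
    write_volume(recon$basis[[3 * (i - 1) + k]],
                 file.path(dir, sprintf("mbc_%d_%s.mha", i, dirs[k])))
  }
  df <- data.frame(time_s = recon$geometry$times, recon$coefficients)
  names(df) <- c("time_s", paste0("w", 1:9))
  write.csv(df, file.path(dir, "coefficients.csv"), row.names = FALSE)
  con <- file(file.path(dir, "log.jsonl"), "w")
  for (stage in names(recon$logs)) {
    lg <- recon$logs[[stage]]
    for (i in seq_len(nrow(lg))) {
      writeLines(jsonlite::toJSON(c(list(stage = stage),
                                    as.list(lg[i, , drop = FALSE])),
                                  auto_unbox = TRUE, digits = 8), con)
    }
  }
  close(con)
  for (k in frames) {
    write_volume(materialize_frame(recon, k),
                 file.path(dir, sprintf("frame_%04d.mha", k)))
  }
  invisible(dir)
}
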