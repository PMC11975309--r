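# Low-rank respiratory motion model: three coarse-to-fine levels of signed
# Gaussian motion-basis components (MBCs), voxelized with the
# negative-permitting voxelizer into nine basis fields (3 levels x 3
# Cartesian directions), composed into DVFs by per-projection coefficients
# from a convolutional encoder, and applied by backward warping.

#' Motion-basis-component model
#'
#' Three Gaussian sets on uniform lattices of increasing density
#' (`M1 < M2 < M3` kernels), each kernel carrying a 3-channel signed density
#' (one channel per Cartesian direction). Voxelized on a coarse motion grid
#' (displacements vary smoothly, so the basis grid is a fraction of the
#' output grid resolution) and upsampled when composing DVFs.
#'
#' @param out_grid The output [volume_grid()] the DVFs will act on.
#' @param levels Integer 3-vector: lattice points per axis for the three
#'   levels (e.g. `c(20, 22, 24)` gives 20^3 < 22^3 < 24^3 kernels).
#' @param grid_fraction Motion-grid resolution as a fraction of the output
#'   grid (per axis).
#' @param scale_factor Initial kernel scale as a multiple of each level's
#'   lattice pitch (overlapping kernels give smooth fields).
#' @return An object of class `mbc_model` with fields `levels` (list of 3
#'   [gaussian_set()]s with M x 3 densities) and `mbc_grid`.
#' @export
mbc_model <- function(out_grid, levels = c(20, 22, 24), grid_fraction = 0.25,
                      scale_factor = 2) {
  stopifnot(length(levels) == 3, all(diff(levels) > 0))
  dim_m <- pmax(2L, as.integer(ceiling(out_grid$dim * grid_fraction)))
  extent <- out_grid$dim * out_grid$spacing
  spacing_m <- extent / dim_m
  origin_m <- out_grid$origin - out_grid$spacing / 2 + spacing_m / 2
  mbc_grid <- volume_grid(dim_m, spacing_m, origin_m)
  sets <- lapply(levels, function(n) {
    axes <- lapply(1:3, function(a) {
      out_grid$origin[a] - out_grid$spacing[a] / 2 +
        (seq_len(n) - 0.5) * extent[a] / n
    })
    pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
    dimnames(pts) <- NULL
    M <- nrow(pts)
    pitch <- mean(extent / n)
    gaussian_set(pts, matrix(0, M, 3), matrix(scale_factor * pitch, M, 3))
  })
  structure(list(levels = sets, mbc_grid = mbc_grid), class = "mbc_model")
}

#' @export
print.mbc_model <- function(x, ...) {
  cat(sprintf("mbc_model: levels of %s kernels on a %dx%dx%d motion grid\n",
              paste(vapply(x$levels, `[[`, 0L, "count"), collapse = " < "),
              x$mbc_grid$dim[1], x$mbc_grid$dim[2], x$mbc_grid$dim[3]))
  invisible(x)
}

#' Voxelize the nine motion-basis fields
#'
#' Each Cartesian channel of each level is voxelized on the motion grid with
#' the negative-permitting voxelizer (signed displacements survive).
#'
#' @param model An [mbc_model()].
#' @return List of 9 [volume()]s ordered (level1: x,y,z, level2: x,y,z,
#'   level3: x,y,z); values in mm of displacement.
#' @export
voxelize_mbcs <- function(model) {
  stopifnot(inherits(model, "mbc_model"))
  out <- vector("list", 9)
  for (i in 1:3) {
    set <- model$levels[[i]]
    for (k in 1:3) {
      gk <- gaussian_set(set$positions, set$densities[, k], set$scales,
                         set$quaternions)
      out[[3 * (i - 1) + k]] <- voxelize(gk, model$mbc_grid,
                                         allow_negative = TRUE)
    }
  }
  out
}

#' Compose a displacement field from basis fields and coefficients
#'
#' `d_k(x) = sum_i w[i,k] * e[i,k](x)` per direction `k`, trilinearly
#' upsampled from the basis grid to `out_grid` when the grids differ.
#' Exactly linear in `w`.
#'
#' @param basis List of 9 [volume()]s from [voxelize_mbcs()], ordered
#'   (level1: x,y,z, ..., level3: x,y,z), sharing one grid.
#' @param w Numeric 9-vector of coefficients, same ordering.
#' @param out_grid Target [volume_grid()].
#' @return A [displacement_field()] on `out_grid`.
#' @export
compose_dvf <- function(basis, w, out_grid) {
  stopifnot(length(basis) == 9, length(w) == 9)
  g0 <- basis[[1]]$grid
  for (b in basis[-1]) {
    if (!grids_equal(b$grid, g0)) {
      stop("compose_dvf: basis fields must share one grid")
    }
  }
  vec <- array(0, c(out_grid$dim, 3))
  for (k in 1:3) {
    comp <- array(0, g0$dim)
    for (i in 1:3) comp <- comp + w[3 * (i - 1) + k] * basis[[3 * (i - 1) + k]]$values
    vec[, , , k] <- if (grids_equal(g0, out_grid)) comp else {
      cpp_resample(as.numeric(comp), g0$dim, g0$spacing, g0$origin,
                   out_grid$dim, out_grid$spacing, out_grid$origin)
    }
  }
  displacement_field(vec, out_grid)
}

#' Backward-warp a volume by a displacement field
#'
#' `out(x) = reference(x + d(x))` by trilinear interpolation with edge
#' clamping outside the reference extent. Differentiable w.r.t. both the
#' reference values and the displacement vectors.
#'
#' @param reference A [volume()].
#' @param dvf A [displacement_field()] on the same grid.
#' @return A [volume()].
#' @export
warp_volume <- function(reference, dvf) {
  stopifnot(inherits(reference, "volume"), inherits(dvf, "displacement_field"))
  if (!grids_equal(reference$grid, dvf$grid)) {
    stop("warp_volume: reference and dvf grids must match")
  }
  g <- reference$grid
  vals <- cpp_warp(as.numeric(reference$values), g$dim, g$spacing, g$origin,
                   as.numeric(dvf$vectors))
  volume(vals, g)
}

#' Normality loss on the nine basis fields
#'
#' `(1/9) * sum over the nine bases of (||e||^2 - 1)^2`, where `||e||^2` is
#' the mean squared voxel value of a basis. Zero iff every basis has unit
#' mean square; resolves the multiplicative gauge between basis amplitudes
#' and coefficients.
#'
#' @param basis List of 9 [volume()]s.
#' @return Non-negative scalar.
#' @export
normality_loss <- function(basis) {
  stopifnot(length(basis) == 9)
  ms <- vapply(basis, function(b) mean(b$values^2), 0)
  mean((ms - 1)^2)
}

# gradient of normality_loss w.r.t. each basis field (list of 9 arrays)
normality_loss_backward <- function(basis) {
  lapply(basis, function(b) {
    ms <- mean(b$values^2)
    (1 / 9) * 2 * (ms - 1) * 2 * b$values / length(b$values)
  })
}

#' Motion encoder architecture description
#'
#' Six 3x3 stride-2 convolution layers with channels (2, 4, 8, 16, 32, 32),
#' each followed by batch normalization and ReLU, then a flatten and one
#' linear layer with nine outputs (one coefficient per motion basis).
#'
#' @param input_size Integer 2-vector (height, width) the projection frames
#'   are resampled to before encoding.
#' @return An object of class `motion_encoder_spec`.
#' @export
motion_encoder_spec <- function(input_size = c(96, 128)) {
  structure(list(input_size = as.integer(input_size),
                 channels = c(2L, 4L, 8L, 16L, 32L, 32L)),
            class = "motion_encoder_spec")
}

encoder_feature_dim <- function(spec) {
  h <- spec$input_size[1]; w <- spec$input_size[2]
  for (l in seq_along(spec$channels)) {
    h <- (h - 1) %/% 2 + 1
    w <- (w - 1) %/% 2 + 1
  }
  as.integer(spec$channels[length(spec$channels)] * h * w)
}

#' Initialize encoder weights
#'
#' He-initialized convolutions, unit-gamma/zero-beta batch normalization,
#' and a small random head so the initial coefficients are near (but not
#' exactly) zero, which breaks the bilinear saddle between zero bases and
#' zero coefficients.
#'
#' @param spec A [motion_encoder_spec()].
#' @param seed Integer RNG seed.
#' @param head_sd Standard deviation of the final linear layer weights.
#' @return List with `params` (flat list: per layer W, b, gamma, beta; then
#'   linear W, b) and `running` (per-layer running mean/var for inference
#'   batch normalization).
#' @export
encoder_init <- function(spec, seed = 0, head_sd = 1e-2) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ch <- spec$channels
  params <- list()
  cin <- 1L
  for (l in seq_along(ch)) {
    fan_in <- 9 * cin
    params[[4 * (l - 1) + 1]] <- array(rnorm(9 * cin * ch[l], sd = sqrt(2 / fan_in)),
                                       c(3, 3, cin, ch[l]))
    params[[4 * (l - 1) + 2]] <- numeric(ch[l])
    params[[4 * (l - 1) + 3]] <- rep(1, ch[l])
    params[[4 * (l - 1) + 4]] <- numeric(ch[l])
    cin <- ch[l]
  }
  K <- encoder_feature_dim(spec)
  params[[4 * length(ch) + 1]] <- matrix(rnorm(K * 9, sd = head_sd), K, 9)
  params[[4 * length(ch) + 2]] <- numeric(9)
  running <- lapply(ch, function(c) list(mean = numeric(c), var = rep(1, c)))
  list(params = params, running = running)
}

# bilinear resize of a matrix (block mean when shrinking by integer factors)
resize_frame <- function(mat, out_h, out_w) {
  h <- nrow(mat); w <- ncol(mat)
  if (h == out_h && w == out_w) return(mat)
  if (h %% out_h == 0 && w %% out_w == 0) {
    fh <- h %/% out_h; fw <- w %/% out_w
    m <- matrix(0, out_h, out_w)
    for (i in seq_len(fh)) {
      for (j in seq_len(fw)) {
        m <- m + mat[seq(i, h, by = fh), seq(j, w, by = fw)]
      }
    }
    return(m / (fh * fw))
  }
  # bilinear sampling at output pixel centers
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h - 1); wy <- pmin(pmax(ys - y0, 0), 1)
  x0 <- pmin(pmax(floor(xs), 1), w - 1); wx <- pmin(pmax(xs - x0, 0), 1)
  m00 <- mat[y0, x0, drop = FALSE]; m01 <- mat[y0, x0 + 1, drop = FALSE]
  m10 <- mat[y0 + 1, x0, drop = FALSE]; m11 <- mat[y0 + 1, x0 + 1, drop = FALSE]
  Wy <- matrix(wy, out_h, out_w); Wx <- matrix(wx, out_h, out_w, byrow = TRUE)
  (1 - Wy) * ((1 - Wx) * m00 + Wx * m01) + Wy * ((1 - Wx) * m10 + Wx * m11)
}

# standardize + resize a stack of frames into the encoder input array (H,W,n)
encoder_prepare <- function(frames, spec) {
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  n <- dim(frames)[3]
  h <- spec$input_size[1]; w <- spec$input_size[2]
  out <- array(0, c(h, w, n))
  for (k in seq_len(n)) {
    f <- resize_frame(frames[, , k], h, w)
    s <- sd(f)
    out[, , k] <- (f - mean(f)) / if (s > 0) s else 1
  }
  out
}

#' Encode projection frames into motion coefficients
#'
#' Standardizes each frame to zero mean and unit variance, resamples it to
#' the encoder input size, and runs the convolutional encoder in inference
#' mode (batch-normalization running averages), producing nine finite
#' coefficients per frame.
#'
#' @param frames One `n_v x n_u` matrix or an `n_v x n_u x n` stack.
#' @param spec A [motion_encoder_spec()].
#' @param weights Encoder weights as returned by [encoder_init()] (fields
#'   `params`, `running`).
#' @return An `n x 9` matrix of coefficients (a plain 9-vector for a single
#'   frame).
#' @export
encode <- function(frames, spec, weights) {
  single <- length(dim(frames)) == 2
  if (!all(is.finite(frames))) stop("encode: non-finite input frame")
  inp <- encoder_prepare(frames, spec)
  res <- cpp_encoder_forward(as.numeric(inp), dim(inp)[1:2], dim(inp)[3],
                             weights$params, spec$channels, FALSE,
                             weights$running)
  if (single) as.numeric(res$coeffs[1, ]) else res$coeffs
}
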