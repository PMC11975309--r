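# Voxel-domain cone-beam forward projector (Joseph-style ray marching with
# an exact adjoint) and FDK reconstruction for initialization.

#' Forward-project a volume into one cone-beam projection
#'
#' Line integrals of the attenuation volume along rays to detector pixel
#' centers, by uniform sub-stepping of the chord through the volume with
#' trilinear interpolation. The operator is linear in the voxel values and
#' its adjoint ([back_project()]) uses identical weights, so gradients
#' propagate exactly.
#'
#' @param vol A [volume()] (attenuation per mm).
#' @param geometry A [scan_geometry()].
#' @param angle_index Projection index (1-based).
#' @param step Integration step in mm; defaults to the smallest voxel spacing.
#' @return An `n_v x n_u` matrix of line integrals; rays that miss the volume
#'   give 0.
#' @export
forward_project <- function(vol, geometry, angle_index, step = NULL) {
  stopifnot(inherits(vol, "volume"), inherits(geometry, "scan_geometry"))
  if (angle_index < 1 || angle_index > length(geometry$angles)) {
    stop("forward_project: angle_index out of range")
  }
  if (is.null(step)) step <- min(vol$grid$spacing)
  vf <- view_frame(geometry, angle_index)
  ax <- detector_axes(geometry)
  cpp_forward_project(as.numeric(vol$values), vol$grid$dim, vol$grid$spacing,
                      vol$grid$origin, vf$o, vf$eu, vf$ev, vf$ew,
                      geometry$sdd, ax$u, ax$v, step)
}

#' Adjoint of [forward_project()]
#'
#' @param frame `n_v x n_u` matrix (e.g. a projection-domain gradient).
#' @param grid Target [volume_grid()].
#' @inheritParams forward_project
#' @return A [volume()] holding the backprojected values.
#' @export
back_project <- function(frame, grid, geometry, angle_index, step = NULL) {
  if (is.null(step)) step <- min(grid$spacing)
  vf <- view_frame(geometry, angle_index)
  ax <- detector_axes(geometry)
  vals <- cpp_back_project(frame, grid$dim, grid$spacing, grid$origin,
                           vf$o, vf$eu, vf$ev, vf$ew, geometry$sdd,
                           ax$u, ax$v, step)
  volume(vals, grid)
}

# discrete ramp filter kernel (Kak & Slaney) for detector pitch du
ramp_kernel <- function(n, du) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  h <- numeric(n)
  h[k == 0] <- 1 / (4 * du^2)
  odd <- (k %% 2) != 0
  h[odd] <- -1 / (pi * k[odd] * du)^2
  h
}

# Parker short-scan weights: beta = angle from arc start (rad), gamma = fan
# angle of the ray (rad), delta = half fan angle.
parker_weights <- function(beta, gamma, delta) {
  w <- matrix(1, length(gamma), length(beta))
  for (j in seq_along(beta)) {
    b <- beta[j]
    for (i in seq_along(gamma)) {
      g <- gamma[i]
      if (b < 2 * (delta + g)) {
        w[i, j] <- sin(pi / 4 * b / (delta + g))^2
      } else if (b > pi + 2 * g) {
        w[i, j] <- sin(pi / 4 * (pi + 2 * delta - b) / (delta - g))^2
      }
      if (!is.finite(w[i, j]) || w[i, j] < 0) w[i, j] <- 0
    }
  }
  w
}

#' Suppress air in a motion-averaged reconstruction
#'
#' Thresholds the volume at `floor`, dilates the resulting support by
#' `dilate` voxels (box dilation), and zeroes everything outside. Used
#' before Gaussian initialization so no kernels are seeded on air noise,
#' which otherwise grows into low-density haze outside the patient.
#'
#' @param vol A [volume()] (e.g. from [fdk_reconstruct()]).
#' @param floor Attenuation threshold (per mm).
#' @param dilate Dilation radius in voxels.
#' @return A [volume()] with out-of-support values set to 0.
#' @export
mask_air <- function(vol, floor = 2e-3, dilate = 2) {
  m <- vol$values >= floor
  for (i in seq_len(dilate)) {
    d <- dim(m)
    m <- m |
      m[c(1, 1:(d[1] - 1)), , ] | m[c(2:d[1], d[1]), , ] |
      m[, c(1, 1:(d[2] - 1)), ] | m[, c(2:d[2], d[2]), ] |
      m[, , c(1, 1:(d[3] - 1))] | m[, , c(2:d[3], d[3])]
  }
  out <- vol$values
  out[!m] <- 0
  volume(out, vol$grid)
}

#' FDK reconstruction
#'
#' Feldkamp-Davis-Kress analytic reconstruction: cosine weighting, row-wise
#' ramp filtering (Ram-Lak, optional Hann apodization) on the virtual
#' isocenter detector, and distance-weighted voxel-driven backprojection.
#' Short-scan arcs (less than 360 degrees) receive Parker redundancy
#' weighting with a message; half-fan (offset-detector) inputs receive a
#' smooth lateral redundancy weighting before filtering.
#'
#' @param pset A [projection_set()] (at least 2 projections).
#' @param grid Output [volume_grid()].
#' @param filter `"ramlak"` or `"hann"`.
#' @param clamp_negative Clamp negative attenuation to zero (the physical
#'   default used before Gaussian initialization).
#' @return A [volume()].
#' @export
fdk_reconstruct <- function(pset, grid, filter = c("ramlak", "hann"),
                            clamp_negative = TRUE) {
  filter <- match.arg(filter)
  stopifnot(inherits(pset, "projection_set"))
  g <- pset$geometry
  n_proj <- length(g$angles)
  if (n_proj < 2) stop("fdk_reconstruct: need at least 2 projections")
  mag <- g$sad / g$sdd
  ax <- detector_axes(g)
  u_iso <- ax$u * mag  # virtual isocenter detector
  v_iso <- ax$v * mag
  du <- u_iso[2] - u_iso[1]
  # covered arc includes the closing sample step (0..358 deg at 2 deg spacing
  # covers the full circle)
  dbeta_deg <- if (length(g$angles) > 1) abs(g$angles[2] - g$angles[1]) else 0
  arc <- (max(g$angles) - min(g$angles) + dbeta_deg) * pi / 180
  fan_half <- atan(max(abs(u_iso)) / g$sad)
  short_scan <- arc < 2 * pi - 1e-6
  if (short_scan && arc < pi + 2 * fan_half) {
    message("fdk_reconstruct: arc (", round(arc * 180 / pi, 1),
            " deg) below 180 + fan; quantitative accuracy degraded")
  }
  # cosine weights
  cosw <- outer(v_iso, u_iso, function(v, u) g$sad / sqrt(g$sad^2 + u^2 + v^2))
  # lateral redundancy weighting for offset-detector (half-fan) scans
  halfw <- NULL
  if (g$fan_mode == "half") {
    umin <- min(abs(range(u_iso)))  # half-width of the doubly-covered band
    uu <- u_iso
    s <- sign(g$detector_offset_u)
    if (s == 0) s <- 1
    w <- numeric(length(uu))
    inside <- abs(uu) <= umin
    w[inside] <- 0.5 * (sin(pi / 2 * (s * uu[inside]) / umin) + 1)
    w[!inside & (s * uu > 0)] <- 1
    halfw <- matrix(rep(w, each = g$n_v), g$n_v, g$n_u)
  }
  # ramp filter (zero-padded FFT)
  npad <- 2^ceiling(log2(2 * g$n_u))
  H <- Re(fft(ramp_kernel(npad, du)))
  if (filter == "hann") {
    fr <- seq(0, npad - 1) / npad
    fr <- pmin(fr, 1 - fr) * 2  # 0..1..0
    H <- H * 0.5 * (1 + cos(pi * fr))
  }
  parker <- NULL
  if (short_scan && g$fan_mode == "full") {
    beta <- (g$angles - g$angles[1]) * pi / 180
    gamma <- atan(u_iso / g$sad)
    parker <- parker_weights(beta, gamma, fan_half)
  }
  filtered <- array(0, dim(pset$frames))
  for (k in seq_len(n_proj)) {
    fr <- pset$frames[, , k] * cosw
    if (!is.null(halfw)) fr <- fr * halfw
    if (!is.null(parker)) fr <- fr * matrix(rep(parker[, k], each = g$n_v),
                                            g$n_v, g$n_u)
    padded <- matrix(0, g$n_v, npad)
    padded[, seq_len(g$n_u)] <- fr
    ft <- t(apply(padded, 1, function(row) Re(fft(fft(row) * H, inverse = TRUE)) / npad))
    filtered[, , k] <- ft[, seq_len(g$n_u)] * du
  }
  # angular weights: d_beta (uniform sampling), with 1/2 for full-circle
  # redundancy (short scans carry it in the Parker weights instead)
  dbeta <- abs(g$angles[2] - g$angles[1]) * pi / 180
  wts <- rep(dbeta, n_proj)
  redundancy <- if (short_scan || g$fan_mode == "half") 1 else 0.5
  wts <- wts * redundancy
  vf <- lapply(seq_len(n_proj), function(k) view_frame(g, k))
  src <- t(vapply(vf, `[[`, numeric(3), "o"))
  euM <- t(vapply(vf, `[[`, numeric(3), "eu"))
  evM <- t(vapply(vf, `[[`, numeric(3), "ev"))
  ewM <- t(vapply(vf, `[[`, numeric(3), "ew"))
  vals <- cpp_fdk_backproject(as.numeric(filtered), g$n_v, g$n_u, src, euM,
                              evM, ewM, g$sad, c(u_iso[1], du),
                              c(v_iso[1], v_iso[2] - v_iso[1]), grid$dim,
                              grid$spacing, grid$origin, wts)
  if (clamp_negative) vals[vals < 0] <- 0
  volume(vals, grid)
}
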