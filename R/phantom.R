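# Programmatic 4D thorax phantom: analytic ellipsoid anatomy with a
# spherical lung tumor, an analytic respiratory displacement field with a
# sliding discontinuity at the spine, seven breathing scenarios, and a scan
# simulator driving the cone-beam projector. Serves as the ground-truth
# source for end-to-end testing; anatomy is a simplified analogue of a
# digital thorax phantom, scaled to the requested grid.

#' Phantom description
#'
#' Anatomy is parameterized relative to the grid extent so any grid size
#' yields a plausible thorax: a soft-tissue body ellipsoid, two low-density
#' lungs, diaphragm domes (soft tissue below a paraboloid surface inside
#' each lung), a spine cylinder with periodic vertebrae, and a spherical
#' tumor in the lower lobe of the right lung. Attenuations (per mm): soft
#' tissue 0.02, lung 0.004, bone 0.04, tumor 0.024.
#'
#' Axes: x lateral (+x = patient left), y anterior-posterior (+y =
#' posterior), z superior-inferior (+z = superior).
#'
#' @param grid A [volume_grid()]; default matches a 200 x 200 x 100 thorax
#'   at 2 mm voxels.
#' @param tumor_diameter_mm Tumor diameter (default 30 mm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = volume_grid(c(200, 200, 100), 2),
                         tumor_diameter_mm = 30) {
  L <- grid$dim * grid$spacing
  c0 <- grid$origin + (grid$dim - 1) / 2 * grid$spacing  # grid center
  body_ax <- c(0.42, 0.32, 0.85) * L
  lung_sep <- 0.175 * L[1]
  lung_ax <- c(0.15, 0.21, 0.33) * L
  lung_cz <- c0[3] + 0.08 * L[3]
  lung_cy <- c0[2] - 0.02 * L[2]
  dia_apex <- lung_cz - 0.12 * L[3]           # diaphragm dome apex height
  dia_curv <- 0.35 * L[3] / (0.2 * L[1])^2    # paraboloid curvature (1/mm)
  spine <- list(center_y = c0[2] + 0.22 * L[2], radius = 0.035 * L[1],
                period = 0.14 * L[3], bone = 0.04, disc = 0.026)
  tumor_r <- tumor_diameter_mm / 2
  tumor_c <- c(c0[1] - lung_sep, lung_cy,
               dia_apex + 0.06 * L[3] + tumor_r / 2)
  spec <- structure(list(
    grid = grid, L = L, center = c0,
    body = list(center = c0, ax = body_ax, mu = 0.02),
    lungs = list(centers = rbind(c(c0[1] - lung_sep, lung_cy, lung_cz),
                                 c(c0[1] + lung_sep, lung_cy, lung_cz)),
                 ax = lung_ax, mu = 0.004),
    diaphragm = list(apex = dia_apex, curv = dia_curv),
    spine = spine,
    tumor = list(center = tumor_c, radius = tumor_r, mu = 0.024),
    mu_soft = 0.02, mu_bone = 0.04,
    # motion profile geometry
    z_apex = lung_cz + lung_ax[3],   # lung apex: zero displacement above
    z_full = tumor_c[3] + tumor_r + 2  # full displacement below
  ), class = "phantom_spec")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %dx%dx%d grid, tumor r=%.1f mm at (%.1f, %.1f, %.1f)\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3], x$tumor$radius,
              x$tumor$center[1], x$tumor$center[2], x$tumor$center[3]))
  invisible(x)
}

# normalized ellipsoid radius^2 for points (n x 3)
ell_r2 <- function(pts, center, ax) {
  ((pts[, 1] - center[1]) / ax[1])^2 + ((pts[, 2] - center[2]) / ax[2])^2 +
    ((pts[, 3] - center[3]) / ax[3])^2
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Analytic attenuation at world points (n x 3). tumor_center allows the
# dynamic (shifted) tumor to be rendered in closed form. Moving interfaces
# (lung boundary, diaphragm dome, tumor surface) are blended over
# `edge_mm` so backward warping across them stays accurate; the static
# body outline and spine stay crisp.
phantom_density_at <- function(spec, pts, tumor_center = spec$tumor$center,
                               edge_mm = 3) {
  mu <- numeric(nrow(pts))
  inb <- ell_r2(pts, spec$body$center, spec$body$ax) <= 1
  mu[inb] <- spec$mu_soft
  # lungs above the diaphragm dome (smooth membership)
  for (li in 1:2) {
    lc <- spec$lungs$centers[li, ]
    r <- sqrt(ell_r2(pts, lc, spec$lungs$ax))
    s_lung <- smoothstep((1 - r) * min(spec$lungs$ax) / edge_mm)
    dome <- spec$diaphragm$apex -
      spec$diaphragm$curv * ((pts[, 1] - lc[1])^2 + (pts[, 2] - lc[2])^2)
    s_dome <- smoothstep((pts[, 3] - dome) / edge_mm)
    f <- s_lung * s_dome * inb
    mu <- mu * (1 - f) + spec$lungs$mu * f
  }
  # spine: posterior cylinder with periodic vertebrae (static, crisp)
  r2s <- (pts[, 1] - spec$center[1])^2 + (pts[, 2] - spec$spine$center_y)^2
  ins <- inb & r2s <= spec$spine$radius^2
  phase <- ((pts[, 3] - spec$center[3]) / spec$spine$period) %% 1
  mu[ins] <- ifelse(phase[ins] < 0.7, spec$spine$bone, spec$spine$disc)
  # tumor (overrides lung, smooth surface)
  dt <- sqrt((pts[, 1] - tumor_center[1])^2 + (pts[, 2] - tumor_center[2])^2 +
               (pts[, 3] - tumor_center[3])^2)
  ft <- smoothstep((spec$tumor$radius - dt) / edge_mm)
  mu <- mu * (1 - ft) + spec$tumor$mu * ft
  mu
}

# Motion weighting profile m(x) in [0, 1] at world points (n x 3):
# 1 below z_full (diaphragm/tumor level and the abdomen), cosine decay to 0
# at the lung apex, 0 outside the body ellipsoid and strictly 0 in a
# cylinder around the spine (sliding discontinuity), with a smooth taper
# toward the body surface.
motion_profile_at <- function(spec, pts) {
  mz <- numeric(nrow(pts))
  z <- pts[, 3]
  mz[z <= spec$z_full] <- 1
  ramp <- z > spec$z_full & z < spec$z_apex
  mz[ramp] <- 0.5 * (1 + cos(pi * (z[ramp] - spec$z_full) /
                               (spec$z_apex - spec$z_full)))
  r2 <- ell_r2(pts, spec$body$center, spec$body$ax)
  taper <- numeric(nrow(pts))
  inner <- r2 <= 0.7^2
  taper[inner] <- 1
  band <- r2 > 0.7^2 & r2 < 1
  taper[band] <- 0.5 * (1 + cos(pi * (sqrt(r2[band]) - 0.7) / 0.3))
  spine_r2 <- (pts[, 1] - spec$center[1])^2 +
    (pts[, 2] - spec$spine$center_y)^2
  in_spine <- spine_r2 <= (1.4 * spec$spine$radius)^2
  m <- mz * taper
  m[in_spine] <- 0
  m
}

# abdomen factor for the anterior-posterior motion component: 1 well below
# the diaphragm apex, smooth ramp to 0 at it
abdomen_profile_at <- function(spec, pts) {
  z <- pts[, 3]
  za <- spec$diaphragm$apex
  width <- 0.1 * spec$L[3]
  a <- numeric(nrow(pts))
  a[z <= za - width] <- 1
  band <- z > za - width & z < za
  a[band] <- 0.5 * (1 + cos(pi * (z[band] - (za - width)) / width))
  a
}

# analytic displacement (n x 3, mm) at world points for a trace value:
# d(x) = trace * (0.2*abdomen*m ey - m ez); positive trace moves anatomy
# inferiorly (backward-warp convention: I(x) = Iref(x + d(x)))
phantom_displacement_at <- function(spec, pts, trace_value) {
  m <- motion_profile_at(spec, pts)
  ab <- abdomen_profile_at(spec, pts) * m
  cbind(0, -0.2 * trace_value * ab, trace_value * m)
}

#' Analytic ground-truth displacement field
#'
#' Evaluates the phantom's displacement model on the grid: superior-inferior
#' displacement equal to the trace value at the diaphragm dome and tumor,
#' decaying smoothly to zero at the lung apex and the body surface, strictly
#' zero on the spine (sliding discontinuity), plus an anterior-posterior
#' component of 0.2 x trace in the abdomen. Linear in the trace value.
#'
#' @param spec A [phantom_spec()].
#' @param trace_value Breathing amplitude in mm (clamped to +-30).
#' @param grid Grid to evaluate on (default the phantom grid).
#' @return A [displacement_field()].
#' @export
analytic_dvf <- function(spec, trace_value, grid = spec$grid) {
  trace_value <- max(-30, min(30, trace_value))
  pts <- grid_points(grid)
  d <- phantom_displacement_at(spec, pts, trace_value)
  displacement_field(array(d, c(grid$dim, 3)), grid)
}

# voxel-center world coordinates as (prod(dim) x 3), x fastest
grid_points <- function(grid) {
  ax <- lapply(1:3, function(a) grid_axis(grid, a))
  cbind(rep(ax[[1]], times = grid$dim[2] * grid$dim[3]),
        rep(rep(ax[[2]], each = grid$dim[1]), times = grid$dim[3]),
        rep(ax[[3]], each = grid$dim[1] * grid$dim[2]))
}

#' Logical body mask of the phantom on a grid
#'
#' @param spec A [phantom_spec()].
#' @param grid Grid to evaluate on (default the phantom grid).
#' @return Logical array, `TRUE` inside the body ellipsoid.
#' @export
phantom_body_mask <- function(spec, grid = spec$grid) {
  pts <- grid_points(grid)
  array(ell_r2(pts, spec$body$center, spec$body$ax) <= 1, grid$dim)
}

#' Render one phantom frame
#'
#' The dynamic anatomy is evaluated in closed form: each voxel center `x`
#' samples the analytic reference anatomy at `x + d(x)` (no resampling
#' blur), and the tumor mask is the exact displaced sphere. The ground-truth
#' displacement field is attached.
#'
#' @param spec A [phantom_spec()].
#' @param trace_value Breathing amplitude in mm.
#' @return A `phantom_frame`: list with `volume`, `tumor_mask` (logical
#'   array), `gt_dvf`, `trace_value`.
#' @export
render_frame <- function(spec, trace_value) {
  trace_value <- max(-30, min(30, trace_value))
  g <- spec$grid
  pts <- grid_points(g)
  d <- phantom_displacement_at(spec, pts, trace_value)
  moved <- pts + d
  mu <- phantom_density_at(spec, moved)
  # tumor sits in the full-displacement region: its dynamic center is the
  # reference center shifted by the local displacement
  ct_dyn <- spec$tumor$center -
    phantom_displacement_at(spec, matrix(spec$tumor$center, 1, 3),
                            trace_value)[1, ]
  dt2 <- (pts[, 1] - ct_dyn[1])^2 + (pts[, 2] - ct_dyn[2])^2 +
    (pts[, 3] - ct_dyn[3])^2
  mask <- array(dt2 <= spec$tumor$radius^2, g$dim)
  structure(list(volume = volume(array(mu, g$dim), g),
                 tumor_mask = mask,
                 gt_dvf = displacement_field(array(d, c(g$dim, 3)), g),
                 trace_value = trace_value),
            class = "phantom_frame")
}

#' Breathing trace container
#'
#' @param times Seconds.
#' @param values Superior-inferior displacement amplitude (mm); positive
#'   values displace the diaphragm and tumor inferiorly (inhale).
#' @param scenario Label `"S1"`..`"S7"`.
#' @return An object of class `breathing_trace`.
#' @export
breathing_trace <- function(times, values, scenario = "S1") {
  if (length(times) != length(values)) {
    stop("breathing_trace: times and values must have equal length")
  }
  if (!all(is.finite(values))) stop("breathing_trace: values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 scenario = scenario), class = "breathing_trace")
}

#' @export
print.breathing_trace <- function(x, ...) {
  cat(sprintf("breathing_trace %s: %d samples over %.1f s, range [%.2f, %.2f] mm\n",
              x$scenario, length(x$times), max(x$times) - min(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

# one quasi-periodic breathing train built cycle by cycle: sin^4 cycles
# (exhale dwell at 0) with per-cycle period/amplitude drawn by `draw`
cycle_train <- function(times, draw) {
  values <- numeric(length(times))
  t0 <- 0
  repeat {
    par <- draw(t0)
    idx <- times >= t0 & times < t0 + par$T
    if (any(idx)) values[idx] <- par$A * sin(pi * (times[idx] - t0) / par$T)^4
    t0 <- t0 + par$T
    if (t0 > max(times)) break
  }
  values
}

#' Generate a breathing trace for one of the seven scenarios
#'
#' Waveforms are raised-sine (`sin^4`) cycles with a flat exhale dwell:
#' \describe{
#'   \item{S1}{quasi-periodic ~5 s cycles, 13 mm peak-to-trough.}
#'   \item{S2}{S1 plus a 5 mm baseline step at mid-scan.}
#'   \item{S3}{cycle-wise amplitude jitter plus a drifting baseline.}
#'   \item{S4}{period increasing linearly from 4 s to 7 s.}
#'   \item{S5}{one single cycle spanning the whole scan (slow breathing).}
#'   \item{S6}{combined period, amplitude and baseline variation.}
#'   \item{S7}{S1 with the amplitude extended to 20 mm.}
#' }
#'
#' @param scenario `"S1"`..`"S7"`.
#' @param duration_s Scan duration (s).
#' @param fps Samples per second.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [breathing_trace()] with `round(duration_s*fps)` samples.
#' @export
make_trace <- function(scenario, duration_s = 60, fps = 11, seed = 0) {
  scenarios <- paste0("S", 1:7)
  if (!scenario %in% scenarios) {
    stop("make_trace: unknown scenario '", scenario, "' (use S1..S7)")
  }
  if (duration_s <= 0 || fps <= 0) stop("make_trace: duration and fps must be > 0")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 1000 * match(scenario, scenarios))
  n <- round(duration_s * fps)
  times <- (seq_len(n) - 1) / fps
  A0 <- 13
  values <- switch(scenario,
    S1 = cycle_train(times, function(t0) list(T = 5 + rnorm(1, 0, 0.25), A = A0)),
    S2 = cycle_train(times, function(t0) list(T = 5 + rnorm(1, 0, 0.25), A = A0)) +
      5 * (times >= duration_s / 2),
    S3 = cycle_train(times, function(t0) {
      list(T = 5 + rnorm(1, 0, 0.25), A = A0 * (1 + runif(1, -0.25, 0.25)))
    }) + 2.5 * sin(2 * pi * times / duration_s),
    S4 = cycle_train(times, function(t0) {
      list(T = 4 + 3 * min(t0, duration_s) / duration_s, A = A0)
    }),
    S5 = A0 * sin(pi * times / duration_s)^4,
    S6 = cycle_train(times, function(t0) {
      list(T = 4 + 2.5 * min(t0, duration_s) / duration_s + rnorm(1, 0, 0.3),
           A = A0 * (1 + runif(1, -0.25, 0.25)))
    }) + 2.5 * sin(2 * pi * times / duration_s) + 3 * (times >= duration_s * 0.6),
    S7 = cycle_train(times, function(t0) {
      list(T = 5 + rnorm(1, 0, 0.25), A = 20)
    }))
  breathing_trace(times, values, scenario)
}

#' Simulate a dynamic cone-beam scan of the phantom
#'
#' For each projection, renders the phantom at the trace value of that
#' time point and forward-projects it at the corresponding gantry angle
#' (line-integral domain). Optional Poisson noise is applied in the
#' intensity domain (`I_raw = I0 * exp(-p)`) and re-logged.
#'
#' @param spec A [phantom_spec()].
#' @param trace A [breathing_trace()] with one value per projection.
#' @param geometry A [scan_geometry()]; angle count must match the trace.
#' @param noise_I0 Photon count for Poisson noise, or `NULL` (noiseless).
#' @param seed RNG seed for the noise.
#' @param keep Which ground-truth pieces to keep per frame: any of
#'   `"volume"`, `"mask"`, `"dvf"`.
#' @return List with `projections` (a [projection_set()]) and `frames`
#'   (list of per-projection ground-truth pieces).
#' @export
simulate_scan <- function(spec, trace, geometry, noise_I0 = NULL, seed = 0,
                          keep = c("volume", "mask", "dvf")) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(trace, "breathing_trace"))
  n <- length(geometry$angles)
  if (length(trace$values) != n) {
    stop("simulate_scan: trace length (", length(trace$values),
         ") != number of projections (", n, ")")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  frames <- array(0, c(geometry$n_v, geometry$n_u, n))
  gt <- vector("list", n)
  # render distinct trace values once (static scans hit a single render)
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(n)) {
    key <- sprintf("%.9g", trace$values[k])
    if (is.null(cache[[key]])) cache[[key]] <- render_frame(spec, trace$values[k])
    ph <- cache[[key]]
    frames[, , k] <- forward_project(ph$volume, geometry, k)
    rec <- list(trace_value = ph$trace_value)
    if ("volume" %in% keep) rec$volume <- ph$volume
    if ("mask" %in% keep) rec$tumor_mask <- ph$tumor_mask
    if ("dvf" %in% keep) rec$gt_dvf <- ph$gt_dvf
    gt[[k]] <- rec
  }
  if (!is.null(noise_I0)) {
    counts <- array(stats::rpois(length(frames), noise_I0 * exp(-frames)),
                    dim(frames))
    frames <- -log(pmax(counts, 0.5) / noise_I0)
  }
  list(projections = projection_set(frames, geometry), frames = gt)
}
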