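#' @useDynLib gaussCBCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd cor approx quantile median var
#' @importFrom utils write.csv read.csv head tail
NULL

# Coordinate conventions (shared by every module):
#   * world origin at the scanner isocenter
#   * right-handed axes: x lateral, y anterior-posterior, z superior-inferior
#   * voxel indices 0-based in C++, 1-based in R arrays; voxel centers at
#     origin + index0 * spacing
#   * gantry angles in degrees externally, radians internally; at 0 degrees the
#     source sits at (0, -SAD, 0) and the beam points along +y
#   * detector u axis is the rotated world x axis, v axis is world z (SI)

#' Cone-beam scan geometry
#'
#' Describes a circular cone-beam acquisition: source-to-axis distance (SAD),
#' source-to-detector distance (SDD), the flat-panel detector layout, and the
#' per-projection gantry angles and acquisition times.
#'
#' @param sad Source-to-axis distance in mm.
#' @param sdd Source-to-detector distance in mm (must exceed `sad`).
#' @param n_u,n_v Detector pixel counts (width, height).
#' @param pixel_u,pixel_v Detector pixel pitch in mm.
#' @param angles Gantry angles in degrees, one per projection.
#' @param times Acquisition timestamps in seconds, strictly increasing,
#'   same length as `angles`.
#' @param fan_mode `"full"` (centered detector) or `"half"` (laterally offset
#'   detector for an enlarged field of view).
#' @param detector_offset_u Lateral detector shift in mm; must be 0 in
#'   full-fan mode.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(sad, sdd, n_u, n_v, pixel_u, pixel_v,
                          angles, times,
                          fan_mode = c("full", "half"),
                          detector_offset_u = 0) {
  fan_mode <- match.arg(fan_mode)
  if (!(sdd > sad && sad > 0)) {
    stop("scan_geometry: need sdd > sad > 0, got sad=", sad, ", sdd=", sdd)
  }
  if (length(angles) != length(times)) {
    stop("scan_geometry: angles (", length(angles), ") and times (",
         length(times), ") must have equal length")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("scan_geometry: times must be strictly increasing")
  }
  if (fan_mode == "full" && detector_offset_u != 0) {
    stop("scan_geometry: detector_offset_u must be 0 in full-fan mode")
  }
  if (n_u < 1 || n_v < 1 || pixel_u <= 0 || pixel_v <= 0) {
    stop("scan_geometry: invalid detector description")
  }
  structure(list(
    sad = sad, sdd = sdd,
    n_u = as.integer(n_u), n_v = as.integer(n_v),
    pixel_u = pixel_u, pixel_v = pixel_v,
    fan_mode = fan_mode, detector_offset_u = detector_offset_u,
    angles = as.numeric(angles), times = as.numeric(times)
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: SAD %.1f mm, SDD %.1f mm, detector %dx%d @ %.2fx%.2f mm, %s fan\n",
    x$sad, x$sdd, x$n_u, x$n_v, x$pixel_u, x$pixel_v, x$fan_mode))
  cat(sprintf("  %d projections, angles %.1f..%.1f deg, t %.2f..%.2f s\n",
              length(x$angles), min(x$angles), max(x$angles),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Regular voxel grid
#'
#' @param dim Integer 3-vector: voxel counts along (x, y, z).
#' @param spacing Numeric 3-vector (or scalar) of mm per voxel.
#' @param origin World coordinates (mm) of the center of voxel (0,0,0).
#'   Default centers the grid on the isocenter.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dim, spacing, origin = NULL) {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 1)) stop("volume_grid: dim must be 3 positive integers")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("volume_grid: spacing must be > 0 on all axes")
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  origin <- rep_len(as.numeric(origin), 3)
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %dx%dx%d @ (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$dim == b$dim) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of voxel centers
#'
#' @param grid A [volume_grid()].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of voxel-center world coordinates (mm) along `axis`.
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing[axis]
}

#' Scalar volume on a regular grid
#'
#' @param values 3D numeric array, dimensions matching `grid$dim`.
#' @param grid A [volume_grid()].
#' @return An object of class `volume`.
#' @export
volume <- function(values, grid) {
  values <- as.array(values)
  if (length(dim(values)) != 3 || !all(dim(values) == grid$dim)) {
    stop("volume: values dimensions ", paste(dim(values), collapse = "x"),
         " do not match grid ", paste(grid$dim, collapse = "x"))
  }
  if (!all(is.finite(values))) stop("volume: values must be finite")
  structure(list(values = values, grid = grid), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume: %dx%dx%d, range [%.4g, %.4g]\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Stack of cone-beam projections
#'
#' Frames are stored in line-integral (post-log) units: each pixel is the
#' integral of attenuation (per mm) along its ray, hence unitless.
#'
#' @param frames 3D array `n_v x n_u x n_frames`, or a list of `n_v x n_u`
#'   matrices.
#' @param geometry A [scan_geometry()]; `n_frames` must equal the number of
#'   angles.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(frames, geometry) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  if (dim(frames)[3] != length(geometry$angles)) {
    stop("projection_set: frame count (", dim(frames)[3],
         ") != number of angles (", length(geometry$angles), ")")
  }
  if (dim(frames)[1] != geometry$n_v || dim(frames)[2] != geometry$n_u) {
    stop("projection_set: frame size ", dim(frames)[1], "x", dim(frames)[2],
         " != detector ", geometry$n_v, "x", geometry$n_u)
  }
  if (!all(is.finite(frames))) stop("projection_set: frames must be finite")
  structure(list(frames = frames, geometry = geometry),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection_set: %d frames of %dx%d, range [%.4g, %.4g]\n",
              dim(x$frames)[3], dim(x$frames)[1], dim(x$frames)[2],
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Displacement vector field
#'
#' Backward-warping convention: a volume deformed by `d` samples the reference
#' at `x + d(x)` (mm).
#'
#' @param vectors 4D array `nx x ny x nz x 3` of displacements in mm; the 4th
#'   dimension orders components as (x, y, z), matching the grid axes.
#' @param grid A [volume_grid()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, grid) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4 || !all(d[1:3] == grid$dim) || d[4] != 3) {
    stop("displacement_field: vectors must be nx x ny x nz x 3 matching the grid")
  }
  if (!all(is.finite(vectors))) stop("displacement_field: vectors must be finite")
  structure(list(vectors = vectors, grid = grid), class = "displacement_field")
}

#' Circular trajectory sampling
#'
#' Uniform-in-time sampling of a circular gantry sweep: `round(duration_s*fps)`
#' samples with angle linear in time starting at `start_deg`.
#'
#' @param start_deg Starting gantry angle in degrees.
#' @param arc_deg Total swept arc in degrees (> 0).
#' @param duration_s Scan duration in seconds (> 0).
#' @param fps Frame rate in projections per second (> 0).
#' @return List with `angles` (degrees) and `times` (seconds).
#' @export
make_circular_trajectory <- function(start_deg, arc_deg, duration_s, fps) {
  if (arc_deg <= 0 || duration_s <= 0 || fps <= 0) {
    stop("make_circular_trajectory: arc_deg, duration_s and fps must be > 0")
  }
  n <- round(duration_s * fps)
  if (n < 1) stop("make_circular_trajectory: duration_s*fps rounds to 0 samples")
  times <- (seq_len(n) - 1) / fps
  angles <- start_deg + arc_deg * times / duration_s
  list(angles = angles, times = times)
}

# Source position and detector frame for one angle (radians internally).
# Returns list(o = source, eu, ev, ew): ew is the unit beam direction
# (source -> detector center), eu/ev the detector in-plane axes.
view_frame <- function(geometry, angle_index) {
  th <- geometry$angles[angle_index] * pi / 180
  o  <- c(geometry$sad * sin(th), -geometry$sad * cos(th), 0)
  eu <- c(cos(th), sin(th), 0)
  ev <- c(0, 0, 1)
  ew <- c(-sin(th), cos(th), 0)
  list(o = o, eu = eu, ev = ev, ew = ew)
}

# Detector pixel center coordinates (mm) along u and v, in detector plane.
detector_axes <- function(geometry) {
  u <- (seq_len(geometry$n_u) - 1 - (geometry$n_u - 1) / 2) * geometry$pixel_u +
    geometry$detector_offset_u
  v <- (seq_len(geometry$n_v) - 1 - (geometry$n_v - 1) / 2) * geometry$pixel_v
  list(u = u, v = v)
}
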