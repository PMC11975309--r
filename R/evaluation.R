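# Quantitative evaluation: per-frame relative error, volumetric SSIM,
# contour propagation with center-of-mass error and Dice, and the
# Amsterdam-Shroud trace pipeline (SI-gradient line profiles stacked over
# time) with localization error and Pearson correlation.

#' Mean per-frame relative error
#'
#' `RE = mean over frames of ||I - I_gt||_2 / ||I_gt||_2`, the L2 norms
#' taken over all voxels of each frame (optionally within a mask).
#'
#' @param recon_frames List of [volume()]s (reconstructed frames).
#' @param gt_frames List of [volume()]s (ground truth), same grids.
#' @param mask Optional logical array restricting the norms.
#' @return Scalar; attribute `"per_frame"` carries the per-frame ratios.
#' @export
relative_error <- function(recon_frames, gt_frames, mask = NULL) {
  if (length(recon_frames) != length(gt_frames)) {
    stop("relative_error: frame counts differ")
  }
  ratios <- vapply(seq_along(recon_frames), function(k) {
    a <- recon_frames[[k]]$values
    b <- gt_frames[[k]]$values
    if (!all(dim(a) == dim(b))) stop("relative_error: grid mismatch at frame ", k)
    if (!is.null(mask)) {
      a <- a[mask]
      b <- b[mask]
    }
    denom <- sqrt(sum(b^2))
    if (denom == 0) {
      stop("relative_error: ground-truth frame ", k,
           " is all-zero (division by zero)")
    }
    sqrt(sum((a - b)^2)) / denom
  }, 0)
  structure(mean(ratios), per_frame = ratios)
}

#' Volumetric SSIM
#'
#' Mean local SSIM with a 7 x 7 x 7 box window; the dynamic range is taken
#' from `b` (the reference).
#'
#' @param a,b [volume()]s on matching grids.
#' @param window Window edge length (odd, default 7).
#' @return Scalar in `(-1, 1]`; 1 iff identical.
#' @export
ssim_volume <- function(a, b, window = 7) {
  if (!grids_equal(a$grid, b$grid)) stop("ssim_volume: grid mismatch")
  drange <- diff(range(b$values))
  if (drange <= 0) drange <- 1
  cpp_ssim3d(as.numeric(a$values), as.numeric(b$values), a$grid$dim, drange,
             as.integer(window))
}

#' Propagate a binary contour with a displacement field
#'
#' Warps the mask as a float volume and re-thresholds at 0.5.
#'
#' @param mask_ref Logical (or 0/1) array on the DVF grid.
#' @param dvf A [displacement_field()].
#' @return Logical array.
#' @export
propagate_contour <- function(mask_ref, dvf) {
  g <- dvf$grid
  if (!all(dim(mask_ref) == g$dim)) stop("propagate_contour: grid mismatch")
  warped <- cpp_warp(as.numeric(mask_ref), g$dim, g$spacing, g$origin,
                     as.numeric(dvf$vectors))
  array(warped >= 0.5, g$dim)
}

#' Center-of-mass error between two binary masks (mm)
#'
#' @param mask_a,mask_b Logical arrays on the same grid.
#' @param grid The shared [volume_grid()].
#' @return Euclidean distance between mask centers of mass in world mm.
#' @export
come <- function(mask_a, mask_b, grid) {
  if (!any(mask_a) || !any(mask_b)) stop("come: empty mask")
  sqrt(sum((mask_com(mask_a, grid) - mask_com(mask_b, grid))^2))
}

mask_com <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE)
  unname(grid$origin + (colMeans(idx) - 1) * grid$spacing)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks count as identical (1, with a
#' warning).
#'
#' @param mask_a,mask_b Logical arrays of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("dice: grid mismatch")
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0) {
    warning("dice: both masks empty; returning 1")
    return(1)
  }
  2 * sum(mask_a & mask_b) / (sa + sb)
}

#' Amsterdam-Shroud image of a projection set
#'
#' Per frame: forward difference along the detector v axis (superior-
#' inferior), summed over a band of detector columns, giving one line
#' profile; profiles are stacked in time order as image columns.
#'
#' @param pset A [projection_set()].
#' @param column_band Integer range of detector u indices (default: an
#'   automatic band where the temporal variance of the gradient profile
#'   exceeds half its maximum).
#' @return `(n_v - 1) x n_frames` matrix; attribute `"band"` records the
#'   band used.
#' @export
as_image <- function(pset, column_band = NULL) {
  fr <- pset$frames
  nv <- dim(fr)[1]; nu <- dim(fr)[2]; np <- dim(fr)[3]
  grad <- fr[-1, , , drop = FALSE] - fr[-nv, , , drop = FALSE]
  if (is.null(column_band)) {
    # temporal variance of the per-column gradient profiles
    colvar <- numeric(nu)
    for (u in seq_len(nu)) {
      prof <- grad[, u, ]
      colvar[u] <- mean(apply(prof, 1, stats::var))
    }
    good <- which(colvar >= max(colvar) / 2)
    if (length(good) == 0) good <- seq_len(nu)
    column_band <- seq(min(good), max(good))
  }
  if (length(column_band) == 0 || any(column_band < 1) ||
      any(column_band > nu)) {
    stop("as_image: column band outside the detector width")
  }
  img <- apply(grad[, column_band, , drop = FALSE], c(1, 3), sum)
  structure(img, band = column_band)
}

#' Extract a breathing trace from an Amsterdam-Shroud image
#'
#' Per column, the dominant gradient extremum is located with subpixel
#' parabolic refinement around the argmax of |AS|, under a +-`max_jump`-row
#' continuity constraint between adjacent columns. Row positions are
#' converted from detector mm to isocenter mm by `sad/sdd`.
#'
#' @param as_img Matrix from [as_image()].
#' @param geometry The scan's [scan_geometry()].
#' @param max_jump Continuity constraint between adjacent columns (rows).
#' @return Numeric vector (one isocenter-mm position per frame); attribute
#'   `"rows"` carries the raw row positions.
#' @export
extract_trace <- function(as_img, geometry, max_jump = 15) {
  nv <- nrow(as_img); np <- ncol(as_img)
  if (all(as_img == 0)) stop("extract_trace: all-zero AS image")
  rows <- numeric(np)
  # Static anatomy edges can outshine the breathing landmark, so restrict
  # tracking to rows whose gradient profile actually moves: suppress rows
  # with low temporal variance, and seed at the most motion-active row.
  row_var <- apply(as_img, 1, stats::var)
  keep_rows <- row_var >= 0.25 * max(row_var)
  as_img <- as_img * keep_rows
  prev <- which.max(row_var)
  for (k in seq_len(np)) {
    col <- abs(as_img[, k])
    if (all(col == 0)) {
      rows[k] <- if (is.na(prev)) NA else prev  # carried over, flagged below
      next
    }
    cand <- seq_len(nv)
    if (!is.na(prev)) {
      cand <- cand[abs(cand - prev) <= max_jump]
    }
    i <- cand[which.max(col[cand])]
    # parabolic subpixel refinement
    r <- i
    if (i > 1 && i < nv) {
      y0 <- col[i - 1]; y1 <- col[i]; y2 <- col[i + 1]
      den <- y0 - 2 * y1 + y2
      if (den < 0) r <- i + 0.5 * (y0 - y2) / den
    }
    rows[k] <- r
    prev <- round(r)
  }
  if (anyNA(rows)) {
    first <- which(!is.na(rows))[1]
    rows[seq_len(first - 1)] <- rows[first]
  }
  iso <- rows * geometry$pixel_v * geometry$sad / geometry$sdd
  structure(iso, rows = rows)
}

#' Pair of aligned motion traces
#'
#' @param times Seconds.
#' @param solved,reference Traces in isocenter mm.
#' @param label Anatomy tracked.
#' @return An object of class `trace_pair`.
#' @export
trace_pair <- function(times, solved, reference, label = "diaphragm") {
  if (length(solved) != length(reference) || length(times) != length(solved)) {
    stop("trace_pair: length mismatch")
  }
  if (!all(is.finite(solved)) || !all(is.finite(reference))) {
    stop("trace_pair: traces must be finite")
  }
  structure(list(times = times, solved = solved, reference = reference,
                 label = label), class = "trace_pair")
}

# The motion model has a sign gauge ((w, e) and (-w, -e) compose the same
# DVF), so trace comparisons allow one global sign flip of the solved trace
# (about its mean), choosing the sign that maximizes |Pearson r|.
align_gauge <- function(tp) {
  s <- tp$solved; r <- tp$reference
  flip <- FALSE
  if (stats::sd(s) > 0 && stats::sd(r) > 0) {
    if (cor(s, r) < cor(-(s - mean(s)) + mean(s), r)) {
      s <- -(s - mean(s)) + mean(s)
      flip <- TRUE
    }
  }
  list(solved = s, reference = r, flipped = flip)
}

#' Localization error between two traces
#'
#' Mean and standard deviation of `|solved - reference|` in isocenter mm,
#' after the optional global sign flip of the motion-model gauge (the flip,
#' when applied, is recorded in the result).
#'
#' @param tp A [trace_pair()].
#' @return List with `mean`, `sd` (mm) and `flipped`.
#' @export
localization_error <- function(tp) {
  al <- align_gauge(tp)
  if (al$flipped) message("localization_error: applied gauge sign flip")
  err <- abs(al$solved - al$reference)
  list(mean = mean(err), sd = stats::sd(err), flipped = al$flipped)
}

#' Pearson correlation between two traces (gauge-aware)
#'
#' @param tp A [trace_pair()].
#' @return Pearson r after the optional global sign flip.
#' @export
trace_pearson <- function(tp) {
  al <- align_gauge(tp)
  if (stats::sd(al$solved) == 0 || stats::sd(al$reference) == 0) {
    stop("trace_pearson: constant trace")
  }
  cor(al$solved, al$reference)
}

#' Threshold-based tumor contour on a reconstructed reference
#'
#' Inside a dilated bounding box of a ground-truth tumor mask, voxels above
#' half of the local intensity range are contoured (the reconstructed tumor
#' is brighter than the surrounding lung).
#'
#' Keep the margin tight: a generous box can reach into mediastinal or
#' chest-wall soft tissue, which is brighter than lung and would pollute
#' the contour.
#'
#' @param reference A [volume()] (the solved reference).
#' @param gt_mask Logical array locating the tumor approximately.
#' @param dilate_mm Margin added around the ground-truth bounding box.
#' @return Logical array.
#' @export
contour_tumor <- function(reference, gt_mask, dilate_mm = 6) {
  g <- reference$grid
  idx <- which(gt_mask, arr.ind = TRUE)
  marg <- ceiling(dilate_mm / g$spacing)
  lo <- pmax(apply(idx, 2, min) - marg, 1)
  hi <- pmin(apply(idx, 2, max) + marg, g$dim)
  box <- reference$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  thr <- min(box) + 0.5 * (max(box) - min(box))
  out <- array(FALSE, g$dim)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- box >= thr
  out
}
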