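# Volume and projection I/O.
#
# Volumes: MetaImage (.mha, header + raw payload in one file) and NIfTI
# (.nii / .nii.gz via RNifti). Both store spacing; .mha also stores the world
# origin exactly (NIfTI keeps it in the sform). Projections: multi-page TIFF
# plus a JSON geometry sidecar.

mha_type_map <- c(MET_DOUBLE = "double", MET_FLOAT = "float",
                  MET_SHORT = "short", MET_USHORT = "ushort",
                  MET_UCHAR = "uchar")
mha_type_size <- c(MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
                   MET_USHORT = 2L, MET_UCHAR = 1L)

#' Write a volume to disk
#'
#' Supported formats (by extension): MetaImage `.mha` (lossless, double
#' precision) and NIfTI `.nii` / `.nii.gz`.
#'
#' @param vol A [volume()].
#' @param path Output path; the extension selects the format.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  if (!all(is.finite(vol$values))) {
    stop("write_volume: refusing to write non-finite voxel values")
  }
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    write_mha(vol, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$grid$spacing
    mat <- diag(c(vol$grid$spacing, 1))
    mat[1:3, 4] <- vol$grid$origin
    RNifti::sform(img) <- structure(mat, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    stop("write_volume: unsupported volume format for '", path,
         "' (supported: .mha, .nii, .nii.gz)")
  }
  invisible(path)
}

write_mha <- function(vol, path) {
  d <- vol$grid$dim
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
    sprintf("Offset = %.17g %.17g %.17g\n", vol$grid$origin[1],
            vol$grid$origin[2], vol$grid$origin[3]),
    "CenterOfRotation = 0 0 0\n",
    sprintf("ElementSpacing = %.17g %.17g %.17g\n", vol$grid$spacing[1],
            vol$grid$spacing[2], vol$grid$spacing[3]),
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    "ElementType = MET_DOUBLE\n",
    "ElementDataFile = LOCAL\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(as.vector(vol$values), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a volume from disk
#'
#' @param path Path to a `.mha`, `.nii` or `.nii.gz` volume.
#' @return A [volume()] with grid metadata (spacing, origin) from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    read_mha(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    xf <- RNifti::xform(img)
    origin <- xf[1:3, 4]
    vals <- array(as.numeric(img), dim = dim(img))
    volume(vals, volume_grid(dim(vals), sp, origin))
  } else {
    stop("read_volume: unsupported volume format for '", path,
         "' (supported: .mha, .nii, .nii.gz)")
  }
}

read_mha <- function(path) {
  if (file.info(path)$size == 0) stop("read_mha: empty file (0-byte payload): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("read_mha: corrupt header (no ElementDataFile): ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("read_mha: corrupt header line: '", line, "'")
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementSpacing", "ElementType")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("read_mha: header missing ", paste(miss, collapse = ", "))
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset)) as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  et <- hdr$ElementType
  if (!et %in% names(mha_type_map)) stop("read_mha: unsupported ElementType ", et)
  if (!identical(hdr$ElementDataFile, "LOCAL")) {
    stop("read_mha: only single-file (ElementDataFile = LOCAL) .mha supported")
  }
  n <- prod(d)
  what <- switch(et, MET_DOUBLE = "double", MET_FLOAT = "double",
                 MET_SHORT = "integer", MET_USHORT = "integer", MET_UCHAR = "integer")
  size <- mha_type_size[[et]]
  signed <- !et %in% c("MET_USHORT", "MET_UCHAR")
  vals <- if (et %in% c("MET_DOUBLE", "MET_FLOAT")) {
    readBin(con, "double", n = n, size = size, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = size, signed = signed, endian = "little")
  }
  if (length(vals) != n) stop("read_mha: truncated payload (", length(vals),
                              " of ", n, " voxels): ", path)
  volume(array(as.numeric(vals), dim = d), volume_grid(d, sp, origin))
}

#' Write a projection set (multi-page TIFF + JSON geometry sidecar)
#'
#' Frames are affinely rescaled to the unit interval for 32-bit TIFF storage;
#' the offset/scale pair is recorded in the sidecar so reads restore the
#' original line-integral values (round-trip error below one part in 2^32 of
#' the dynamic range).
#'
#' @param pset A [projection_set()].
#' @param path Output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_projections <- function(pset, path) {
  stopifnot(inherits(pset, "projection_set"))
  g <- pset$geometry
  lo <- min(pset$frames); hi <- max(pset$frames)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(pset$frames)[3]), function(k) {
    (pset$frames[, , k] - lo) / scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    sad = g$sad, sdd = g$sdd, n_u = g$n_u, n_v = g$n_v,
    pixel_u = g$pixel_u, pixel_v = g$pixel_v,
    fan_mode = g$fan_mode, detector_offset_u = g$detector_offset_u,
    angles = g$angles, times = g$times,
    intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projection set written by [write_projections()]
#'
#' @param path Path to the multi-page TIFF; `<path>.json` must exist.
#' @return A [projection_set()].
#' @export
read_projections <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("read_projections: file not found: ", path)
  if (!file.exists(sidecar_path)) {
    stop("read_projections: geometry sidecar not found: ", sidecar_path)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  geom <- scan_geometry(sad = sc$sad, sdd = sc$sdd, n_u = sc$n_u, n_v = sc$n_v,
                        pixel_u = sc$pixel_u, pixel_v = sc$pixel_v,
                        angles = sc$angles, times = sc$times,
                        fan_mode = sc$fan_mode,
                        detector_offset_u = sc$detector_offset_u)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(geom$angles)) {
    stop("read_projections: frame count (", length(pages),
         ") != angle count (", length(geom$angles), ")")
  }
  frames <- simplify2array(pages) * sc$intensity_scale + sc$intensity_offset
  projection_set(frames, geom)
}

#' Write a breathing trace as CSV (columns `time_s`, `si_mm`)
#' @param trace A [breathing_trace()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(time_s = trace$times, si_mm = trace$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a breathing trace CSV written by [write_trace()]
#' @param path CSV path.
#' @param scenario Scenario label to attach.
#' @return A [breathing_trace()].
#' @export
read_trace <- function(path, scenario = "S1") {
  df <- read.csv(path)
  breathing_trace(df$time_s, df$si_mm, scenario)
}

#' Save / load a Gaussian set
#'
#' Serialized with R's native serialization as a plain list of named arrays
#' `positions` (M x 3, mm), `densities` (M or M x 3), `scales` (M x 3, mm),
#' `quaternions` (M x 4, unit), so the file is inspectable with `readRDS()`.
#'
#' @param gset A [gaussian_set()].
#' @param path Output `.rds` path.
#' @return Invisibly, `path`.
#' @export
write_gaussian_set <- function(gset, path) {
  stopifnot(inherits(gset, "gaussian_set"))
  saveRDS(list(positions = gset$positions, densities = gset$densities,
               scales = gset$scales, quaternions = gset$quaternions), path)
  invisible(path)
}

#' @rdname write_gaussian_set
#' @export
read_gaussian_set <- function(path) {
  x <- readRDS(path)
  gaussian_set(x$positions, x$densities, x$scales, x$quaternions)
}
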