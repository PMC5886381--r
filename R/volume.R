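#' 3-D scalar volume with physical metadata
#'
#' A `gf_volume` is the basic image container of the package: a 3-D numeric
#' array of intensities together with per-axis voxel spacing (mm) and the
#' physical position of voxel `(0, 0, 0)` (mm). Voxel indices are 0-based in
#' the physical mapping `physical = origin + index * spacing`; within R,
#' arrays are indexed 1-based as usual, so R index `i` sits at physical
#' position `origin + (i - 1) * spacing`.
#'
#' @param data numeric 3-D array of finite intensities, at least 2 voxels
#'   per axis.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @return An object of class `gf_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- volume3d(array(rnorm(4^3), c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(v$data)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got ", length(dim(data)), " dimensions")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis")
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("volume intensities must be finite (no NA/NaN/Inf)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "gf_volume")
}

#' @export
print.gf_volume <- function(x, ...) {
  cat("<gf_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  cat("  intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

is_volume <- function(x) inherits(x, "gf_volume")

# accept a gf_volume or a bare array; return the array
vol_data <- function(x) {
  if (is_volume(x)) x$data else as.array(x)
}

same_grid <- function(a, b) {
  identical(dim(vol_data(a)), dim(vol_data(b)))
}

file_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p) || grepl("\\.nii$", p)) return("nifti")
  if (grepl("\\.mha$", p)) return("mha")
  if (grepl("\\.mhd$", p)) return("mhd")
  stop("unsupported volume format for '", path,
       "' (expected .nii, .nii.gz, .mha or .mhd)")
}

# ---------------------------------------------------------------------------
# NIfTI backend (RNifti)
# ---------------------------------------------------------------------------

nifti_read_raw <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.double(img), dim(img)) # strip niftiImage attributes
  nd <- length(dim(arr))
  pd <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  offd <- xf[1:3, 1:3]
  diag(offd) <- 0
  if (any(abs(offd) > 1e-6 * max(abs(pd))))
    stop("volume has non-axis-aligned direction cosines; ",
         "resample to an axis-aligned grid before loading")
  if (any(diag(xf[1:3, 1:3]) < 0))
    stop("volume has flipped (negative) direction cosines; ",
         "resample to an axis-aligned grid before loading")
  list(data = arr, spacing = as.numeric(pd[1:3]),
       origin = as.numeric(xf[1:3, 4]), ndim = nd)
}

nifti_write_raw <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing[seq_len(min(length(dim(arr)), 3L))]
  aff <- diag(c(spacing[1:3], 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# MetaImage backend (.mha single-file, .mhd header + raw). The format is a
# plain key = value text header followed by (or pointing at) a raw block in
# x-fastest order, which matches R's column-major layout directly.
# ---------------------------------------------------------------------------

meta_types <- list(
  MET_DOUBLE = list(what = "double", size = 8L),
  MET_FLOAT  = list(what = "double", size = 4L),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_LONG   = list(what = "integer", size = 8L, signed = TRUE)
)

meta_read_raw <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10L))
  hdr <- list()
  data_offset <- NA_integer_
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw[start:(pos - 1L)])
    line <- sub("\r$", "", line)
    start <- pos + 1L
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) == 3L) hdr[[kv[2]]] <- kv[3]
    if (length(kv) == 3L && kv[2] == "ElementDataFile") {
      data_offset <- start
      break
    }
  }
  if (is.null(hdr$ElementDataFile))
    stop("malformed MetaImage header in '", path, "': no ElementDataFile")
  if (!is.null(hdr$CompressedData) &&
      tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage data is not supported")
  ndims <- as.integer(hdr$NDims %||% "3")
  dims <- as.integer(strsplit(trimws(hdr$DimSize), "\\s+")[[1]])
  if (length(dims) != ndims) stop("MetaImage DimSize does not match NDims")
  nchan <- as.integer(hdr$ElementNumberOfChannels %||% "1")
  spacing <- as.numeric(strsplit(trimws(hdr$ElementSpacing %||%
                                          hdr$ElementSize %||%
                                          paste(rep("1", ndims), collapse = " ")),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(hdr$Offset %||% hdr$Position %||%
                                         paste(rep("0", ndims), collapse = " ")),
                                "\\s+")[[1]])
  if (!is.null(hdr$TransformMatrix)) {
    tm <- as.numeric(strsplit(trimws(hdr$TransformMatrix), "\\s+")[[1]])
    if (max(abs(tm - as.vector(diag(ndims)))) > 1e-6)
      stop("MetaImage with non-identity TransformMatrix is not supported; ",
           "resample to an axis-aligned grid before loading")
  }
  tname <- hdr$ElementType %||% "MET_DOUBLE"
  tinfo <- meta_types[[tname]]
  if (is.null(tinfo)) stop("unsupported MetaImage ElementType: ", tname)
  endian <- if (!is.null(hdr$BinaryDataByteOrderMSB) &&
                tolower(hdr$BinaryDataByteOrderMSB) == "true") "big" else "little"
  n <- prod(dims) * nchan
  src <- hdr$ElementDataFile
  if (toupper(src) == "LOCAL") {
    payload <- raw[data_offset:length(raw)]
    vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                    signed = isTRUE(tinfo$signed) || tinfo$size > 2L,
                    endian = endian)
  } else {
    dfile <- file.path(dirname(path), src)
    if (!file.exists(dfile)) stop("MetaImage data file not found: ", dfile)
    vals <- readBin(dfile, tinfo$what, n = n, size = tinfo$size,
                    signed = isTRUE(tinfo$signed) || tinfo$size > 2L,
                    endian = endian)
  }
  if (length(vals) != n) stop("truncated MetaImage data in '", path, "'")
  vals <- as.double(vals)
  if (nchan > 1L) {
    arr <- aperm(array(vals, c(nchan, dims)), c(seq_along(dims) + 1L, 1L))
  } else {
    arr <- array(vals, dims)
  }
  list(data = arr, spacing = spacing, origin = origin, ndim = ndims,
       nchannels = nchan)
}

meta_write_raw <- function(arr, spacing, origin, path, nchannels = 1L) {
  dims <- dim(arr)
  if (nchannels > 1L) {
    stopifnot(dims[length(dims)] == nchannels)
    sdims <- dims[-length(dims)]
    vals <- as.vector(aperm(arr, c(length(dims), seq_len(length(dims) - 1L))))
  } else {
    sdims <- dims
    vals <- as.vector(arr)
  }
  nd <- length(sdims)
  ext <- tolower(tools::file_ext(path))
  hdr <- c(
    "ObjectType = Image",
    paste("NDims =", nd),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(as.vector(diag(nd)), collapse = " ")),
    paste("Offset =", paste(format(origin[seq_len(nd)], digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing[seq_len(nd)], digits = 17), collapse = " ")),
    paste("DimSize =", paste(sdims, collapse = " ")),
    if (nchannels > 1L) paste("ElementNumberOfChannels =", nchannels),
    "ElementType = MET_DOUBLE"
  )
  if (ext == "mhd") {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c(hdr, paste("ElementDataFile =", rawname))
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(as.double(vals), con, size = 8L, endian = "little")
  } else {
    hdr <- c(hdr, "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.double(vals), con, size = 8L, endian = "little")
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Public I/O
# ---------------------------------------------------------------------------

#' Read a 3-D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage
#' (`.mha`, `.mhd`). Spacing and origin are taken from the file header;
#' only axis-aligned grids (identity direction cosines) are accepted.
#'
#' @param path path to the volume file.
#' @return A [volume3d()] object.
#' @seealso [write_volume()], [read_field()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- file_format(path)
  raw <- if (fmt == "nifti") nifti_read_raw(path) else meta_read_raw(path)
  if (length(dim(raw$data)) != 3L) {
    # tolerate trailing singleton dimensions (some writers pad to 4-D)
    d <- dim(raw$data)
    if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
      raw$data <- array(raw$data, d[1:3])
    } else {
      stop("expected a 3-D scalar volume, got dimensions ",
           paste(dim(raw$data), collapse = " x "),
           " (use read_field() for vector fields)")
    }
  }
  if (any(!is.finite(raw$data)))
    stop("volume in '", path, "' contains non-finite intensities")
  volume3d(raw$data, raw$spacing[1:3], raw$origin[1:3])
}

#' Write a 3-D volume to NIfTI or MetaImage
#'
#' Data are stored as 64-bit floating point in both formats so that
#' write-then-read round-trips are lossless.
#'
#' @param volume a [volume3d()] object.
#' @param path output path; format chosen by extension
#'   (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume(volume))
  if (any(!is.finite(volume$data)))
    stop("refusing to write volume with non-finite intensities")
  fmt <- file_format(path)
  if (fmt == "nifti") {
    nifti_write_raw(volume$data, volume$spacing, volume$origin, path)
  } else {
    meta_write_raw(volume$data, volume$spacing, volume$origin, path)
  }
  invisible(path)
}

#' Read landmarks from a plain-text file
#'
#' One point per line, `x y z` in physical mm, comma- or
#' whitespace-delimited. Lines starting with `#` and blank lines are
#' ignored. A fourth column, when present, is kept as a point label.
#'
#' @param path path to the landmark file.
#' @return A data frame of class `gf_landmarks` with columns
#'   `x`, `y`, `z` (mm) and `label`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  pts <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ln <- lines[idx[i]]
    tok <- strsplit(trimws(ln), "[,;[:space:]]+")[[1]]
    if (length(tok) < 3L)
      stop("landmark parse error at line ", idx[i], ": need 3 coordinates")
    xyz <- suppressWarnings(as.numeric(tok[1:3]))
    if (any(is.na(xyz)))
      stop("landmark parse error at line ", idx[i],
           ": non-numeric coordinate in '", ln, "'")
    lab <- if (length(tok) >= 4L) paste(tok[-(1:3)], collapse = " ") else
      as.character(i)
    pts[[i]] <- data.frame(x = xyz[1], y = xyz[2], z = xyz[3], label = lab,
                           stringsAsFactors = FALSE)
  }
  out <- if (length(pts)) do.call(rbind, pts) else
    data.frame(x = numeric(), y = numeric(), z = numeric(),
               label = character(), stringsAsFactors = FALSE)
  class(out) <- c("gf_landmarks", "data.frame")
  out
}

#' Write landmarks to a plain-text file
#'
#' @param landmarks data frame with columns `x`, `y`, `z` (mm) and
#'   optionally `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  lab <- if ("label" %in% names(landmarks)) landmarks$label else
    as.character(seq_len(nrow(landmarks)))
  lines <- sprintf("%.10g %.10g %.10g %s",
                   landmarks$x, landmarks$y, landmarks$z, lab)
  writeLines(c("# x y z label (mm)", lines), path)
  invisible(path)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear resampling onto an isotropic grid with the same origin. The
#' output size per axis is `round((n - 1) * spacing / target) + 1`
#' (node-centered: the physical extent between first and last voxel centers
#' is preserved up to rounding).
#'
#' @param volume a [volume3d()] object.
#' @param target_spacing positive scalar, target voxel size in mm.
#' @return A resampled [volume3d()] with spacing
#'   `c(target_spacing, target_spacing, target_spacing)`.
#' @export
resample_isotropic <- function(volume, target_spacing) {
  stopifnot(is_volume(volume), length(target_spacing) == 1L,
            is.finite(target_spacing), target_spacing > 0)
  d <- dim(volume$data)
  nd <- pmax(2L, as.integer(round((d - 1) * volume$spacing / target_spacing)) + 1L)
  # continuous source voxel coordinate of each target voxel, per axis
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) * target_spacing / volume$spacing[a])
  xs <- rep(ax[[1]], times = nd[2] * nd[3])
  ys <- rep(rep(ax[[2]], each = nd[1]), times = nd[3])
  zs <- rep(ax[[3]], each = nd[1] * nd[2])
  vals <- cpp_trilinear(as.vector(volume$data), d, xs, ys, zs)
  volume3d(array(vals, nd), rep(target_spacing, 3), volume$origin)
}

#' Clip intensities to percentiles and rescale to [0, 1]
#'
#' Intensities are clipped to the `low` and `high` percentiles (type-7
#' quantiles) and then mapped affinely onto `[0, 1]`. A constant volume has
#' no usable range and is returned as all zeros with a warning.
#'
#' @param volume a [volume3d()] object.
#' @param low,high percentiles in `[0, 100]` with `low < high`.
#' @return A [volume3d()] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(volume, low = 0, high = 100) {
  stopifnot(is_volume(volume), low >= 0, high <= 100, low < high)
  q <- stats::quantile(volume$data, c(low, high) / 100, names = FALSE, type = 7)
  if (q[2] - q[1] <= 0) {
    warning("degenerate intensity range; returning all-zero volume")
    return(volume3d(array(0, dim(volume$data)), volume$spacing, volume$origin))
  }
  x <- pmin(pmax(volume$data, q[1]), q[2])
  volume3d((x - q[1]) / (q[2] - q[1]), volume$spacing, volume$origin)
}
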