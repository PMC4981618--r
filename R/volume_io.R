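# Volume containers and NIfTI-1 input/output.
#
# All computation in the package happens in voxel space on one shared grid:
# inputs are contractually co-registered and the orientation/affine part of
# the header is carried along opaquely, never used for resampling.

FWHM_TO_SIGMA <- 2 * sqrt(2 * log(2)) # 2.3548...

#' 3D scalar volume
#'
#' Lightweight carrier for a 3D image: a numeric array plus voxel spacing in
#' mm. The (opaque) 348-byte NIfTI-1 header is preserved when the volume was
#' read from disk so that orientation metadata survives a round-trip.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param header optional raw(348) NIfTI-1 header to preserve on write.
#' @return object of class `wml_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), header = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got dimensions: ",
         paste(dim(data), collapse = "x"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  structure(list(data = data, spacing = spacing, header = header),
            class = "wml_volume")
}

#' Binary mask on a volume grid
#'
#' @param data 3D array with values in {0, 1} (logical accepted).
#' @inheritParams volume
#' @return object of class `wml_mask` (inherits `wml_volume`).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), header = NULL) {
  if (is.logical(data)) {
    d <- dim(data)
    data <- array(as.integer(data), dim = d)
  }
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be in {0,1}; found: ",
         paste(utils::head(setdiff(vals, c(0, 1)), 5), collapse = ", "))
  v <- volume(array(as.integer(data), dim = dim(data)), spacing, header)
  class(v) <- c("wml_mask", class(v))
  v
}

#' @export
print.wml_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, range [%g, %g]\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "wml_volume")

grid_str <- function(v) {
  sprintf("%s @ %s mm", paste(dim(v$data), collapse = "x"),
          paste(signif(v$spacing, 6), collapse = "x"))
}

#' Enforce the co-registration contract
#'
#' Registration itself is out of scope: all volumes entering the pipeline
#' must already live on one grid. This checks shapes and voxel spacings
#' (spacing tolerance 1e-3 mm) and fails loudly otherwise.
#'
#' @param vols list of `wml_volume` / `wml_mask` objects (NULLs are skipped).
#' @return invisibly TRUE; errors on any mismatch naming both grids.
#' @export
assert_coregistered <- function(vols) {
  vols <- Filter(Negate(is.null), vols)
  if (length(vols) == 0L) stop("assert_coregistered: empty volume list")
  ref <- vols[[1L]]
  for (v in vols[-1L]) {
    if (!identical(dim(v$data), dim(ref$data)) ||
        any(abs(v$spacing - ref$spacing) > 1e-3))
      stop("volumes are not co-registered: [", grid_str(ref), "] vs [",
           grid_str(v), "]")
  }
  invisible(TRUE)
}

# ---- NIfTI-1 low-level ------------------------------------------------------

nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L),
  `256` = list(what = "integer", size = 1L, signed = TRUE,  bitpix = 8L),
  `512` = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L))

read_all_bytes <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  out <- list()
  repeat {
    chunk <- readBin(con, "raw", n = 1048576L)
    if (length(chunk) == 0L) break
    out[[length(out) + 1L]] <- chunk
  }
  do.call(c, out)
}

hdr_field <- function(raw, offset, what, n, size, signed = TRUE, endian) {
  readBin(raw[(offset + 1L):(offset + n * size)], what, n = n, size = size,
          signed = signed, endian = endian)
}

#' Read a NIfTI-1 volume
#'
#' Supports `.nii` and `.nii.gz`, little- and big-endian files, and the
#' common scalar datatypes (uint8/int8, int16/uint16, int32, float32,
#' float64). `scl_slope`/`scl_inter` scaling is applied. Only 3D images are
#' accepted; a 4D time series is an error.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `wml_volume` with spacing from the header and the raw header kept.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  raw <- read_all_bytes(path)
  if (length(raw) < 352L) stop("read_volume: not a NIfTI-1 file (too short): ", path)
  endian <- "little"
  if (hdr_field(raw, 0L, "integer", 1L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (hdr_field(raw, 0L, "integer", 1L, 4L, endian = endian) != 348L)
      stop("read_volume: not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_volume: not a NIfTI-1 file (bad magic '", magic, "'): ", path)
  dims <- hdr_field(raw, 40L, "integer", 8L, 2L, endian = endian)
  ndim <- dims[1L]
  shape <- dims[seq(2L, 1L + max(ndim, 1L))]
  if (ndim > 3L && any(shape[-(1:3)] > 1L))
    stop("read_volume: expected a 3D image, got ", ndim, "D with shape ",
         paste(shape, collapse = "x"), ": ", path)
  if (ndim < 3L) shape <- c(shape, rep(1L, 3L - ndim))
  shape <- shape[1:3]
  datatype <- hdr_field(raw, 70L, "integer", 1L, 2L, endian = endian)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("read_volume: unsupported NIfTI datatype code ", datatype)
  pixdim <- hdr_field(raw, 76L, "double", 8L, 4L, endian = endian)
  vox_offset <- hdr_field(raw, 108L, "double", 1L, 4L, endian = endian)
  scl_slope <- hdr_field(raw, 112L, "double", 1L, 4L, endian = endian)
  scl_inter <- hdr_field(raw, 116L, "double", 1L, 4L, endian = endian)
  n <- prod(shape)
  off <- as.integer(round(vox_offset))
  need <- off + n * dt$size
  if (length(raw) < need)
    stop("read_volume: truncated data section in ", path)
  vals <- readBin(raw[(off + 1L):need], dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- pixdim[2:4]
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  volume(array(as.double(vals), dim = shape), spacing, header = raw[1:348])
}

put_field <- function(hdr, offset, values, what, size) {
  b <- writeBin(if (what == "integer") as.integer(values) else as.double(values),
                raw(), size = size, endian = "little")
  hdr[(offset + 1L):(offset + length(b))] <- b
  hdr
}

build_nifti_header <- function(vol, datatype, bitpix) {
  hdr <- if (!is.null(vol$header) && length(vol$header) == 348L) vol$header
         else raw(348L)
  hdr <- put_field(hdr, 0L, 348L, "integer", 4L)
  hdr <- put_field(hdr, 40L, c(3L, dim(vol$data), 1L, 1L, 1L, 1L), "integer", 2L)
  hdr <- put_field(hdr, 70L, datatype, "integer", 2L)
  hdr <- put_field(hdr, 72L, bitpix, "integer", 2L)
  hdr <- put_field(hdr, 76L, c(1, vol$spacing, 0, 0, 0, 0), "double", 4L)
  hdr <- put_field(hdr, 108L, 352, "double", 4L)
  hdr <- put_field(hdr, 112L, 1, "double", 4L)  # scl_slope
  hdr <- put_field(hdr, 116L, 0, "double", 4L)  # scl_inter
  if (all(hdr[255:256] == as.raw(0))) {
    # fresh header: write a plain scaled-identity sform and mm units
    hdr <- put_field(hdr, 123L, 2L, "integer", 1L)  # xyzt_units = mm
    hdr <- put_field(hdr, 254L, 1L, "integer", 2L)  # sform_code
    hdr <- put_field(hdr, 280L, c(vol$spacing[1], 0, 0, 0), "double", 4L)
    hdr <- put_field(hdr, 296L, c(0, vol$spacing[2], 0, 0), "double", 4L)
    hdr <- put_field(hdr, 312L, c(0, 0, vol$spacing[3], 0), "double", 4L)
  }
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  hdr
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are stored as float64 (bit-exact round-trip), masks as uint8.
#' A `.gz` suffix triggers transparent gzip compression.
#'
#' @param vol `wml_volume` or `wml_mask`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return invisibly `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  if (!dir.exists(dirname(path)))
    stop("write_volume: parent directory does not exist: ", dirname(path))
  is_mask <- inherits(vol, "wml_mask")
  datatype <- if (is_mask) 2L else 64L
  bitpix <- if (is_mask) 8L else 64L
  hdr <- build_nifti_header(vol, datatype, bitpix)
  con <- tryCatch(
    if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb"),
    error = function(e) stop("write_volume: cannot open ", path, ": ",
                             conditionMessage(e)))
  ok <- FALSE
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)  # extension flag: none
  vals <- as.vector(vol$data)
  tryCatch({
    if (is_mask) writeBin(as.integer(vals), con, size = 1L, endian = "little")
    else writeBin(as.double(vals), con, size = 8L, endian = "little")
  }, error = function(e) stop("write_volume: I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
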