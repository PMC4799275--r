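# Raw headered array (".ctp4d", little-endian): a minimal exact container
# for uncompressed dynamic volumes, used by the phantom tools and the CLI.
#   magic "CTPRAW4D", u32 version, u32 Z, Y, X, n,
#   u8 has_times [+ n doubles], int16 data in (t, z, y, x) order, t fastest.

RAW_MAGIC <- "CTPRAW4D"

#' Write a dynamic image as a raw headered array
#'
#' A minimal little-endian binary format: an eight-byte magic tag, geometry,
#' optional acquisition times, then the int16 intensities with `t` varying
#' fastest. Round-trips bit-exactly through [read_raw_array()].
#'
#' @param img A [dynamic_image()].
#' @param path Output path (conventionally `.ctp4d`).
#' @return Number of bytes written, invisibly.
#' @export
write_raw_array <- function(img, path) {
  if (!inherits(img, "dynamic_image")) stop_domain("'img' must be a dynamic_image")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(RAW_MAGIC), con)
  write_u32(con, 1)
  write_u32(con, img$shape[1]); write_u32(con, img$shape[2])
  write_u32(con, img$shape[3]); write_u32(con, img$n)
  writeBin(as.integer(!is.null(img$times)), con, size = 1L)
  if (!is.null(img$times))
    writeBin(as.numeric(img$times), con, size = 8L, endian = "little")
  writeBin(as.vector(img$data), con, size = 2L, endian = "little")
  invisible(file.size(path))
}

#' Read a dynamic image from a raw headered array
#'
#' @param path Path written by [write_raw_array()].
#' @return A [dynamic_image()].
#' @export
read_raw_array <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 8L)
  if (length(magic) != 8L || !identical(rawToChar(magic), RAW_MAGIC))
    stop_corrupt("not a raw headered array (bad magic tag)")
  version <- read_u32(con)
  if (version > 1) stop_corrupt(sprintf("unsupported raw array version %d", version))
  g <- read_u32(con, 4L)
  Z <- g[1]; Y <- g[2]; X <- g[3]; n <- g[4]
  times <- NULL
  if (read_exact(con, integer(), 1L, 1L) != 0L)
    times <- read_exact(con, numeric(), n, 8L)
  data <- read_exact(con, integer(), n * Z * Y * X, 2L)
  dim(data) <- c(n, Z, Y, X)
  dynamic_image(data, times = times)
}

#' Write a dynamic image as 4D NIfTI
#'
#' Stores the series as a NIfTI-1 file with int16 voxels, dimension order
#' `(x, y, z, t)` as the format prescribes.
#'
#' @param img A [dynamic_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_nifti_image <- function(img, path) {
  if (!inherits(img, "dynamic_image")) stop_domain("'img' must be a dynamic_image")
  arr <- aperm(img$data, c(4, 3, 2, 1)) # (t,z,y,x) -> (x,y,z,t)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  invisible(path)
}

read_nifti_image <- function(path) {
  arr <- RNifti::readNifti(path)
  arr <- unclass(arr)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop_io("NIfTI file does not hold a 3D/4D volume")
  storage.mode(arr) <- "integer"
  dynamic_image(aperm(arr, c(4, 3, 2, 1)))
}

#' Write a mask volume as 8-bit NIfTI
#'
#' @param mask A `mask_volume` (3D reduction or 4D per-timestep).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  if (!inherits(mask, "mask_volume")) stop_domain("'mask' must be a mask_volume")
  arr <- array(as.integer(mask), dim = dim(mask))
  perm <- if (length(dim(arr)) == 4L) c(4, 3, 2, 1) else c(3, 2, 1)
  arr <- aperm(arr, perm)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' Load a dynamic image from any supported input
#'
#' Dispatches on `format` or, for `"auto"`, on the input itself: a directory
#' is read as a DICOM series, files with a recognised magic tag as raw
#' headered arrays, and `.nii`/`.nii.gz` files as NIfTI. Stored pixel values
#' are used verbatim — no rescale slope/intercept is applied (any DICOM
#' rescale information is recorded in the result's `provenance` attribute).
#'
#' @param path File or directory path.
#' @param format One of `"auto"`, `"raw"`, `"nifti"`, `"dicom"`.
#' @return A [dynamic_image()].
#' @export
load_dynamic_image <- function(path, format = c("auto", "raw", "nifti",
                                                "dicom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "dicom"
    } else if (grepl("\\.nii(\\.gz)?$", path)) {
      "nifti"
    } else {
      "raw"
    }
  }
  switch(format,
    raw = read_raw_array(path),
    nifti = read_nifti_image(path),
    dicom = read_dicom_series(path)
  )
}
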