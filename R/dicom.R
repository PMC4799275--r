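# Minimal DICOM support.  No DICOM package ships with this toolchain, so the
# package carries a deliberately small reader for uncompressed Explicit VR
# Little Endian series (the transfer syntax of raw CT exports): top-level
# elements only, no sequences with undefined length, pixel data as int16.
# The companion writer emits *synthetic* single-frame files in exactly that
# subset — enough for fixtures and phantom export, not a general DICOM writer.

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
TSUID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# parse one file; returns the fields the series reader needs
parse_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, raw(), n = 132L)
  if (length(pre) != 132L || !identical(rawToChar(pre[129:132]), "DICM"))
    stop_io(sprintf("%s: not a DICOM part-10 file (missing DICM tag)", path))
  out <- list(path = path)
  repeat {
    hdr <- readBin(con, integer(), n = 2L, size = 2L, signed = FALSE,
                   endian = "little")
    if (length(hdr) < 2L) break
    group <- hdr[1]; elem <- hdr[2]
    vr <- rawToChar(readBin(con, raw(), n = 2L))
    if (vr %in% LONG_VRS) {
      readBin(con, raw(), n = 2L) # reserved
      len <- read_u32(con)
    } else {
      len <- as.numeric(readBin(con, integer(), n = 1L, size = 2L,
                                signed = FALSE, endian = "little"))
    }
    if (len == 4294967295)
      stop_io(sprintf("%s: undefined-length element (%04X,%04X) unsupported",
                      path, group, elem))
    tag <- sprintf("%04X%04X", group, elem)
    if (tag == "7FE00010") {
      if (vr != "OW" && vr != "OB")
        stop_io(sprintf("%s: unexpected pixel data VR '%s'", path, vr))
      out$pixels <- readBin(con, integer(), n = len / 2, size = 2L,
                            signed = TRUE, endian = "little")
      if (length(out$pixels) != len / 2)
        stop_io(sprintf("%s: truncated pixel data", path))
      break
    }
    value <- readBin(con, raw(), n = len)
    if (length(value) != len)
      stop_io(sprintf("%s: truncated element (%04X,%04X)", path, group, elem))
    if (vr == "US") {
      v <- readBin(value, integer(), n = len / 2, size = 2L, signed = FALSE,
                   endian = "little")
    } else if (vr %in% c("IS", "DS", "TM", "UI", "CS", "LO", "SH")) {
      v <- trimws(rawToChar(value[value != as.raw(0)])) # strip NUL padding
    } else {
      v <- value # keep unparsed
    }
    out[[tag]] <- v
  }
  if (!is.null(out[["00020010"]]) &&
      out[["00020010"]] != TSUID_EXPLICIT_LE)
    stop_io(sprintf("%s: unsupported transfer syntax %s (only %s)",
                    path, out[["00020010"]], TSUID_EXPLICIT_LE))
  if (is.null(out$pixels)) stop_io(sprintf("%s: no pixel data", path))
  need <- c(rows = "00280010", cols = "00280011", bits = "00280100")
  for (k in names(need))
    if (is.null(out[[need[[k]]]]))
      stop_io(sprintf("%s: missing %s element", path, k))
  if (out[["00280100"]][1] != 16L)
    stop_io(sprintf("%s: only 16 bits/voxel supported", path))
  out
}

num_or_na <- function(x) if (is.null(x)) NA_real_ else suppressWarnings(as.numeric(x))

#' Load a DICOM series directory as a dynamic image
#'
#' Reads every file in `dir` (uncompressed Explicit VR Little Endian,
#' single-frame), groups slices into time steps and sorts them by slice
#' location. The grouping key preference is: Temporal Position Identifier
#' (0020,0100) when present on all files, else Acquisition Time (0008,0032),
#' else contiguous Instance Number blocks of one volume each (slice count
#' inferred from the number of distinct slice locations). Stored pixel values
#' are used verbatim; rescale slope/intercept, when present, are recorded in
#' the result's `provenance` attribute but never applied.
#'
#' @param dir Directory holding one series.
#' @param group_by Override the grouping key: `"auto"`, `"temporal_position"`,
#'   `"acquisition_time"` or `"instance_blocks"`.
#' @return A [dynamic_image()] of shape `(n, Z, Y, X)`.
#' @export
read_dicom_series <- function(dir, group_by = c("auto", "temporal_position",
                                                "acquisition_time",
                                                "instance_blocks")) {
  group_by <- match.arg(group_by)
  if (!dir.exists(dir)) stop_io(sprintf("no such directory: %s", dir))
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop_io(sprintf("no files in %s", dir))
  slices <- lapply(sort(files), parse_dicom_file)

  rows <- vapply(slices, function(s) as.integer(s[["00280010"]][1]), 1L)
  cols <- vapply(slices, function(s) as.integer(s[["00280011"]][1]), 1L)
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L)
    stop_io("mixed slice geometry across the series")
  Y <- rows[1]; X <- cols[1]
  loc  <- vapply(slices, function(s) num_or_na(s[["00201041"]]), 1)
  tpos <- vapply(slices, function(s) num_or_na(s[["00200100"]]), 1)
  acqt <- vapply(slices, function(s) num_or_na(s[["00080032"]]), 1)
  inst <- vapply(slices, function(s) num_or_na(s[["00200013"]]), 1)

  if (group_by == "auto") {
    group_by <- if (!anyNA(tpos)) "temporal_position"
                else if (!anyNA(acqt) && length(unique(acqt)) > 1L) "acquisition_time"
                else "instance_blocks"
  }
  key <- switch(group_by,
    temporal_position = tpos,
    acquisition_time = acqt,
    instance_blocks = {
      if (anyNA(inst)) stop_io("instance numbers required for block grouping")
      Zg <- length(unique(loc[!is.na(loc)]))
      if (Zg < 1L || length(slices) %% Zg != 0L)
        stop_io("cannot infer time steps from instance-number blocks")
      ord <- order(inst)
      k <- numeric(length(slices))
      k[ord] <- rep(seq_len(length(slices) / Zg), each = Zg)
      k
    }
  )
  if (anyNA(key)) stop_io("missing temporal metadata for the chosen grouping")
  tlevels <- sort(unique(key))
  n <- length(tlevels)
  Z <- length(slices) / n
  if (Z != round(Z)) stop_io("unequal number of slices per time step")
  Z <- as.integer(Z)
  data <- array(0L, dim = c(n, Z, Y, X))
  for (ti in seq_len(n)) {
    idx <- which(key == tlevels[ti])
    idx <- idx[order(loc[idx], inst[idx])]
    if (length(idx) != Z) stop_io("unequal number of slices per time step")
    for (zi in seq_len(Z)) {
      s <- slices[[idx[zi]]]
      if (length(s$pixels) != Y * X)
        stop_io(sprintf("%s: pixel count does not match rows x columns", s$path))
      data[ti, zi, , ] <- t(matrix(s$pixels, nrow = X, ncol = Y)) # row-major
    }
  }
  img <- dynamic_image(data,
                       times = if (group_by == "acquisition_time" &&
                                   !is.unsorted(tlevels, strictly = TRUE) &&
                                   all(tlevels >= 0)) tlevels else NULL)
  attr(img, "provenance") <- list(
    format = "dicom", grouping = group_by, files = length(slices),
    rescale_intercept = num_or_na(slices[[1]][["00281052"]]),
    rescale_slope = num_or_na(slices[[1]][["00281053"]])
  )
  img
}

# ---- synthetic writer -----------------------------------------------------

pad_even <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2L) c(x, pad) else x
}

dcm_element <- function(group, elem, vr, value_raw) {
  value_raw <- pad_even(value_raw, if (vr %in% c("UI", "OB")) as.raw(0) else as.raw(0x20))
  rc <- rawConnection(raw(0), "wb")
  on.exit(close(rc))
  writeBin(as.integer(c(group, elem)), rc, size = 2L, endian = "little")
  writeBin(charToRaw(vr), rc)
  if (vr %in% LONG_VRS) {
    writeBin(raw(2), rc)
    write_u32(rc, length(value_raw))
  } else {
    writeBin(as.integer(length(value_raw)), rc, size = 2L, endian = "little")
  }
  writeBin(value_raw, rc)
  rawConnectionValue(rc)
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us  <- function(group, elem, v) {
  dcm_element(group, elem, "US", writeBin(as.integer(v), raw(), size = 2L,
                                          endian = "little"))
}

#' Write a dynamic image as a synthetic DICOM series
#'
#' Emits one minimal single-frame Explicit-VR-little-endian file per
#' `(t, z)` slice, carrying only the elements [read_dicom_series()] consumes
#' (geometry, temporal position, acquisition time, instance number, slice
#' location, identity rescale, pixel data). These files are synthetic test
#' fixtures — intentionally not complete, conformant clinical DICOM objects.
#'
#' @param img A [dynamic_image()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_synthetic_dicom_series <- function(img, dir) {
  if (!inherits(img, "dynamic_image")) stop_domain("'img' must be a dynamic_image")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Z <- img$shape[1]; Y <- img$shape[2]; X <- img$shape[3]
  times <- if (!is.null(img$times)) img$times else (seq_len(img$n) - 1)
  for (t in seq_len(img$n)) {
    for (z in seq_len(Z)) {
      meta_ts <- dcm_str(0x0002, 0x0010, "UI", TSUID_EXPLICIT_LE)
      meta_len <- dcm_element(0x0002, 0x0000, "UL",
                              writeBin(length(meta_ts), raw(), size = 4L,
                                       endian = "little"))
      slice <- img$data[t, z, , ] # (Y, X); DICOM pixel order is row-major
      pix <- writeBin(as.vector(t(slice)), raw(), size = 2L,
                      endian = "little")
      body <- c(
        dcm_str(0x0008, 0x0032, "TM", sprintf("%.3f", times[t])),
        dcm_str(0x0020, 0x0013, "IS", as.character((t - 1L) * Z + z)),
        dcm_str(0x0020, 0x0100, "IS", as.character(t)),
        dcm_str(0x0020, 0x1041, "DS", sprintf("%.1f", 5 * (z - 1))),
        dcm_us(0x0028, 0x0002, 1L),
        dcm_us(0x0028, 0x0010, Y),
        dcm_us(0x0028, 0x0011, X),
        dcm_us(0x0028, 0x0100, 16L),
        dcm_us(0x0028, 0x0101, 16L),
        dcm_us(0x0028, 0x0102, 15L),
        dcm_us(0x0028, 0x0103, 1L),
        dcm_str(0x0028, 0x1052, "DS", "0"),
        dcm_str(0x0028, 0x1053, "DS", "1"),
        dcm_element(0x7FE0, 0x0010, "OW", pix)
      )
      path <- file.path(dir, sprintf("t%03d_z%03d.dcm", t, z))
      con <- file(path, "wb")
      writeBin(c(raw(128L), charToRaw("DICM"), meta_len, meta_ts, body), con)
      close(con)
    }
  }
  invisible(dir)
}
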