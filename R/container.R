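# On-disk container for compressed images (".dicopp", format version 1).
# All multi-byte fields are little-endian.  Layout:
#   magic "DICOPPIM" (8 bytes)
#   u32 version
#   u32 flags (bit 0: offsets persisted, bit 1: checksum present)
#   u32 Z, Y, X, n
#   u8 has_times  [+ n doubles]
#   u8 has_spacing [+ 3 doubles]
#   u64 byte lengths of the C, B, O, D payloads (0 for O when not persisted)
#   u64 bit length of the delta stream D
#   payloads: C (int16), B (u8), O (u64, optional), D (u32 words)
#   u32 CRC-32 over the concatenated payload bytes (when flagged)
# O is derivable from B by one prefix-sum traversal, so by default it is not
# persisted and is reconstructed on load.

DICOPP_MAGIC <- "DICOPPIM"
DICOPP_VERSION <- 1L

u32_to_int <- function(x) as.integer(ifelse(x >= 2^31, x - 2^32, x))

write_u32 <- function(con, x) {
  writeBin(u32_to_int(as.numeric(x)), con, size = 4L, endian = "little")
}

write_u64 <- function(con, x) {
  x <- as.numeric(x)
  write_u32(con, x %% 2^32)
  write_u32(con, x %/% 2^32)
}

read_u32 <- function(con, n = 1L) {
  v <- readBin(con, integer(), n = n, size = 4L, endian = "little")
  if (length(v) != n) stop_corrupt("truncated container: header cut short")
  v <- as.numeric(v)
  v[v < 0] <- v[v < 0] + 2^32
  v
}

read_u64 <- function(con, n = 1L) {
  v <- read_u32(con, 2L * n)
  v[seq(1, 2 * n, by = 2)] + v[seq(2, 2 * n, by = 2)] * 2^32
}

# serialise the four payloads to raw for checksumming / writing
payload_raw <- function(cim, persist_offsets) {
  rc <- rawConnection(raw(0), "wb")
  on.exit(close(rc))
  writeBin(cim$C, rc, size = 2L, endian = "little")
  writeBin(cim$B, rc, size = 1L)
  if (persist_offsets) {
    writeBin(u32_to_int(cim$O %% 2^32), rc, size = 4L, endian = "little")
    writeBin(u32_to_int(cim$O %/% 2^32), rc, size = 4L, endian = "little")
  }
  writeBin(cim$D$words, rc, size = 4L, endian = "little")
  rawConnectionValue(rc)
}

#' Write a compressed image to a bit-exact container file
#'
#' Serialises the C/B/(O)/D arrays with a self-describing little-endian header
#' and a CRC-32 over the payload. Output is byte-identical for identical
#' input. By default the offset array is not persisted (it is reconstructed
#' from the widths on load); set `persist_offsets = TRUE` to store the 64-bit
#' offsets for direct-mapped use at the cost of 8 bytes per voxel.
#'
#' @param cim A `dicopp_compressed` object.
#' @param path Output file path (conventionally `.dicopp`).
#' @param persist_offsets Store the offset array O in the file?
#' @param checksum Append a CRC-32 over the payload (default `TRUE`)?
#' @return The number of bytes written, invisibly.
#' @seealso [read_container()]
#' @export
write_container <- function(cim, path, persist_offsets = FALSE,
                            checksum = TRUE) {
  if (!inherits(cim, "dicopp_compressed"))
    stop_domain("'cim' must be a dicopp_compressed object")
  validate_compressed(cim)
  m <- prod(cim$shape)
  payload <- payload_raw(cim, persist_offsets)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(DICOPP_MAGIC), con)
  write_u32(con, DICOPP_VERSION)
  flags <- as.numeric(persist_offsets) + 2 * as.numeric(checksum)
  write_u32(con, flags)
  write_u32(con, cim$shape[1]); write_u32(con, cim$shape[2])
  write_u32(con, cim$shape[3]); write_u32(con, cim$n)
  writeBin(as.integer(!is.null(cim$times)), con, size = 1L)
  if (!is.null(cim$times))
    writeBin(as.numeric(cim$times), con, size = 8L, endian = "little")
  writeBin(as.integer(!is.null(cim$spacing)), con, size = 1L)
  if (!is.null(cim$spacing))
    writeBin(as.numeric(cim$spacing), con, size = 8L, endian = "little")
  write_u64(con, 2 * m)
  write_u64(con, m)
  write_u64(con, if (persist_offsets) 8 * m else 0)
  write_u64(con, 4 * length(cim$D$words))
  write_u64(con, cim$D$bit_length)
  writeBin(payload, con)
  if (checksum) write_u32(con, .crc32(payload))
  invisible(file.size(path))
}

read_exact <- function(con, what, n, size, signed = TRUE) {
  v <- readBin(con, what, n = n, size = size, signed = signed,
               endian = "little")
  if (length(v) != n) stop_corrupt("truncated container: payload cut short")
  v
}

#' Read a compressed image from a container file
#'
#' Inverse of [write_container()]. Validates the magic tag, format version,
#' declared array lengths and the payload checksum; offsets are reconstructed
#' via [compute_offsets()] when not persisted, and verified against the
#' widths when they are.
#'
#' @param path Path to a `.dicopp` container.
#' @return A `dicopp_compressed` object.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 8L)
  if (length(magic) != 8L || !identical(rawToChar(magic), DICOPP_MAGIC))
    stop_corrupt("not a dicopp container (bad magic tag)")
  version <- read_u32(con)
  if (version > DICOPP_VERSION)
    stop_corrupt(sprintf("unsupported container version %d (max %d)",
                         version, DICOPP_VERSION))
  flags <- read_u32(con)
  persist_offsets <- bitwAnd(flags, 1) != 0
  has_checksum <- bitwAnd(flags, 2) != 0
  g <- read_u32(con, 4L)
  Z <- g[1]; Y <- g[2]; X <- g[3]; n <- g[4]
  if (any(g < 1)) stop_corrupt("invalid geometry in header")
  m <- Z * Y * X
  times <- NULL
  if (read_exact(con, integer(), 1L, 1L) != 0L)
    times <- read_exact(con, numeric(), n, 8L)
  spacing <- NULL
  if (read_exact(con, integer(), 1L, 1L) != 0L)
    spacing <- read_exact(con, numeric(), 3L, 8L)
  lens <- read_u64(con, 4L)
  bit_length <- read_u64(con)
  if (lens[1] != 2 * m || lens[2] != m)
    stop_corrupt("declared C/B payload lengths do not match geometry")
  if (lens[3] != (if (persist_offsets) 8 * m else 0))
    stop_corrupt("declared O payload length inconsistent with flags")
  payload <- readBin(con, raw(), n = sum(lens))
  if (length(payload) != sum(lens))
    stop_corrupt("truncated container: payload cut short")
  if (has_checksum) {
    crc <- read_u32(con)
    if (crc != .crc32(payload))
      stop_corrupt("checksum mismatch: container payload is damaged")
  }
  pc <- rawConnection(payload, "rb")
  on.exit(close(pc), add = TRUE)
  C <- read_exact(pc, integer(), m, 2L)
  B <- read_exact(pc, integer(), m, 1L, signed = FALSE)
  O <- compute_offsets(B, n)
  if (persist_offsets) {
    lo <- read_u32(pc, m)
    hi <- read_u32(pc, m)
    if (!isTRUE(all.equal(lo + hi * 2^32, O, tolerance = 0)))
      stop_corrupt("persisted offsets disagree with the width array")
  }
  nwords <- lens[4] / 4
  words <- read_exact(pc, integer(), nwords, 4L)
  if (bit_length > 4 * lens[4] * 2 || ceiling(bit_length / 32) != nwords)
    stop_corrupt("delta stream length inconsistent with payload size")
  cim <- new_compressed(C, B, O, bitstream(bit_length, words), n, c(Z, Y, X),
                        times, spacing)
  tryCatch(validate_compressed(cim), dicopp_corrupt_error = function(e) stop(e))
  cim
}
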