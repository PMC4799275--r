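#' Packed bit streams
#'
#' A `bitstream` stores a sequence of bits in 32-bit words, LSB-first: stream
#' bit \eqn{b} occupies bit position \eqn{b \bmod 32} of word
#' \eqn{\lfloor b/32 \rfloor}. Values written with [write_bits()] are encoded
#' little-endian-in-bits, so a field of width \eqn{w} starting at any offset
#' spans at most two words and is recovered with a constant number of shift and
#' mask operations. Bits beyond `bit_length` are guaranteed zero (canonical
#' padding), which makes serialised streams byte-exact.
#'
#' @param nbits Number of valid bits the stream holds (non-negative).
#' @param words Optional integer vector of pre-existing 32-bit words (bit
#'   patterns; R's signed representation is reinterpreted as unsigned).
#' @return An object of class `bitstream` with fields `words` (integer vector)
#'   and `bit_length` (double, exact for lengths far beyond 2^31).
#' @examples
#' bs <- bitstream(64)
#' bs <- write_bits(bs, bit_offset = 10, width = 12, value = 2917)
#' read_bits(bs, 10, 12)
#' @export
bitstream <- function(nbits, words = NULL) {
  nbits <- check_scalar_int(nbits, "nbits")
  if (nbits < 0) stop_domain("'nbits' must be non-negative")
  nwords <- ceiling(nbits / 32)
  if (is.null(words)) {
    words <- integer(nwords)
  } else {
    words <- as.integer(words)
    if (length(words) < nwords)
      stop_domain("'words' holds fewer than ceiling(nbits / 32) elements")
  }
  structure(list(words = words, bit_length = nbits), class = "bitstream")
}

#' @export
print.bitstream <- function(x, ...) {
  cat(sprintf("<bitstream: %.0f bits in %d words>\n",
              x$bit_length, length(x$words)))
  invisible(x)
}

#' @export
length.bitstream <- function(x) x$bit_length

check_width <- function(width) {
  width <- check_scalar_int(width, "width")
  if (width < 0 || width > 32) stop_domain("'width' must be in 0..32")
  as.integer(width)
}

#' Write a variable-width unsigned integer into a bitstream
#'
#' Encodes `value` LSB-first into bits `[bit_offset, bit_offset + width)`.
#' All other bits are unchanged; `width = 0` is a no-op. The stream is treated
#' as immutable: a modified copy is returned.
#'
#' @param stream A [bitstream()].
#' @param bit_offset 0-based bit position of the field's least significant bit.
#' @param width Field width in bits, 0..32.
#' @param value Unsigned integer `< 2^width` (pass as double for widths > 30).
#' @return The modified `bitstream`.
#' @export
write_bits <- function(stream, bit_offset, width, value) {
  stopifnot(inherits(stream, "bitstream"))
  width <- check_width(width)
  bit_offset <- check_scalar_int(bit_offset, "bit_offset")
  value <- check_scalar_int(value, "value")
  if (bit_offset < 0 || bit_offset + width > 32 * length(stream$words))
    stop_bounds("write extends beyond the stream's word capacity")
  if (value < 0 || (width < 32 && value >= 2^width) || value >= 2^32)
    stop_domain(sprintf("value %.0f does not fit in %d bits", value, width))
  if (width == 0L) return(stream)
  stream$words <- .bs_write(stream$words, bit_offset, width, value)
  stream
}

#' Read a variable-width unsigned integer from a bitstream
#'
#' Decodes the LSB-first field at `[bit_offset, bit_offset + width)`. At most
#' two words of the stream are inspected, regardless of stream size; `width = 0`
#' returns 0.
#'
#' @inheritParams write_bits
#' @return The decoded value as a double (exact up to 2^32 - 1).
#' @export
read_bits <- function(stream, bit_offset, width) {
  stopifnot(inherits(stream, "bitstream"))
  width <- check_width(width)
  bit_offset <- check_scalar_int(bit_offset, "bit_offset")
  if (bit_offset < 0 || bit_offset + width > stream$bit_length)
    stop_bounds("read extends beyond the stream's bit_length")
  if (width == 0L) return(0)
  .bs_read(stream$words, bit_offset, width)
}

#' Pack a sequence of equal-width values into a fresh bitstream
#'
#' Value `i` (1-based in R) occupies bits `[(i-1) * width, i * width)`. The
#' resulting stream has `bit_length = width * length(values)` and is
#' zero-padded to the next word boundary only at its end, so concatenating
#' per-voxel records at prefix-sum offsets stays exact.
#'
#' @param values Numeric vector of unsigned integers, each `< 2^width`.
#' @param width Common field width in bits, 0..32.
#' @return A [bitstream()].
#' @examples
#' pack_sequence(c(0, 2, 1, 0), width = 2)
#' @export
pack_sequence <- function(values, width) {
  width <- check_width(width)
  values <- as.numeric(values)
  if (anyNA(values)) stop_domain("'values' must not contain NA")
  if (length(values) && width < 32 && any(values < 0 | values >= 2^width))
    stop_domain(sprintf("all values must lie in 0 .. 2^%d - 1", width))
  if (length(values) && any(values < 0 | values >= 2^32))
    stop_domain("all values must fit in 32 bits")
  p <- .bs_pack(values, width)
  structure(list(words = p$words, bit_length = p$bit_length),
            class = "bitstream")
}
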