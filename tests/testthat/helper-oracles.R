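# Independent bit-level oracles built on base R's intToBits/packBits, used to
# cross-check the compiled bit packing.  The stream layout contract: stream
# bit b lives in word floor(b/32) at position b %% 32, values LSB-first.

# logical bit vector of a stream (intToBits is LSB-first per word, matching
# the layout contract)
stream_bits <- function(stream) {
  bits <- as.logical(intToBits(stream$words))
  bits[seq_len(stream$bit_length)]
}

# decode width bits at 0-based offset from a logical bit vector
oracle_read <- function(bits, offset, width) {
  if (width == 0) return(0)
  sum(2^(seq_len(width) - 1)[bits[offset + seq_len(width)]])
}

# pack equal-width values bit by bit into a logical vector, then into words
oracle_pack_bits <- function(values, width) {
  bits <- logical(width * length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    for (b in seq_len(width)) {
      bits[(i - 1) * width + b] <- (v %% 2) == 1
      v <- v %/% 2
    }
  }
  bits
}

bits_to_words <- function(bits) {
  pad <- (-length(bits)) %% 32
  packBits(c(bits, logical(pad)), type = "integer")
}

# random dynamic image; with extremes, sprinkle the 16-bit endpoints in
rand_image <- function(n, Z, Y, X, extremes = FALSE) {
  k <- n * Z * Y * X
  v <- sample.int(65536L, k, replace = TRUE) - 32769L
  if (extremes && k >= 4) {
    at <- sample.int(k, 4)
    v[at] <- c(-32768L, 32767L, -32768L, 32767L)
  }
  dynamic_image(array(v, dim = c(n, Z, Y, X)))
}

# straddling-rich phantom: noise wide enough that many voxel bound intervals
# cross a 0..15 HU band, exercising the delta-read path of the mask
straddle_phantom <- function(seed, shape = c(2, 24, 24)) {
  classes <- default_tissue_classes()
  classes[[3]]$baseline <- 12 # tissue sits on the threshold band
  generate_phantom(phantom_spec(shape = shape, seed = seed,
                                noise_sigma = 8, tissue_classes = classes))
}

expect_same_mask <- function(m1, m2) {
  expect_identical(dim(m1), dim(m2))
  expect_true(all(as.logical(m1) == as.logical(m2)))
}
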