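test_that("required_bits is the exact ceil(log2(range + 1))", {
  expect_identical(required_bits(46, 191), 8L)
  expect_identical(required_bits(22, 72), 6L)
  expect_identical(required_bits(500, 500), 0L)
  expect_identical(required_bits(0, 65535), 16L)
  expect_identical(required_bits(-32768, 32767), 16L)
  expect_error(required_bits(10, 9), class = "dicopp_domain_error")
  # exact powers of two sit on the ceiling boundary
  expect_identical(required_bits(0, c(1, 2, 3, 4, 255, 256)),
                   c(1L, 2L, 2L, 3L, 8L, 9L))
})

test_that("widening a temporal range never decreases the width", {
  set.seed(3)
  for (k in 1:50) {
    lo <- sample(-2000:2000, 1)
    hi <- lo + sample(0:5000, 1)
    expect_lte(required_bits(lo, hi), required_bits(lo - 1, hi + 1))
  }
})

test_that("a single-voxel series is encoded as min + packed deltas", {
  img <- dynamic_image(array(c(10L, 12L, 11L, 10L), c(4, 1, 1, 1)))
  cim <- dicopp_compress(img)
  expect_identical(cim$C, 10L)
  expect_identical(cim$B, 2L) # ceil(log2(3)) = 2
  expect_identical(cim$O, 0)
  expect_identical(cim$D$bit_length, 8)
  deltas <- vapply(0:3, function(t) read_bits(cim$D, t * 2, 2), 0)
  expect_identical(deltas, c(0, 2, 1, 0))
  expect_identical(read_timeseries(cim, 1, 1, 1), c(10L, 12L, 11L, 10L))
  expect_identical(read_voxel(cim, 1, 1, 1, 2), 12L) # second time step
  expect_true(dicopp_decompress(cim) == img)
})

test_that("temporally constant images compress to zero delta bits", {
  img <- dynamic_image(array(rep(-77L, 24 * 2 * 3 * 4), c(24, 2, 3, 4)))
  cim <- dicopp_compress(img)
  expect_true(all(cim$B == 0L))
  expect_identical(cim$D$bit_length, 0)
  expect_true(dicopp_decompress(cim) == img)
  expect_true(all(read_timeseries(cim, 2, 3, 4) == -77L))
})

test_that("a 24-step voxel spanning 46..191 contributes exactly 192 bits", {
  series <- as.integer(round(seq(46, 191, length.out = 24)))
  series[c(1, 24)] <- c(46L, 191L)
  img <- dynamic_image(array(series, c(24, 1, 1, 1)))
  cim <- dicopp_compress(img)
  expect_identical(cim$B, 8L)
  expect_identical(cim$D$bit_length, 24 * 8) # 192
})

test_that("compress/decompress round-trips randomized 16-bit arrays", {
  set.seed(101)
  for (k in 1:30) {
    n <- sample(c(1L, 2L, 24L), 1)
    img <- rand_image(n, sample(1:4, 1), sample(1:12, 1), sample(1:12, 1),
                      extremes = (k %% 2 == 0))
    cim <- dicopp_compress(img)
    expect_true(dicopp_decompress(cim) == img)
    # per-voxel bound invariant
    dec <- dicopp_decompress(cim)$data
    mins <- apply(dec, 2:4, min)
    maxs <- apply(dec, 2:4, max)
    expect_true(all(aperm(mins, 3:1) == array(cim$C, dim(mins)[3:1])))
    expect_true(all(aperm(maxs - mins, 3:1) <=
                      array(2^cim$B - 1, dim(mins)[3:1])))
  }
})

test_that("random access agrees with full decompression", {
  set.seed(55)
  # exhaustive on a small image
  img <- rand_image(4, 3, 5, 6)
  cim <- dicopp_compress(img)
  for (t in 1:4) for (z in 1:3) for (y in 1:5) for (x in 1:6)
    expect_identical(read_voxel(cim, z, y, x, t), img$data[t, z, y, x])
  # sampled on a phantom
  ph <- generate_phantom(phantom_spec(shape = c(4, 32, 32), seed = 9))
  cph <- dicopp_compress(ph$image)
  for (k in 1:500) {
    z <- sample(4, 1); y <- sample(32, 1); x <- sample(32, 1)
    t <- sample(24, 1)
    expect_identical(read_voxel(cph, z, y, x, t), ph$image$data[t, z, y, x])
  }
  # and full time series against the decompressed column
  dec <- dicopp_decompress(cph)$data
  for (k in 1:50) {
    z <- sample(4, 1); y <- sample(32, 1); x <- sample(32, 1)
    expect_identical(read_timeseries(cph, z, y, x), dec[, z, y, x])
  }
})

test_that("offsets are the exclusive prefix sum of n * B", {
  expect_identical(compute_offsets(c(6L, 8L), 24), c(0, 144))
  expect_identical(compute_offsets(integer(0), 24), numeric(0))
  set.seed(77)
  for (k in 1:20) {
    B <- sample(0:16, sample(1:50, 1), replace = TRUE)
    n <- sample(c(1, 2, 24), 1)
    # naive loop oracle
    O <- numeric(length(B))
    acc <- 0
    for (j in seq_along(B)) { O[j] <- acc; acc <- acc + n * B[j] }
    expect_identical(compute_offsets(B, n), O)
  }
  img <- rand_image(24, 2, 6, 6)
  cim <- dicopp_compress(img)
  expect_identical(cim$O, compute_offsets(cim$B, cim$n))
  expect_identical(cim$D$bit_length, sum(cim$n * as.numeric(cim$B)))
})

test_that("each voxel's encoding is independent of all other voxels", {
  # compressing any voxel's series alone yields the same base, width and
  # delta bits as in the full image: the per-voxel records are independent,
  # so any chunked or parallel traversal produces identical output
  set.seed(13)
  img <- rand_image(24, 2, 5, 5)
  cim <- dicopp_compress(img)
  Y <- 5; X <- 5
  for (k in 1:20) {
    z <- sample(2, 1); y <- sample(Y, 1); x <- sample(X, 1)
    j <- ((z - 1) * Y + (y - 1)) * X + (x - 1) # x-fastest linearisation
    solo <- dicopp_compress(dynamic_image(array(img$data[, z, y, x],
                                                c(24, 1, 1, 1))))
    expect_identical(solo$C, cim$C[j + 1])
    expect_identical(solo$B, cim$B[j + 1])
    if (solo$B > 0) {
      full_deltas <- vapply(0:23, function(t)
        read_bits(cim$D, cim$O[j + 1] + t * cim$B[j + 1], cim$B[j + 1]), 0)
      solo_deltas <- vapply(0:23, function(t)
        read_bits(solo$D, t * solo$B, solo$B), 0)
      expect_identical(full_deltas, solo_deltas)
    }
  }
  # and repeated compression is bit-identical
  expect_identical(dicopp_compress(img)$D$words, cim$D$words)
})

test_that("compressed-size accounting follows the four-array convention", {
  img <- dynamic_image(array(rep(100L, 24 * 2 * 4 * 4), c(24, 2, 4, 4)))
  st <- compression_stats(dicopp_compress(img))
  m <- 2 * 4 * 4
  expect_identical(st$compressed_bits / m, 56) # 16 + 32 + 8 + 0 per voxel
  expect_equal(st$ratio, 384 / 56)
  expect_identical(st$uncompressed_bits, 16 * m * 24)
  # 64-bit offsets convention
  st64 <- compression_stats(dicopp_compress(img), offset_bits = 64)
  expect_identical(st64$compressed_bits / m, 88)

  # an incompressible image: every voxel spans the full 16-bit range
  k <- 24 * 2 * 4 * 4
  v <- sample.int(65536L, k, replace = TRUE) - 32769L
  arr <- array(v, c(24, 2, 4, 4))
  arr[1, , , ] <- -32768L
  arr[2, , , ] <- 32767L
  sti <- compression_stats(dicopp_compress(dynamic_image(arr)))
  expect_lt(sti$ratio, 1)
  expect_equal(sum(sti$width_histogram), m)
  expect_equal(unname(sti$width_histogram["16"]), m)
})

test_that("one full-scale volume is 160 MB uncompressed, a series 3840 MB", {
  bits_per_volume <- 16 * (320 * 512 * 512)
  expect_identical(bits_per_volume / 8 / 2^20, 160)
  expect_identical(24 * bits_per_volume / 8 / 2^20, 3840)
})

test_that("invalid images are rejected", {
  expect_error(dynamic_image(array(70000L, c(2, 1, 1, 1))),
               class = "dicopp_domain_error")
  expect_error(dynamic_image(array(0.5, c(2, 1, 1, 1))),
               class = "dicopp_domain_error")
  expect_error(dynamic_image(matrix(1L, 2, 2)), class = "dicopp_domain_error")
  img <- rand_image(2, 1, 2, 2)
  cim <- dicopp_compress(img)
  expect_error(read_voxel(cim, 1, 1, 3, 1), class = "dicopp_bounds_error")
  expect_error(read_voxel(cim, 1, 1, 1, 3), class = "dicopp_bounds_error")
  # structurally inconsistent compressed arrays are flagged as corruption
  bad <- cim; bad$O[2] <- bad$O[2] + 1
  expect_error(dicopp_decompress(bad), class = "dicopp_corrupt_error")
  bad2 <- cim; bad2$B <- c(bad2$B, 1L)
  expect_error(dicopp_decompress(bad2), class = "dicopp_corrupt_error")
})
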