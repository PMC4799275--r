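test_that("container write/read round-trips compressed images bit-exactly", {
  set.seed(7)
  for (k in 1:5) {
    img <- rand_image(sample(c(1L, 2L, 24L), 1), sample(1:3, 1),
                      sample(1:8, 1), sample(1:8, 1), extremes = TRUE)
    cim <- dicopp_compress(img)
    path <- tempfile(fileext = ".dicopp")
    write_container(cim, path)
    got <- read_container(path)
    expect_identical(got$C, cim$C)
    expect_identical(got$B, cim$B)
    expect_identical(got$O, cim$O)
    expect_identical(got$D$words, cim$D$words)
    expect_identical(got$D$bit_length, cim$D$bit_length)
    expect_true(dicopp_decompress(got) == img)
    # reconstructed offsets are the prefix sum of the stored widths
    expect_identical(got$O, compute_offsets(got$B, got$n))
    # byte-stable: writing the same object twice is identical
    path2 <- tempfile(fileext = ".dicopp")
    write_container(cim, path2)
    expect_identical(readBin(path, raw(), file.size(path)),
                     readBin(path2, raw(), file.size(path2)))
  }
})

test_that("acquisition times and spacing survive the container round trip", {
  ph <- generate_phantom(phantom_spec(shape = c(1, 12, 12), seed = 3))
  cim <- dicopp_compress(ph$image)
  path <- tempfile(fileext = ".dicopp")
  write_container(cim, path)
  expect_identical(read_container(path)$times, ph$image$times)
})

test_that("the compressed file size follows the stated layout exactly", {
  img <- dynamic_image(array(c(10L, 12L, 11L, 10L), c(4, 1, 1, 1)))
  cim <- dicopp_compress(img) # 1 voxel, B = 2, 8 delta bits -> one word
  path <- tempfile(fileext = ".dicopp")
  write_container(cim, path)
  m <- 1
  header <- 8 + 4 + 4 + 16 + 1 + 1 + 4 * 8 + 8 # magic..flags..geometry..lengths
  expect_equal(file.size(path), header + 2 * m + m + 4 + 4) # C+B+D+crc
  # persisting offsets adds 8 bytes per voxel
  path2 <- tempfile(fileext = ".dicopp")
  write_container(cim, path2, persist_offsets = TRUE)
  expect_equal(file.size(path2), file.size(path) + 8 * m)
  got <- read_container(path2)
  expect_identical(got$O, cim$O)
})

test_that("flipping any payload byte breaks the checksum", {
  img <- rand_image(24, 1, 4, 4)
  path <- tempfile(fileext = ".dicopp")
  write_container(dicopp_compress(img), path)
  bytes <- readBin(path, raw(), file.size(path))
  payload_start <- length(bytes) - 4 - (2 * 16 + 16 +
                                          4 * length(dicopp_compress(img)$D$words))
  for (k in 1:5) {
    corrupted <- bytes
    at <- sample(seq(payload_start + 1, length(bytes) - 4), 1)
    corrupted[at] <- xor(corrupted[at], as.raw(0x40))
    writeBin(corrupted, path)
    expect_error(read_container(path), class = "dicopp_corrupt_error")
  }
})

test_that("bad magic, truncation and future versions raise typed errors", {
  img <- rand_image(2, 1, 3, 3)
  path <- tempfile(fileext = ".dicopp")
  write_container(dicopp_compress(img), path)
  bytes <- readBin(path, raw(), file.size(path))

  bad <- bytes; bad[1] <- as.raw(0x58)
  writeBin(bad, path)
  expect_error(read_container(path), class = "dicopp_corrupt_error")

  writeBin(bytes[1:20], path)
  expect_error(read_container(path), class = "dicopp_corrupt_error")

  future <- bytes; future[9] <- as.raw(99) # version field
  writeBin(future, path)
  expect_error(read_container(path), "version",
               class = "dicopp_corrupt_error")

  expect_error(read_container(tempfile()), class = "dicopp_io_error")
})

test_that("raw headered arrays round-trip exactly", {
  ph <- generate_phantom(phantom_spec(shape = c(2, 12, 12), seed = 8))
  path <- tempfile(fileext = ".ctp4d")
  write_raw_array(ph$image, path)
  got <- read_raw_array(path)
  expect_identical(got$data, ph$image$data)
  expect_identical(got$times, ph$image$times)
  expect_identical(load_dynamic_image(path)$data, ph$image$data)
  writeBin(as.raw(1:16), path)
  expect_error(read_raw_array(path), class = "dicopp_corrupt_error")
})

test_that("NIfTI export reloads element-identical", {
  ph <- generate_phantom(phantom_spec(shape = c(2, 12, 12), seed = 9))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_image(ph$image, path)
  got <- load_dynamic_image(path, format = "nifti")
  expect_identical(got$data, ph$image$data)
  # masks export as 8-bit volumes
  mk <- threshold_mask(dicopp_compress(ph$image), 0, 15, "any_timestep")
  mpath <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(mk, mpath)
  back <- RNifti::readNifti(mpath)
  expect_equal(sum(back), sum(mk))
})

test_that("a synthetic DICOM series loads with the written geometry", {
  ph <- generate_phantom(phantom_spec(shape = c(2, 10, 12), seed = 4))
  arr <- ph$image$data[1:2, , , , drop = FALSE] # 2 time points, 2 slices
  img <- dynamic_image(arr)
  dir <- file.path(tempdir(), "dcm_series")
  unlink(dir, recursive = TRUE)
  write_synthetic_dicom_series(img, dir)
  expect_length(list.files(dir), 4) # 2 time points x 2 slices
  got <- read_dicom_series(dir)
  expect_identical(dim(got$data), c(2L, 2L, 10L, 12L))
  expect_identical(got$data, img$data)
  prov <- attr(got, "provenance")
  expect_identical(prov$grouping, "temporal_position")
  expect_identical(prov$rescale_slope, 1)
  # the other grouping keys give the same volume
  got2 <- read_dicom_series(dir, group_by = "acquisition_time")
  expect_identical(got2$data, img$data)
  got3 <- read_dicom_series(dir, group_by = "instance_blocks")
  expect_identical(got3$data, img$data)
  expect_identical(load_dynamic_image(dir)$data, img$data)
})
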