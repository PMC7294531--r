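test_that("image_volume validates geometry and maps voxels to mm", {
  vol <- image_volume(array(0, c(4, 5, 6)), spacing = c(0.5, 0.6, 0.7),
                      origin = c(-1, 2, 3))
  expect_equal(unname(voxel_to_world(vol, c(1, 1, 1))[1, ]), c(-1, 2, 3))
  expect_equal(unname(voxel_to_world(vol, c(3, 2, 4))[1, ]),
               c(-1 + 2 * 0.5, 2 + 0.6, 3 + 3 * 0.7))
  # round trip world -> voxel -> world
  ijk <- rbind(c(1, 1, 1), c(4, 5, 6), c(2, 3, 4))
  expect_equal(world_to_voxel(vol, voxel_to_world(vol, ijk)), ijk)

  expect_error(image_volume(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(image_volume(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
  expect_error(binary_mask(array(3, c(2, 2, 2)), c(1, 1, 1)), "0 or 255")
})

test_that("MetaImage round trip is the identity on data, spacing and origin", {
  vol <- image_volume(array(rnorm(3 * 4 * 5) * 100, c(3, 4, 5)),
                      spacing = c(0.5, 0.586, 0.586),
                      origin = c(-7.25, 0.125, 19))
  path <- withr::local_tempfile(fileext = ".mha")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(back$data, vol$data)   # MET_DOUBLE: bit-exact
  expect_identical(back$spacing, vol$spacing)
  expect_identical(back$origin, vol$origin)

  tiny <- image_volume(array(42, c(1, 1, 1)), c(1, 1, 1))
  path2 <- withr::local_tempfile(fileext = ".mha")
  write_volume(tiny, path2)
  expect_identical(read_volume(path2)$data, tiny$data)
})

test_that("NIfTI round trip preserves values and anisotropic spacing", {
  vol <- image_volume(array(sample(-1000:2000, 4 * 6 * 5), c(4, 6, 5)),
                      spacing = c(0.8, 0.683, 0.683),
                      origin = c(4, -3, 12.5))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
})

test_that("DICOM series round trips and stored values obey slope/intercept", {
  set.seed(11)
  arr <- array(round(runif(4 * 6 * 5, -200, 500)), c(4, 6, 5))
  vol <- image_volume(arr, spacing = c(0.5, 0.586, 0.586), origin = c(1, 2, 3))
  dir <- withr::local_tempdir()
  write_volume(vol, dir, format = "dicom_dir")
  back <- read_volume(dir)
  expect_equal(back$data, arr)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)

  # byte-level oracle, independent of the tag parser: the writer appends
  # PixelData last, so the trailing rows*cols int16 words are the stored
  # values; HU must equal slope * stored + intercept (slope 1, intercept
  # -1024) on every voxel
  f <- sort(list.files(dir, full.names = TRUE))[1]
  bytes <- readBin(f, "raw", file.size(f))
  npix <- 6 * 5
  stored <- readBin(bytes[(length(bytes) - 2 * npix + 1):length(bytes)],
                    "integer", npix, size = 2, signed = TRUE, endian = "little")
  hu_oracle <- t(matrix(1 * stored + (-1024), nrow = 5, ncol = 6))
  expect_equal(back$data[1, , ], hu_oracle)
  # stored value 1104 corresponds to 80 HU under this rescale
  expect_equal(1 * 1104 + (-1024), 80)
})

test_that("DICOM loader rejects mixed series and non-uniform slice gaps", {
  arr <- array(0, c(3, 4, 4))
  vol <- image_volume(arr, spacing = c(0.6, 0.5, 0.5))
  dir <- withr::local_tempdir()
  write_volume(vol, dir, format = "dicom_dir")

  # inject a slice from a series with different in-plane spacing
  alien_dir <- withr::local_tempdir()
  alien <- image_volume(array(0, c(1, 4, 4)), spacing = c(0.6, 0.9, 0.9),
                        origin = c(9, 0, 0))
  write_volume(alien, alien_dir, format = "dicom_dir")
  file.copy(list.files(alien_dir, full.names = TRUE)[1],
            file.path(dir, "alienslice.dcm"))
  expect_error(read_volume(dir), "PixelSpacing differs in slice")

  # non-uniform gap: extra slice at a non-lattice position
  dir2 <- withr::local_tempdir()
  write_volume(vol, dir2, format = "dicom_dir")
  odd_dir <- withr::local_tempdir()
  odd <- image_volume(array(0, c(1, 4, 4)), spacing = c(0.6, 0.5, 0.5),
                      origin = c(1.45, 0, 0))
  write_volume(odd, odd_dir, format = "dicom_dir")
  file.copy(list.files(odd_dir, full.names = TRUE)[1],
            file.path(dir2, "oddgap.dcm"))
  expect_error(read_volume(dir2), "non-uniform|unsorted")
})

test_that("external DICOM reader agrees with ours on a written series", {
  arr <- array(seq(-100, by = 7, length.out = 2 * 3 * 4), c(2, 3, 4))
  vol <- image_volume(arr, spacing = c(0.7, 0.586, 0.683), origin = c(0, 0, 0))
  dir <- withr::local_tempdir()
  write_volume(vol, dir, format = "dicom_dir")
  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- paste(
    "import pydicom, sys, json",
    "ds = pydicom.dcmread(sys.argv[1])",
    "hu = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)",
    "print(json.dumps({'hu': hu.tolist(), 'ps': [float(x) for x in ds.PixelSpacing]}))",
    sep = "\n")
  f <- sort(list.files(dir, full.names = TRUE))[2]
  out <- system2(py, c("-c", shQuote(script), shQuote(f)), stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(parsed$hu, arr[2, , ])
  expect_equal(parsed$ps, c(0.586, 0.683))
})
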