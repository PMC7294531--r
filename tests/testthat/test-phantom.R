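test_that("noiseless unblurred phantom is exactly two-valued", {
  spec <- straight_tube_spec(peak = 336)
  ph <- generate_phantom(spec)
  vals <- sort(unique(as.vector(ph$volume$data)))
  expect_identical(vals, c(80, 336))
  # every ground-truth lumen voxel carries the plateau value
  expect_true(all(ph$volume$data[ph$truth$lumen_mask$data == 255] == 336))
})

test_that("straight tube voxel volume matches the analytic cylinder", {
  spec <- straight_tube_spec(radius_mm = 3, length_mm = 40)
  ph <- generate_phantom(spec)
  vox <- mask_count(ph$truth$lumen_mask) * voxel_volume(ph$truth$lumen_mask)
  expect_equal(vox, pi * 3^2 * 40, tolerance = 0.05)
  expect_equal(ph$truth$analytic_volumes_mm3$tube, pi * 3^2 * 40)
})

test_that("phantom generation is bit-deterministic in the seed", {
  spec <- function(s) straight_tube_spec(noise_sigma_hu = 15,
                                         blur_fwhm_mm = 1, seed = s)
  a <- generate_phantom(spec(42))
  b <- generate_phantom(spec(42))
  c <- generate_phantom(spec(43))
  expect_identical(a$volume$data, b$volume$data)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("lumen voxel count tracks the analytic union for separated shapes", {
  # tube and aneurysm sphere disjoint: union volume is the exact sum
  spec <- phantom_spec(
    grid_shape = c(24, 30, 44), spacing = c(1, 1, 1),
    centerline = rbind(c(11.5, 7, 4), c(11.5, 7, 39)),
    vessel_radius_mm = 3.5,
    aneurysm_center = c(11.5, 21, 22), aneurysm_diameter_mm = 12,
    lumen_peak_hu = 306)
  ph <- generate_phantom(spec)
  vox <- mask_count(ph$truth$lumen_mask) * voxel_volume(ph$truth$lumen_mask)
  analytic <- ph$truth$analytic_volumes_mm3$tube + ph$truth$analytic_volumes_mm3$sphere
  expect_equal(vox, analytic, tolerance = 0.10)
})

test_that("partial-volume blur leaves the eroded lumen interior at the peak", {
  spec <- straight_tube_spec(radius_mm = 4, blur_fwhm_mm = 1, peak = 406)
  ph <- generate_phantom(spec)
  # erode the truth by ~2 voxels: interior voxels must still read the plateau
  inner <- straight_tube_spec(radius_mm = 2, length_mm = 36, peak = 406,
                              grid_half_mm = 6, grid_len_mm = 52)
  interior <- generate_phantom(inner)$truth$lumen_mask$data == 255
  interior_vals <- ph$volume$data[interior]
  expect_gt(length(interior_vals), 100)
  expect_equal(max(abs(interior_vals - 406)), 0, tolerance = 0.5)
  hist <- compute_histogram(ph$volume, binary_mask(interior, spec$spacing))
  expect_equal(histogram_peak(hist), 406)
})

test_that("geometry outside the grid is a spec error", {
  expect_error(phantom_spec(
    grid_shape = c(10, 10, 10), spacing = c(1, 1, 1),
    centerline = rbind(c(5, 5, 0), c(5, 5, 30)), vessel_radius_mm = 2,
    aneurysm_center = c(5, 5, 5), aneurysm_diameter_mm = 4,
    lumen_peak_hu = 300), "outside the grid")
  expect_error(phantom_spec(
    grid_shape = c(10, 10, 10), spacing = c(1, 1, 1),
    centerline = rbind(c(5, 5, 2), c(5, 5, 8)), vessel_radius_mm = 2,
    aneurysm_center = c(5, 5, 5), aneurysm_diameter_mm = 4,
    lumen_peak_hu = 50), "exceed")
})

test_that("dice matches direct counting and its edge cases", {
  sp <- c(1, 1, 1)
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[2:3, 1, 1] <- TRUE
  expect_equal(dice(binary_mask(a, sp), binary_mask(b, sp)), 0.5)  # 2*1/(2+2)
  expect_equal(dice(binary_mask(a, sp), binary_mask(a, sp)), 1)
  disjoint <- array(FALSE, c(4, 4, 4)); disjoint[4, 4, 4] <- TRUE
  expect_equal(dice(binary_mask(a, sp), binary_mask(disjoint, sp)), 0)
  empty <- binary_mask(array(FALSE, c(4, 4, 4)), sp)
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(binary_mask(a, sp), binary_mask(array(FALSE, c(5, 4, 4)), sp)),
               "different grids")
  # symmetry on random masks
  set.seed(5)
  for (i in 1:10) {
    m1 <- random_small_mask(); m2 <- random_small_mask()
    expect_equal(dice(m1, m2), dice(m2, m1))
  }
})

test_that("volume_error is the signed relative count difference", {
  sp <- c(1, 1, 1)
  t100 <- array(FALSE, c(5, 5, 5)); t100[1:4, 1:5, 1:5] <- TRUE  # 100 voxels
  p110 <- t100; p110[5, 1:2, 1:5] <- TRUE                        # 110 voxels
  expect_equal(volume_error(binary_mask(p110, sp), binary_mask(t100, sp)), 0.10)
  expect_equal(volume_error(binary_mask(t100, sp), binary_mask(t100, sp)), 0)
  expect_gt(volume_error(binary_mask(p110, sp), binary_mask(t100, sp)), 0)
  expect_error(volume_error(binary_mask(t100, sp),
                            binary_mask(array(FALSE, c(5, 5, 5)), sp)),
               "empty truth")
})
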