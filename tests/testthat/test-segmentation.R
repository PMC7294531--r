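test_that("histogram counts are conserved and bins land where expected", {
  sp <- c(1, 1, 1)
  vol <- image_volume(array(336, c(4, 4, 4)), sp)
  h <- compute_histogram(vol)
  expect_identical(sum(h$counts), 64L)
  expect_identical(h$roi_voxel_count, 64L)
  occupied <- h$bin_centers[h$counts > 0]
  expect_identical(occupied, 336)

  # two-value ROI {80 x 10, 336 x 30}
  data <- array(80, c(2, 4, 5))
  data[seq_len(40)[-(1:10)]] <- 336
  roi <- binary_mask(array(TRUE, c(2, 4, 5)), sp)
  h2 <- compute_histogram(image_volume(data, sp), roi)
  expect_identical(h2$counts[h2$bin_centers == 80], 10L)
  expect_identical(h2$counts[h2$bin_centers == 336], 30L)
  expect_identical(sum(h2$counts), 40L)

  # conservation on a noisy phantom with a sub-ROI
  ph <- generate_phantom(straight_tube_spec(noise_sigma_hu = 25, seed = 2))
  roi2 <- ph$truth$lumen_mask
  h3 <- compute_histogram(ph$volume, roi2)
  expect_identical(sum(h3$counts), mask_count(roi2))
  expect_error(compute_histogram(ph$volume,
                                 binary_mask(array(FALSE, dim(ph$volume$data)),
                                             ph$volume$spacing)),
               "empty ROI")
})

test_that("histogram peak is the argmax bin centre with low-HU tie-break", {
  sp <- c(1, 1, 1)
  vol <- image_volume(array(c(rep(300, 20), rep(400, 20), rep(350, 14)),
                            c(3, 3, 6)), sp)
  expect_equal(histogram_peak(compute_histogram(vol)), 300)  # tie -> lowest

  # brute-force argmax oracle on random histograms
  set.seed(9)
  for (i in 1:20) {
    vals <- sample(seq(-50, 450, by = 1), 200, replace = TRUE)
    vol <- image_volume(array(vals[1:180], c(6, 6, 5)), sp)
    h <- compute_histogram(vol)
    best <- min(h$bin_centers[h$counts == max(h$counts)])
    expect_identical(histogram_peak(h), best)
  }
})

test_that("partial-volume threshold formula and its monotonicity", {
  expect_identical(threshold_from_peak(336), 208)
  expect_identical(threshold_from_peak(406), 243)
  expect_identical(threshold_from_peak(218), 149)
  expect_identical(threshold_from_peak(306), 193)
  expect_identical(threshold_from_peak(80, 80), 80)  # peak at background

  peaks <- seq(80, 600, by = 7)
  th <- threshold_from_peak(peaks)
  expect_true(all(diff(th) > 0))                 # strictly increasing
  expect_true(all(th >= 80 & th <= peaks))       # background <= T <= peak
  expect_warning(threshold_from_peak(40, 80), "below the background")
})

test_that("thresholding uses the inclusive >= convention", {
  sp <- c(1, 1, 1)
  vol <- image_volume(array(80, c(3, 3, 3)), sp)
  expect_identical(mask_count(apply_threshold(vol, 208)), 0L)

  v2 <- image_volume(array(c(207.999, 208, 208.001), c(3, 1, 1)), sp)
  m2 <- apply_threshold(v2, 208)
  expect_identical(as.vector(m2$data), c(0, 255, 255))

  ph <- generate_phantom(straight_tube_spec(peak = 336))
  m <- apply_threshold(ph$volume, threshold_from_peak(336))
  expect_identical(m$data, ph$truth$lumen_mask$data)  # noiseless, no blur
  expect_true(all(m$data %in% c(0, 255)))
})

test_that("component selection equals an independent flood fill", {
  sp <- c(1, 1, 1)
  two <- array(FALSE, c(7, 7, 7))
  two[2:3, 2:3, 2:3] <- TRUE
  two[6:7, 6:7, 6:7] <- TRUE
  sel <- select_component(binary_mask(two, sp), c(2, 2, 2))
  expect_identical(mask_count(sel), 8L)
  expect_true(all(sel$data[6:7, 6:7, 6:7] == 0))

  expect_identical(select_component(binary_mask(two, sp), c(6, 6, 6))$data[6, 6, 6], 255)
  expect_error(select_component(binary_mask(two, sp), c(1, 1, 1)), "background")
  expect_error(select_component(binary_mask(two, sp), c(9, 1, 1)), "outside")

  set.seed(31)
  for (i in 1:8) {
    m <- random_small_mask(c(7, 7, 7), p = 0.35)
    fg <- which(m$data == 255, arr.ind = TRUE)
    seed <- fg[sample(nrow(fg), 1), ]
    sel <- select_component(m, seed)
    oracle <- bfs_component(m$data == 255, seed)
    expect_identical(sel$data == 255, oracle)
  }
})

test_that("region cutting clears outside the box and keeps the grid", {
  set.seed(4)
  m <- random_small_mask(c(8, 8, 8))
  full <- crop_box(m, rbind(c(1, 1, 1), c(8, 8, 8)))
  expect_identical(full$data, m$data)

  box <- rbind(c(2, 3, 4), c(5, 6, 8))
  cropped <- crop_box(m, box)
  expect_identical(dim(cropped$data), dim(m$data))
  inside_count <- sum(m$data[2:5, 3:6, 4:8] == 255)
  expect_identical(mask_count(cropped), inside_count)
  expect_true(all(cropped$data[1, , ] == 0))
  expect_error(crop_box(m, rbind(c(5, 1, 1), c(2, 8, 8))), "inverted")
  expect_error(crop_box(m, rbind(c(1, 1, 1), c(9, 8, 8))), "outside")
})

test_that("segmentation recovers the lumen on a blurred phantom", {
  spec <- straight_tube_spec(radius_mm = 3.5, blur_fwhm_mm = 1, peak = 336)
  ph <- generate_phantom(spec)
  th <- threshold_from_peak(336)
  mask <- apply_threshold(ph$volume, th)
  seed <- round(world_to_voxel(ph$volume, spec$centerline[1, ] +
                                 c(0, 0, 1)))[1, ]
  mask <- select_component(mask, seed)
  expect_gte(dice(mask, ph$truth$lumen_mask), 0.95)
})
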