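test_that("mask inversion is an involution that swaps the voxel counts", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_small_mask(c(6, 7, 5))
    inv <- invert_mask(m)
    expect_identical(invert_mask(inv)$data, m$data)
    expect_identical(mask_count(inv), length(m$data) - mask_count(m))
    expect_true(all(inv$data %in% c(0, 255)))
  }
  all_on <- binary_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  expect_identical(mask_count(invert_mask(all_on)), 0L)
})

test_that("block complement is the expanded box minus the lumen", {
  sp <- c(1, 1, 1)
  lum <- array(FALSE, c(9, 9, 9)); lum[5, 5, 5] <- TRUE
  lumen <- binary_mask(lum, sp)
  cfg <- hollow_config(block_margin_mm = 0,
                       ports = list(list(seed = c(5, 5, 5), direction = "+col")))
  solid <- make_block_complement(lumen, cfg)
  # margin 0, single-voxel lumen: box is that voxel alone, so no solid
  expect_identical(mask_count(solid), 0L)

  cfg2 <- hollow_config(block_margin_mm = 2,
                        ports = list(list(seed = c(5, 5, 5), direction = "+col")))
  solid2 <- make_block_complement(lumen, cfg2)
  expect_identical(mask_count(solid2), 124L)  # 5x5x5 box minus the lumen voxel
  expect_true(all(solid2$data[lum] == 0))           # solid and lumen disjoint

  # mass balance |solid| + |lumen| = |box| on a random lumen
  set.seed(8)
  m <- random_small_mask(c(8, 8, 8), p = 0.2)
  if (mask_count(m) == 0) m$data[4, 4, 4] <- 255
  cfgm <- hollow_config(block_margin_mm = 1,
                        ports = list(list(seed = c(4, 4, 4), direction = "+col")))
  sm <- make_block_complement(m, cfgm)
  box <- attr(sm, "block_box")
  box_n <- prod(box$hi - box$lo + 1)
  expect_identical(mask_count(sm) + mask_count(m), as.integer(box_n))
})

test_that("margins beyond the grid pad the volume instead of truncating", {
  sp <- c(0.5, 0.5, 0.5)
  lum <- array(FALSE, c(6, 6, 6)); lum[3:4, 3:4, 3:4] <- TRUE
  lumen <- binary_mask(lum, sp, origin = c(10, 20, 30))
  cfg <- hollow_config(block_margin_mm = 4,  # 8 voxels > grid on all sides
                       ports = list(list(seed = c(3, 3, 3), direction = "+col")))
  solid <- make_block_complement(lumen, cfg)
  expect_true(all(dim(solid$data) > dim(lumen$data)))
  # origin shifts back by the padding so physical positions are unchanged
  shift <- round((lumen$origin - solid$origin) / sp)
  expect_true(all(shift > 0))
  expect_identical(solid$data[3 + shift[1], 3 + shift[2], 3 + shift[3]], 0)
  box <- attr(solid, "block_box")
  expect_identical(mask_count(solid) + mask_count(lumen),
                   as.integer(prod(box$hi - box$lo + 1)))
})

test_that("shell mode builds a wall of the requested physical thickness", {
  spec <- straight_tube_spec(radius_mm = 3, length_mm = 20,
                             spacing = c(0.5, 1, 1), grid_half_mm = 8)
  lumen <- generate_phantom(spec)$truth$lumen_mask
  cfg <- hollow_config(mode = "shell", wall_thickness_mm = 2.5,
                       ports = list(list(seed = c(1, 1, 1), direction = "+col")))
  shell <- make_shell(lumen, cfg)
  expect_identical(sum(shell$data == 255 & lumen$data == 255), 0L)

  # brute-force distance oracle on a mid-tube cross-section: shell voxels
  # are exactly the non-lumen voxels within 2.5 mm of the lumen
  mid <- round(dim(lumen$data)[3] / 2)
  fg <- which(lumen$data == 255, arr.ind = TRUE)
  fg_mm <- sweep(sweep(fg - 1, 2, lumen$spacing, "*"), 2, lumen$origin, "+")
  d <- dim(lumen$data)
  for (i in seq(1, d[1], by = 3)) for (j in seq(1, d[2], by = 3)) {
    p <- (c(i, j, mid) - 1) * lumen$spacing + lumen$origin
    dist <- sqrt(min(colSums((t(fg_mm) - p)^2)))
    in_shell <- shell$data[i, j, mid] == 255
    if (lumen$data[i, j, mid] == 255) {
      expect_false(in_shell)
    } else {
      expect_identical(in_shell, dist <= 2.5)
    }
  }

  # wall thinner than a voxel: degenerate, warned, possibly empty
  expect_warning(
    thin <- make_shell(lumen, hollow_config(mode = "shell",
      wall_thickness_mm = 0.2,
      ports = list(list(seed = c(1, 1, 1), direction = "+col")))),
    "discontinuous")
  expect_lt(mask_count(thin), mask_count(shell))
})

test_that("ports connect the cavity to the exterior", {
  spec <- straight_tube_spec(radius_mm = 3, length_mm = 24)
  ph <- generate_phantom(spec)
  lumen <- ph$truth$lumen_mask
  seed_vox <- round(world_to_voxel(lumen, spec$centerline[1, ] + c(0, 0, 2)))[1, ]
  cfg <- hollow_config(block_margin_mm = 4,
                       ports = list(list(seed = seed_vox, direction = "-col"),
                                    list(seed = seed_vox, direction = "+col")))
  solid <- make_block_complement(lumen, cfg)
  opened <- open_ports(solid, lumen, cfg)

  # flood fill from outside the padded grid must reach the whole cavity:
  # no voxel of the lumen may sit in a sealed pocket
  d <- dim(opened$data)
  cav <- array(TRUE, d + 2)
  cav[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- opened$data == 0
  reach <- bfs6_reachable(cav)
  shift <- round((lumen$origin - opened$origin) / opened$spacing)
  fg <- which(lumen$data == 255, arr.ind = TRUE)
  fg_shifted <- sweep(fg, 2, as.integer(shift) + 1L, "+")
  expect_true(all(reach[fg_shifted]))

  # port channel cross-section equals the lumen cross-section at the seed
  ch <- opened$data == 0 & solid$data == 255   # voxels cleared by the port
  sl <- seed_vox[3] + shift[3]
  lum_cross <- lumen$data[, , seed_vox[3]] == 255
  first_col <- which(apply(ch, 3, any))[1]
  ch_cross <- ch[, , first_col]
  embedded <- array(FALSE, dim(ch_cross))
  embedded[shift[1] + seq_len(nrow(lum_cross)), shift[2] + seq_len(ncol(lum_cross))] <- lum_cross
  expect_identical(ch_cross, embedded)

  expect_error(open_ports(solid, lumen, hollow_config(
    ports = list(list(seed = c(1, 1, 1), direction = "+col")))),
    "lumen")
  expect_error(hollow_config(ports = list()), "port")
})
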