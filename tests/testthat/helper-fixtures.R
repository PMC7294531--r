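# Fixtures are built in code at test time; nothing binary ships with the
# package.

# unit cube [0,1]^3 as a closed, outward-oriented 12-triangle mesh
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces as vertex indices into the expand.grid order, outward winding
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # x = 0
    c(2, 4, 8), c(2, 8, 6),   # x = 1
    c(1, 6, 5), c(1, 2, 6),   # y = 0
    c(3, 8, 4), c(3, 7, 8),   # y = 1
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 8, 7), c(5, 6, 8))   # z = 1
  triangle_mesh(v, f)
}

# voxelized sphere of radius r (voxels) on an isotropic grid, centred
voxel_sphere_mask <- function(r, spacing = c(1, 1, 1), pad = 3) {
  n <- 2 * (r + pad) + 1
  cc <- (n + 1) / 2
  idx <- seq_len(n)
  d2 <- outer(outer((idx - cc)^2, (idx - cc)^2, "+"), (idx - cc)^2, "+")
  binary_mask(d2 <= r^2, spacing)
}

# straight-tube phantom: cylinder along array axis 3, with the mandatory
# aneurysm sphere fully inside the tube so the lumen stays an exact cylinder
straight_tube_spec <- function(radius_mm = 3, length_mm = 40,
                               spacing = c(1, 1, 1), peak = 336,
                               grid_half_mm = radius_mm + 2,
                               grid_len_mm = length_mm + 2 * radius_mm + 4,
                               ...) {
  half <- ceiling(grid_half_mm / spacing[1:2])
  n12 <- 2 * half + 1
  n3 <- ceiling(grid_len_mm / spacing[3])
  extent <- (c(n12, n3) - 1) * spacing[c(1, 2, 3)]
  mid <- c((n12[1] - 1) * spacing[1], (n12[2] - 1) * spacing[2]) / 2
  x0 <- ((n3 - 1) * spacing[3] - length_mm) / 2
  centerline <- rbind(c(mid[1], mid[2], x0),
                      c(mid[1], mid[2], x0 + length_mm))
  phantom_spec(grid_shape = c(n12, n3), spacing = spacing,
               centerline = centerline, vessel_radius_mm = radius_mm,
               aneurysm_center = c(mid[1], mid[2], x0 + length_mm / 2),
               aneurysm_diameter_mm = min(radius_mm, 2),
               lumen_peak_hu = peak, ...)
}

# independent 26-connected flood fill, plain R breadth-first search
bfs_component <- function(arr, seed) {
  d <- dim(arr)
  visited <- array(FALSE, d)
  queue <- matrix(seed, ncol = 3)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  while (nrow(queue) > 0) {
    cur <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    for (o in seq_len(nrow(offsets))) {
      nb <- cur + offsets[o, ]
      if (any(nb < 1) || any(nb > d)) next
      if (arr[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  visited
}

random_small_mask <- function(d = c(6, 6, 6), p = 0.4, spacing = c(1, 1, 1)) {
  binary_mask(array(stats::runif(prod(d)) < p, d), spacing)
}

# 6-connected reachability over TRUE voxels from corner (1,1,1), by
# repeated axis-shift dilation (independent of the package's C code)
bfs6_reachable <- function(open) {
  d <- dim(open)
  reach <- array(FALSE, d)
  stopifnot(open[1, 1, 1])
  reach[1, 1, 1] <- TRUE
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & open
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}
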