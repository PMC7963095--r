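test_that("the tessellation partitions the box: volume is conserved exactly", {
  ph <- small_phantom()
  vox <- voxel_volume(ph$stack)
  total <- prod(stack_extent(ph$stack))
  expect_identical(sum(ph$cells$true_volume) + sum(ph$label_map == 0L) * vox,
                   total)
  expect_equal(nrow(ph$cells), length(unique(ph$label_map[ph$label_map > 0L])))
  expect_true(all(ph$cells$true_volume ==
                    ph$cells$interior_voxel_count * vox))
  expect_true(all(ph$stack$intensities >= 0L &
                    ph$stack$intensities <= ph$stack$depth))
})

test_that("a single cell filling the box leaves membrane only at the faces", {
  ph <- generate_adipose_phantom(
    extent = c(100, 100, 100), n_cells = 1, voxel_pitch = c(5, 5, 5),
    boundary_membrane = TRUE, noise_sd = 0, seed = 3
  )
  expect_equal(nrow(ph$cells), 1)
  expect_equal(ph$cells$interior_voxel_count, 18L^3)
  expect_equal(ph$cells$true_volume, 18^3 * 125)
})

test_that("requesting an exact cell count yields exactly that many labels", {
  ph <- generate_adipose_phantom(
    extent = c(250, 250, 250), n_cells = 50, voxel_pitch = c(5, 5, 5), seed = 5
  )
  expect_equal(nrow(ph$cells), 50)
  expect_equal(sort(unique(as.vector(ph$label_map[ph$label_map > 0L]))), 1:50)
})

test_that("identical config and seed give bit-identical phantoms", {
  cfg <- list(extent = c(150, 150, 150), mean_volume = 2e5, cv = 0.25,
              voxel_pitch = c(5, 5, 5), seed = 21)
  a <- do.call(generate_adipose_phantom, cfg)
  b <- do.call(generate_adipose_phantom, cfg)
  expect_identical(a$stack$intensities, b$stack$intensities)
  expect_identical(a$label_map, b$label_map)
  expect_equal(a$cells, b$cells)
})

test_that("membranes are continuous: no two interiors are 6-adjacent", {
  ph <- small_phantom()
  lab <- ph$label_map
  d <- dim(lab)
  viol <- 0L
  a <- lab[-d[1], , ]; b <- lab[-1, , ]
  viol <- viol + sum(a > 0L & b > 0L & a != b)
  a <- lab[, -d[2], ]; b <- lab[, -1, ]
  viol <- viol + sum(a > 0L & b > 0L & a != b)
  a <- lab[, , -d[3]]; b <- lab[, , -1]
  viol <- viol + sum(a > 0L & b > 0L & a != b)
  expect_identical(viol, 0L)
})

test_that("non-periodic interiors are 6-connected within the box", {
  ph <- generate_adipose_phantom(
    extent = c(200, 200, 200), mean_volume = 3e5, cv = 0.25,
    voxel_pitch = c(5, 5, 5), periodic = FALSE, seed = 31
  )
  dims <- dim(ph$label_map)
  for (k in sample(ph$cells$cell_id, min(10, nrow(ph$cells)))) {
    comp <- adipostereo:::cpp_label_components(as.vector(ph$label_map == k), dims)
    expect_equal(max(comp), 1L)
  }
})

test_that("nuclei lie inside their cells", {
  ph <- small_phantom()
  dims <- dim(ph$label_map)
  pitch <- ph$stack$pitch
  for (i in seq_len(nrow(ph$cells))) {
    ctr <- c(ph$cells$nucleus_z[i], ph$cells$nucleus_y[i], ph$cells$nucleus_x[i])
    vi <- adipostereo:::point_to_voxel(dims, pitch, ctr)
    expect_false(is.na(vi))
    expect_equal(ph$label_map[vi], ph$cells$cell_id[i])
  }
})

test_that("generated volumes match the configured distribution over seeds", {
  target_mean <- 1e6
  target_sd <- 0.3 * target_mean
  stats <- t(sapply(1:10, function(s) {
    ph <- generate_adipose_phantom(
      extent = c(600, 600, 600), mean_volume = target_mean, cv = 0.3,
      voxel_pitch = c(10, 10, 10), noise_sd = 0, seed = 400 + s
    )
    v <- ph$cells$true_volume
    c(mean = mean(v), sd = stats::sd(v))
  }))
  expect_lt(abs(mean(stats[, "mean"]) - target_mean),
            max(3 * stats::sd(stats[, "mean"]) / sqrt(10), 0.01 * target_mean))
  expect_lt(abs(mean(stats[, "sd"]) - target_sd),
            max(3 * stats::sd(stats[, "sd"]) / sqrt(10), 0.05 * target_sd))
})

test_that("connective-tissue strands carve stroma without losing volume", {
  ph <- generate_adipose_phantom(
    extent = c(150, 150, 150), n_cells = 6, voxel_pitch = c(5, 5, 5),
    n_strands = 2, strand_radius = 5, noise_sd = 0, seed = 19
  )
  expect_gt(ph$strand_voxels, 0)
  vox <- voxel_volume(ph$stack)
  expect_identical(sum(ph$cells$true_volume) + sum(ph$label_map == 0L) * vox,
                   prod(stack_extent(ph$stack)))
})

test_that("invalid configurations are rejected", {
  expect_error(generate_adipose_phantom(extent = c(103, 100, 100),
                                        n_cells = 5, voxel_pitch = c(5, 5, 5)),
               "integral")
  expect_error(generate_adipose_phantom(extent = c(100, 100, 100),
                                        mean_volume = 1e7,
                                        voxel_pitch = c(5, 5, 5)),
               "unachievable")
  expect_error(generate_adipose_phantom(extent = c(50, 50, 50),
                                        n_cells = 1000,
                                        voxel_pitch = c(5, 5, 5)),
               "accommodate")
  expect_error(generate_adipose_phantom(extent = c(100, 100, 100),
                                        voxel_pitch = c(5, 5, 5)),
               "either")
})

test_that("bead phantoms rasterize spheres faithfully", {
  bp <- generate_bead_phantom(1, diameter_mean = 100, diameter_sd = 0,
                              voxel_pitch = c(5, 5, 5), noise_sd = 0, seed = 2)
  stack <- bp$stack
  n_bright <- sum(stack$intensities > 10000)
  vol_raster <- n_bright * voxel_volume(stack)
  expect_lt(abs(vol_raster - sphere_volume(100)) / sphere_volume(100), 0.05)
  # brute-force voxel-centre-in-sphere oracle agrees exactly
  dims <- dim(stack$intensities)
  ctr <- adipostereo:::vox_centers(dims, stack$pitch, seq_len(prod(dims)))
  inside <- (ctr[, 1] - bp$beads$z)^2 + (ctr[, 2] - bp$beads$y)^2 +
    (ctr[, 3] - bp$beads$x)^2 <= 50^2
  expect_identical(n_bright, sum(inside))
})

test_that("empty bead phantoms are uniformly dark", {
  bp <- generate_bead_phantom(0, noise_sd = 0, extent = c(100, 100, 100),
                              seed = 1)
  expect_equal(nrow(bp$beads), 0)
  expect_true(all(bp$stack$intensities == bp$stack$intensities[1]))
})

test_that("bead diameters follow the configured distribution", {
  bp <- generate_bead_phantom(100, diameter_mean = 99.9, diameter_sd = 1.8,
                              seed = 8)
  expect_equal(nrow(bp$beads), 100)
  expect_lt(abs(mean(bp$beads$diameter) - 99.9), 3 * 1.8 / sqrt(100))
  # no two beads overlap
  d <- as.matrix(stats::dist(bp$beads[, c("z", "y", "x")]))
  diag(d) <- Inf
  rsum <- outer(bp$beads$diameter / 2, bp$beads$diameter / 2, `+`)
  expect_true(all(d >= rsum))
})

test_that("impossible bead packings fail with a diagnostic", {
  expect_error(generate_bead_phantom(30, diameter_mean = 100, diameter_sd = 0,
                                     extent = c(300, 300, 300), seed = 1,
                                     max_tries = 50L),
               "packing|extent too small")
})
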