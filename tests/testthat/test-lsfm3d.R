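test_that("region growing recovers label regions exactly on crisp phantoms", {
  ph <- crisp_phantom()
  gp <- grow_params(tolerance = 10000, max_voxels = 100000L)
  ids <- head(ph$cells$cell_id[order(-ph$cells$interior_voxel_count)], 8)
  for (k in ids) {
    rg <- region_grow(ph, cell_seed_voxel(ph, k), gp)
    expect_false(rg$overflow)
    expect_setequal(rg$indices, which(ph$label_map == k))
  }
})

test_that("region growing is accurate on noisy, blurred phantoms", {
  ph <- small_phantom()
  gp <- grow_params(tolerance = 10000, max_voxels = 100000L)
  ids <- head(ph$cells$cell_id[!ph$cells$clipped_by_boundary &
                                 ph$cells$interior_voxel_count > 500], 6)
  for (k in ids) {
    rg <- region_grow(ph, cell_seed_voxel(ph, k), gp)
    truth <- sum(ph$label_map == k)
    expect_lt(abs(length(rg$indices) - truth) / truth, 0.05)
  }
})

test_that("membrane gaps merge adjacent cells and trip the safety bound", {
  ph <- generate_adipose_phantom(
    extent = c(150, 150, 150), n_cells = 8, voxel_pitch = c(5, 5, 5),
    noise_sd = 0, blur_sigma = 0, membrane_gaps = 1, gap_radius = 8,
    periodic = FALSE, seed = 17
  )
  # the gap joins two labels: growing from one side reaches the other
  dims <- dim(ph$label_map)
  gap_vox <- adipostereo:::point_to_voxel(dims, ph$stack$pitch, ph$gaps[1, ])
  joined <- unique(ph$label_map[c(gap_vox)])
  k <- ph$label_map[gap_vox]
  gp_loose <- grow_params(tolerance = 10000, max_voxels = 500000L)
  rg <- region_grow(ph, cell_seed_voxel(ph, k), gp_loose)
  labs_reached <- unique(ph$label_map[rg$indices])
  expect_gt(length(setdiff(labs_reached, c(0L, k))), 0)
  # with a tight bound the runaway region is flagged, not measured
  gp_tight <- grow_params(tolerance = 10000,
                          max_voxels = sum(ph$label_map == k) + 10L)
  rg2 <- region_grow(ph, cell_seed_voxel(ph, k), gp_tight)
  expect_true(rg2$overflow)
})

test_that("seeding the wand on a membrane voxel is a precondition error", {
  ph <- crisp_phantom()
  dims <- dim(ph$label_map)
  mem_idx <- which(ph$label_map == 0L)[1000]
  co <- adipostereo:::vox_coords(dims, mem_idx)
  expect_error(region_grow(ph, co[1, ], grow_params()), "polarity")
})

test_that("3D disector counts equal the label-map oracle under frame tiling", {
  ph <- crisp_phantom()
  dims <- dim(ph$stack$intensities)
  frames <- tile_frames(dims[2:3] * ph$stack$pitch[2:3], c(100, 100), guard = 1)
  gp <- grow_params(tolerance = 10000, max_voxels = 100000L)
  for (seed in c(2, 5)) {
    pair <- sample_disector_planes(dims[1], ph$stack$pitch[1], 4, seed = seed)
    dc <- disector_count_3d(ph$stack, pair, frames, gp,
                            min_profile_area = 25, both_directions = TRUE)
    q_oracle <- oracle_disector_q(ph, pair$reference_index, pair$lookup_index) +
      oracle_disector_q(ph, pair$lookup_index, pair$reference_index)
    expect_equal(dc$q, q_oracle)
  }
})

test_that("cells spanning both planes are never counted", {
  ph <- small_phantom()
  dims <- dim(ph$stack$intensities)
  frames <- tile_frames(dims[2:3] * ph$stack$pitch[2:3], c(100, 100), guard = 1)
  pair <- sample_disector_planes(dims[1], ph$stack$pitch[1], 4, seed = 3)
  dc <- disector_count_3d(ph$stack, pair, frames, grow_params(max_voxels = 100000L))
  counted <- dc$cells[dc$cells$counted & dc$cells$accepted, ]
  for (i in seq_len(nrow(counted))) {
    zs <- adipostereo:::vox_coords(dims, counted$region[[i]])[, 1]
    ref_of_dir <- if (counted$direction[i] == 1) pair$reference_index else pair$lookup_index
    luk_of_dir <- if (counted$direction[i] == 1) pair$lookup_index else pair$reference_index
    expect_true(ref_of_dir %in% zs)
    expect_false(luk_of_dir %in% zs)
  }
})

test_that("counting is invariant to interchanging the plane roles", {
  ph <- small_phantom()
  dims <- dim(ph$stack$intensities)
  frames <- tile_frames(dims[2:3] * ph$stack$pitch[2:3], c(100, 100), guard = 1)
  gp <- grow_params(max_voxels = 100000L)
  pair <- sample_disector_planes(dims[1], ph$stack$pitch[1], 4, seed = 9)
  swapped <- pair
  swapped$reference_index <- pair$lookup_index
  swapped$lookup_index <- pair$reference_index
  a <- disector_count_3d(ph$stack, pair, frames, gp, both_directions = TRUE)
  b <- disector_count_3d(ph$stack, swapped, frames, gp, both_directions = TRUE)
  expect_equal(a$q, b$q)
  # determinism of repeated runs
  a2 <- disector_count_3d(ph$stack, pair, frames, gp, both_directions = TRUE)
  expect_equal(a$q, a2$q)
  expect_equal(a$cells$voxel_count, a2$cells$voxel_count)
})

test_that("accepted cells are never double counted across frames", {
  ph <- small_phantom()
  dims <- dim(ph$stack$intensities)
  frames <- tile_frames(dims[2:3] * ph$stack$pitch[2:3], c(100, 100), guard = 1)
  pair <- sample_disector_planes(dims[1], ph$stack$pitch[1], 4, seed = 12)
  dc <- disector_count_3d(ph$stack, pair, frames, grow_params(max_voxels = 100000L))
  counted <- dc$cells[dc$cells$counted & dc$cells$accepted, ]
  # regions of distinct counted candidates are disjoint
  if (nrow(counted) > 1) {
    all_idx <- unlist(counted$region)
    expect_equal(length(all_idx), length(unique(all_idx)))
  }
  # q equals the number of counted & accepted candidates
  expect_equal(dc$q, sum(dc$cells$counted & dc$cells$accepted & !dc$cells$overflow))
})

test_that("measured cell volumes apply the voxel and shrinkage arithmetic", {
  ph <- crisp_phantom()
  fake <- tibble::tibble(
    candidate = 1L, region_key = "1", seed_z = 1L, seed_y = 1L, seed_x = 1L,
    voxel_count = 8000L, counted = TRUE, overflow = FALSE, clipped = FALSE,
    region = list(integer()), accepted = TRUE, direction = 1L
  )
  m <- measure_sampled_cells(fake, ph$stack, f_s = 1)
  expect_equal(m$raw_volume, 1e6)
  m2 <- measure_sampled_cells(fake, ph$stack, f_s = 0.92)
  expect_equal(m2$corrected_volume, 1e6 / 0.92^3)
  expect_true(m2$valid)
  fake$clipped <- TRUE
  expect_false(measure_sampled_cells(fake, ph$stack)$valid)
})

test_that("disector-sampled cell volumes match ground truth", {
  ph <- small_phantom()
  dims <- dim(ph$stack$intensities)
  frames <- tile_frames(dims[2:3] * ph$stack$pitch[2:3], c(100, 100), guard = 1)
  gp <- grow_params(max_voxels = 100000L)
  meas <- list()
  for (s in 1:4) {
    pair <- sample_disector_planes(dims[1], ph$stack$pitch[1], 4, seed = 20 + s)
    dc <- disector_count_3d(ph$stack, pair, frames, gp, both_directions = TRUE)
    m <- measure_sampled_cells(dc, ph$stack)
    # match each measured region to its ground-truth cell
    cells <- dc$cells[dc$cells$counted & dc$cells$accepted, ]
    for (i in seq_len(nrow(cells))) {
      labs <- ph$label_map[cells$region[[i]]]
      main <- as.integer(names(which.max(table(labs[labs > 0]))))
      truth <- sum(ph$label_map == main)
      if (!cells$clipped[i] && truth > 160) { # cells at least ~20 voxels across
        expect_lt(abs(cells$voxel_count[i] - truth) / truth, 0.05)
      }
    }
  }
})

test_that("bead QC recovers true bead volumes within tolerance", {
  bp <- generate_bead_phantom(5, diameter_mean = 100, diameter_sd = 0,
                              voxel_pitch = c(5, 5, 5), noise_sd = 0,
                              extent = c(400, 400, 400), seed = 9)
  qc <- bead_qc(bp)
  expect_equal(nrow(qc$beads), 5)
  expect_lt(qc$mean_abs_volume_dev_pct, 5)
  expect_true(qc$pass)
  # finer rasterization reduces the deviation
  bp2 <- generate_bead_phantom(5, diameter_mean = 100, diameter_sd = 0,
                               voxel_pitch = c(2.5, 2.5, 2.5), noise_sd = 0,
                               extent = c(400, 400, 400), seed = 9)
  qc2 <- bead_qc(bp2)
  expect_lt(qc2$mean_abs_volume_dev_pct, qc$mean_abs_volume_dev_pct + 0.5)
  expect_lt(qc2$mean_abs_volume_dev_pct, 2)
  expect_error(bead_qc(generate_bead_phantom(0, extent = c(100, 100, 100),
                                             noise_sd = 0, seed = 1),
                       truth = tibble::tibble()),
               "no beads")
})
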