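#' Region-growing parameters (the "magic wand")
#'
#' @param polarity `"dark"` (unstained cell interiors) or `"bright"`
#'   (beads).
#' @param tolerance absolute intensity half-width around the seed value;
#'   growth includes connected voxels with `|I - I_seed| <= tolerance`. The
#'   default mirrors a wand tolerance of 10000 on a 16-bit range and is
#'   instrument-specific.
#' @param connectivity 6-neighbourhood in 3D (the 2D restriction is the
#'   4-neighbourhood); fixed, recorded for provenance.
#' @param max_voxels safety bound: a region that exceeds it (runaway growth
#'   through a membrane gap) is flagged instead of measured.
#' @return object of class `grow_params`.
#' @export
grow_params <- function(polarity = c("dark", "bright"), tolerance = 10000,
                        max_voxels = 500000L, connectivity = 6L) {
  polarity <- match.arg(polarity)
  if (tolerance < 0) abort("`tolerance` must be >= 0")
  if (max_voxels < 1) abort("`max_voxels` must be positive")
  structure(list(polarity = polarity, tolerance = tolerance,
                 connectivity = as.integer(connectivity),
                 max_voxels = as.integer(max_voxels)),
            class = "grow_params")
}

# Otsu threshold for an integer-intensity matrix/array
otsu_threshold <- function(x, depth) {
  m <- matrix(as.numeric(x) / depth) # column matrix; EBImage accepts any 2D
  as.numeric(EBImage::otsu(m, range = c(0, 1), levels = 256L)) * depth
}

#' Grow a connected region from a seed (tolerance flood fill)
#'
#' The maximal 6-connected (4-connected in 2D) set of voxels containing the
#' seed whose intensities lie within `tolerance` of the seed intensity.
#' Growth is halted by membrane voxels; a region exceeding the safety bound
#' is returned with `overflow = TRUE` and must not be used as a measurement
#' (it indicates growth through a membrane gap, which merges adjacent
#' cells).
#'
#' @param stack a [voxel_stack()] (or a `tissue_phantom`, whose stack is
#'   used).
#' @param seed_point voxel indices `(z, y, x)`, 1-based.
#' @param params a [grow_params()].
#' @return object of class `cell_region`: list with `indices` (1-based
#'   linear voxel indices), `overflow`, `seed_point`, `seed_intensity`.
#' @export
region_grow <- function(stack, seed_point, params = grow_params()) {
  if (inherits(stack, "tissue_phantom")) stack <- stack$stack
  dims <- dim(stack$intensities)
  sp <- as.integer(seed_point)
  if (any(sp < 1L) || any(sp > dims)) abort("seed point outside the grid")
  si <- vox_index(dims, sp[1], sp[2], sp[3])
  val <- stack$intensities[si]
  plane <- stack$intensities[sp[1], , ]
  thr <- otsu_threshold(plane, stack$depth)
  if (params$polarity == "dark" && val >= thr) {
    abort("seed intensity inconsistent with dark-object polarity (membrane voxel?)")
  }
  if (params$polarity == "bright" && val <= thr) {
    abort("seed intensity inconsistent with bright-object polarity")
  }
  res <- cpp_flood(stack$intensities, dims, as.integer(si - 1),
                   val - params$tolerance, val + params$tolerance,
                   params$max_voxels)
  structure(list(indices = res$indices, overflow = res$overflow,
                 seed_point = sp, seed_intensity = val),
            class = "cell_region")
}

#' Count adipocytes in a 3D optical disector
#'
#' On the reference optical plane, dark profiles are detected (automatic
#' threshold, 4-connected components), each is grown into its 3D region with
#' the wand, and a cell is counted if its 3D region intersects the reference
#' plane but not the look-up plane and its reference-plane profile (the
#' intersection of the 3D region with that plane) is accepted by one of the
#' unbiased counting frames. With `both_directions = TRUE` the roles of the
#' two planes are interchanged and the tallies summed, doubling the
#' efficiency; the examined disector volume doubles accordingly.
#'
#' Candidates whose growth overflows the safety bound (suspected membrane
#' gap) are excluded from the count and flagged in the output.
#'
#' @param stack a [voxel_stack()] or `tissue_phantom`.
#' @param pair a [sample_disector_planes()] row (`disector_pair`).
#' @param frames list of [counting_frame()] in plane coordinates (um,
#'   congruent on both planes).
#' @param params a [grow_params()] (dark objects).
#' @param min_profile_area smallest profile area considered a cell profile,
#'   um^2.
#' @param both_directions run both counting directions (default `TRUE`).
#' @return list of class `disector_count`: `q` (total Q-), `tally`
#'   (a [disector_tally()], one row per direction), `cells` (tibble of all
#'   sampled candidates with regions and flags).
#' @export
disector_count_3d <- function(stack, pair, frames, params = grow_params(),
                              min_profile_area = 100, both_directions = TRUE) {
  ph <- if (inherits(stack, "tissue_phantom")) stack else NULL
  if (!is.null(ph)) stack <- ph$stack
  dims <- dim(stack$intensities)
  pitch <- stack$pitch
  dirs <- if (both_directions) {
    list(c(pair$reference_index, pair$lookup_index),
         c(pair$lookup_index, pair$reference_index))
  } else {
    list(c(pair$reference_index, pair$lookup_index))
  }
  area_frames <- sum(vapply(frames, frame_area, numeric(1)))
  all_cells <- list()
  q_dir <- integer(length(dirs))
  for (d in seq_along(dirs)) {
    zr <- dirs[[d]][1]; zl <- dirs[[d]][2]
    cells <- disector_pass(stack, zr, zl, frames, params, min_profile_area)
    cells$direction <- d
    q_dir[d] <- sum(cells$counted & cells$accepted & !cells$overflow)
    all_cells[[d]] <- cells
  }
  cells <- bind_rows(all_cells)
  tally <- disector_tally(q = q_dir, area = area_frames, h = pair$h)
  structure(list(q = sum(q_dir), tally = tally, cells = cells,
                 pair = pair, frames = frames),
            class = "disector_count")
}

# one counting direction: detect profiles on the reference plane, grow 3D,
# apply the disector rule and the counting-frame rule
disector_pass <- function(stack, zr, zl, frames, params, min_profile_area) {
  dims <- dim(stack$intensities)
  pitch <- stack$pitch
  plane <- stack$intensities[zr, , ]
  thr <- otsu_threshold(plane, stack$depth)
  mask <- plane < thr
  lab2 <- matrix(cpp_label_components(as.vector(mask), c(1L, dims[2], dims[3])),
                 dims[2], dims[3])
  min_px <- max(1L, ceiling(min_profile_area / (pitch[2] * pitch[3])))
  sizes <- tabulate(lab2[lab2 > 0L])
  cand_ids <- which(sizes >= min_px)
  if (length(cand_ids) == 0) {
    return(empty_candidates())
  }
  rows <- list()
  seen <- character()
  prof_mat <- matrix(0L, dims[2], dims[3])
  ci <- 0L
  for (id in cand_ids) {
    pix <- which(lab2 == id)
    # seed at the pixel of median profile intensity: a typical interior
    # value, robust against noise minima that would shift the wand window
    seed_pix <- pix[which.min(abs(plane[pix] - stats::median(plane[pix])))]
    iy <- (seed_pix - 1L) %% dims[2] + 1L
    ix <- (seed_pix - 1L) %/% dims[2] + 1L
    si <- vox_index(dims, zr, iy, ix)
    val <- stack$intensities[si]
    if (val >= thr) next # not a dark seed
    res <- cpp_flood(stack$intensities, dims, as.integer(si - 1),
                     val - params$tolerance, val + params$tolerance,
                     params$max_voxels)
    if (length(res$indices) == 0) next
    key <- as.character(min(res$indices))
    if (key %in% seen) next
    seen <- c(seen, key)
    co <- vox_coords(dims, res$indices)
    counted <- !any(co[, 1] == zl)
    clipped <- any(co[, 1] == 1L | co[, 1] == dims[1] |
                     co[, 2] == 1L | co[, 2] == dims[2] |
                     co[, 3] == 1L | co[, 3] == dims[3])
    ci <- ci + 1L
    ref_pix <- co[co[, 1] == zr, , drop = FALSE]
    prof_mat[cbind(ref_pix[, 2], ref_pix[, 3])] <- ci
    rows[[ci]] <- tibble(
      candidate = ci, region_key = key,
      seed_z = zr, seed_y = iy, seed_x = ix,
      voxel_count = length(res$indices),
      counted = counted, overflow = res$overflow, clipped = clipped,
      region = list(res$indices)
    )
  }
  if (ci == 0L) return(empty_candidates())
  cells <- bind_rows(rows)
  acc <- integer()
  for (f in frames) {
    acc <- union(acc, apply_counting_frame(f, prof_mat,
                                           pixel_pitch = pitch[2:3],
                                           origin = c(0, 0)))
  }
  cells$accepted <- cells$candidate %in% acc
  cells
}

empty_candidates <- function() {
  tibble(candidate = integer(), region_key = character(),
         seed_z = integer(), seed_y = integer(), seed_x = integer(),
         voxel_count = integer(), counted = logical(), overflow = logical(),
         clipped = logical(), region = list(), accepted = logical())
}

#' Measure individual volumes of disector-sampled cells
#'
#' Voxel-count volumetry of the cells sampled (counted) by the 3D disector:
#' `raw = voxel count x voxel volume`, shrinkage-corrected
#' `V_i = raw / f_s^3`. Cells clipped by the stack boundary are flagged
#' invalid (their volumes would be truncated); overflowed regions are
#' flagged as membrane-gap suspects and invalid.
#'
#' @param counts a `disector_count` (or a tibble of its `cells`).
#' @param stack the [voxel_stack()] the regions were grown in (for the
#'   voxel pitch).
#' @param f_s linear tissue shrinkage factor used for correction.
#' @param counted_only measure only cells that satisfied the disector rule
#'   and frame rule (the unbiased number-weighted sample); default `TRUE`.
#' @return tibble of class `cell_measurements`: `cell_id`, `voxel_count`,
#'   `raw_volume`, `corrected_volume`, `f_s`, `clipped`, `gap_suspect`,
#'   `valid`.
#' @export
measure_sampled_cells <- function(counts, stack, f_s = 1, counted_only = TRUE) {
  cells <- if (inherits(counts, "disector_count")) counts$cells else counts
  if (inherits(stack, "tissue_phantom")) stack <- stack$stack
  vv <- voxel_volume(stack)
  if (counted_only && nrow(cells) > 0) {
    cells <- dplyr::filter(cells, .data$counted & .data$accepted)
  }
  raw <- cells$voxel_count * vv
  out <- tibble(
    cell_id = seq_len(nrow(cells)),
    voxel_count = cells$voxel_count,
    raw_volume = raw,
    corrected_volume = correct_cell_volume(raw, f_s),
    f_s = f_s,
    clipped = cells$clipped,
    gap_suspect = cells$overflow,
    valid = !cells$clipped & !cells$overflow
  )
  structure(out, class = c("cell_measurements", class(tibble())))
}

#' Microbead imaging quality control
#'
#' Segments bright spherical microbeads from a calibration stack
#' (automatic threshold, 6-connected components), measures each bead's
#' voxel-count volume and equivalent-sphere diameter, matches beads to the
#' ground truth by nearest centre, and reports percent deviations from the
#' analytic sphere volumes — the check that voxel scaling and volume
#' rendering are faithful.
#'
#' @param phantom a bead `tissue_phantom` (from [generate_bead_phantom()]),
#'   or a [voxel_stack()] plus `truth`.
#' @param truth tibble of true beads (`bead_id`, `z`, `y`, `x`,
#'   `diameter`); defaults to the phantom's ground truth.
#' @param pass_threshold acceptable mean absolute volume deviation, percent.
#' @param min_voxels smallest component considered a bead.
#' @return list of class `bead_qc`: `beads` (per-bead tibble),
#'   `mean_abs_volume_dev_pct`, `mean_volume_dev_pct`, `pass`.
#' @export
bead_qc <- function(phantom, truth = NULL, pass_threshold = 5, min_voxels = 8L) {
  stack <- if (inherits(phantom, "tissue_phantom")) phantom$stack else phantom
  if (is.null(truth)) {
    if (!inherits(phantom, "tissue_phantom")) abort("`truth` required")
    truth <- phantom$beads
  }
  if (nrow(truth) == 0) abort("no beads in the ground truth")
  dims <- dim(stack$intensities)
  pitch <- stack$pitch
  thr <- otsu_threshold(stack$intensities, stack$depth)
  mask <- as.vector(stack$intensities) > thr
  lab <- cpp_label_components(mask, dims)
  sizes <- tabulate(lab[lab > 0L])
  ids <- which(sizes >= min_voxels)
  if (length(ids) == 0) abort("no beads found in the stack")
  vv <- voxel_volume(stack)
  idx <- which(lab > 0L)
  labv <- lab[idx]
  keepv <- labv %in% ids
  idx <- idx[keepv]; labv <- labv[keepv]
  ctr <- vox_centers(dims, pitch, idx)
  cen <- rowsum(ctr, labv) / sizes[ids]
  meas <- tibble(
    component = ids,
    z = cen[, 1], y = cen[, 2], x = cen[, 3],
    measured_volume = sizes[ids] * vv,
    measured_diameter = 2 * (3 * sizes[ids] * vv / (4 * pi))^(1 / 3)
  )
  # nearest-centre matching
  res <- purrr::map_dfr(seq_len(nrow(truth)), function(b) {
    d2 <- (meas$z - truth$z[b])^2 + (meas$y - truth$y[b])^2 + (meas$x - truth$x[b])^2
    j <- which.min(d2)
    true_vol <- sphere_volume(truth$diameter[b])
    tibble(
      bead_id = truth$bead_id[b],
      true_diameter = truth$diameter[b],
      true_volume = true_vol,
      measured_volume = meas$measured_volume[j],
      measured_diameter = meas$measured_diameter[j],
      center_offset = sqrt(d2[j]),
      volume_dev_pct = 100 * (meas$measured_volume[j] - true_vol) / true_vol,
      diameter_dev_pct = 100 * (meas$measured_diameter[j] - truth$diameter[b]) /
        truth$diameter[b]
    )
  })
  mean_abs <- mean(abs(res$volume_dev_pct))
  structure(
    list(beads = res,
         mean_abs_volume_dev_pct = mean_abs,
         mean_volume_dev_pct = mean(res$volume_dev_pct),
         pass = mean_abs <= pass_threshold,
         pass_threshold = pass_threshold,
         n_components = length(ids)),
    class = "bead_qc"
  )
}

#' @export
print.bead_qc <- function(x, ...) {
  cat(sprintf("<bead_qc> %d beads, mean |volume deviation| %.2f%% (%s at %.0f%%)\n",
              nrow(x$beads), x$mean_abs_volume_dev_pct,
              if (x$pass) "PASS" else "FAIL", x$pass_threshold))
  invisible(x)
}
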