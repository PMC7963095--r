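#' Generate a microbead calibration phantom
#'
#' Simulates the imaging quality-control object used to verify voxel scaling
#' and volume rendering: fluorescent spherical microbeads (default diameter
#' 99.9 +/- 1.8 um) embedded at random, non-overlapping positions with
#' continuous (sub-voxel) centre offsets, rasterized as bright solid spheres
#' on a dark background.
#'
#' @param n_beads number of beads (0 gives a uniformly dark stack).
#' @param diameter_mean,diameter_sd bead diameter distribution in
#'   micrometres.
#' @param voxel_pitch voxel pitch `(dz, dy, dx)` in micrometres.
#' @param extent physical box `(z, y, x)` in micrometres; `NULL` picks a box
#'   sized for ~20% bead packing.
#' @param bead_intensity,background_intensity,noise_sd intensity model.
#' @param min_separation minimum surface-to-surface distance between beads
#'   (micrometres). Keep it above ~2 voxels so that rasterized beads can
#'   never touch and merge into one segmented component.
#' @param max_tries placement rejection-sampling budget per bead.
#' @param depth intensity depth.
#' @param seed RNG seed.
#'
#' @return A `tissue_phantom` whose `beads` tibble holds the ground truth
#'   (`bead_id`, centre `z`, `y`, `x` in um, `diameter` in um); `cells` is
#'   empty and `label_map` is `NULL`.
#' @export
#' @examples
#' bp <- generate_bead_phantom(3, seed = 1)
#' bp$beads
generate_bead_phantom <- function(n_beads,
                                  diameter_mean = 99.9,
                                  diameter_sd = 1.8,
                                  voxel_pitch = c(5, 5, 5),
                                  extent = NULL,
                                  bead_intensity = 30000,
                                  background_intensity = 500,
                                  noise_sd = 300,
                                  min_separation = 12,
                                  max_tries = 500L,
                                  depth = 65535L,
                                  seed = NULL) {
  voxel_pitch <- as.numeric(voxel_pitch)
  if (n_beads < 0) abort("`n_beads` must be >= 0")
  if (is.null(extent)) {
    d_hi <- diameter_mean + 4 * diameter_sd
    side <- max(
      (max(n_beads, 1) * sphere_volume(d_hi + min_separation) / 0.2)^(1 / 3) +
        d_hi + 6 * max(voxel_pitch),
      d_hi + 6 * max(voxel_pitch)
    )
    extent <- rep(ceiling(side / max(voxel_pitch)) * max(voxel_pitch), 3)
  }
  extent <- as.numeric(extent)
  dims <- extent / voxel_pitch
  if (any(abs(dims - round(dims)) > 1e-8)) {
    abort("`extent` must be an integral number of voxels for the given `voxel_pitch`")
  }
  dims <- as.integer(round(dims))

  config <- list(
    n_beads = n_beads, diameter_mean = diameter_mean, diameter_sd = diameter_sd,
    voxel_pitch = voxel_pitch, extent = extent, bead_intensity = bead_intensity,
    background_intensity = background_intensity, noise_sd = noise_sd,
    min_separation = min_separation, depth = depth
  )

  with_seed(seed, {
    diam <- if (n_beads > 0) {
      pmax(rnorm(n_beads, diameter_mean, diameter_sd), 2 * max(voxel_pitch))
    } else numeric()
    centers <- matrix(NA_real_, n_beads, 3)
    for (b in seq_len(n_beads)) {
      r <- diam[b] / 2
      margin <- r + max(voxel_pitch)
      if (any(extent - 2 * margin <= 0)) {
        abort("extent too small to contain a bead")
      }
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- margin + runif(3) * (extent - 2 * margin)
        if (b == 1L) { centers[b, ] <- cand; placed <- TRUE; break }
        prev <- centers[seq_len(b - 1L), , drop = FALSE]
        dist <- sqrt(rowSums(sweep(prev, 2, cand)^2))
        if (all(dist >= r + diam[seq_len(b - 1L)] / 2 + min_separation)) {
          centers[b, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) {
        abort(sprintf(
          "bead packing failed at bead %d of %d after %d tries; enlarge the extent",
          b, n_beads, max_tries
        ))
      }
    }

    img <- array(background_intensity, dims)
    for (b in seq_len(n_beads)) {
      r <- diam[b] / 2
      zr <- max(1, floor((centers[b, 1] - r) / voxel_pitch[1])):min(dims[1], ceiling((centers[b, 1] + r) / voxel_pitch[1]))
      yr <- max(1, floor((centers[b, 2] - r) / voxel_pitch[2])):min(dims[2], ceiling((centers[b, 2] + r) / voxel_pitch[2]))
      xr <- max(1, floor((centers[b, 3] - r) / voxel_pitch[3])):min(dims[3], ceiling((centers[b, 3] + r) / voxel_pitch[3]))
      g <- expand.grid(iz = zr, iy = yr, ix = xr)
      gz <- (g$iz - 0.5) * voxel_pitch[1]
      gy <- (g$iy - 0.5) * voxel_pitch[2]
      gx <- (g$ix - 0.5) * voxel_pitch[3]
      inside <- (gz - centers[b, 1])^2 + (gy - centers[b, 2])^2 +
        (gx - centers[b, 3])^2 <= r^2
      img[vox_index(dims, g$iz[inside], g$iy[inside], g$ix[inside])] <- bead_intensity
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img <- round(pmin(pmax(img, 0), depth))
    stack <- voxel_stack(array(as.integer(img), dims), voxel_pitch, depth)

    beads <- tibble(
      bead_id = seq_len(n_beads),
      z = centers[, 1], y = centers[, 2], x = centers[, 3],
      diameter = diam
    )
    structure(
      list(stack = stack, label_map = NULL,
           cells = tibble(cell_id = integer(), interior_voxel_count = integer(),
                          true_volume = numeric()),
           beads = beads, gaps = NULL, config = config, seed = seed),
      class = "tissue_phantom"
    )
  })
}
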