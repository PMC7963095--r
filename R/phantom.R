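#' Generate a synthetic adipose tissue phantom with exhaustive ground truth
#'
#' Builds a membrane-labelled 3D stack of space-filling polyhedral adipocytes
#' from a seeded additively weighted Voronoi (Laguerre) tessellation. Cell
#' membranes are rendered as a bright, thin, continuous sheet (one rasterized
#' wall voxel between any two adjacent cell interiors), interiors are dark,
#' and additive Gaussian noise emulates detector noise. Every cell's interior
#' voxel count, volume, centroid, nucleus position and boundary-clipping flag
#' are recorded, so stereological estimators can be validated against exact
#' ground truth.
#'
#' Individual target cell volumes are drawn from a Normal distribution
#' truncated at `0.01 * mean_volume` (unilocular adipocyte volumes are
#' reported to be normally distributed). Because the tessellation is
#' space-filling, the achieved mean interior volume is set by the number of
#' seeds and the achieved spread by the Laguerre weights; both are calibrated
#' iteratively against the rasterized interior volumes when `calibrate` is
#' `TRUE`.
#'
#' @param extent physical box size `(z, y, x)` in micrometres; must be an
#'   integer number of voxels along each axis.
#' @param n_cells target number of cells (alternative to `mean_volume`).
#' @param mean_volume target mean individual cell volume in cubic
#'   micrometres (alternative to `n_cells`).
#' @param cv coefficient of variation of individual cell volumes.
#' @param membrane_thickness membrane thickness in micrometres; rasterized to
#'   at least one voxel.
#' @param membrane_intensity,interior_intensity intensity plateaus (16-bit
#'   scale by default).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units); 0 disables noise.
#' @param blur_sigma Gaussian blur of the rendered plateaus, in voxels
#'   (default 0.42, i.e. a kernel of one voxel FWHM). The sub-voxel default
#'   keeps rendered membranes thin, mirroring the practice of limiting
#'   stained membrane width below the voxel pitch, and keeps the blurred
#'   interior shell inside the default wand tolerance window.
#' @param n_strands number of connective-tissue strands traversing the box.
#' @param strand_radius strand radius in micrometres.
#' @param voxel_pitch voxel pitch `(dz, dy, dx)` in micrometres.
#' @param nucleus_diameter nucleus diameter in micrometres. One spherical
#'   nucleus per cell is placed adjacent to the membrane (peripheral rim
#'   nucleus of unilocular fat cells).
#' @param membrane_gaps number of membrane gaps to inject (default 0: the
#'   membrane is continuous and interiors are guaranteed disconnected).
#' @param gap_radius radius of each injected gap in micrometres.
#' @param periodic tessellate on a torus (wrapped distances; default
#'   `TRUE`). Periodic phantoms are statistically homogeneous — no boundary
#'   layer of smaller cells, and cell "tops" are exactly uniform in z — so
#'   the number density `n_cells / extent volume` is the exact ground truth
#'   for disector estimates. Cells crossing a box face appear as
#'   face-touching fragments and are flagged `clipped_by_boundary` (on the
#'   torus they are single connected cells; within the box their fragments
#'   share one label). With `periodic = FALSE` the box is partitioned
#'   outright and every interior region is 6-connected within the box.
#' @param boundary_membrane render a membrane shell on the six box faces
#'   (default `FALSE`: the stack is an interior sub-volume of tissue and
#'   boundary cells are clipped and flagged).
#' @param calibrate iteratively tune seed count and Laguerre weight spread to
#'   the target mean/CV. With `FALSE` the first pass is used as-is, which
#'   makes phantoms at geometrically scaled configurations exactly similar
#'   (used for shrinkage round trips).
#' @param depth intensity depth (maximum representable value).
#' @param seed RNG seed; identical `(config, seed)` gives an identical
#'   phantom.
#'
#' @return An object of class `tissue_phantom`: list with `stack`
#'   ([voxel_stack()]), `label_map` (3D integer array, 0 = membrane/stroma,
#'   k = interior of cell k), `cells` (tibble of ground truth), `beads`
#'   (empty tibble), `gaps`, `config`, `seed`.
#' @export
#' @examples
#' ph <- generate_adipose_phantom(
#'   extent = c(200, 200, 200), n_cells = 8, voxel_pitch = c(10, 10, 10),
#'   noise_sd = 0, seed = 1
#' )
#' ph$cells
generate_adipose_phantom <- function(extent = c(500, 500, 500),
                                     n_cells = NULL,
                                     mean_volume = NULL,
                                     cv = 0.3,
                                     membrane_thickness = 5,
                                     membrane_intensity = 45000,
                                     interior_intensity = 2000,
                                     noise_sd = 800,
                                     blur_sigma = 0.42,
                                     n_strands = 0,
                                     strand_radius = 5,
                                     voxel_pitch = c(5, 5, 5),
                                     nucleus_diameter = 10,
                                     membrane_gaps = 0,
                                     gap_radius = 8,
                                     periodic = TRUE,
                                     boundary_membrane = FALSE,
                                     calibrate = TRUE,
                                     depth = 65535L,
                                     seed = NULL) {
  extent <- as.numeric(extent)
  voxel_pitch <- as.numeric(voxel_pitch)
  dims <- extent / voxel_pitch
  if (any(abs(dims - round(dims)) > 1e-8)) {
    abort("`extent` must be an integral number of voxels for the given `voxel_pitch`")
  }
  dims <- as.integer(round(dims))
  if (any(dims < 2L)) abort("extent too small for the given pitch")
  vox_vol <- prod(voxel_pitch)
  v_box <- prod(extent)
  if (is.null(n_cells) && is.null(mean_volume)) {
    abort("give either `n_cells` or `mean_volume`")
  }
  if (!is.null(mean_volume) && mean_volume > 0.9 * v_box) {
    abort("target mean cell volume is unachievable within the extent")
  }
  if (!is.null(n_cells) && (n_cells < 1 || n_cells * 8 * vox_vol > v_box)) {
    abort("extent cannot accommodate the requested number of cells")
  }

  config <- list(
    extent = extent, n_cells = n_cells, mean_volume = mean_volume, cv = cv,
    membrane_thickness = membrane_thickness,
    membrane_intensity = membrane_intensity,
    interior_intensity = interior_intensity, noise_sd = noise_sd,
    blur_sigma = blur_sigma, n_strands = n_strands,
    strand_radius = strand_radius, voxel_pitch = voxel_pitch,
    nucleus_diameter = nucleus_diameter, membrane_gaps = membrane_gaps,
    gap_radius = gap_radius, periodic = periodic,
    boundary_membrane = boundary_membrane,
    calibrate = calibrate, depth = depth
  )

  with_seed(seed, {
    interior_frac_guess <- 0.875
    if (!is.null(n_cells)) {
      K <- as.integer(n_cells)
      scale_vol <- interior_frac_guess * v_box / K
    } else {
      K <- max(1L, as.integer(round(interior_frac_guess * v_box / mean_volume)))
      scale_vol <- mean_volume
    }

    mem_thick_vox <- max(1L, as.integer(round(membrane_thickness / min(voxel_pitch))))

    # ---- calibration: K sets the mean (phase 1, fresh geometry per K),
    # ---- the Laguerre weight spread s sets the CV (phase 2, frozen
    # ---- geometry so the secant iteration sees a smooth response) ----
    s <- 0.35
    run_once <- function(seeds_um, radii, s) {
      w <- s * radii^2
      owner_v <- cpp_lag_assign(dims, voxel_pitch, seeds_um, w, periodic)
      owner <- array(owner_v, dims)
      partition_interiors(owner, dims, mem_thick_vox, boundary_membrane,
                          periodic)
    }
    seeds_um <- draw_cell_seeds(K, extent, periodic)
    vols_target <- rtrunc_normal(K, scale_vol, cv * scale_vol,
                                 lower = 0.01 * scale_vol)
    radii <- (3 * vols_target / (4 * pi))^(1 / 3)
    res <- run_once(seeds_um, radii, s)
    if (calibrate) {
      # phase 1: hit the target mean (or exact cell count)
      for (iter in seq_len(5L)) {
        vols <- res$counts * vox_vol
        if (!is.null(n_cells)) {
          if (length(vols) == n_cells) break
          s <- s * 0.5 # lost cells to empty Laguerre regions: damp weights
        } else {
          if (abs(mean(vols) / mean_volume - 1) < 0.008) break
          K <- max(1L, as.integer(round(K * mean(vols) / mean_volume)))
          seeds_um <- draw_cell_seeds(K, extent, periodic)
          vols_target <- rtrunc_normal(K, scale_vol, cv * scale_vol,
                                       lower = 0.01 * scale_vol)
          radii <- (3 * vols_target / (4 * pi))^(1 / 3)
        }
        res <- run_once(seeds_um, radii, s)
      }
      # phase 2: bracketed secant on log-spread for the CV
      if (!is.na(cv) && cv > 0 && length(res$counts) > 2) {
        s_lo <- NA_real_; cv_lo <- NA_real_; s_hi <- NA_real_; cv_hi <- NA_real_
        for (iter in seq_len(10L)) {
          vols <- res$counts * vox_vol
          cvhat <- stats::sd(vols) / mean(vols)
          bad_n <- !is.null(n_cells) && length(vols) != n_cells
          if (!bad_n && abs(cvhat / cv - 1) < 0.02) break
          if (bad_n || cvhat > cv) { s_hi <- s; cv_hi <- cvhat } else { s_lo <- s; cv_lo <- cvhat }
          if (!is.na(s_lo) && !is.na(s_hi)) {
            s <- sqrt(s_lo * s_hi)
          } else if (cvhat > 0) {
            s <- s * min(max((cv / cvhat)^1.5, 0.25), 4)
          } else {
            s <- s * 2
          }
          s <- min(max(s, 1e-4), 1e3)
          res <- run_once(seeds_um, radii, s)
        }
      }
    }

    label <- res$label
    owner <- res$owner
    keep_ids <- res$keep_ids # original seed indices of surviving cells, in label order
    counts <- res$counts

    # ---- optional membrane gaps ----
    gaps <- NULL
    if (membrane_gaps > 0) {
      gp <- inject_membrane_gaps(label, owner, dims, voxel_pitch,
                                 membrane_gaps, gap_radius)
      label <- gp$label
      counts <- tabulate(label[label > 0L], nbins = length(keep_ids))
      gaps <- gp$gaps
    }

    # ---- ground truth ----
    idx_in <- which(label > 0L)
    lab_in <- label[idx_in]
    ctr <- vox_centers(dims, voxel_pitch, idx_in)
    centroid <- if (periodic) {
      # wrapped mean relative to each cell's seed (cells may span box faces)
      sd_of_vox <- seeds_um[keep_ids, , drop = FALSE][lab_in, , drop = FALSE]
      delta <- ctr - sd_of_vox
      delta <- sweep(delta, 2, extent, function(d, L) (d + L / 2) %% L - L / 2)
      (seeds_um[keep_ids, , drop = FALSE] +
         rowsum(delta, lab_in) / as.vector(counts)) %%
        matrix(extent, length(keep_ids), 3, byrow = TRUE)
    } else {
      rowsum(ctr, lab_in) / as.vector(counts)
    }
    face_owner <- unique(c(owner[1, , ], owner[dims[1], , ],
                           owner[, 1, ], owner[, dims[2], ],
                           owner[, , 1], owner[, , dims[3]]))
    clipped <- seq_along(keep_ids) %in% match(face_owner, keep_ids)
    nuc <- place_nuclei(label, dims, voxel_pitch, centroid,
                        nucleus_diameter / 2, idx_in, lab_in)

    cells <- tibble(
      cell_id = seq_along(keep_ids),
      interior_voxel_count = as.integer(counts),
      true_volume = counts * vox_vol,
      centroid_z = centroid[, 1], centroid_y = centroid[, 2],
      centroid_x = centroid[, 3],
      nucleus_z = nuc[, 1], nucleus_y = nuc[, 2], nucleus_x = nuc[, 3],
      nucleus_radius = nucleus_diameter / 2,
      clipped_by_boundary = clipped
    )

    # ---- strands ----
    strand_mask <- NULL
    if (n_strands > 0) {
      strand_mask <- draw_strands(dims, voxel_pitch, extent, n_strands, strand_radius)
      label[strand_mask] <- 0L
      # re-tally after strand carving
      counts2 <- tabulate(label[label > 0L], nbins = nrow(cells))
      cells$interior_voxel_count <- as.integer(counts2)
      cells$true_volume <- counts2 * vox_vol
      cells <- dplyr::filter(cells, .data$interior_voxel_count > 0L)
      cells$cell_id <- seq_len(nrow(cells)) # relabel below
      label <- relabel_dense(label)
    }

    # ---- render intensities ----
    base <- array(interior_intensity, dims)
    base[label == 0L] <- membrane_intensity
    if (blur_sigma > 0) base <- gauss_blur3(base, blur_sigma)
    if (noise_sd > 0) base <- base + rnorm(length(base), 0, noise_sd)
    base <- round(pmin(pmax(base, 0), depth))
    stack <- voxel_stack(array(as.integer(base), dims), voxel_pitch, depth)

    structure(
      list(stack = stack, label_map = label, cells = cells,
           beads = tibble(bead_id = integer(), z = numeric(), y = numeric(),
                          x = numeric(), diameter = numeric()),
           gaps = gaps, strand_voxels = sum(strand_mask %||% 0),
           config = config, seed = seed,
           seeds_um = seeds_um[keep_ids, , drop = FALSE],
           weights = s * radii[keep_ids]^2),
      class = "tissue_phantom"
    )
  })
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("<tissue_phantom> %d cells, %d beads, seed %s\n",
              nrow(x$cells), nrow(x$beads),
              if (is.null(x$seed)) "<none>" else format(x$seed)))
  print(x$stack)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Isotropic low-variance seed points: hard-core (Poisson-disk) rejection
# sampling followed by a few Lloyd relaxation steps on a coarse grid whose
# resolution is tied to the extent (so geometrically scaled configurations
# yield exactly scaled seeds). Unlike lattice seeds this has no preferred
# planes, so probe positions never align with cell layers.
draw_cell_seeds <- function(K, extent, periodic = TRUE, hardcore_frac = 0.7,
                            lloyd_iter = 2L, lloyd_res = 32L) {
  s2 <- (hardcore_frac * (prod(extent) / K)^(1 / 3))^2
  pts <- matrix(NA_real_, K, 3)
  n <- 0L; tries <- 0L; max_tries <- 4000L * K
  min_d2 <- function(existing, cand) {
    d <- abs(sweep(existing, 2, cand))
    if (periodic) {
      d <- pmin(d, sweep(-d, 2, extent, `+`))
    }
    min(rowSums(d^2))
  }
  while (n < K && tries < max_tries) {
    tries <- tries + 1L
    cand <- runif(3) * extent
    if (n == 0L || min_d2(pts[seq_len(n), , drop = FALSE], cand) >= s2) {
      n <- n + 1L
      pts[n, ] <- cand
    }
  }
  if (n < K) { # dense packing stalled: fill the rest unconstrained
    extra <- matrix(runif(3 * (K - n)), ncol = 3) *
      matrix(extent, K - n, 3, byrow = TRUE)
    pts[(n + 1L):K, ] <- extra
  }
  if (lloyd_iter > 0L) {
    gdim <- rep(as.integer(lloyd_res), 3)
    gpitch <- extent / lloyd_res
    for (it in seq_len(lloyd_iter)) {
      o <- cpp_lag_assign(gdim, gpitch, pts, rep(0, K), periodic)
      ctr <- vox_centers(gdim, gpitch, seq_along(o))
      if (periodic) {
        # wrapped mean relative to each seed
        delta <- ctr - pts[o, , drop = FALSE]
        delta <- sweep(delta, 2, extent, function(d, L) (d + L / 2) %% L - L / 2)
        sums <- rowsum(delta, o)
        cnts <- tabulate(o, K)
        nz <- cnts > 0L
        ids <- as.integer(rownames(sums))
        pts[ids, ] <- (pts[ids, , drop = FALSE] + sums / cnts[nz]) %%
          matrix(extent, length(ids), 3, byrow = TRUE)
      } else {
        sums <- rowsum(ctr, o)
        cnts <- tabulate(o, K)
        nz <- cnts > 0L
        pts[as.integer(rownames(sums)), ] <- sums / cnts[nz]
      }
    }
  }
  pts
}

# Normal(mean, sd) truncated below at `lower`, by resampling
rtrunc_normal <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    tries <- tries + 1L
  }
  x[x < lower] <- lower
  x
}

# Mark single-sided membrane walls wherever the Laguerre owner changes along
# a positive axis step (cyclically for periodic tessellations), thicken to
# `thick` voxels, enforce per-cell interior connectivity (in the box for
# plain tessellations; on the torus a cell's box fragments are kept), and
# relabel densely.
partition_interiors <- function(owner, dims, thick, boundary_membrane,
                                periodic = FALSE) {
  mem <- array(FALSE, dims)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  mark_axis <- function(mem, a, b, axis) {
    # mark voxels at index set a where owner differs from index set b
    if (axis == 1) {
      df <- owner[a, , , drop = FALSE] != owner[b, , , drop = FALSE]
      sub <- mem[a, , , drop = FALSE]; sub[df] <- TRUE; mem[a, , ] <- sub
      if (thick >= 2) { sub <- mem[b, , , drop = FALSE]; sub[df] <- TRUE; mem[b, , ] <- sub }
    } else if (axis == 2) {
      df <- owner[, a, , drop = FALSE] != owner[, b, , drop = FALSE]
      sub <- mem[, a, , drop = FALSE]; sub[df] <- TRUE; mem[, a, ] <- sub
      if (thick >= 2) { sub <- mem[, b, , drop = FALSE]; sub[df] <- TRUE; mem[, b, ] <- sub }
    } else {
      df <- owner[, , a, drop = FALSE] != owner[, , b, drop = FALSE]
      sub <- mem[, , a, drop = FALSE]; sub[df] <- TRUE; mem[, , a] <- sub
      if (thick >= 2) { sub <- mem[, , b, drop = FALSE]; sub[df] <- TRUE; mem[, , b] <- sub }
    }
    mem
  }
  lower <- function(n) if (periodic) seq_len(n) else seq_len(n - 1)
  upper <- function(n) if (periodic) c(seq_len(n)[-1], 1L) else seq_len(n)[-1]
  if (nz > 1) mem <- mark_axis(mem, lower(nz), upper(nz), 1)
  if (ny > 1) mem <- mark_axis(mem, lower(ny), upper(ny), 2)
  if (nx > 1) mem <- mark_axis(mem, lower(nx), upper(nx), 3)
  if (thick > 2) for (i in seq_len(ceiling((thick - 2) / 2))) mem <- dilate6(mem)
  if (boundary_membrane) {
    mem[1, , ] <- TRUE; mem[nz, , ] <- TRUE
    mem[, 1, ] <- TRUE; mem[, ny, ] <- TRUE
    mem[, , 1] <- TRUE; mem[, , nx] <- TRUE
  }
  comp_v <- cpp_label_components(!mem, dims)
  ncomp <- max(comp_v)
  first_idx <- match(seq_len(ncomp), comp_v)
  comp_owner <- owner[first_idx]
  comp_size <- tabulate(comp_v[comp_v > 0L], nbins = ncomp)
  keep <- rep(TRUE, ncomp)
  if (!periodic) {
    # per owner, keep only the largest box component
    keep[] <- FALSE
    ord <- order(comp_owner, -comp_size)
    keep[ord[!duplicated(comp_owner[ord])]] <- TRUE
  }
  surviving_owner <- sort(unique(comp_owner[keep]))
  owner_to_label <- integer(max(owner))
  owner_to_label[surviving_owner] <- seq_along(surviving_owner)
  comp_to_label <- integer(ncomp)
  comp_to_label[keep] <- owner_to_label[comp_owner[keep]]
  label <- array(0L, dims)
  nzc <- comp_v > 0L
  label[nzc] <- comp_to_label[comp_v[nzc]]
  counts <- tabulate(label[label > 0L], nbins = length(surviving_owner))
  list(label = label, owner = owner, keep_ids = surviving_owner, counts = counts)
}

dilate6 <- function(m) {
  d <- dim(m); out <- m
  out[-1, , ] <- out[-1, , , drop = FALSE] | m[-d[1], , , drop = FALSE]
  out[-d[1], , ] <- out[-d[1], , , drop = FALSE] | m[-1, , , drop = FALSE]
  out[, -1, ] <- out[, -1, , drop = FALSE] | m[, -d[2], , drop = FALSE]
  out[, -d[2], ] <- out[, -d[2], , drop = FALSE] | m[, -1, , drop = FALSE]
  out[, , -1] <- out[, , -1, drop = FALSE] | m[, , -d[3], drop = FALSE]
  out[, , -d[3]] <- out[, , -d[3], drop = FALSE] | m[, , -1, drop = FALSE]
  out
}

relabel_dense <- function(label) {
  ids <- sort(unique(label[label > 0L]))
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  nzc <- label > 0L
  label[nzc] <- map[label[nzc]]
  label
}

# one spherical nucleus per cell, tucked against the membrane
place_nuclei <- function(label, dims, pitch, centroid, radius, idx_in, lab_in) {
  K <- nrow(centroid)
  out <- matrix(NA_real_, K, 3)
  by_cell <- split(idx_in, lab_in)
  for (k in seq_len(K)) {
    idx <- by_cell[[as.character(k)]]
    ctr <- vox_centers(dims, pitch, idx)
    d2 <- (ctr[, 1] - centroid[k, 1])^2 + (ctr[, 2] - centroid[k, 2])^2 +
      (ctr[, 3] - centroid[k, 3])^2
    far <- which.max(d2)
    dir <- ctr[far, ] - centroid[k, ]
    nd <- sqrt(sum(dir^2))
    cand <- if (nd > 1e-9) ctr[far, ] - dir / nd * radius else centroid[k, ]
    vi <- point_to_voxel(dims, pitch, cand)
    if (!is.na(vi) && label[vi] == k) {
      out[k, ] <- cand
    } else {
      # fall back to the interior voxel centre closest to the candidate
      dc <- (ctr[, 1] - cand[1])^2 + (ctr[, 2] - cand[2])^2 + (ctr[, 3] - cand[3])^2
      out[k, ] <- ctr[which.min(dc), ]
    }
  }
  out
}

inject_membrane_gaps <- function(label, owner, dims, pitch, n_gaps, gap_radius) {
  # wall voxels sitting between two different surviving interiors
  wall <- which(label == 0L)
  if (length(wall) == 0) abort("no membrane voxels to open")
  gaps <- matrix(NA_real_, 0, 3)
  opened <- 0L
  cand <- sample(wall)
  for (v in cand) {
    if (opened >= n_gaps) break
    c0 <- vox_coords(dims, v)
    nb <- neighbor_labels(label, dims, c0)
    nb <- unique(nb[nb > 0L])
    if (length(nb) < 2L) next
    ctr <- vox_centers(dims, pitch, v)
    # clear membrane within the gap ball: those voxels revert to the owner's interior
    rz <- ceiling(gap_radius / pitch[1]); ry <- ceiling(gap_radius / pitch[2])
    rx <- ceiling(gap_radius / pitch[3])
    zr <- max(1, c0[1] - rz):min(dims[1], c0[1] + rz)
    yr <- max(1, c0[2] - ry):min(dims[2], c0[2] + ry)
    xr <- max(1, c0[3] - rx):min(dims[3], c0[3] + rx)
    g <- as.matrix(expand.grid(iz = zr, iy = yr, ix = xr))
    gc <- cbind((g[, 1] - 0.5) * pitch[1], (g[, 2] - 0.5) * pitch[2],
                (g[, 3] - 0.5) * pitch[3])
    inball <- rowSums((gc - matrix(ctr, nrow(gc), 3, byrow = TRUE))^2) <= gap_radius^2
    gi <- vox_index(dims, g[inball, 1], g[inball, 2], g[inball, 3])
    gi <- gi[label[gi] == 0L]
    # fill the opened voxels with the label of the first adjacent interior
    label[gi] <- nb[1]
    gaps <- rbind(gaps, ctr)
    opened <- opened + 1L
  }
  if (opened < n_gaps) warn("fewer membrane gaps injected than requested")
  list(label = label, gaps = gaps)
}

neighbor_labels <- function(label, dims, c0) {
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  nb <- sweep(offs, 2, as.numeric(c0), `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
    nb[, 3] >= 1 & nb[, 3] <= dims[3]
  nb <- nb[ok, , drop = FALSE]
  label[vox_index(dims, nb[, 1], nb[, 2], nb[, 3])]
}

draw_strands <- function(dims, pitch, extent, n_strands, radius) {
  mask <- array(FALSE, dims)
  diag_len <- sqrt(sum(extent^2))
  for (i in seq_len(n_strands)) {
    p0 <- runif(3) * extent
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    tt <- seq(-diag_len, diag_len, by = min(pitch) / 2)
    pts <- cbind(p0[1] + tt * dir[1], p0[2] + tt * dir[2], p0[3] + tt * dir[3])
    inside <- pts[, 1] >= 0 & pts[, 1] < extent[1] &
      pts[, 2] >= 0 & pts[, 2] < extent[2] &
      pts[, 3] >= 0 & pts[, 3] < extent[3]
    vi <- point_to_voxel(dims, pitch, pts[inside, , drop = FALSE])
    mask[vi[!is.na(vi)]] <- TRUE
  }
  rounds <- max(0L, as.integer(round(radius / min(pitch))) - 1L)
  for (r in seq_len(rounds)) mask <- dilate6(mask)
  mask
}

# separable 3D Gaussian blur with edge replication, sigma in voxels
gauss_blur3 <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) arr <- conv_axis(arr, k, axis)
  arr
}

conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  out <- array(0, d)
  for (o in seq_along(k)) {
    off <- o - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n) # replicate edges
    sl <- switch(axis,
                 arr[src, , , drop = FALSE],
                 arr[, src, , drop = FALSE],
                 arr[, , src, drop = FALSE])
    out <- out + k[o] * sl
  }
  out
}
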