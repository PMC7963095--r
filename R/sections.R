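#' Virtual section through a tissue phantom
#'
#' Cuts a planar slab of given thickness through the phantom, resamples the
#' slab onto a 2D pixel grid (projection = mean intensity across the slab)
#' and records per-cell profile truth: which cells' interiors intersect the
#' slab, their profile pixel masks, and whether (and where) each cell's
#' nucleus intersects the slab. Nucleus-slab intersection is evaluated
#' geometrically (sphere vs slab), matching the detectability assumption of
#' the physical disector.
#'
#' @param phantom a `tissue_phantom`.
#' @param normal unit normal of the section plane, `(z, y, x)` components
#'   (normalised internally). Ignored when `isotropic = TRUE`.
#' @param position signed offset of the slab centre from the specimen centre
#'   along the normal, um.
#' @param thickness slab thickness `d` in micrometres (> 0).
#' @param pixel_pitch section pixel size in micrometres (isotropic).
#' @param isotropic draw the section orientation uniformly at random on the
#'   sphere (isotropic uniform random section planes).
#' @param seed RNG seed (only used with `isotropic = TRUE`).
#'
#' @return object of class `section_image`: list with `intensities`
#'   (integer matrix, `NA` outside the specimen), `pixel_pitch`,
#'   `thickness`, `normal`, `position`, `axes` (in-plane basis vectors),
#'   `profile_truth` (tibble: `cell_id`, `pixels` list-column of linear
#'   pixel indices, `nucleus_profile_present`, `nucleus_y`, `nucleus_x`,
#'   `nucleus_profile_radius`).
#' @export
virtual_section <- function(phantom, normal = c(1, 0, 0), position = 0,
                            thickness = NULL, pixel_pitch = NULL,
                            isotropic = FALSE, seed = NULL) {
  stack <- phantom$stack
  pitch <- stack$pitch
  dims <- dim(stack$intensities)
  extent <- dims * pitch
  if (is.null(thickness)) thickness <- min(pitch)
  if (thickness <= 0) abort("section thickness must be positive")
  if (is.null(pixel_pitch)) pixel_pitch <- min(pitch)
  if (isotropic) {
    normal <- with_seed(seed, {
      z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      c(z, r * cos(phi), r * sin(phi))
    })
  }
  n <- normal / sqrt(sum(normal^2))
  # in-plane orthonormal basis
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  center <- extent / 2

  # exact in-plane bounding rectangle of the specimen box
  corners <- as.matrix(expand.grid(z = c(0, extent[1]), y = c(0, extent[2]),
                                   x = c(0, extent[3])))
  rel <- sweep(corners, 2, center)
  u_rng <- range(rel %*% e1)
  v_rng <- range(rel %*% e2)
  n_u <- max(1L, ceiling((u_rng[2] - u_rng[1]) / pixel_pitch))
  n_v <- max(1L, ceiling((v_rng[2] - v_rng[1]) / pixel_pitch))
  us <- u_rng[1] + (seq_len(n_u) - 0.5) * pixel_pitch
  vs <- v_rng[1] + (seq_len(n_v) - 0.5) * pixel_pitch

  n_sub <- max(1L, ceiling(thickness / min(pitch)))
  subs <- if (n_sub == 1L) 0 else seq(-thickness / 2, thickness / 2, length.out = n_sub)
  subs <- subs[order(abs(subs))] # centre-out: first non-zero label wins

  uu <- matrix(us, n_u, n_v)
  vv <- matrix(vs, n_u, n_v, byrow = TRUE)
  base <- cbind(
    center[1] + position * n[1] + as.vector(uu) * e1[1] + as.vector(vv) * e2[1],
    center[2] + position * n[2] + as.vector(uu) * e1[2] + as.vector(vv) * e2[2],
    center[3] + position * n[3] + as.vector(uu) * e1[3] + as.vector(vv) * e2[3]
  )

  has_labels <- !is.null(phantom$label_map)
  acc <- matrix(0, n_u, n_v)
  cnt <- matrix(0L, n_u, n_v)
  lab <- matrix(0L, n_u, n_v)
  any_in <- FALSE
  for (s in subs) {
    pts <- base + matrix(s * n, nrow(base), 3, byrow = TRUE)
    vi <- point_to_voxel(dims, pitch, pts)
    ok <- !is.na(vi)
    if (any(ok)) any_in <- TRUE
    ints <- rep(NA_real_, length(vi))
    ints[ok] <- stack$intensities[vi[ok]]
    acc <- acc + matrix(ifelse(is.na(ints), 0, ints), n_u, n_v)
    cnt <- cnt + matrix(as.integer(!is.na(ints)), n_u, n_v)
    if (has_labels) {
      ls <- rep(0L, length(vi))
      ls[ok] <- phantom$label_map[vi[ok]]
      lm <- matrix(ls, n_u, n_v)
      sel <- lab == 0L & lm > 0L
      lab[sel] <- lm[sel]
    }
  }
  if (!any_in) abort("section slab lies entirely outside the specimen")
  ints <- ifelse(cnt > 0, acc / cnt, NA_real_)

  # --- profile truth ---
  profile_truth <- tibble(cell_id = integer(), pixels = list(),
                          nucleus_profile_present = logical(),
                          nucleus_y = numeric(), nucleus_x = numeric(),
                          nucleus_profile_radius = numeric())
  if (has_labels && nrow(phantom$cells) > 0) {
    cells <- phantom$cells
    nuc_rel <- cbind(cells$nucleus_z - center[1], cells$nucleus_y - center[2],
                     cells$nucleus_x - center[3])
    ax <- as.vector(nuc_rel %*% n) - position
    r <- cells$nucleus_radius
    nuc_present <- abs(ax) <= thickness / 2 + r
    over <- pmax(abs(ax) - thickness / 2, 0)
    r_prof <- ifelse(nuc_present, sqrt(pmax(r^2 - over^2, 0)), NA_real_)
    nuc_u <- as.vector(nuc_rel %*% e1) - u_rng[1]
    nuc_v <- as.vector(nuc_rel %*% e2) - v_rng[1]
    pix_by_cell <- split(which(lab > 0L), lab[lab > 0L])
    ids <- sort(unique(c(as.integer(names(pix_by_cell)),
                         cells$cell_id[nuc_present])))
    profile_truth <- tibble(
      cell_id = ids,
      pixels = lapply(as.character(ids), function(k) pix_by_cell[[k]] %||% integer()),
      nucleus_profile_present = nuc_present[match(ids, cells$cell_id)],
      nucleus_y = nuc_u[match(ids, cells$cell_id)],
      nucleus_x = nuc_v[match(ids, cells$cell_id)],
      nucleus_profile_radius = r_prof[match(ids, cells$cell_id)]
    )
    # render nucleus profiles into the image (mid-grey)
    for (i in seq_len(nrow(profile_truth))) {
      if (!isTRUE(profile_truth$nucleus_profile_present[i])) next
      rp <- max(profile_truth$nucleus_profile_radius[i], pixel_pitch / 2)
      cy <- profile_truth$nucleus_y[i]; cx <- profile_truth$nucleus_x[i]
      iy <- pmax(1, floor((cy - rp) / pixel_pitch)):pmin(n_u, ceiling((cy + rp) / pixel_pitch))
      ix <- pmax(1, floor((cx - rp) / pixel_pitch)):pmin(n_v, ceiling((cx + rp) / pixel_pitch))
      for (jx in ix) for (jy in iy) {
        py <- (jy - 0.5) * pixel_pitch; px <- (jx - 0.5) * pixel_pitch
        if ((py - cy)^2 + (px - cx)^2 <= rp^2 && !is.na(ints[jy, jx])) {
          ints[jy, jx] <- 20000
        }
      }
    }
  }

  structure(
    list(
      intensities = round(ints),
      labels = lab,
      pixel_pitch = c(pixel_pitch, pixel_pitch),
      thickness = thickness,
      normal = n, position = position,
      axes = list(e1 = e1, e2 = e2, u_origin = u_rng[1], v_origin = v_rng[1]),
      profile_truth = profile_truth
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, pitch %.3g um, thickness %.3g um, %d profiles\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_pitch[1],
              x$thickness, nrow(x$profile_truth)))
  invisible(x)
}

#' Labelled profile matrix of a section
#'
#' @param section a [virtual_section()] result.
#' @return integer matrix with each profile's pixels set to its `cell_id`.
#' @export
profile_label_matrix <- function(section) {
  m <- matrix(0L, nrow(section$intensities), ncol(section$intensities))
  pt <- section$profile_truth
  for (i in seq_len(nrow(pt))) m[pt$pixels[[i]]] <- pt$cell_id[i]
  m
}

#' Series of consecutive serial sections with nucleus truth
#'
#' Emulates a physical serial-section series: consecutive, parallel sections
#' of nominal thickness with per-section factual thickness jitter (as when
#' factual thicknesses are measured by reflectometry), cut perpendicular to
#' a chosen direction. Nucleus profile presence is recorded per section from
#' exact sphere-slab geometry.
#'
#' @param phantom a `tissue_phantom` with cells.
#' @param n_sections number of consecutive sections (>= 2).
#' @param nominal_thickness nominal section thickness, um.
#' @param thickness_jitter_sd SD of the factual thickness around nominal;
#'   non-positive draws are resampled (bounded retries).
#' @param pixel_pitch section pixel size, um.
#' @param normal cutting direction `(z, y, x)`; use `isotropic = TRUE` for
#'   an isotropic uniform random direction.
#' @param isotropic draw the direction at random.
#' @param start position of the first section's leading face along the
#'   normal (um, relative to specimen centre); default: uniform random such
#'   that the whole series lies inside the specimen.
#' @param seed RNG seed.
#' @return list of `section_image` objects; attribute `thicknesses` holds
#'   the factual thicknesses.
#' @export
nucleus_section_series <- function(phantom, n_sections, nominal_thickness = 1,
                                   thickness_jitter_sd = 0,
                                   pixel_pitch = 2,
                                   normal = c(1, 0, 0), isotropic = FALSE,
                                   start = NULL, seed = NULL) {
  if (n_sections < 2) abort("a disector series needs at least 2 sections")
  with_seed(seed, {
    if (isotropic) {
      z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
      normal <- c(z, sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi))
    }
    n <- normal / sqrt(sum(normal^2))
    th <- numeric(n_sections)
    for (i in seq_len(n_sections)) {
      t_i <- rnorm(1, nominal_thickness, thickness_jitter_sd)
      tries <- 0L
      while (t_i <= 0 && tries < 100L) {
        t_i <- rnorm(1, nominal_thickness, thickness_jitter_sd)
        tries <- tries + 1L
      }
      if (t_i <= 0) abort("could not draw a positive section thickness")
      th[i] <- t_i
    }
    extent <- dim(phantom$stack$intensities) * phantom$stack$pitch
    support <- sum(abs(n) * extent) # box support width along the normal
    total <- sum(th)
    if (total > support) abort("section series thicker than the specimen")
    if (is.null(start)) start <- runif(1, -support / 2, support / 2 - total)
    pos <- start + cumsum(th) - th / 2
    out <- lapply(seq_len(n_sections), function(i) {
      virtual_section(phantom, normal = n, position = pos[i], thickness = th[i],
                      pixel_pitch = pixel_pitch)
    })
    attr(out, "thicknesses") <- th
    attr(out, "normal") <- n
    attr(out, "start") <- start
    out
  })
}
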