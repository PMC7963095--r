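#' Physical disector count on a serial-section pair
#'
#' Counts nuclei (not cells) on a pair of parallel, aligned sections:
#' a nucleus is tallied (Q-) when its section profile is present in the
#' reference section but absent in the look-up section and its reference
#' profile is accepted by one of the unbiased counting frames. With
#' `both_directions = TRUE` the section roles are interchanged and the
#' tallies summed (doubling the efficiency); the examined disector volume
#' grows accordingly. The disector height of each direction is the factual
#' thickness of its reference section (adjacent physical sections).
#'
#' A validation warning is raised when the disector height exceeds one third
#' of the nucleus diameter (nuclei could then be lost between sections).
#'
#' @param reference,lookup two `section_image`s from the same series.
#' @param frames list of [counting_frame()] in section coordinates (um).
#' @param both_directions count both directions (default `TRUE`).
#' @param nucleus_diameter nominal nucleus diameter (um) for the
#'   height-validation warning.
#' @return list of class `disector_count`: `q`, `tally` (one row per
#'   direction), `nuclei` (tibble of candidate nuclei and flags).
#' @export
physical_disector_count <- function(reference, lookup, frames,
                                    both_directions = TRUE,
                                    nucleus_diameter = 10) {
  check_aligned_sections(reference, lookup)
  dirs <- if (both_directions) list(list(reference, lookup), list(lookup, reference))
  else list(list(reference, lookup))
  area_frames <- sum(vapply(frames, frame_area, numeric(1)))
  qs <- numeric(length(dirs)); hs <- numeric(length(dirs))
  nuclei <- list()
  for (d in seq_along(dirs)) {
    ref <- dirs[[d]][[1]]; luk <- dirs[[d]][[2]]
    if (ref$thickness > nucleus_diameter / 3) {
      warn("disector height exceeds one third of the nucleus diameter")
    }
    rt <- ref$profile_truth
    lt <- luk$profile_truth
    in_ref <- rt$cell_id[which(rt$nucleus_profile_present)]
    in_luk <- lt$cell_id[which(lt$nucleus_profile_present)]
    cand <- setdiff(in_ref, in_luk)
    # frame rule on the nucleus profile disks, rasterized on the ref grid
    lab <- matrix(0L, nrow(ref$intensities), ncol(ref$intensities))
    for (k in cand) {
      i <- match(k, rt$cell_id)
      lab <- draw_disk(lab, rt$nucleus_y[i], rt$nucleus_x[i],
                       rt$nucleus_profile_radius[i], ref$pixel_pitch, k)
    }
    acc <- integer()
    for (f in frames) {
      acc <- union(acc, apply_counting_frame(f, lab, pixel_pitch = ref$pixel_pitch,
                                             origin = c(0, 0)))
    }
    qs[d] <- length(intersect(cand, acc))
    hs[d] <- ref$thickness
    nuclei[[d]] <- tibble(direction = d, cell_id = cand,
                          accepted = cand %in% acc)
  }
  tally <- disector_tally(q = qs, area = area_frames, h = hs)
  structure(list(q = sum(qs), tally = tally, nuclei = bind_rows(nuclei)),
            class = "disector_count")
}

check_aligned_sections <- function(a, b) {
  if (max(abs(a$normal - b$normal)) > 1e-9 ||
      !identical(dim(a$intensities), dim(b$intensities)) ||
      max(abs(a$pixel_pitch - b$pixel_pitch)) > 1e-12) {
    abort("sections are not parallel/aligned in a shared coordinate frame")
  }
  invisible(TRUE)
}

# rasterize a disk (always at least the centre pixel) into a label matrix
draw_disk <- function(lab, cy, cx, r, pitch, value) {
  if (is.na(r)) return(lab)
  ny <- nrow(lab); nx <- ncol(lab)
  iy0 <- min(max(floor(cy / pitch[1]) + 1L, 1L), ny)
  ix0 <- min(max(floor(cx / pitch[2]) + 1L, 1L), nx)
  iy <- max(1L, floor((cy - r) / pitch[1])):min(ny, ceiling((cy + r) / pitch[1]) + 1L)
  ix <- max(1L, floor((cx - r) / pitch[2])):min(nx, ceiling((cx + r) / pitch[2]) + 1L)
  any_set <- FALSE
  for (jx in ix) for (jy in iy) {
    py <- (jy - 0.5) * pitch[1]; px <- (jx - 0.5) * pitch[2]
    if ((py - cy)^2 + (px - cx)^2 <= r^2) { lab[jy, jx] <- value; any_set <- TRUE }
  }
  if (!any_set) lab[iy0, ix0] <- value
  lab
}

#' 2D profile morphometry of a section
#'
#' Conventional adipocyte section-profile measurements: dark profiles are
#' segmented (automatic threshold, 4-connected components), sampled with
#' unbiased counting frames, and for every accepted profile the area
#' (pixel count x pixel area), the maximal Feret diameter (largest caliper
#' distance, computed exactly on the convex hull of the profile's pixel
#' corners) and the numerical area density of profiles (accepted profiles
#' per 10^6 um^2 of frame area) are reported.
#'
#' @param section a `section_image` (or a plain intensity matrix).
#' @param frames list of [counting_frame()] in section coordinates.
#' @param pixel_pitch pixel size `(dy, dx)` um; taken from the section when
#'   available.
#' @param threshold intensity threshold separating dark profiles from
#'   membrane; `NULL` uses an automatic (Otsu) threshold.
#' @param min_area smallest profile area considered, um^2.
#' @param depth intensity depth for the automatic threshold.
#' @return list of class `profile_stats`: `profiles` (tibble: `profile_id`,
#'   `area`, `max_diameter`), `density_per_1e6um2`, `n_accepted`,
#'   `frame_area`.
#' @export
profile_morphometry <- function(section, frames, pixel_pitch = NULL,
                                threshold = NULL, min_area = 25,
                                depth = 65535L) {
  img <- if (inherits(section, "section_image")) section$intensities else section
  if (is.null(pixel_pitch)) {
    pixel_pitch <- if (inherits(section, "section_image")) section$pixel_pitch else c(1, 1)
  }
  work <- img
  work[is.na(work)] <- depth # outside-specimen pixels are never "dark"
  if (is.null(threshold)) threshold <- otsu_threshold(work, depth)
  mask <- work < threshold
  lab <- matrix(cpp_label_components(as.vector(mask), c(1L, nrow(img), ncol(img))),
                nrow(img), ncol(img))
  px_area <- prod(pixel_pitch)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes * px_area < min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  acc <- integer()
  for (f in frames) {
    acc <- union(acc, apply_counting_frame(f, lab, pixel_pitch = pixel_pitch,
                                           origin = c(0, 0)))
  }
  fa <- sum(vapply(frames, frame_area, numeric(1)))
  if (length(acc) == 0) {
    warn("no profiles accepted by the counting frames")
    return(structure(list(profiles = tibble(profile_id = integer(),
                                            area = numeric(),
                                            max_diameter = numeric()),
                          density_per_1e6um2 = 0, n_accepted = 0L,
                          frame_area = fa),
                     class = "profile_stats"))
  }
  profiles <- purrr::map_dfr(sort(acc), function(id) {
    pix <- which(lab == id)
    iy <- (pix - 1L) %% nrow(img) + 1L
    ix <- (pix - 1L) %/% nrow(img) + 1L
    tibble(profile_id = id,
           area = length(pix) * px_area,
           max_diameter = feret_max(iy, ix, pixel_pitch))
  })
  structure(
    list(profiles = profiles,
         density_per_1e6um2 = length(acc) / fa * 1e6,
         n_accepted = length(acc),
         frame_area = fa),
    class = "profile_stats"
  )
}

# maximal Feret (caliper) diameter of a pixel set, exact on the convex hull
# of the pixel corner points
feret_max <- function(iy, ix, pitch) {
  ylo <- (iy - 1) * pitch[1]; yhi <- iy * pitch[1]
  xlo <- (ix - 1) * pitch[2]; xhi <- ix * pitch[2]
  pts <- unique(rbind(cbind(ylo, xlo), cbind(ylo, xhi),
                      cbind(yhi, xlo), cbind(yhi, xhi)))
  if (nrow(pts) == 1) return(0)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  d2 <- outer(hp[, 1], hp[, 1], `-`)^2 + outer(hp[, 2], hp[, 2], `-`)^2
  sqrt(max(d2))
}
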