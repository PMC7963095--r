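#' Systematic uniform random (SUR) sample of indices
#'
#' Fixed-interval sampling with one random start: with interval
#' `k = n_total / n_take` and a random phase `u ~ Uniform[0, k)`, the sampled
#' (1-based) indices are `floor(u + j * k) + 1` for `j = 0 .. n_take - 1`.
#' Every index is selected with probability `n_take / n_total`, and the
#' returned indices are distinct and strictly increasing.
#'
#' @param n_total number of available items.
#' @param n_take number of items to sample (`1 <= n_take <= n_total`).
#' @param seed RNG seed (optional).
#' @param phase fixed start `u` in `[0, k)`, overriding the random draw
#'   (used for reproducing a specific systematic sample).
#' @return integer vector of `n_take` strictly increasing 1-based indices.
#' @export
#' @examples
#' sur_sample(60, 6, phase = 0) # 1, 11, 21, 31, 41, 51
sur_sample <- function(n_total, n_take, seed = NULL, phase = NULL) {
  if (n_take < 1 || n_take > n_total) {
    abort("`n_take` must lie in [1, n_total]")
  }
  k <- n_total / n_take
  u <- if (!is.null(phase)) {
    if (phase < 0 || phase >= k) abort("`phase` must lie in [0, k)")
    phase
  } else {
    with_seed(seed, runif(1, 0, k))
  }
  idx <- floor(u + (seq_len(n_take) - 1) * k) + 1
  as.integer(idx)
}

#' SUR sample of rectangular fields of view
#'
#' Places fields on a 2D systematic grid with a single random 2D phase. The
#' grid period per axis is chosen so the number of fully-inside fields is as
#' close to `n_fields` as the grid allows; with `phase = c(0, 0)` and an
#' exactly divisible region the fields tile the region once.
#'
#' @param region_extent region size `(y, x)` in micrometres.
#' @param field_size field of view size `(height, width)` in micrometres.
#' @param n_fields target number of fields.
#' @param seed RNG seed.
#' @param phase fixed 2D phase `(y, x)` in `[0, period)`, overriding the
#'   random draw.
#' @return tibble with `field_id`, `y`, `x` (origin of each field, um).
#' @export
#' @examples
#' sur_fields(c(1000, 1000), c(100, 100), 100, phase = c(0, 0))
sur_fields <- function(region_extent, field_size, n_fields, seed = NULL,
                       phase = NULL) {
  H <- region_extent[1]; W <- region_extent[2]
  fh <- field_size[1]; fw <- field_size[2]
  if (fh > H || fw > W) abort("field larger than region")
  if (n_fields < 1) abort("`n_fields` must be >= 1")
  n_y <- max(1L, round(sqrt(n_fields * (H / fh) / (W / fw))))
  n_y <- min(n_y, floor(H / fh))
  n_x <- max(1L, round(n_fields / n_y))
  n_x <- min(n_x, floor(W / fw))
  py <- H / n_y; px <- W / n_x
  u <- if (!is.null(phase)) {
    if (any(phase < 0) || phase[1] >= py || phase[2] >= px) {
      abort("`phase` must lie in [0, period)")
    }
    phase
  } else {
    with_seed(seed, c(runif(1, 0, py), runif(1, 0, px)))
  }
  ys <- u[1] + (seq_len(n_y) - 1) * py
  xs <- u[2] + (seq_len(n_x) - 1) * px
  g <- expand.grid(y = ys, x = xs)
  g <- g[g$y + fh <= H + 1e-9 & g$x + fw <= W + 1e-9, , drop = FALSE]
  tibble(field_id = seq_len(nrow(g)), y = g$y, x = g$x)
}

#' Point grid test system
#'
#' A regular 2D grid of test points with spacing and phase offset, covering
#' a rectangular extent. Used for point-counting volume densities.
#'
#' @param spacing point spacing `(dy, dx)` in micrometres (> 0).
#' @param offset grid phase `(oy, ox)` with `0 <= offset < spacing`.
#' @param extent region covered `(y, x)` in micrometres.
#' @return object of class `point_grid`.
#' @export
point_grid <- function(spacing, offset = spacing / 2, extent) {
  spacing <- rep_len(as.numeric(spacing), 2)
  offset <- rep_len(as.numeric(offset), 2)
  if (any(spacing <= 0)) abort("`spacing` must be positive")
  if (any(offset < 0) || any(offset >= spacing)) {
    abort("`offset` must lie within one grid period")
  }
  structure(list(spacing = spacing, offset = offset, extent = as.numeric(extent)),
            class = "point_grid")
}

#' Grid points of a point grid
#'
#' @param grid a [point_grid()].
#' @return matrix with columns `y`, `x` of point positions (um).
#' @export
grid_points <- function(grid) {
  ys <- seq(grid$offset[1], grid$extent[1] - 1e-9, by = grid$spacing[1])
  xs <- seq(grid$offset[2], grid$extent[2] - 1e-9, by = grid$spacing[2])
  as.matrix(expand.grid(y = ys, x = xs))
}

#' Count point hits per class
#'
#' Tallies, for every grid point, the class of the image pixel containing it
#' (pixels are half-open boxes; a point on a pixel boundary belongs to the
#' pixel whose half-open box contains it — no fractional counting).
#'
#' @param grid a [point_grid()]; its extent must lie within the image.
#' @param image 2D matrix of integer class labels, rows = y, columns = x.
#' @param pixel_pitch pixel size `(dy, dx)` in micrometres.
#' @param class_map optional named vector mapping label values to class
#'   names.
#' @return tibble with `class`, `hits`, plus one `total` attribute equal to
#'   the number of grid points.
#' @export
#' @examples
#' img <- matrix(1L, 10, 10)
#' point_hits(point_grid(c(2, 2), c(1, 1), c(10, 10)), img, c(1, 1))
point_hits <- function(grid, image, pixel_pitch = c(1, 1), class_map = NULL) {
  pts <- grid_points(grid)
  if (nrow(pts) == 0) abort("empty point grid")
  img_ext <- dim(image) * pixel_pitch
  if (grid$extent[1] > img_ext[1] + 1e-9 || grid$extent[2] > img_ext[2] + 1e-9) {
    abort("grid extent exceeds the image")
  }
  iy <- floor(pts[, "y"] / pixel_pitch[1]) + 1
  ix <- floor(pts[, "x"] / pixel_pitch[2]) + 1
  vals <- image[cbind(iy, ix)]
  if (!is.null(class_map)) vals <- class_map[as.character(vals)]
  tab <- table(vals)
  out <- tibble(class = names(tab), hits = as.integer(tab))
  attr(out, "total") <- nrow(pts)
  out
}

#' Unbiased counting frame (Gundersen frame)
#'
#' A rectangular sampling frame with inclusion edges (top and right) and
#' exclusion edges (left and bottom, with their infinite line extensions).
#' Coordinates are continuous `(y, x)` micrometre positions with `y`
#' increasing towards "top".
#'
#' @param origin frame origin `(y, x)`: the bottom-left corner, um.
#' @param edge frame edge lengths `(height, width)`, um.
#' @return object of class `counting_frame`.
#' @export
counting_frame <- function(origin, edge) {
  origin <- as.numeric(origin); edge <- rep_len(as.numeric(edge), 2)
  if (any(edge <= 0)) abort("frame edges must be positive")
  structure(list(origin = origin, edge = edge), class = "counting_frame")
}

#' Frame area in square micrometres
#' @param frame a [counting_frame()].
#' @export
frame_area <- function(frame) prod(frame$edge)

#' Apply the counting-frame rule to labelled profiles
#'
#' A profile is accepted if its mask intersects the closed frame and does
#' not touch the forbidden line: the left edge extended infinitely upward,
#' the bottom edge, and the downward infinite extension at the bottom-right
#' corner. For connected profiles this rule counts every profile exactly
#' once when congruent frames tile the plane, regardless of profile size or
#' shape.
#'
#' @param frame a [counting_frame()].
#' @param profiles labelled 2D integer matrix (0 = background), rows = y,
#'   columns = x, sharing the frame's coordinate system.
#' @param pixel_pitch pixel size `(dy, dx)` in micrometres.
#' @param origin position `(y, x)` of the lower-left corner of pixel
#'   `[1, 1]`, um.
#' @return integer vector of accepted profile labels (possibly empty).
#' @export
apply_counting_frame <- function(frame, profiles, pixel_pitch = c(1, 1),
                                 origin = c(0, 0)) {
  ids <- sort(unique(profiles[profiles > 0L]))
  if (length(ids) == 0) return(integer())
  idx <- which(profiles > 0L)
  lab <- profiles[idx]
  iy <- (idx - 1L) %% nrow(profiles) + 1L
  ix <- (idx - 1L) %/% nrow(profiles) + 1L
  ylo <- origin[1] + (iy - 1) * pixel_pitch[1]
  yhi <- ylo + pixel_pitch[1]
  xlo <- origin[2] + (ix - 1) * pixel_pitch[2]
  xhi <- xlo + pixel_pitch[2]
  fy0 <- frame$origin[1]; fx0 <- frame$origin[2]
  fy1 <- fy0 + frame$edge[1]; fx1 <- fx0 + frame$edge[2]
  in_frame <- ylo <= fy1 & yhi >= fy0 & xlo <= fx1 & xhi >= fx0
  on_excl <-
    (xlo <= fx0 & xhi >= fx0 & yhi >= fy0) | # left edge + upward extension
    (ylo <= fy0 & yhi >= fy0 & xhi >= fx0 & xlo <= fx1) | # bottom edge
    (xlo <= fx1 & xhi >= fx1 & ylo <= fy0) # downward extension, bottom-right
  hit <- rowsum(as.numeric(in_frame), lab)[, 1] > 0
  bad <- rowsum(as.numeric(on_excl), lab)[, 1] > 0
  ids[hit[as.character(ids)] & !bad[as.character(ids)]]
}

#' Tile counting frames over a region
#'
#' Convenience constructor for an exact tiling of congruent frames, with an
#' optional guard band of extra frame rows/columns beyond the region (so
#' profiles near the region border still meet their unique accepting frame).
#'
#' @param region_extent `(y, x)` extent to tile, um.
#' @param edge frame edge `(height, width)`, um.
#' @param guard number of extra frame rows/columns on every side.
#' @return list of [counting_frame()] objects.
#' @export
tile_frames <- function(region_extent, edge, guard = 0L) {
  edge <- rep_len(as.numeric(edge), 2)
  n_y <- ceiling(region_extent[1] / edge[1])
  n_x <- ceiling(region_extent[2] / edge[2])
  ys <- ((-guard):(n_y + guard - 1)) * edge[1]
  xs <- ((-guard):(n_x + guard - 1)) * edge[2]
  g <- expand.grid(y = ys, x = xs)
  purrr::pmap(g, function(y, x) counting_frame(c(y, x), edge))
}

#' Sample an optical disector plane pair
#'
#' Draws a reference optical section plane uniformly from a sampling zone of
#' the stack (default: the middle third) such that both the reference and
#' the look-up plane (`reference + separation_planes`) lie inside the zone.
#' The disector height is `separation_planes * step`.
#'
#' @param n_planes number of optical planes in the stack.
#' @param step axial distance between consecutive planes, um.
#' @param separation_planes number of planes between reference and look-up
#'   (> 0).
#' @param zone `"middle_third"` or `"full"`, or an integer vector
#'   `c(first, last)` of 1-based plane indices delimiting the zone.
#' @param seed RNG seed.
#' @return tibble of class `disector_pair` with `reference_index`,
#'   `lookup_index` (1-based plane indices), `separation_planes`, `step`,
#'   `h` (um).
#' @export
#' @examples
#' sample_disector_planes(322, 5, 10, seed = 1)
sample_disector_planes <- function(n_planes, step, separation_planes,
                                   zone = "middle_third", seed = NULL) {
  if (separation_planes < 1) abort("`separation_planes` must be >= 1 (h > 0)")
  if (step <= 0) abort("`step` must be positive")
  zr <- if (is.numeric(zone)) {
    as.integer(zone)
  } else if (identical(zone, "middle_third")) {
    c(floor(n_planes / 3) + 1L, floor(2 * n_planes / 3))
  } else if (identical(zone, "full")) {
    c(1L, n_planes)
  } else {
    abort("unknown `zone`")
  }
  feasible <- seq(zr[1], zr[2])
  feasible <- feasible[feasible + separation_planes <= zr[2]]
  if (length(feasible) == 0) {
    abort("separation infeasible: zone has too few planes")
  }
  ref <- with_seed(seed, feasible[sample.int(length(feasible), 1)])
  structure(
    tibble(
      reference_index = ref,
      lookup_index = ref + as.integer(separation_planes),
      separation_planes = as.integer(separation_planes),
      step = step,
      h = separation_planes * step
    ),
    class = c("disector_pair", "tbl_df", "tbl", "data.frame")
  )
}
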