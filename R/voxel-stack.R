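#' Voxel stack: a 3D intensity grid with known voxel pitch
#'
#' The unit of light-sheet style imaging in this package: a non-negative
#' integer intensity grid with dimensions ordered `(z, y, x)` and a physical
#' voxel pitch in micrometres. Voxel `i` (1-based) along an axis with pitch
#' `p` spans the half-open interval `[(i-1)*p, i*p)`; physical positions of
#' voxels refer to their centres.
#'
#' @param intensities 3D array of non-negative integers, dim `(nz, ny, nx)`.
#' @param pitch numeric length-3, voxel pitch `(dz, dy, dx)` in micrometres.
#'   All components must be positive. The default 5 um isotropic pitch
#'   matches the axial step and lateral resolution of the light-sheet set-up
#'   the package emulates.
#' @param depth maximum representable intensity (default 65535, 16-bit).
#'
#' @return An object of class `voxel_stack`: a list with elements
#'   `intensities`, `pitch`, `depth`.
#' @export
#' @examples
#' vs <- voxel_stack(array(0L, c(4, 4, 4)), pitch = c(5, 5, 5))
#' voxel_volume(vs)
voxel_stack <- function(intensities, pitch = c(5, 5, 5), depth = 65535L) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3D array (z, y, x)")
  }
  if (any(dim(intensities) < 1L)) abort("stack grid must be non-empty")
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0)) {
    abort("`pitch` must be 3 positive numbers (dz, dy, dx) in micrometres")
  }
  storage.mode(intensities) <- "integer"
  rng <- range(intensities)
  if (rng[1] < 0L || rng[2] > depth) {
    abort("intensities must lie within [0, depth]")
  }
  structure(
    list(intensities = intensities, pitch = pitch, depth = as.integer(depth)),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<voxel_stack> %d x %d x %d voxels (z,y,x), pitch %.3g x %.3g x %.3g um, %d-bit-range\n",
    d[1], d[2], d[3], x$pitch[1], x$pitch[2], x$pitch[3],
    as.integer(round(log2(x$depth + 1)))
  ))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param stack a [voxel_stack()].
#' @return voxel volume in cubic micrometres.
#' @export
voxel_volume <- function(stack) prod(stack$pitch)

#' Physical extent of a stack
#'
#' @param stack a [voxel_stack()].
#' @return numeric length-3 `(z, y, x)` extent in micrometres.
#' @export
stack_extent <- function(stack) dim(stack$intensities) * stack$pitch

# linear 1-based voxel index for (iz, iy, ix) matrices / vectors
vox_index <- function(dims, iz, iy, ix) {
  iz + dims[1] * ((iy - 1) + dims[2] * (ix - 1))
}

# inverse: linear index -> integer (iz, iy, ix) matrix
vox_coords <- function(dims, idx) {
  idx0 <- idx - 1L
  iz <- idx0 %% dims[1]
  iy <- (idx0 %/% dims[1]) %% dims[2]
  ix <- idx0 %/% (dims[1] * dims[2])
  cbind(iz = iz + 1L, iy = iy + 1L, ix = ix + 1L)
}

# voxel centres in micrometres for linear indices
vox_centers <- function(dims, pitch, idx) {
  co <- vox_coords(dims, idx)
  cbind(
    z = (co[, 1] - 0.5) * pitch[1],
    y = (co[, 2] - 0.5) * pitch[2],
    x = (co[, 3] - 0.5) * pitch[3]
  )
}

# point (z,y,x) in micrometres -> containing voxel index (half-open boxes),
# NA when outside the grid
point_to_voxel <- function(dims, pitch, pts) {
  pts <- matrix(pts, ncol = 3)
  iz <- floor(pts[, 1] / pitch[1]) + 1
  iy <- floor(pts[, 2] / pitch[2]) + 1
  ix <- floor(pts[, 3] / pitch[3]) + 1
  ok <- iz >= 1 & iz <= dims[1] & iy >= 1 & iy <= dims[2] & ix >= 1 & ix <= dims[3]
  out <- rep(NA_integer_, nrow(pts))
  out[ok] <- as.integer(vox_index(dims, iz[ok], iy[ok], ix[ok]))
  out
}

# deterministic child seeds below 2^31 derived from a master seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max, n))
  withr_seed <- seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  sample.int(.Machine$integer.max, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# evaluate expr with a local RNG state seeded by `seed` (NULL = use the
# current stream and advance it, like base R's r* functions)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}
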