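# Small fixtures rebuilt in code and cached per test file.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# ~27 cell phantom, 40^3 voxels, with noise: the default realistic fixture
small_phantom <- function() {
  cached_fixture("small", generate_adipose_phantom(
    extent = c(200, 200, 200), mean_volume = 2.3e5, cv = 0.25,
    voxel_pitch = c(5, 5, 5), seed = 11
  ))
}

# noiseless, blur-free, non-periodic phantom: intensities are exactly two
# plateaus and every label is one box-connected region, so tolerance flood
# fill recovers label regions exactly
crisp_phantom <- function() {
  cached_fixture("crisp", generate_adipose_phantom(
    extent = c(200, 200, 200), mean_volume = 2.3e5, cv = 0.25,
    voxel_pitch = c(5, 5, 5), noise_sd = 0, blur_sigma = 0,
    periodic = FALSE, seed = 12
  ))
}

# interior voxel of a cell whose intensity is typical (median) for growing
cell_seed_voxel <- function(ph, k) {
  dims <- dim(ph$stack$intensities)
  idx <- which(ph$label_map == k)
  v <- ph$stack$intensities[idx]
  i <- idx[which.min(abs(v - stats::median(v)))]
  iz <- (i - 1) %% dims[1] + 1
  iy <- ((i - 1) %/% dims[1]) %% dims[2] + 1
  ix <- (i - 1) %/% (dims[1] * dims[2]) + 1
  c(iz, iy, ix)
}

# brute-force z-presence oracle for disector counts on the label map
oracle_disector_q <- function(ph, zr, zl, frames = NULL) {
  lr <- ph$label_map[zr, , ]
  ll <- ph$label_map[zl, , ]
  cand <- setdiff(unique(lr[lr > 0]), unique(ll[ll > 0]))
  if (is.null(frames)) return(length(cand))
  acc <- integer()
  for (f in frames) {
    acc <- union(acc, apply_counting_frame(f, lr,
                                           pixel_pitch = ph$stack$pitch[2:3]))
  }
  length(intersect(cand, acc))
}
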