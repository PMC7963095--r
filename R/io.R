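#' Write a voxel stack as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-plane (16-bit by default, or 8-bit for stacks with
#' `depth` 255). The sidecar `<path>.json` records the voxel pitch, the
#' intensity depth and any extra metadata, so a stack round-trips
#' losslessly.
#'
#' @param stack a [voxel_stack()].
#' @param path output TIFF path.
#' @param metadata named list of extra sidecar fields (e.g. seed, config
#'   hash).
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata = list(), sidecar = TRUE) {
  depth <- stack$depth
  bits <- if (depth <= 255) 8L else 16L
  scale <- if (bits == 8L) 255 else 65535
  if (depth > scale) abort("intensity depth exceeds 16-bit TIFF range")
  pages <- lapply(seq_len(dim(stack$intensities)[1]), function(z) {
    stack$intensities[z, , ] / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  if (sidecar) {
    meta <- c(list(pitch_um = stack$pitch, depth = depth, bits = bits,
                   dim = dim(stack$intensities)), metadata)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a voxel stack from multi-page TIFF
#'
#' Reads the sidecar `<path>.json` for the voxel pitch and depth; without a
#' sidecar the pitch must be given explicitly.
#'
#' @param path TIFF path.
#' @param pitch voxel pitch `(dz, dy, dx)` um; overrides/replaces the
#'   sidecar.
#' @param depth intensity depth; inferred from the TIFF bit depth when
#'   missing.
#' @return a [voxel_stack()].
#' @export
read_stack <- function(path, pitch = NULL, depth = NULL) {
  sc_path <- paste0(path, ".json")
  meta <- if (file.exists(sc_path)) jsonlite::read_json(sc_path, simplifyVector = TRUE) else NULL
  if (is.null(pitch)) pitch <- meta$pitch_um
  if (is.null(pitch)) {
    abort("no voxel pitch: provide `pitch` or a sidecar JSON")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  scale <- if (bits == 8L) 255 else 65535
  if (is.null(depth)) depth <- meta$depth %||% scale
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0L, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- as.integer(round(pages[[z]] * scale))
  voxel_stack(arr, pitch = pitch, depth = depth)
}

#' Write a study results bundle to disk
#'
#' `estimates.csv` (one row per subject x depot x route), `cells.csv`
#' (per-cell measurements) and `summary.json` (group means +/- SD per depot
#' and parameter, the config hash and the master seed), making the bundle
#' regenerable from its embedded provenance.
#'
#' @param study an `adipo_study` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est <- study$estimates
  est$config_hash <- study$config_hash
  utils::write.csv(est, file.path(out_dir, "estimates.csv"), row.names = FALSE)
  if (!is.null(study$cells)) {
    utils::write.csv(study$cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
  }
  summ <- est |>
    group_by(.data$group, .data$depot, .data$route) |>
    summarise(
      n = dplyr::n(),
      across(c("v_v", "v_ac_cm3", "n_total", "v_bar_um3"),
             list(mean = mean, sd = stats::sd)),
      .groups = "drop"
    )
  jsonlite::write_json(
    list(config_hash = study$config_hash,
         seed = study$config$seed,
         groups = summ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(out_dir)
}
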