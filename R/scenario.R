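#' Study-scenario manifest: lean vs obese, two depots
#'
#' Lays out a two-group, two-depot study as a manifest of phantom samples
#' with depot-level ground truth. The default design encodes the qualitative
#' pattern of diet-induced obesity in minipigs: in the subcutaneous depot
#' adipocyte growth is both hypertrophic and hyperplastic (mean volume ratio
#' 3.61, number ratio 2.7 obese/lean), in the visceral depot purely
#' hypertrophic (mean volume ratio 4.06, number ratio 1.0). Between-subject
#' variability is lognormal with unit mean, so group-level ratios are
#' preserved in expectation.
#'
#' Phantom stacks are not generated here; each manifest row carries the
#' generator parameters and a derived seed, and [phantom_for_sample()]
#' renders a sample on demand. Depot-level truths recorded per subject:
#' `v_atd_cm3` (depot volume), `v_bar_um3` (true mean cell volume),
#' `v_v` (design volume density) and `n_total_true = v_v * v_atd / v_bar`.
#'
#' @param n_lean,n_obese subjects per group.
#' @param samples_per_subject tissue samples per subject and depot.
#' @param depots depot names.
#' @param v_atd_lean_cm3 named lean depot volumes, cm^3.
#' @param v_bar_lean_um3 named lean mean cell volumes, um^3.
#' @param vbar_ratio named obese/lean mean-volume ratios.
#' @param number_ratio named obese/lean total-number ratios.
#' @param v_v_lean,v_v_obese named volume densities (fractions).
#' @param subject_cv between-subject coefficient of variation of mean cell
#'   volume and depot volume (lognormal, unit mean).
#' @param cell_cv within-sample CV of individual cell volumes.
#' @param sample_extent phantom box `(z, y, x)`, um.
#' @param voxel_pitch phantom voxel pitch, um.
#' @param seed RNG seed.
#' @return tibble of class `scenario_manifest`, one row per
#'   subject x depot x sample, with a `design` attribute.
#' @export
#' @examples
#' man <- scenario_suite(seed = 1)
#' nrow(man) # 132 = (5 + 6) subjects x 2 depots x 6 samples
scenario_suite <- function(n_lean = 5, n_obese = 6,
                           samples_per_subject = 6,
                           depots = c("subcutaneous", "visceral"),
                           v_atd_lean_cm3 = c(subcutaneous = 1500, visceral = 700),
                           v_bar_lean_um3 = c(subcutaneous = 5.5e5, visceral = 4.5e5),
                           vbar_ratio = c(subcutaneous = 3.61, visceral = 4.06),
                           number_ratio = c(subcutaneous = 2.7, visceral = 1.0),
                           v_v_lean = c(subcutaneous = 0.87, visceral = 0.89),
                           v_v_obese = c(subcutaneous = 0.91, visceral = 0.93),
                           subject_cv = 0.15,
                           cell_cv = 0.3,
                           sample_extent = c(400, 400, 400),
                           voxel_pitch = c(5, 5, 5),
                           seed = NULL) {
  # tolerate list-valued parameters (e.g. from YAML configs)
  v_atd_lean_cm3 <- unlist(v_atd_lean_cm3)
  v_bar_lean_um3 <- unlist(v_bar_lean_um3)
  vbar_ratio <- unlist(vbar_ratio)
  number_ratio <- unlist(number_ratio)
  v_v_lean <- unlist(v_v_lean)
  v_v_obese <- unlist(v_v_obese)
  sample_extent <- unlist(sample_extent)
  voxel_pitch <- unlist(voxel_pitch)
  depots <- unlist(depots)
  if (n_lean < 0 || n_obese < 0 || n_lean + n_obese < 1) {
    abort("the scenario needs at least one subject")
  }
  if (samples_per_subject < 1) abort("`samples_per_subject` must be >= 1")
  if (any(vbar_ratio <= 0) || any(number_ratio <= 0)) {
    abort("ratios must be positive")
  }
  um3_per_cm3 <- 1e12
  subjects <- tibble(
    subject_id = c(sprintf("lean_%02d", seq_len(n_lean)),
                   sprintf("obese_%02d", seq_len(n_obese))),
    group = rep(c("lean", "obese"), c(n_lean, n_obese))
  )
  sdlog <- sqrt(log(1 + subject_cv^2))
  with_seed(seed, {
    eff_v <- stats::rlnorm(nrow(subjects) * length(depots), -sdlog^2 / 2, sdlog)
    eff_a <- stats::rlnorm(nrow(subjects) * length(depots), -sdlog^2 / 2, sdlog)
    grid <- tidyr::expand_grid(subjects, depot = depots)
    grid$eff_vbar <- eff_v
    grid$eff_atd <- eff_a
    grid <- dplyr::mutate(
      grid,
      obese = .data$group == "obese",
      v_v = ifelse(.data$obese, v_v_obese[.data$depot], v_v_lean[.data$depot]),
      v_bar_group = v_bar_lean_um3[.data$depot] *
        ifelse(.data$obese, vbar_ratio[.data$depot], 1),
      n_lean_depot = v_v_lean[.data$depot] * v_atd_lean_cm3[.data$depot] *
        um3_per_cm3 / v_bar_lean_um3[.data$depot],
      n_group = .data$n_lean_depot *
        ifelse(.data$obese, number_ratio[.data$depot], 1),
      # subject-level truths
      v_bar_um3 = .data$v_bar_group * .data$eff_vbar,
      n_total_true = .data$n_group * .data$eff_atd,
      v_atd_cm3 = .data$n_total_true * .data$v_bar_um3 / .data$v_v / um3_per_cm3
    )
    grid <- dplyr::select(grid, "subject_id", "group", "depot", "v_v",
                          "v_bar_um3", "v_atd_cm3", "n_total_true")
    man <- tidyr::expand_grid(grid, sample = seq_len(samples_per_subject))
    man$phantom_seed <- derive_seeds(NULL, nrow(man))
    man$extent_z <- sample_extent[1]
    man$extent_y <- sample_extent[2]
    man$extent_x <- sample_extent[3]
    man$pitch_z <- voxel_pitch[1]
    man$pitch_y <- voxel_pitch[2]
    man$pitch_x <- voxel_pitch[3]
    man$cell_cv <- cell_cv
    design <- list(
      n_lean = n_lean, n_obese = n_obese,
      samples_per_subject = samples_per_subject, depots = depots,
      v_atd_lean_cm3 = v_atd_lean_cm3, v_bar_lean_um3 = v_bar_lean_um3,
      vbar_ratio = vbar_ratio, number_ratio = number_ratio,
      v_v_lean = v_v_lean, v_v_obese = v_v_obese,
      subject_cv = subject_cv, cell_cv = cell_cv,
      sample_extent = sample_extent, voxel_pitch = voxel_pitch, seed = seed
    )
    structure(man, design = design,
              class = c("scenario_manifest", class(tibble())))
  })
}

#' Render the phantom for one manifest row
#'
#' @param manifest_row one row of a [scenario_suite()] manifest.
#' @param ... overrides passed to [generate_adipose_phantom()] (e.g.
#'   `noise_sd`).
#' @return a `tissue_phantom` whose mean cell volume matches the row's
#'   subject-level truth.
#' @export
phantom_for_sample <- function(manifest_row, ...) {
  generate_adipose_phantom(
    extent = c(manifest_row$extent_z, manifest_row$extent_y, manifest_row$extent_x),
    mean_volume = manifest_row$v_bar_um3,
    cv = manifest_row$cell_cv,
    voxel_pitch = c(manifest_row$pitch_z, manifest_row$pitch_y, manifest_row$pitch_x),
    seed = manifest_row$phantom_seed,
    ...
  )
}
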