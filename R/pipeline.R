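#' Default analysis configuration
#'
#' Probe and correction settings for [run_pipeline()]: optical disector
#' separation (10 planes at 5 um = 50 um height), 300 x 300 um unbiased
#' counting frames, wand tolerance 10000 (16-bit), point-counting grid, and
#' the linear shrinkage factors per preparation (0.92 for solvent-cleared
#' and stained tissue, 0.93 for plastic-embedded tissue).
#'
#' @param ... overrides of the default fields.
#' @return a nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    scenario = list(),
    probes = list(
      pairs_per_sample = 8L,
      separation_planes = 10L,
      frame_edge = 300,
      frame_margin = 100,
      tolerance = 10000,
      min_profile_area = 100,
      point_spacing = 50,
      point_planes = 3L
    ),
    shrinkage = list(f_s_cleared = 0.92, f_s_embedded = 0.93, apply = FALSE),
    seed = NULL
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full phantom-to-estimates analysis pipeline
#'
#' For every sample of a study scenario: generates the tissue phantom,
#' samples optical disector plane pairs from the middle third of the stack,
#' counts adipocytes in both disector directions with unbiased counting
#' frames, measures the sampled cells' individual volumes, and estimates the
#' adipocyte volume density by point counting on SUR-sampled planes. Counts
#' and areas are pooled per subject and depot (ratio of sums, not mean of
#' ratios) before forming the numerical density, and depot totals are
#' derived by both number routes: the stereology route (`N = N_V x V_ATD`)
#' and the volumetry route (`N = V_AC / v_bar`).
#'
#' Every random step consumes a seed derived from the master seed, so a
#' rerun with the same configuration reproduces the results exactly.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file with the same structure. `config$scenario` holds
#'   [scenario_suite()] arguments; `config$seed` the master seed.
#' @param keep_cells keep per-cell measurements in the result (default
#'   `TRUE`).
#' @param out_dir optional directory: writes `estimates.csv`, `cells.csv`
#'   and `summary.json` (with config hash and seeds) there.
#' @return object of class `adipo_study`: list with `estimates` (tibble,
#'   one row per subject x depot x route), `cells`, `manifest`, `config`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), keep_cells = TRUE,
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(), config)
  probes <- config$probes
  f_s <- if (isTRUE(config$shrinkage$apply)) config$shrinkage$f_s_cleared else 1
  seeds <- derive_seeds(config$seed, 2L)
  manifest <- do.call(scenario_suite, c(config$scenario, list(seed = seeds[1])))
  if (nrow(manifest) == 0) abort("the scenario produced no samples")
  sample_seeds <- derive_seeds(seeds[2], nrow(manifest))

  per_sample <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    ph <- phantom_for_sample(row)
    analyze_sample(ph, probes, f_s, sample_seeds[i])
  })

  tallies <- bind_rows(purrr::map(per_sample, "tally"), .id = "row_id")
  tallies$row_id <- as.integer(tallies$row_id)
  points <- bind_rows(purrr::map(per_sample, "points"), .id = "row_id")
  points$row_id <- as.integer(points$row_id)
  cells <- bind_rows(purrr::map(per_sample, "cells"), .id = "row_id")
  if (nrow(cells) == 0) {
    cells <- tibble(row_id = character(), cell_id = integer(),
                    voxel_count = integer(), raw_volume = numeric(),
                    corrected_volume = numeric(), f_s = numeric(),
                    clipped = logical(), gap_suspect = logical(),
                    valid = logical())
  }
  cells$row_id <- as.integer(cells$row_id)
  man_key <- dplyr::mutate(manifest, row_id = dplyr::row_number())
  key_cols <- c("subject_id", "group", "depot")
  cells <- left_join(cells,
                     dplyr::select(man_key, "row_id", dplyr::all_of(key_cols)),
                     by = "row_id")

  est <- purrr::map_dfr(
    split(seq_len(nrow(man_key)), man_key[key_cols]),
    function(rows) {
      if (length(rows) == 0) return(NULL)
      sub <- man_key[rows, ]
      tal <- dplyr::filter(tallies, .data$row_id %in% sub$row_id)
      pts <- dplyr::filter(points, .data$row_id %in% sub$row_id)
      cl <- dplyr::filter(cells, .data$row_id %in% sub$row_id, .data$valid)
      tal_obj <- disector_tally(tal$q, tal$area, tal$h)
      n_v <- numerical_density(tal_obj, f_s = f_s)
      ce <- if (nrow(tal_obj) >= 2 && sum(tal_obj$q) > 0) ce_ratio(tal_obj) else NA_real_
      v_v <- volume_density(sum(pts$hits_structure), sum(pts$hits_total))
      v_atd <- sub$v_atd_cm3[1]
      e1 <- derive_totals(v_v = v_v, v_atd_cm3 = v_atd, n_v = n_v, ce = ce)
      e2 <- if (nrow(cl) > 0) {
        derive_totals(v_v = v_v, v_atd_cm3 = v_atd,
                      v_bar = mean(cl$corrected_volume))
      } else NULL
      out <- bind_rows(e1, e2)
      out$subject_id <- sub$subject_id[1]
      out$group <- sub$group[1]
      out$depot <- sub$depot[1]
      out$q_total <- sum(tal_obj$q)
      out$n_disectors <- nrow(tal_obj)
      out$n_cells_measured <- nrow(cl)
      out$v_bar_true <- sub$v_bar_um3[1]
      out$n_total_true <- sub$n_total_true[1]
      out
    }
  )
  est <- dplyr::relocate(est, "subject_id", "group", "depot", "route")

  res <- structure(
    list(estimates = est,
         cells = if (keep_cells) cells else NULL,
         manifest = manifest, config = config,
         config_hash = rlang::hash(config)),
    class = "adipo_study"
  )
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

#' @export
print.adipo_study <- function(x, ...) {
  cat(sprintf("<adipo_study> %d samples, %d subject-depot estimates, config %s\n",
              nrow(x$manifest), nrow(x$estimates), substr(x$config_hash, 1, 8)))
  invisible(x)
}

# disector counting + cell volumetry + point counting for one sample stack
analyze_sample <- function(ph, probes, f_s, seed) {
  stack <- ph$stack
  dims <- dim(stack$intensities)
  pitch <- stack$pitch
  plane_ext <- dims[2:3] * pitch[2:3]
  edge <- min(probes$frame_edge, min(plane_ext) - 2 * probes$frame_margin)
  frames <- list(counting_frame(c(probes$frame_margin, probes$frame_margin),
                                c(edge, edge)))
  exp_vol <- ph$config$mean_volume %||%
    (prod(stack_extent(stack)) / max(nrow(ph$cells), 1))
  gp <- grow_params(
    polarity = "dark", tolerance = probes$tolerance,
    max_voxels = as.integer(ceiling(20 * exp_vol / voxel_volume(stack)))
  )
  seeds <- derive_seeds(seed, probes$pairs_per_sample + probes$point_planes + 1L)
  tals <- list(); cell_rows <- list()
  for (j in seq_len(probes$pairs_per_sample)) {
    pair <- sample_disector_planes(dims[1], pitch[1], probes$separation_planes,
                                   zone = "middle_third", seed = seeds[j])
    dc <- disector_count_3d(stack, pair, frames, gp,
                            min_profile_area = probes$min_profile_area,
                            both_directions = TRUE)
    tals[[j]] <- dc$tally
    meas <- measure_sampled_cells(dc, stack, f_s = f_s)
    if (nrow(meas) > 0) cell_rows[[length(cell_rows) + 1L]] <- meas
  }
  # point-counting volume density on SUR planes
  pts_hits <- 0L; pts_total <- 0L
  plane_idx <- sur_sample(dims[1], min(probes$point_planes, dims[1]),
                          seed = seeds[probes$pairs_per_sample + 1L])
  for (k in seq_along(plane_idx)) {
    plane <- stack$intensities[plane_idx[k], , ]
    thr <- otsu_threshold(plane, stack$depth)
    cls <- matrix(as.integer(plane < thr), dims[2], dims[3])
    off <- with_seed(seeds[probes$pairs_per_sample + 1L + k],
                     runif(2, 0, probes$point_spacing))
    grid <- point_grid(rep(probes$point_spacing, 2), off, plane_ext)
    hits <- point_hits(grid, cls, pixel_pitch = pitch[2:3])
    pts_total <- pts_total + attr(hits, "total")
    pts_hits <- pts_hits + sum(hits$hits[hits$class == "1"])
  }
  list(
    tally = bind_rows(tals),
    points = tibble(hits_structure = pts_hits, hits_total = pts_total),
    cells = bind_rows(cell_rows)
  )
}

#' Group comparison of depot estimates
#'
#' Per depot and parameter: group means and SDs and a two-sample t-test
#' (Welch by default) with the usual significance stars (* p < 0.05,
#' ** p < 0.01). Degenerate (zero-variance) comparisons are flagged and
#' their p omitted.
#'
#' @param estimates tibble of depot estimates (e.g. from an `adipo_study`),
#'   with one row per subject and depot for one route.
#' @param params parameter columns to compare.
#' @param group_col,depot_col grouping columns.
#' @param var_equal pooled-variance t instead of Welch.
#' @return object of class `group_comparison`; see [tidy()] and
#'   [glance()].
#' @export
compare_groups <- function(estimates,
                           params = c("v_bar_um3", "n_total", "v_ac_cm3"),
                           group_col = "group", depot_col = "depot",
                           var_equal = FALSE) {
  groups <- sort(unique(estimates[[group_col]]))
  if (length(groups) != 2) abort("`compare_groups` needs exactly two groups")
  n_per <- table(estimates[[group_col]], estimates[[depot_col]])
  if (any(n_per < 2)) abort("need at least 2 subjects per group and depot")
  depots <- unique(estimates[[depot_col]])
  rows <- list()
  for (dp in depots) {
    sub <- estimates[estimates[[depot_col]] == dp, ]
    for (pm in params) {
      a <- sub[[pm]][sub[[group_col]] == groups[1]]
      b <- sub[[pm]][sub[[group_col]] == groups[2]]
      degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
      if (degenerate) {
        tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
      } else {
        tt <- t.test(b, a, var.equal = var_equal)
      }
      p <- tt$p.value
      rows[[length(rows) + 1L]] <- tibble(
        depot = dp, parameter = pm,
        group_1 = groups[1], mean_1 = mean(a), sd_1 = stats::sd(a), n_1 = length(a),
        group_2 = groups[2], mean_2 = mean(b), sd_2 = stats::sd(b), n_2 = length(b),
        ratio = mean(b) / mean(a),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = p,
        significance = p_stars(p),
        degenerate = degenerate
      )
    }
  }
  structure(list(table = bind_rows(rows), groups = groups,
                 var_equal = var_equal),
            class = "group_comparison")
}

p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (%s t-test)\n",
              x$groups[2], x$groups[1],
              if (x$var_equal) "pooled" else "Welch"))
  print(x$table)
  invisible(x)
}

#' Paired comparison of two estimation methods
#'
#' Matches estimates of the same quantity obtained by two methods (routes)
#' on the same subject x depot units and reports the mean percent deviation
#' between methods and a paired t-test of equality.
#'
#' @param estimates tibble with a method column and matching id columns.
#' @param param value column to compare.
#' @param method_col column identifying the two methods.
#' @param id_cols columns identifying matched units.
#' @return tibble: methods, n pairs, `mean_pct_deviation`,
#'   `sd_pct_deviation`, paired `statistic`, `p_value`, `significance`.
#' @export
compare_methods <- function(estimates, param = "n_total",
                            method_col = "route",
                            id_cols = c("subject_id", "depot")) {
  methods <- sort(unique(estimates[[method_col]]))
  if (length(methods) != 2) abort("`compare_methods` needs exactly two methods")
  wide <- tidyr::pivot_wider(
    estimates[, c(id_cols, method_col, param)],
    names_from = dplyr::all_of(method_col),
    values_from = dplyr::all_of(param)
  )
  a <- wide[[methods[1]]]; b <- wide[[methods[2]]]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) abort("need at least 2 matched pairs")
  dev <- 100 * (b - a) / a
  tt <- if (stats::sd(b - a) == 0) {
    list(statistic = NA_real_, p.value = if (all(b == a)) 1 else NA_real_)
  } else {
    t.test(b, a, paired = TRUE)
  }
  tibble(
    method_1 = methods[1], method_2 = methods[2], n_pairs = length(a),
    mean_pct_deviation = mean(dev), sd_pct_deviation = stats::sd(dev),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    significance = p_stars(tt$p.value)
  )
}
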