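#' Tidy a group comparison
#'
#' @param x a [compare_groups()] result.
#' @param ... ignored.
#' @return a tibble with one row per depot and parameter: group means, SDs,
#'   the obese/lean-style ratio, t statistic, degrees of freedom, p value
#'   and significance stars.
#' @export
tidy.group_comparison <- function(x, ...) x$table

#' Glance at a group comparison
#'
#' @param x a [compare_groups()] result.
#' @param ... ignored.
#' @return one-row tibble: the two groups, number of comparisons, test
#'   flavour.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(group_1 = x$groups[1], group_2 = x$groups[2],
         n_comparisons = nrow(x$table),
         test = if (x$var_equal) "pooled t" else "Welch t")
}

#' Tidy a study result
#'
#' @param x an `adipo_study` from [run_pipeline()].
#' @param ... ignored.
#' @return the estimates tibble (one row per subject x depot x route).
#' @export
tidy.adipo_study <- function(x, ...) x$estimates

#' Glance at a study result
#'
#' @param x an `adipo_study`.
#' @param ... ignored.
#' @return one-row tibble with sample counts and the config hash.
#' @export
glance.adipo_study <- function(x, ...) {
  tibble(
    n_samples = nrow(x$manifest),
    n_subjects = length(unique(x$manifest$subject_id)),
    n_estimates = nrow(x$estimates),
    config_hash = x$config_hash
  )
}

#' Tidy a bead QC report
#'
#' @param x a [bead_qc()] result.
#' @param ... ignored.
#' @return the per-bead tibble.
#' @export
tidy.bead_qc <- function(x, ...) x$beads

#' Glance at a bead QC report
#'
#' @param x a [bead_qc()] result.
#' @param ... ignored.
#' @return one-row tibble: bead count, mean absolute and signed volume
#'   deviation (percent), pass flag.
#' @export
glance.bead_qc <- function(x, ...) {
  tibble(
    n_beads = nrow(x$beads),
    mean_abs_volume_dev_pct = x$mean_abs_volume_dev_pct,
    mean_volume_dev_pct = x$mean_volume_dev_pct,
    pass = x$pass
  )
}
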