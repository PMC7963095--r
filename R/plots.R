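#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_errorbar labs
#'   facet_wrap position_dodge theme_minimal
NULL

#' Plot a cell-volume size distribution
#'
#' Bar chart of the percentage of cells per volume class (classes are
#' fractions of the mean cell volume).
#'
#' @param object a [size_distribution()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.size_distribution <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot(df, aes(x = .data$mid, y = .data$percent)) +
    geom_col(width = (df$bin_hi - df$bin_lo)[1] * 0.9, fill = "grey35") +
    labs(x = "individual volume (multiples of the mean)",
         y = "% of cells",
         title = "Individual cell volume distribution") +
    theme_minimal()
}

#' Plot bead QC deviations
#'
#' Measured versus true bead volumes with the identity line.
#'
#' @param object a [bead_qc()] result.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.bead_qc <- function(object, ...) {
  df <- object$beads
  ggplot(df, aes(x = .data$true_volume / 1e3, y = .data$measured_volume / 1e3)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = expression("true volume (x10"^3 * " " * mu * m^3 * ")"),
         y = expression("measured volume (x10"^3 * " " * mu * m^3 * ")"),
         title = sprintf("Bead QC: mean |deviation| %.1f%%",
                         object$mean_abs_volume_dev_pct)) +
    theme_minimal()
}

#' Plot group comparisons of depot estimates
#'
#' Group means with SD error bars per depot, faceted by parameter, with the
#' significance annotation of each comparison.
#'
#' @param object a [compare_groups()] result.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.group_comparison <- function(object, ...) {
  tb <- object$table
  long <- bind_rows(
    tibble(depot = tb$depot, parameter = tb$parameter, group = tb$group_1,
           mean = tb$mean_1, sd = tb$sd_1),
    tibble(depot = tb$depot, parameter = tb$parameter, group = tb$group_2,
           mean = tb$mean_2, sd = tb$sd_2)
  )
  ggplot(long, aes(x = .data$depot, y = .data$mean, fill = .data$group)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  position = position_dodge(width = 0.8), width = 0.25) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "Depot estimates by group (mean ± SD)") +
    theme_minimal()
}
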