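#' Volume density from point counts
#'
#' The volume fraction of a structure in its reference compartment estimated
#' by point counting: `V_V = hits on the structure / hits on the reference`.
#'
#' @param hits_structure number of test points hitting the structure.
#' @param hits_reference number of test points hitting the reference
#'   compartment (must be positive and >= `hits_structure`).
#' @return the volume fraction in `[0, 1]`.
#' @export
#' @examples
#' volume_density(91, 100)
volume_density <- function(hits_structure, hits_reference) {
  if (any(hits_reference <= 0)) abort("reference hit count must be positive")
  if (any(hits_structure < 0) || any(hits_structure > hits_reference)) {
    abort("structure hits must lie in [0, reference hits]")
  }
  hits_structure / hits_reference
}

#' Disector tally
#'
#' One row per disector: the number of particles counted (`q`), the section
#' area examined within the counting frames (`area`, square micrometres) and
#' the disector height (`h`, micrometres).
#'
#' @param q integer particle counts (Q-) per disector.
#' @param area frame area examined per disector, um^2.
#' @param h disector height per disector, um.
#' @return a tibble of class `disector_tally`.
#' @export
disector_tally <- function(q, area, h) {
  n <- max(length(q), length(area), length(h))
  q <- rep_len(q, n); area <- rep_len(area, n); h <- rep_len(h, n)
  if (any(q < 0)) abort("counts must be >= 0")
  if (any(area <= 0)) abort("frame areas must be positive")
  if (any(h <= 0)) abort("disector heights must be positive")
  structure(tibble(q = as.numeric(q), area = as.numeric(area), h = as.numeric(h)),
            class = c("disector_tally", "tbl_df", "tbl", "data.frame"))
}

#' Numerical volume density of particles from disector counts
#'
#' `N_V = sum(Q-) / sum(h_i * A_i) * f_s^3`: the cumulative particle count
#' over the cumulative disector volume, corrected for linear tissue
#' shrinkage. With a uniform disector height the denominator reduces exactly
#' to `h * sum(A)`; with per-disector factual section thicknesses the
#' volume-weighted generalisation is used.
#'
#' @param tally a [disector_tally()] (or data frame with columns `q`, `area`,
#'   `h`).
#' @param f_s linear tissue shrinkage factor in `(0, 1]`; 1 is the
#'   no-shrinkage identity.
#' @return numerical volume density in particles per cubic micrometre.
#' @export
#' @examples
#' numerical_density(disector_tally(q = 10, area = 1e6, h = 50))
numerical_density <- function(tally, f_s = 1) {
  if (nrow(tally) == 0) abort("empty disector tally")
  if (f_s <= 0) abort("`f_s` must be positive")
  vol <- sum(tally$h * tally$area)
  if (vol <= 0) abort("zero cumulative disector volume")
  sum(tally$q) / vol * f_s^3
}

#' Coefficient of error of a disector ratio estimate
#'
#' Precision of the ratio `R = sum(q) / sum(area)` across disectors, using
#' the Cochran ratio-estimator form:
#' `CE^2 = n/(n-1) * (sum(q^2)/sum(q)^2 - 2*sum(q*a)/(sum(q)*sum(a)) +
#' sum(a^2)/sum(a)^2)`.
#'
#' @param tally a [disector_tally()] with at least two disectors.
#' @return the coefficient of error (>= 0).
#' @export
#' @examples
#' ce_ratio(disector_tally(q = c(1, 3), area = c(1, 1), h = 1))
ce_ratio <- function(tally) {
  n <- nrow(tally)
  if (n < 2) abort("CE needs at least two disectors")
  q <- tally$q; a <- tally$area
  if (sum(q) == 0) abort("CE undefined: no particles counted")
  ce2 <- n / (n - 1) *
    (sum(q^2) / sum(q)^2 - 2 * sum(q * a) / (sum(q) * sum(a)) + sum(a^2) / sum(a)^2)
  sqrt(max(ce2, 0))
}

#' Volume from mass and density
#'
#' Depot volumetry from weight and tissue density, and submersion
#' (Archimedes) volumetry from displaced-liquid mass and liquid density.
#'
#' @param mass mass in grams (of the object, or of the displaced liquid for
#'   the submersion technique).
#' @param density density in g/cm^3 (tissue, or submersion liquid).
#' @return volume in cm^3.
#' @export
#' @examples
#' volume_from_mass(900, 0.9) # adipose depot, rho = 0.9 g/cm3
volume_from_mass <- function(mass, density) {
  if (any(density <= 0)) abort("density must be positive")
  mass / density
}

#' Linear tissue shrinkage factor
#'
#' From a before/after volume quotient (dimension 3) or section-area
#' quotient (dimension 2): `f_s = (after / before)^(1/dimension)`. The cube
#' of `f_s` converts between pre- and post-processing volumes.
#'
#' @param before,after measured volume (um^3) or area (um^2) before/after
#'   processing; both positive.
#' @param dimension 3 for a volume quotient, 2 for an area quotient.
#' @return a tibble of class `shrinkage_record` with `before`, `after`,
#'   `dimension`, `f_s` and a `swelling` flag (`after > before`).
#' @export
#' @examples
#' shrinkage_factor(1, 0.79, dimension = 3) # 21% volume shrinkage -> 0.92
shrinkage_factor <- function(before, after, dimension = 3) {
  if (!dimension %in% c(2, 3)) abort("`dimension` must be 2 or 3")
  if (any(before <= 0) || any(after <= 0)) abort("`before` and `after` must be positive")
  f_s <- (after / before)^(1 / dimension)
  swelling <- after > before
  if (any(swelling)) warn("`after` exceeds `before`: tissue swelling flagged")
  structure(
    tibble(before = before, after = after, dimension = dimension,
           f_s = f_s, swelling = swelling),
    class = c("shrinkage_record", "tbl_df", "tbl", "data.frame")
  )
}

#' Correct a measured cell volume for tissue shrinkage
#'
#' Restores the pre-shrinkage scale of a volume measured in shrunken tissue:
#' `V_i = raw / f_s^3`. This is the exact inverse of the `f_s^3` factor in
#' the numerical-density formula.
#'
#' @param raw_volume measured volume in um^3.
#' @param f_s linear shrinkage factor; values outside `(0, 1]` are flagged.
#' @return corrected volume in um^3.
#' @export
#' @examples
#' correct_cell_volume(778688, 0.92) # = 1e6
correct_cell_volume <- function(raw_volume, f_s) {
  if (any(f_s <= 0)) abort("`f_s` must be positive")
  if (any(f_s > 1)) warn("`f_s` > 1: correction shrinks the measured volume")
  raw_volume / f_s^3
}

#' Volume of a sphere from its diameter
#'
#' @param diameter diameter in micrometres (> 0).
#' @return volume in cubic micrometres, `(4/3) * pi * (d/2)^3`.
#' @export
#' @examples
#' sphere_volume(99.9) / 1e3 # ~522 (x10^3 um^3)
sphere_volume <- function(diameter) {
  if (any(diameter < 0)) abort("`diameter` must be >= 0")
  (4 / 3) * pi * (diameter / 2)^3
}

#' Depot-level derived quantities
#'
#' Combines a volume density, the depot volume and one number route into the
#' full parameter set for one depot: total adipocyte volume
#' `V_AC = V_V * V_ATD`, and either the stereology route
#' (`N = N_V * V_ATD`, `v_bar = V_V / N_V`) or the volumetry route
#' (`v_bar` given as the mean corrected individual volume,
#' `N = V_AC / v_bar`).
#'
#' @param v_v volume density of adipocytes (fraction in `[0, 1]`).
#' @param v_atd_cm3 depot volume in cm^3 (1 cm^3 = 1e12 um^3 internally).
#' @param n_v numerical volume density in cells/um^3 (stereology route).
#' @param v_bar mean individual cell volume in um^3 (volumetry route).
#' @param ce optional coefficient of error to carry along.
#' @return one-row tibble of class `depot_estimates` with columns
#'   `v_atd_cm3`, `v_v`, `v_ac_cm3`, `n_v_per_um3`, `n_total`, `v_bar_um3`,
#'   `ce`, `route`.
#' @export
#' @examples
#' derive_totals(v_v = 0.9, v_atd_cm3 = 1000, n_v = 1e-6)
#' derive_totals(v_v = 0.9, v_atd_cm3 = 1000, v_bar = 9e5)
derive_totals <- function(v_v, v_atd_cm3, n_v = NULL, v_bar = NULL, ce = NA_real_) {
  if (v_v < 0 || v_v > 1) abort("`v_v` must be a fraction in [0, 1]")
  if (v_atd_cm3 < 0) abort("`v_atd_cm3` must be >= 0")
  um3_per_cm3 <- 1e12
  v_atd_um3 <- v_atd_cm3 * um3_per_cm3
  v_ac_um3 <- v_v * v_atd_um3
  if (!is.null(n_v)) {
    route <- "stereology"
    n_total <- n_v * v_atd_um3
    v_bar_out <- if (n_v > 0) v_v / n_v else NA_real_
    n_v_out <- n_v
  } else if (!is.null(v_bar)) {
    route <- "volumetry"
    if (v_bar <= 0) abort("`v_bar` must be positive")
    n_total <- v_ac_um3 / v_bar
    n_v_out <- n_total / v_atd_um3
    v_bar_out <- v_bar
  } else {
    abort("give either `n_v` (stereology route) or `v_bar` (volumetry route)")
  }
  structure(
    tibble(
      v_atd_cm3 = v_atd_cm3, v_v = v_v, v_ac_cm3 = v_ac_um3 / um3_per_cm3,
      n_v_per_um3 = n_v_out, n_total = n_total, v_bar_um3 = v_bar_out,
      ce = ce, route = route
    ),
    class = c("depot_estimates", "tbl_df", "tbl", "data.frame")
  )
}

#' Size distribution of individual cell volumes
#'
#' Bins individual volumes into classes of a fixed fraction of the mean
#' volume (default 20%): `[0, 0.2*vbar)`, `[0.2*vbar, 0.4*vbar)`, ... Heights
#' are percentages of cells and sum to 100. A Shapiro-Wilk statistic on the
#' raw volumes is attached as a normality report.
#'
#' @param volumes individual cell volumes, um^3 (at least one).
#' @param bin_fraction bin width as a fraction of the mean volume.
#' @return tibble of class `size_distribution` with `bin_lo`, `bin_hi` (in
#'   multiples of the mean), `n`, `percent`; attributes `mean_volume`,
#'   `normality` (tibble with `statistic`, `p_value`).
#' @export
#' @examples
#' sd <- size_distribution(rnorm(200, 1e6, 3e5))
#' head(sd)
size_distribution <- function(volumes, bin_fraction = 0.2) {
  volumes <- volumes[is.finite(volumes)]
  if (length(volumes) == 0) abort("no volumes to bin")
  if (any(volumes < 0)) abort("volumes must be >= 0")
  vbar <- mean(volumes)
  rel <- volumes / vbar
  bin <- floor(rel / bin_fraction)
  nb <- max(bin) + 1
  counts <- tabulate(bin + 1L, nbins = nb)
  out <- tibble(
    bin_lo = (seq_len(nb) - 1) * bin_fraction,
    bin_hi = seq_len(nb) * bin_fraction,
    n = counts,
    percent = 100 * counts / length(volumes)
  )
  normality <- if (length(volumes) >= 3 && length(volumes) <= 5000 &&
                   stats::sd(volumes) > 0) {
    sw <- shapiro.test(volumes)
    tibble(statistic = unname(sw$statistic), p_value = sw$p.value)
  } else {
    tibble(statistic = NA_real_, p_value = NA_real_)
  }
  structure(out, mean_volume = vbar, normality = normality,
            class = c("size_distribution", "tbl_df", "tbl", "data.frame"))
}
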