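---
title: "Design-based stereology of adipose tissue: models, probes and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology of adipose tissue: models, probes and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipostereo)
```

## The estimation problem

Obesity research needs unbiased, assumption-free estimates of three
depot-level quantities for adipocytes: the total volume of adipocytes in a
depot ($V_{AC}$), their total number ($N$), and their mean individual volume
($\bar v$). Profile-based 2D measurements cannot deliver number-weighted 3D
quantities without shape assumptions; design-based stereology can, via three
probes:

* **Point counting** on uniformly sampled sections estimates the volume
  density $V_V = P_{\text{structure}} / P_{\text{reference}}$, and
  $V_{AC} = V_V \cdot V_{ATD}$, where the depot volume $V_{ATD}$ comes from
  depot mass and tissue density ($\rho \approx 0.9\,\mathrm{g/cm^3}$) or
  from submersion volumetry.
* **The disector** — two parallel planes a known distance $h$ apart —
  counts a cell exactly when it appears in the reference plane but not the
  look-up plane, giving the numerical volume density
  $$N_V = \frac{\sum Q^-}{\sum (h_i A_i)} \cdot f_s^3,$$
  unbiased by cell size, shape or orientation. $\sum A$ is the section area
  examined inside unbiased counting frames, and $f_s$ the linear tissue
  shrinkage factor. Then $N = N_V \cdot V_{ATD}$ and
  $\bar v = V_V / N_V$.
* **Voxel volumetry** in 3D image stacks of optically cleared,
  membrane-stained tissue measures individual cell volumes $V_i$ directly
  (voxel count of the dark interior enclosed by the bright membrane, times
  the voxel volume), corrected for clearing shrinkage as $V_i / f_s^3$.
  This provides the second, independent route $N = V_{AC} / \bar v$.

`adipostereo` implements both routes end to end, plus the probes,
corrections and reports around them, and validates every estimator against
synthetic tissue phantoms with exhaustive ground truth.

## Shrinkage correction

Tissue processing shrinks samples; volumes measured after processing refer
to the shrunken state. From a before/after volume quotient $q$ the linear
factor is $f_s = q^{1/3}$ (or $q^{1/2}$ for a section-area quotient). A 21%
volume shrinkage — typical for solvent clearing of adipose tissue, and of
the same size as plastic-embedding shrinkage — gives $f_s = 0.79^{1/3}
= 0.92$. Densities estimated in shrunken tissue are *multiplied* by
$f_s^3$ (the reference volume was larger before shrinkage); individual
volumes are *divided* by $f_s^3$. The two corrections are exact inverses,
which the test suite asserts symbolically. Note that a printed pair of
"21% shrinkage, $f_s = 0.93$" is internally inconsistent at two decimals
($0.79^{1/3} = 0.924$); `shrinkage_factor()` always derives $f_s$ from the
measured quotient rather than accepting a rounded factor.

## The counting frame

`apply_counting_frame()` implements the unbiased counting frame: a profile
is accepted if it intersects the frame and does not touch the forbidden
line — the left edge extended infinitely upward, the bottom edge, and the
downward infinite extension at the bottom-right corner. For connected
profiles this rule counts every profile exactly once under a tiling of
congruent frames, for profiles of any size and shape. We verify the
exactly-once property by brute force on random profile sets, including
non-convex profiles and tilted ellipses larger than a frame — a
configuration in which simpler formulations of the edge rule (for example,
treating both exclusion edges as full infinite lines) demonstrably leak
counts and bias $N_V$ downward by several percent.

A practical corollary implemented in the pipeline: a *single* frame's
forbidden lines extend across the whole field of view, so profiles of cells
clipped by the image border can collide with them. Keeping the frame
centred, a cell-diameter away from the stack border, avoids this edge
artefact; the default probe geometry therefore centres one
$300 \times 300\,\mu m$ frame in the field.

## The tissue phantom

The generator (`generate_adipose_phantom()`) builds space-filling polyhedral
cells as an additively weighted Voronoi (Laguerre) tessellation of seed
points, rendered into a voxel stack: membranes as a thin bright sheet
(single-voxel wall with sub-voxel Gaussian blur, mirroring the practice of
keeping stained membranes narrower than the voxel pitch), interiors dark,
plus Gaussian detector noise, optional connective-tissue strands, one
peripheral nucleus per cell, and optional membrane gaps (the known failure
mode in which two cells merge under the wand).

Choices that matter for validity:

* **Periodic tessellation (default).** Distances wrap around the box, so
  the tissue is statistically homogeneous: there is no boundary layer of
  smaller cells and the upper endpoints ("tops") of cells are exactly
  uniform in $z$. The number density $K / V_{\text{box}}$ is then the exact
  ground truth for disector estimates. During development we measured that
  a plain (non-periodic) partition produces a face layer whose excess top
  density biases interior probes by 5–10% — an artefact of the box, not of
  the estimator. Cells crossing a box face appear as face-touching
  fragments; they are flagged `clipped_by_boundary`, remain countable for
  $N$ (the disector needs only presence/absence) and are excluded from
  volume measurement, where truncation would bias $\bar v$ downward.
* **Seed point process.** Hard-core (Poisson-disk) sampling followed by two
  Lloyd relaxation steps on a coarse periodic grid. This is isotropic —
  unlike jittered-lattice seeds, whose axis-aligned cell layers interact
  with plane probes — and has a low baseline volume spread, leaving room to
  calibrate the spread upward.
* **Volume law and calibration.** Target volumes are drawn from a Normal
  distribution truncated at 1% of the mean (individual adipocyte volumes
  are reported to be normally distributed). Because the tessellation is
  space-filling, the achieved mean is set by the seed count and the
  achieved CV by the Laguerre weight spread; both are calibrated
  iteratively against the rasterized interior volumes (seed count first,
  then a bracketed secant on the log weight-spread) to within 0.8% and 2%
  respectively. With `calibrate = FALSE` one pass is used, which makes
  geometrically scaled configurations exactly similar — the basis of the
  shrinkage round-trip test.
* **Intensity model.** 16-bit depth; membrane plateau 45000, interior 2000,
  Gaussian blur of one voxel FWHM ($\sigma = 0.42$ voxel), noise SD 800.
  With the default wand tolerance of 10000 (absolute intensity units around
  the seed value, an instrument-specific setting) the blurred interior
  shell adjacent to the membrane — including shell voxels along polyhedron
  edges and corners that receive blur from two or three walls — stays
  inside the wand window, so tolerance-based growth recovers the rasterized
  interior exactly on noise-free stacks and to within ~1% on noisy ones.
  (With a broader blur, corner shells cross the window and individual
  volumes read a few percent low.)

What the phantom does *not* emulate: light-sheet optics (PSF anisotropy,
attenuation with depth, spherical aberration), multilocular or brown
adipocytes, vessels and inflammatory infiltrates, and intensity
inhomogeneity across the field. Passing the recovery tests therefore shows
the *estimators* are correct on geometry resembling adipose tissue; it does
not certify segmentation robustness on real light-sheet stacks.

## Probe geometry and sampling

Systematic uniform random (SUR) sampling is used throughout: interval
$k = n_{\text{total}}/n_{\text{take}}$, one random phase $u \sim U[0, k)$,
indices $\lfloor u + jk \rfloor$ (returned 1-based). The real-valued
interval keeps every index equiprobable for any $n_{\text{total}}$,
$n_{\text{take}}$. Optical disector plane pairs are drawn from the middle
third of the stack (both planes constrained to the zone), with height
$h$ = plane separation × axial step; the default 10 planes at 5 um gives
$h = 50\,\mu m$, safely below the typical adipocyte height, and the
restriction to the middle third keeps the probe away from the axial stack
faces where qualifying positions would be truncated. Point grids use the
half-open pixel convention — a point on a pixel boundary belongs to exactly
one pixel, so no fractional counting is needed.

## Serial sections and the physical disector

`nucleus_section_series()` cuts consecutive virtual sections with factual
thickness jitter (emulating reflectometric thickness measurement of
physical sections, e.g. nominal 1.00 um cutting yielding 1.34 ± 0.28 um
sections). Nucleus presence in a slab is decided by exact sphere–slab
geometry, matching the physical disector's detectability assumption; the
counting code warns when the disector height exceeds one third of the
nucleus diameter. In the density formula the denominator generalises to
$\sum_i h_i A_i$ with per-disector factual heights, reducing exactly to
$h \sum A$ for uniform $h$. Counts and areas are pooled per subject before
the ratio is formed (ratio of sums, not mean of ratios).

## Numerical choices and degenerate inputs

* Automatic thresholds use Otsu's method (via EBImage) on the plane or
  stack at hand; profile seeds for the wand are taken at the pixel of
  median profile intensity, which is robust to noise minima that would
  shift the wand window.
* Profiles smaller than `min_profile_area` (default 100 um^2) are not
  treated as cell profiles; runaway regions beyond `max_voxels` (default
  sized at 20 x the expected cell volume) are flagged as membrane-gap
  suspects and excluded from counts and measurements.
* The coefficient of error of the density estimate uses the Cochran
  ratio-estimator form across disectors,
  $CE^2 = \frac{n}{n-1}\left(\frac{\sum q^2}{(\sum q)^2} -
  \frac{2\sum qa}{\sum q \sum a} + \frac{\sum a^2}{(\sum a)^2}\right)$,
  a documented choice among the family of section-sampling CE estimators.
* Degenerate inputs are errors, not silent defaults: empty tallies, zero
  disector volume, non-positive densities and thicknesses, grids larger
  than their image, infeasible plane separations, bead packings that do not
  fit.

## Study scenario and statistics

`scenario_suite()` encodes a two-group, two-depot design: subcutaneous
adipocyte growth both hypertrophic and hyperplastic (mean-volume ratio
3.61, number ratio 2.7 obese/lean), visceral growth hypertrophic only
(ratio 4.06, number ratio 1.0), volume densities near 0.9, and lognormal
between-subject variability (CV 0.15, unit mean, so group ratios are
preserved in expectation). Depot volumes default to plausible minipig
values (lean 1500 cm^3 subcutaneous, 700 cm^3 visceral) as the depot masses
behind the published design are not tabulated. Within-sample individual
volumes use CV 0.3. Group contrasts use Welch t-tests with the usual
star thresholds and no multiple-testing correction, matching the simple
two-group reporting the design calls for; the two estimation routes are
compared by paired t-test and mean percent deviation.

The default problem sizes used by the test-suite and the acceptance script
— 500 um cubic phantoms at 5 um pitch (about 110 cells of mean volume
$10^6\,\mu m^3$), 8 plane pairs counted in both directions (16 disectors,
roughly 60–120 cells per depot), and single-sample subjects in scenario
runs — were chosen to reproduce the sampling effort of a realistic depot
analysis while keeping a full validation run on one CPU in minutes; the
phantom is a sample-sized window, not a whole depot, and all depot totals
enter through $V_{ATD}$.

## Known limitations

* The wand tolerance, intensity plateaus and blur are an idealised
  instrument model; on real stacks the tolerance is an operator-tuned,
  instrument-specific setting.
* Mean-volume recovery is validated on unclipped (complete) cells; in very
  small fields where most cells touch the border, the unclipped sample is
  small and mildly size-biased, exactly as in the physical procedure that
  excludes boundary cells.
* The phantom's membrane is geometrically closed by construction;
  real membrane-staining gaps are only emulated through the explicit
  gap-injection option, whose size/frequency is a free parameter.
* Periodic phantoms relax the within-box connectivity of boundary cells
  (fragments of one torus cell share a label); with `periodic = FALSE`
  every labelled interior is 6-connected inside the box, at the cost of
  boundary inhomogeneity.
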