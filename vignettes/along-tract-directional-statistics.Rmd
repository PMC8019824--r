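---
title: "Along-tract group analysis of principal diffusion directions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract group analysis of principal diffusion directions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractdir)
```

## The problem

Group studies of diffusion-tensor imaging usually compare scalar
summaries such as fractional anisotropy, which discard the *direction*
of diffusion. The principal diffusion direction (PDD) — the unit
eigenvector of the tensor with the largest eigenvalue — is an axis
(`x` and `-x` are the same observation), and differences in fiber
orientation between groups are invisible to scalar tests. `tractdir`
compares two subject groups *along* a white-matter bundle: it reduces
the multi-subject bundle to a medial line, cuts the bundle into
cross-sectional slabs every 2 mm, pools each group's PDDs slab by slab,
models them with axial distributions on the sphere, and asks, slab by
slab, whether the mean axes of the two groups are distinguishable.

The pipeline expects inputs already registered to a common grid:
per-subject binary bundle masks, per-subject PDD fields, and an
integer-labelled region volume (all NIfTI-1). Registration,
tractography and tensor estimation are upstream of this package.

## Pipeline

1. **Overlap.** `intersect_subject_masks()` keeps voxels black in every
   subject's mask; `largest_component()` then drops stray fragments
   (outlier bundles) by keeping the largest 26-connected component —
   a deterministic, parameter-free reading of "outlier removal".
   Outliers are removed before thinning: thinning a fragmented volume
   would preserve each fragment as a separate curve, so pruning first
   is the conservative order.
2. **Medial line.** `curve_thin()` applies 6-subiteration sequential
   directional thinning (direction order U, D, N, S, E, W, i.e. +z,
   -z, +y, -y, +x, -x) deleting only *simple points* — voxels whose
   removal provably preserves local topology (one 26-component of
   black in the 26-neighbourhood, one 6-component of white in the
   18-neighbourhood touching the voxel) — while protecting curve
   endpoints. The component count of the volume is invariant by
   construction, and the result is a one-voxel-wide curve.
3. **Smoothing.** `order_skeleton()` walks the curve end to end (the
   pipeline falls back to the skeleton graph's diameter path when
   ragged masks leave spurs), and `fit_bspline()` fits a clamped cubic
   B-spline by least squares: chord-length parameters, uniform interior
   knots, and a Cholesky solve of the banded normal equations. The
   default `n_ctrl = max(4, #points/4)` smooths voxel-level jitter
   without straightening anatomy; it is exposed for tuning.
4. **Slicing.** `sample_slices()` places frames every 2 mm of arc
   length (arc length by adaptive quadrature of `|dX/dt|`, tolerance
   1e-6 mm; both the `s = 0` and the final `s <= L` frame included);
   `cut_cross_section()` collects bundle voxels within half a slab
   thickness (one voxel) of each cutting plane, restricted to the
   26-connected in-slab component at the frame point so that a folded
   tract crossing the same plane elsewhere is not captured.
5. **Per-slice test.** Each group's PDDs in the slab (pooled over
   subjects, at voxels where the subject's own mask is black) form an
   axial sample. `bingham_mle()` fits a Bingham distribution,
   `confidence_ellipse()` builds the large-sample confidence region of
   the mean axis, and `groups_differ()` flags the slice when the two
   groups' cones of confidence are separated — the angular distance
   between mean axes exceeds the sum of the ellipse radii along the
   connecting great circle. Slices with fewer than `min_axes = 10`
   axes in either group are untestable (degenerate eigen-spectra
   otherwise dominate) and break cluster contiguity.
6. **Clusters and the difference matrix.** `count_clusters()` counts
   maximal runs of at least `n_min = 4` consecutive significant
   slices; `difference_matrix()` records that count as the weight of
   each region pair. No further multiple-testing correction is applied
   across slices or pairs — the contiguity rule is the built-in guard,
   and the calibration experiments below quantify the family-wise
   behaviour it achieves.

The per-slice level is `alpha = 0.005` by default, and `n_min = 4` at
2-mm slicing asks for roughly a centimetre of consistent difference.
(Note the arithmetic tension if one motivates `n_min` from a 10-mm
minimum at the 2.2-mm acquisition spacing: 4 x 2.2 = 8.8 mm. Both
knobs are configurable; the defaults are kept as stated.)

## Directional models

For an axial sample `x_1 ... x_n` (canonicalized to one hemisphere),
the scatter matrix `T = (1/n) sum x x'` has eigenvalues
`t1 >= t2 >= t3` summing to 1.

**Watson.** `W(x; mu, kappa) = c(kappa) exp(kappa (mu'x)^2)` with
`c(kappa) = Gamma(3/2) / (2 pi^{3/2} M(1/2, 3/2, kappa))`, `M` being
Kummer's confluent hypergeometric function (`kummer_M()`, positive-term
series with the Kummer transformation for negative arguments). The MLE
takes `mu` from the leading (bipolar) or trailing (girdle) eigenvector
and solves `D3(kappa) = mu'T mu`, where `D3` is the logarithmic
derivative of `M(1/2, 3/2, .)` — strictly increasing, `D3(0) = 1/3` —
by Newton-Raphson with a maintained bracket (`watson_kappa_solve()`).
Concentrations are capped at |kappa| = 700, the double-exponential
overflow guard; the cap warns.

**Bingham.** `B(x; K) = c(K) exp(x'Kx)`, `K = U diag(0, k2, k3) U'`
with the gauge `0 >= k2 >= k3` (K is identifiable only up to adding a
multiple of the identity). The fit is a closed-form moment estimator:
the axes are the scatter eigenvectors; for a bipolar sample
(`t1 >= 1/2`, the symmetric midpoint of the Watson moment range) the
rotationally symmetric Watson solution `kappa0 = -D3^{-1}(t1)` is
split harmonically across the minor axes,
`k_j = kappa0 (t2 + t3) / (2 t_j)`, which preserves
`1/k2 + 1/k3 = 2/kappa0` and is exact both in the symmetric limit
(`k2 = k3 = kappa0`) and in the high-concentration limit
(`k_j -> -1/(2 t_j)`). For a girdle sample, `k3 = D3^{-1}(t3)` is the
Watson girdle concentration and the in-plane anisotropy solves the
circular moment equation `D2(k2) = t2/(t1 + t2)`. Perturbative
delta-corrections of the symmetric solution were considered and
rejected: they are only valid near isotropy and collapse the
asymmetry of concentrated samples, which is precisely what the
per-slice test relies on. The normalising constant of the density is
evaluated by doubling tensor Gauss-Legendre spherical quadrature to a
relative 1e-8 and cached per concentration pair; a saddlepoint
approximation would be faster but has no error bound.

**Sampling** (`sample_model()`) uses rejection from an
angular-central-Gaussian envelope: with `A = -K` and `b` solving
`sum 1/(b + 2 lambda_i) = 1`, the envelope `ACG(I + 2A/b)` gives the
acceptance bound `exp(-(3-b)/2) (3/b)^{3/2}`. Watson models are routed
through their Bingham gauge equivalents.

**Confidence ellipse.** The large-sample region for the mean axis has
angular semi-axes `e_m = sqrt(chi2_{1-alpha,2} / (2N (k1-k_m)(w1-w_m)))`
toward the minor axes (`w` the scatter eigenvalues, `N` the fitted
sample size). Literature statements of the specialized `alpha = 0.01`
semi-axes carry a pre-multiplied constant; the package implements the
general formula only — the Monte-Carlo coverage experiment below is
the ground truth for its calibration. The degenerate case
(`k` or `w` gaps vanishing) raises an error and the affected slice
becomes untestable.

## Goodness of fit

`goodness_of_fit()` rotates the sample so its reference axis (vector
resultant for Watson; leading/trailing scatter eigenvector for bipolar
/ girdle Bingham) points along +z, fixes the antipodal representative
in that frame (z >= 0), and bins the x-y azimuth into 50 bins of 7.2
degrees. The binned sample is compared against a binned synthetic
reference of 700 axes — drawn either from the fitted model (a
calibration reading) or uniformly on the sphere (a structure reading:
a small p-value means the azimuthal anisotropy the Bingham ellipse
describes is really present). Because both histograms are finite
samples, the statistic is the *two-sample* Pearson chi-square
`sum (sqrt(m/n) O_i - sqrt(n/m) S_i)^2 / (O_i + S_i)`; the classic
one-sample form with the synthetic counts scaled up is badly
anti-conservative when `n >> m` and is not offered. Degrees of freedom
default to `bins - 1`; a fitted-parameter subtraction is available via
`n_params` but off by default, because the model parameters are
estimated from the full 3D sample rather than from the azimuth
histogram, and subtracting them measurably left-shifts the null
p-value distribution.

`aggregate_mode_fit()` applies this to a labelled region under three
aggregation modes — all region voxels (voxel-based analysis), the
curve-thinned region skeleton (skeleton-based), or the pooled profile
slabs (the along-tract reading) — fitting both Watson and Bingham. A
model is a candidate when its structure test is significant at 0.05;
between candidates the calibration reading decides, which penalises a
rotationally symmetric Watson fit on elliptically dispersed axes.

## The synthetic cohort generator

`make_cohort()` is first-class, tested code and defines the study
conditions for every calibration and power experiment:

* **Geometry.** A tube of radius 5 mm around a parametric centerline
  (straight, arc or helix) on an isotropic 2.2-mm grid — the spacing
  of a typical clinical DTI acquisition. Rasterization is
  partial-volume (a voxel is black when at least half its volume,
  estimated on a 4^3 subgrid, is inside the tube) with the grid
  deliberately aligned 0.35 voxel off the centerline: voxel-centre
  membership on a grid running through (or exactly between) voxel
  centres biases the discretized tube volume by up to ~30% at these
  radii, while this rasterization stays within ~7% of `pi r^2 L`.
* **Inter-subject variation.** Each subject's mask perturbs boundary
  sites with total probability 0.1 (half erosions, half dilations).
* **PDDs.** At each mask voxel an axis is drawn from a Bingham
  distribution with mean axis along the local centerline tangent and
  concentrations `(0, -5, -40)` by default — strongly tube-aligned
  with mildly elliptical dispersion, as in coherent white matter.
* **Group effect.** A rigid rotation of the local mean axis (default
  experiments: 45 degrees over a 16-mm window) applied to group B
  before sampling — a mean-direction difference, which is what the
  separated-cones test targets. A concentration change would alter
  ellipse sizes instead and is left to robustness experiments.
* Everything is a pure function of `(spec, kappas, effect, seed)`.

What the generator does *not* emulate: crossing fibers, partial-volume
PDD averaging at bundle boundaries, registration error beyond boundary
jitter, noise-floor effects on eigenvector estimation, or anatomical
curvature variability beyond the arc/helix phantoms. Passing
calibration and power experiments on these cohorts therefore
demonstrates the statistical machinery under clean axial dispersion,
not performance on clinical data.

## Experiment design and problem sizes

The test suite and `scripts/acceptance.R` re-run, at fixed seeds:

* Watson recovery (50 x n = 1000, kappa = 10) and Bingham recovery
  (30 x n = 2000, kappas (0, -5, -20)) — medians of the concentration
  estimates and their truth ratios.
* Ellipse coverage: 500 replicates at n = 200, alpha = 0.01.
* Two-group calibration: 1000 null replicate pairs at n = 60,
  alpha = 0.005 — the separated-cones criterion is conservative by
  construction (it demands non-overlap of two 99.5% regions).
* End-to-end detection: 20 cohorts (8 subjects/group) with the
  45-degree, 16-mm effect; detection scored by Jaccard overlap >= 0.5
  between flagged clusters and the ground-truth window; 20 null
  cohorts scored for zero weight.
* Length effect: tracts of 20-100 mm with a constant per-slice effect.
  The effect magnitude (6 degrees) is set at the per-slice detection
  boundary — large enough to flag most slices, small enough that runs
  of four break stochastically — because the experiment's target is
  the *accumulation* of clusters with length, which saturates if every
  slice is flagged and vanishes if none is. Cluster-count and length
  z-scores are then regressed by ordinary least squares.

These sizes keep the whole suite within a few minutes on a single
core while leaving the Monte-Carlo margins comfortably away from the
pass thresholds.

## Numerical choices and degenerate inputs

* Eigenvector signs are fixed (first nonzero component positive), so
  fits, rotations and serialized models are bit-reproducible.
* `D3` is computed from positive-term Kummer series for |kappa| <= 500
  and from a max-scaled integral representation beyond; its inverse
  round-trips to 1e-6 across the working range.
* All-identical axes drive the Watson solve to the +700 cap (warning);
  isotropic samples fit near-zero concentrations on either branch.
* Empty overlap, too-short medial lines, starved slices, and
  degenerate eigen-spectra all degrade to explicit "untestable" /
  empty-profile outcomes rather than errors in the pipeline surface.
* Slabs cut where the plane misses the bundle return empty cross
  sections; they are flagged untestable downstream.
* The B-spline derivative uses the standard knot-differenced control
  points; published statements of this formula are occasionally
  garbled, so it is validated against central finite differences in
  the tests.

## Command line

`inst/cli/tractdir.R` wraps the package for shell use:
`simulate` writes a seeded cohort (NIfTI + manifest CSV + truth JSON),
`profile` writes a per-slice report CSV, `matrix` writes the
difference-matrix CSV and edge list, and `gof` runs the region-level
model fits; `--alpha`, `--n-min`, `--spacing-mm`, `--mode`, `--seed`
and `--config config.yaml` mirror the function arguments.

## Limitations

* Pooling PDDs across subjects within a slice treats subjects as
  exchangeable axis sources; a per-subject second-level analysis is a
  known alternative the package does not implement.
* The Bingham fit is a moment estimator, not the full
  matrix-hypergeometric MLE; its accuracy is quantified by the
  recovery experiments (medians within ~10% at the default
  concentrations) rather than by asymptotic theory.
* Thinning operates on the lattice and ignores anisotropic spacing;
  spacing enters downstream through world coordinates.
* Branching bundles are reduced to their longest medial path; true
  bifurcations are out of scope.
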