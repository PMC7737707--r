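---
title: "Multi-parametric phenotypic scoring: models and methods"
author: "phenoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parametric phenotypic scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

## The problem

High-content screens treat cultured cells with dilution series of many
compounds, image each well in several fluorescence channels (here: a nuclear
stain, F-actin, and immunolabelled tubulin), and quantify a vector of
attributes for every segmented cell — areas, axis lengths,
background-subtracted intensities, fiber lengths, texture. Profiling a drug
through any single attribute is misleading: different drugs move different
attributes, attributes live on different scales with different cell-to-cell
variability, and many are strongly correlated (total protein content tracks
cell size). phenoscreen implements a scoring scheme that condenses the whole
attribute vector into one unbiased potency score per cell, aggregates it to
wells and plates, and feeds the resulting dose-response curves into
median-effect and drug-combination analysis.

## The control hyper-ellipsoid and the Mahalanobis score

Let $x \in \mathbb{R}^p$ be a cell's attribute vector. The control cells of
a plate define a multivariate distribution with center $\mu$ and covariance
$\Sigma$; PCA of the control population fits the hyper-ellipsoid whose
principal axes $V$ and axis variances $\lambda$ are the eigenvectors and
eigenvalues of $\Sigma$. The score of any cell is its Mahalanobis distance

$$D(x) = \sqrt{(x-\mu)^\top \Sigma^{-1} (x-\mu)}
       = \sqrt{\sum_k \frac{y_k^2}{\lambda_k}}, \qquad y = V^\top (x-\mu),$$

which balances scales, weights attributes by their natural variability, and
discounts correlated directions. It is non-negative by construction, zero at
the control center, and for control-distributed cells $D^2 \sim \chi^2_d$
with $d$ the retained dimension — which gives calibrated outlier thresholds
for free.

Implementation choices:

* **Standardization.** Attributes are divided by their control standard
  deviation before the PCA. Mahalanobis distances are unchanged by this in
  the full-rank case, but it makes the eigenvalue floor (below) meaningful:
  raw attribute variances span many orders of magnitude (pixel areas next to
  intensity sums), and any relative floor on raw eigenvalues would silently
  discard the small-scale attributes.
* **Robustness by chi-square trimming.** The control wells contain technical
  artifacts — bubbles, dead cells, clumps. `fit_control_model()` iterates:
  fit center/PCA on current inliers, drop points with
  $D^2 > \chi^2_d(q)$ (default $q = 0.975$), refit, until the inlier set is
  stable (at most `max_iter = 10` rounds). Trimming is deterministic and
  auditable; the model records the trim history.
* **Consistency correction.** A covariance estimated from points inside the
  trim radius underestimates the true covariance by the closed-form factor
  $\mathrm{P}(\chi^2_{d+2} \le k)/\mathrm{P}(\chi^2_d \le k)$ at radius
  $k = \chi^2_d(q)$; the fitted variances are inflated back by its
  reciprocal. Without this correction null squared distances are biased
  upward and no longer follow $\chi^2_d$.
* **Rank deficiency.** Axes with variance below `variance_floor` ($10^{-6}$)
  times the mean eigenvalue are dropped from the retained set; perfectly
  correlated attribute pairs therefore reduce $d$ by one instead of
  exploding distances. The retained dimension is always reported.

### Attribute contributions

Once a cell scores high, the question is *which* attributes moved. With
$g = \Sigma^{+}(x-\mu)$ (pseudo-inverse through the retained axes), the
squared distance decomposes additively over attributes,

$$c_j = \frac{(x-\mu)_j \, g_j}{D^2}, \qquad \sum_j c_j = 1,$$

and ranking by $|c_j|$ identifies the most affected attributes. In an
uncorrelated model this reduces to the share of squared z-scores. Other
normalizations of per-attribute contributions exist in the literature; this
package uses the additive decomposition because it is exact, signed, and
sums to one by construction.

### Wells, outliers, plates

Per-cell flags use the $\chi^2_d$ quantile at 0.999: control-distributed
cells are flagged at a rate of about 0.1%. The well score is the **median**
distance over non-flagged cells (the mean is fragile to residual
artifacts), with the MAD as dispersion. One deliberate asymmetry: artifact
rejection is only trusted when it concerns a minority of a well. If the
chi-square rule would flag more than half the cells, the well is exhibiting
a coherent treatment effect, not artifacts, and the median is taken over
all cells — otherwise a saturating dose would be discarded as "all
outliers" instead of scored. Control pooling is per plate; cross-plate
normalization is out of scope.

## Median-effect dose-response

Well scores along a dilution series are fit with the median-effect (Chou)
form

$$\mathrm{score}(D) = A\,f(D) + B, \qquad
  f(D) = \frac{1}{1 + (D_m/D)^s},$$

where $B$ is the baseline at zero drug, $A$ the amplitude at saturation,
$D_m$ the median-effect concentration and $s$ the Hill exponent. Fitting
proceeds in the classical two stages: $A$ and $B$ from the curve extremes;
$(D_m, s)$ from the linearization
$\log(1/f - 1) = s\,\log(D_m/D)$, which is exact on noiseless data; then a
bounded Levenberg–Marquardt refinement of all four parameters
(`minpack.lm`), which never ends worse than its initialization. Fractional
effects are clipped to $[\delta, 1-\delta]$ with $\delta = 0.01$ before
taking logs; clipped points are excluded from the linear fit but included
in the nonlinear one (the untransformed model needs no clipping). Duplicate
doses are averaged before fitting, matching the virtual-plate convention.
Parameter bounds: $A \in [0, 10\,\mathrm{range}]$,
$B \in [\min \pm \mathrm{range}]$,
$D_m \in [\min D/100,\ \max D \cdot 100]$, $s \in [0.1, 10]$. Curves with
fewer than 4 points or spanning under two dose decades are flagged
low-confidence; with fewer points than parameters the linearized estimate
is returned directly.

Screens that report the half-effect position as a plate column index use
`column_to_concentration()`: with 3-fold dilutions in duplicate columns
starting at $10 \times \mathrm{GI}_{50}$, column $D_m$ corresponds to
$10 \cdot \mathrm{GI}_{50} \cdot 3^{\,1 - D_m/2}$. The fitted $D_m$ is
reported as a continuous concentration; mapping it back to a (fractional)
column index is left to the caller because the physical column pairing of
duplicates is plate-specific.

## Drug combinations: Loewe and Bliss nulls

For a binary combination matrix the single-agent edges give
$(D_{m1}, s_1)$ and $(D_{m2}, s_2)$. Two null surfaces are spanned over the
dose grid:

* **Loewe additivity** treats the drugs as dilutions of one another. The
  combination fraction $f$ solves
  $$\frac{D_1}{D_{m1}\,[f/(1-f)]^{1/s_1}} +
    \frac{D_2}{D_{m2}\,[f/(1-f)]^{1/s_2}} = 1,$$
  which is strictly monotone in $f$, so `loewe_predict()` brackets the
  unique root on $(0,1)$ (bisection-safeguarded `uniroot`, residual below
  $10^{-8}$ at return). At a zero partner dose it reduces exactly to the
  single-agent curve, and for identical drugs to the dose-additive closed
  form $f(D_1+D_2)$. The combination index
  $\mathrm{CI} = D_1/D_{x1} + D_2/D_{x2}$ with
  $D_{xi} = D_{mi} [f/(1-f)]^{1/s_i}$ quantifies departure: 1 additive,
  $<1$ synergy, $>1$ antagonism.
* **Bliss independence** is implemented, by default, as the plain product of
  the two effect fractions, $f_{\mathrm{comb}} = f_1 f_2$. Note this
  convention: under it a zero partner dose yields $f_{\mathrm{comb}} = 0$,
  not the single-agent curve; the conventional independence form
  $f_1 + f_2 - f_1 f_2$ is available via `convention = "independence"`.

`fit_combination_joint()` refits all four parameters to every cell of the
observed grid simultaneously (bounded least squares from the edge-fit
initialization), and `synergy_report()` summarizes departures from the
fitted null: per-cell residuals, the mean signed residual with a seeded
sign-flip randomization p-value (1000 draws; a positional shuffle of
residuals cannot test the mean, which it leaves unchanged), the largest
residual cell, and the CI map.

When a combination block is assembled from raw well scores
(`as_combination_matrix()`), fractions are normalized with $B$ from the
control wells and $A$ from the block maximum. Because the observed maximum
sits below the true asymptote, normalized fractions are slightly inflated;
on noiseless synthetic surfaces this biases recovered $D_m$ by a few
percent. It is the price of normalizing without an independent estimate of
the saturating score.

## The synthetic-data generator

All tests and calibration runs use generated data with known ground truth,
at two levels.

**Feature level.** `feature_sim_spec()` defines a multivariate normal
control population with covariance $LL^\top + \mathrm{diag}(\psi)$ — low-rank
loading factors plus independent noise, positive semi-definite by
construction, imitating the correlated attribute families of real data
(size with total intensities; staining level; fiber content). Treated
populations at dose $D$ shift the chosen effect attributes by
`max_shift` (in control-SD units) times $f(D) = 1/(1+(d_m/D)^{s})$ — the
same functional form the fitter assumes, so recovery studies are
well-specified. The packaged default (`default_feature_spec()`) is a
16-attribute population at the synthetic image scale whose treatment
emulates a microtubule-depolymerizing drug (tubulin intensities and fiber
length fall by 2–3 SD at saturation, nuclear DNA content rises by 1.5 SD)
with $d_m = 0.3$ on the micromolar scale and $s = 1.5$. Optional
multiplicative lognormal well-level noise (sd 0.05 by default in
`simulate_score_curve()`) supports robustness studies. Per-well seeds are
derived deterministically by hashing (experiment seed, plate, well), so
duplicates are distinct draws from identical distributions and entire
plates are reproducible from one integer.

**Image level.** `render_synthetic_field()` draws non-overlapping elliptical
cells (eccentricity up to 0.8, so the long-axis attribute has non-trivial
truth) with concentric bright nucleus disks and random line-segment fibers,
plus Gaussian pixel noise, and returns exact label masks, per-cell areas,
axis lengths, fiber lengths and noiseless channel intensities. What it does
*not* emulate: optics (no PSF), uneven illumination, overlapping or
touching cells beyond abutting islands, cell-cycle heterogeneity, or
realistic fiber curvature. Green tests on these fields therefore establish
correctness of the measurement chain, not segmentation performance on real
micrographs.

## Segmentation and feature extraction

The segmentation strategy follows the field's standard recipe and is
deliberately replaceable:

* **Nuclei**: Gaussian smoothing ($\sigma = 2$ px), global Otsu threshold,
  hole filling, distance-transform watershed to split touching nuclei, area
  filter (defaults 50–5000 px² at the synthetic scale). Because Otsu always
  splits a histogram, a guard requires the threshold to clear the
  background mode by three noise MADs — a fluorescence-free field returns
  an empty mask rather than noise blobs.
* **Cells**: nucleus-seeded propagation (`EBImage::propagate`) over an
  above-background foreground mask of the cytoplasmic channel, giving
  exactly one region per retained nucleus, each containing its seed. The
  foreground threshold uses light smoothing ($\sigma = 1$): heavier
  smoothing biases the global threshold when bright fibers add a third
  intensity mode, eroding small cells. Nuclei falling mostly outside the
  foreground are flagged, never silently dropped.
* **Fibers**: white top-hat enhancement (disc diameter 7 px), robust
  threshold at median + 3 MAD of the in-cell response, floored at 30% of
  its 99th percentile — a plain mean + k·SD rule fails on fiber-dense cells,
  where fibers dominate the response distribution and push the threshold
  above the single-fiber plateau. The thresholded mask is skeletonized
  (Zhang–Suen thinning) and measured as link length (diagonal steps
  $\sqrt 2$) with a +1 px correction per skeleton endpoint for the pixel
  thinning erodes at each fiber end.
* **Background** per channel and field is the median intensity outside all
  cells (robust to dim halos); `_Bck` attributes subtract it. Tubulin
  texture is the within-cell coefficient of variation — an acknowledged
  approximation, as texture is underdetermined by name alone.

## Problem sizes, tolerances, known limitations

The packaged calibration studies use sizes chosen to make their statistical
assertions sharp while remaining desk-scale: chi-square calibration on
5000 control cells of the 16-attribute default spec (KS test against
$\chi^2_d$); oracle equivalence of the PCA-route distance against the
direct inverse-covariance form on 100 random full-rank 8-attribute
populations (agreement to $10^{-8}$ relative; observed $\sim 10^{-14}$);
100-seed noisy median-effect recovery (median $|\hat D_m/D_m - 1|$
$\approx$ 8–9% at 5% multiplicative noise on a ten-point 3-fold series);
contribution ranking with a planted 4-SD shift (top-ranked in $\ge 95\%$ of
200 trials); and imaging on rendered fields of 6 cells at 2% noise (exact
counts, areas and intensities within 5%). `scripts/acceptance.R` recomputes
all of these from scratch.

Known limitations: per-plate control pooling only (no cross-plate
normalization or plate-effect correction); the attribute registry covers
the 16 attributes named above and is extensible but not exhaustive;
`Norm.Contr.Maha`-style contribution values from other software are not
comparable to this package's decomposition, whose normalization is
documented above; the Loewe solver rejects degenerate parameter sets
(non-positive $D_m$ or $s$) rather than extrapolating; and the synthetic
image fields are a correctness instrument, not a realism benchmark.
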