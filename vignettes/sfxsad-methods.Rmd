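---
title: "Treating serial-crystallography still data for SAD phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treating serial-crystallography still data for SAD phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfxsad)
```

## The problem

Serial femtosecond crystallography (SFX) records one still diffraction
pattern per microcrystal.  Every observation is partial (no rotation
during the femtosecond exposure) and every shot differs in crystal size
and quality, pulse energy and spectrum, so integrated intensities
fluctuate strongly from image to image.  Monte Carlo merging — averaging
many observations of each unique reflection — converges on accurate
structure-factor amplitudes, but single-wavelength anomalous diffraction
(SAD) phasing from endogenous sulfur asks for Bijvoet differences of
only 1–2% of the intensity, which systematic errors swamp unless they
are treated explicitly.  This package implements that treatment chain on
synthetic still data with a recoverable ground truth: detector geometry
diagnostics and refinement, two-pass per-image scaling, half-dataset
quality metrics, correlation-based image selection, anomalous difference
Patterson/Fourier analysis, and consensus filtering of substructure
solutions.

## The synthetic model

`build_ground_truth()` draws protein background amplitudes from Wilson
statistics (complex Gaussian for acentrics; real Gaussian with the
symmetry-imposed phase restriction for centrics) and adds an anomalous
substructure with resolution-independent scattering factors
$f_0 + f' + i f''$, summed over the symmetry-expanded sites.  Bijvoet
differences therefore arise only from $f''$, centrics carry none by
construction, and a brute-force structure-factor sum is an exact oracle.
Form-factor falloff and B-factors are deliberately omitted: the
procedures under test are intensity-statistical, and a resolution-flat
model keeps every oracle closed-form.

Defaults emulate the native-sulfur regime of a thaumatin-like
P4~1~2~1~2 crystal (a = b = 58.6 Å, c = 151.3 Å): 17 sites
(16 cysteines, one methionine), $f'' = 0.7\,e$ (sulfur near 6 keV), and
a protein background scale of 650 e chosen so that the Bijvoet ratio
$\langle|\Delta F|\rangle/\langle F\rangle$ sits near 1.5%.

`simulate_images()` models the fluctuation structure of still data:

* per-image multiplicative scale, log-normal with log-sd `scale_sigma`
  (default 0.3) — the shot-to-shot distribution is not constrained by
  published data, so the family and width are declared modelling
  choices;
* partiality as an i.i.d. uniform multiplier on (`p_min`, 1), not a
  rocking-curve model: merging relies only on convergence of the mean,
  which a bounded multiplier exercises fully;
* counting noise Normal(0, `noise_gain`·sqrt(max(I, 1))); negative
  observations are kept, as real merging keeps them;
* detector-distance drift between runs through the proportional
  surrogate *apparent cell = true cell × assumed/true distance*, plus a
  small per-axis indexing jitter (relative sd `5e-4`, matching the
  few-hundredths-of-an-Ångström widths seen in indexed-cell histograms);
* random per-tile rigid offsets for the metrology module.

What the simulator does **not** contain: pixel-level spot profiles,
resolution-dependent signal decay, misindexing, spectral bandwidth, or
correlated (beam-drift) noise.  Passing tests therefore demonstrate that
the procedures are correct and self-consistent under the declared error
model, not that they are sufficient for any particular real detector.

## Geometry refinement

Multimodal unit-cell histograms are the fingerprint of a
sample-to-detector distance that changed between portions of a data set.
`fit_cell_mixture()` (EM with BIC selection, capped at three components)
quantifies the modality; `detect_run_changepoint()` tabulates, per run,
the fraction of images whose axis exceeds a threshold and reports where
the majority flips, localizing the change to a run boundary.

`refine_distance()` scans candidate distances with a coarse step of
100 µm and a fine step of 20 µm, rescaling every apparent cell length by
D/assumed.  Under the proportional surrogate a common rescaling leaves a
single group's coefficient of variation unchanged, so the objective is
anchored: the pooled deviation of the rescaled lengths from a
*reference cell*, each axis standardized by its reference length so the
long axis does not dominate.  With a known target cell (the usual
situation for a known crystal form) the true distance is recovered
exactly up to the fine-step grid; without one, the per-axis median is
used and the scan correctly returns the initial distance.  This anchor
is the package's resolution of an identifiability gap in a pure
"minimize the spread" objective; it reproduces the intended acceptance
picture (post-refinement pooled cells select a one-component mixture).

`refine_tiles()` is closed-form 2-D rigid registration per tile
(centroid subtraction, 2×2 cross-covariance, rotation from its polar
decomposition).  The least-squares optimum can never be worse than the
identity, so the residual RMS never increases.

## Scaling and merging

Merging is plain Monte Carlo: the unweighted mean per unique reflection
(per Bijvoet class when anomalous), sigma as the standard error of the
mean, and half-sets assigned by parity of a seeded shuffle of image ids
— deterministic yet independent of acquisition order.  The two-pass
scheme merges everything unscaled (Friedel mates together, so the scales
are not biased by the anomalous signal), derives per-image scales
against that reference, renormalizes them to geometric mean 1, and
re-merges the scaled observations with Bijvoet classes separate.

The per-image scale uses the sum-ratio form
$s = \sum I_{\mathrm{ref}} / \sum I_{\mathrm{obs}}$ over the reflections
an image shares with the reference.  A mean-of-ratios alternative is
available behind `form = "ratio_mean"`; the sum-ratio is the default
because it is the form implied by defining one reference sum and one
observed sum per image, and it is robust to weak denominators.  One
derivation pass is the default; each extra `n_iter` pass re-derives the
scales against the updated reference and removes most of the residual
contamination of the reference by the scale mix (two passes reduce the
residual scale spread by roughly an order of magnitude on clean data).

Outlier rejection is a documented z-score rule rather than a Wilson-plot
procedure: observations scatter about the Monte Carlo mean far beyond
their counting sigma because of partiality, so the effective sigma is
$\sqrt{\sigma^2 + (\kappa I_{\mathrm{merged}})^2}$ with $\kappa$ the MAD
of the relative residuals, and observations beyond `z_max = 4` effective
sigmas are dropped.  A gross spike is caught; the bounded partiality
scatter of clean data is not.

Image selection keeps images whose Pearson correlation to the merged
reference reaches `cc_min`, the correlation-threshold device used to
build "high-quality" subsets.

## Quality metrics

`r_split()`, `cc_half_and_star()` and `anomalous_stats()` implement the
standard half-dataset statistics
($R_{\mathrm{split}} = 2^{-1/2}\sum|I_1-I_2| / \tfrac12\sum(I_1+I_2)$,
CC~1/2~, $CC^* = \sqrt{2CC_{1/2}/(1+CC_{1/2})}$, $R_{\mathrm{ano}}$ over
complete Bijvoet pairs, CC~ano~ as the half-set correlation of
$\Delta I$).  Shells hold equal numbers of observed unique reflections
(the binning rule is not standardized elsewhere; equal-count is the
documented default), completeness counts distinct asymmetric-unit
reflections against the theoretical set (Bijvoet mates separately when
anomalous), reflections present in only one half are excluded from
paired metrics but counted in completeness, and undefined metrics are
emitted as NA, never zero.  The overall row is pooled, not a mean of
shells.

## Anomalous difference maps

Amplitudes come from square-root truncation ($F = \sqrt{\max(I, 0)}$) —
a documented simplification in place of a Bayesian intensity-to-amplitude
treatment.  Maps are direct cosine summations over the
symmetry-expanded reflection set: at desk-scale reflection counts this
is exact, dependency-free, and directly testable against a per-point
oracle.  Patterson coefficients $\Delta F^2$ are translation-invariant,
so expansion leaves their phase zero and the map is centrosymmetric to
machine precision.  The difference Fourier uses the *signed* Bijvoet
difference with phase $\varphi_{\mathrm{calc}} - 90^\circ$
(structure-factor phases transform as
$\varphi(hR) = \varphi(h) - 2\pi h\cdot t$ under expansion); the sign
convention is validated by the property that true sites are positive
maxima.  Maps are normalized to zero mean and unit RMS so `s_ano()`
reads in sigma units; `map_correlation()` is plain Pearson over grid
values.

## Substructure consensus

Solutions from a dual-space solver are defined only up to an allowed
origin shift, hand inversion (with the enantiomorph switch) and
per-site symmetry images.  Allowed shifts are found by brute-force
normalizer search over a quarter-fraction grid — self-verifying, and
trivially extensible.  `align_solution()` searches shifts × hand with
symmetry-aware site matching; a global symmetry operator is deliberately
absent from the search because per-site symmetry expansion absorbs it.
Because a site list alone does not reveal which enantiomorph convention
it is written in, `consensus_filter()` tries both interpretations of the
reference solution and keeps the one the remaining solutions match
better.  Pooled sites are clustered by single linkage at `tol` (default
1.5 Å, appropriate at ~2 Å data; no published tolerance exists, so it
is a parameter), votes count distinct supporting solutions, cluster
positions are occupancy-weighted means, and a cluster is flagged
disulfide if any contributor flagged it.

`occupancy_cutoff()` places the cut at the largest relative occupancy
gap past `min_keep`; occupancy does not weight the voting (a documented
choice — recurrence, not refinement detail, is the filter).
`expand_disulfide()` splits a superatom into two half-occupancy sites
2.05 Å apart along the a axis; superatoms carry no orientation, so the
axis is necessarily a convention.

## Numerical and design notes

* Operator translations are stored as integer twelfths; composition and
  closure are exact.
* The unique-reflection representative is the lexicographically greatest
  index over all rotation images and Friedel mates — any self-consistent
  convention works, and this one is deterministic and order-free.
* Distance scans break objective ties toward the initial distance, so a
  flat objective is a no-op.
* Minimum-image distances are computed per axis, exact for the
  orthogonal cells this package targets.
* Degenerate inputs are handled explicitly: constant cell samples return
  a one-component fit with a sigma floor; flat (null-signal) difference
  Fouriers are left at zero rather than normalized; images with
  non-positive intensity sums or too few common reflections are flagged
  unusable rather than scaled.

## Problem sizes

The shipped tests and examples run on a 20 × 20 × 30 Å toy tetragonal
cell (a few hundred unique reflections) with hundreds to a few thousand
images, and on the thaumatin-like cell at low resolution for geometry
work — sizes chosen so that every stage, including direct-summation
maps, completes in seconds while exercising the same code paths as a
full-size data set.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(cell = tetragonal_cell(20, 30), d_min = 2.8,
                       n_sites = 3, f_double_prime = 1.5, tol = 0.8,
                       protein_scale = 150, n_images = 400, seed = 1)
res <- run_pipeline(cfg, "sfxsad_out")
res$shells          # resolution-shelled R_split / CC1/2 / CC_ano table
res$log$s_ano_truth_sites   # anomalous peak height at the true sites
```

## Known limitations

* Only P1 and the P4~1~2~1~2 / P4~3~2~1~2 pair are supported; the
  machinery (generator closure, brute-force normalizer) extends to other
  groups but none are tabulated.
* The proportional distance–cell surrogate isolates the geometry logic
  but does not model re-indexing effects; absolute distances are only
  identifiable against a reference cell.
* No post-refinement or partiality modelling: partiality is averaged
  out, never estimated.
* Consensus assumes all solutions share one declared space group (up to
  hand); mixed-indexing-ambiguity inputs are out of scope.
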