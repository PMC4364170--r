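---
title: "Methods: models, parameters, and design choices in cbfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in cbfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbfc)
```

# Overview

`cbfc` implements a seed-based resting-state functional-connectivity
(FC) pipeline for the cerebellum: cortical network seeds are built from
a 17-network parcellation, each subject's BOLD series is conditioned
and regressed voxelwise on the seed time course with nuisance
covariates, group contrasts are cluster-corrected by permutation, the
resulting maps are scored against a canonical cerebellar parcellation,
and cluster connectivity is correlated with symptom scales. A
synthetic-cohort generator provides ground truth for all of it. This
vignette records the models, the parameters that matter, and the design
decisions taken where the design was genuinely open.

# The generative model behind the synthetic cohorts

Each network $k$ has a latent time course $L_k$: Gaussian white noise
band-passed to 0.01–0.08 Hz and standardized to unit variance. The
band-limiting is deliberate — planted connectivity must live inside the
band the analysis retains, otherwise the pipeline's own filters would
destroy the ground truth the tests rely on. A voxel $v$ in the cortical
or cerebellar territory of network $k$ evolves as

$$ y_v(t) = c_{k,s} \, L_k(t) + \varepsilon_v(t) + d_v(t) + g(t) + 100, $$

with, per subject $s$:

* $c_{k,s}$ — the subject's true coupling: the group value
  (`coupling_hc` / `coupling_sz`, dimensionless in $[0,1]$) plus
  Gaussian between-subject jitter (`coupling_jitter_sd`, default 0.05,
  truncated to $[0,1]$). The jitter gives the group stage genuine
  between-subject variance and gives the symptom model a coupling
  deviation to act on.
* $\varepsilon_v$ — stationary AR(1) noise with autocorrelation
  `ar1_phi` (default 0.3) and innovation SD `noise_sd` (default 1, in
  the same arbitrary BOLD units as the couplings); marginal variance
  $\sigma^2/(1-\phi^2)$.
* $d_v$ — scanner drift: a linear ramp plus a 0.005 Hz cosine, each
  scaled by `drift_amp` (default 3) and by an independent standard
  normal amplitude *per voxel*. Drift is spatially varying by design: a
  perfectly global drift component shared by seed voxels, nuisance
  compartments, and target voxels alike is a rank-one confound that no
  regression can attribute, and it is also not what scanners produce.
* $g$ — a global "cardiac" sinusoid at `cardio_freq_hz` (default
  0.15 Hz, below the 0.2 Hz Nyquist at TR 2.5 s) with amplitude
  `cardio_amp`; the low-pass filter is expected to remove it.

White-matter and CSF compartments additionally carry their own slow
latent series, which is what makes the WM/CSF nuisance regressors
informative. Head motion is a six-parameter random walk (step SDs
`motion_sd_mm` = 0.15 mm, `motion_sd_deg` = 0.1°); those defaults put
the Jenkinson mean absolute displacement near 0.3 mm, the scale
reported for typical compliant clinical cohorts. Motion is generated as
a nuisance trace only — the images are simulated already aligned,
because registration of real EPI is out of scope.

Symptom scores are `mean + slope × (coupling deviation) + noise`,
truncated at zero, with scale means and SDs at values typical of a
chronic psychosis sample (SAPS 35.8 ± 19.1, SANS 23.5 ± 15.9, YMRS
14.7 ± 8.0, MADRS 14.4 ± 9.3, PSYRATS-AH 12.7 ± 14.3). The default
slope is 0, making symptom–FC correlations null by construction;
positive-control tests use slope 150 with scale noise 5. Scores exist
for patients only, and a `missing_rate` (default 0.15) knocks out
entries to emulate real missingness. Chlorpromazine equivalents are
lognormal with mean ≈ 580 mg for patients and 0 for controls.

The atlas is geometric, not anatomical: cortex, cerebellum, WM and CSF
occupy disjoint fractional boxes of the grid, and territories are grown
as compact blobs around lattice-spaced centers. Overlap metrics and
cluster inference need geometry (compactness, adjacency,
disjointness), not anatomy. Default grid: 30×30×20 voxels at 3 mm
isotropic (near the 3.5 mm of typical EPI), TR 2.5 s, 240 volumes,
12 subjects per group, ten networks with cortical/cerebellar
territories of 80/60 voxels.

What the generator does *not* emulate — hemodynamic response shape,
spatial autocorrelation of physiological noise, registration error,
partial-volume effects, site/scanner heterogeneity beyond a binary
flag — bounds what passing tests show: they validate the statistical
machinery (calibration, recovery, bookkeeping), not robustness to every
artifact of real scans.

# Seed construction

The seed recipe follows the standard reduction of the 17-network
parcellation: nearest-neighbour resampling (labels are categorical and
must never be averaged; the nearest source voxel center is found by
rounding the continuous source index, exact for the axis-aligned
affines used here), splitting into per-network masks, merging networks
9 and 10 into a single limbic seed, excluding the six networks with
≤ 30 cerebellar voxels, and eroding each survivor by one voxel layer.

"A 3D kernel" for erosion is read as the full 3×3×3 structuring
element (a voxel survives only if all 26 neighbours are present) —
the maximally conservative reading consistent with guarding against
boundary contamination; the 6-connectivity cross is available via
`connectivity = 6`. Erosion is applied after resampling, matching the
order resample → segment → erode. Voxel indices are 0-based in the
affine convention; world coordinates come from the 4×4 voxel-to-world
matrix.

# Subject-level conditioning

* First 4 volumes discarded (magnet stabilization), motion rows
  trimmed identically.
* Spatial smoothing: separable Gaussian, $\sigma_{mm} =
  \mathrm{FWHM}/(2\sqrt{2\ln 2})$ with FWHM 6 mm, reflective boundaries
  (constants and volume totals preserved).
* Temporal band-pass: Gaussian-weighted running-line filters in the
  "sigma in volumes" convention, $\sigma = 1/(2 f \, TR)$: high-pass at
  0.009 Hz ($\sigma = 22.2$ volumes) subtracts the running mean,
  low-pass at 0.08 Hz ($\sigma = 2.5$ volumes) smooths what remains.
  Note the two printed sigma values pair with the cutoffs exactly this
  way around — the formula admits only one consistent assignment, and
  `filter_spec()` applies it. Edge weights are renormalized truncated
  Gaussians, so constants map to numerical zero everywhere including
  the boundaries. The operator is linear; its amplitude response is the
  product $(1 - e^{-2\pi^2 f^2 \sigma_{hp,t}^2})\, e^{-2\pi^2 f^2
  \sigma_{lp,t}^2}$ (σ in seconds), which the tests verify empirically
  across 0.005–0.19 Hz. A Gaussian low-pass rolls off gently: gain at
  the nominal 0.08 Hz cutoff is far below ½, and full (> 0.8)
  transmission holds only below ≈ 0.015 Hz. This is a property of the
  sigma-parameterized filter family itself, worth knowing when
  interpreting "the 0.01–0.08 Hz band".
* Motion QC: Jenkinson mean absolute displacement. For consecutive
  volumes with rigid transforms $M_i$, the relative transform
  $M_i M_{i-1}^{-1} = \begin{pmatrix} A+I & b \\ 0 & 1 \end{pmatrix}$
  gives RMS displacement $\sqrt{R^2 \mathrm{tr}(A^\top A)/5 + b^\top b}$
  over a solid sphere of radius $R = 80$ mm. Only relative motion
  counts; composing all transforms with a fixed rigid offset cancels.

Smoothing precedes filtering; both precede time-course extraction.
Because the filters are linear, filtering an extracted mean equals the
mean of filtered voxels, and the implementation exploits this by
filtering the cerebellar voxel matrix and the extracted seed/WM/CSF
time courses in one operation.

# First level

Each cerebellar voxel is regressed by OLS on
[seed, WM, CSF, 6 motion, intercept], all non-intercept columns
mean-centered, design rank-checked with collinear columns named in the
error. The seed t statistic (residual dof = timepoints − 10) is mapped
to z by the quantile transform $z = \Phi^{-1}(F_t(t))$, computed in the
log-tail for numerical stability, monotone and sign-preserving, with
$|z|$ clamped at 38 (beyond double-precision tail resolution) under a
warning. Zero-variance voxels get t = 0 and a degenerate flag.

No prewhitening is applied: the band-pass has already colored the
noise, so first-level dof are nominal rather than effective; validity
of the group inference rests on the permutation scheme, not on
first-level variance estimates. z maps (not betas) are passed to the
group stage; betas are retained for inspection.

# Group inference

The group design has one row per subject: group indicator, age, sex,
scanner-upgrade flag, optionally chlorpromazine equivalents (the
primary analysis includes them, the medication-sensitivity analysis
drops them), covariates mean-centered, plus intercept. Contrasts SZ>HC
and HC>SZ are run as separate one-sided analyses with voxel threshold
$z \ge \Phi^{-1}(0.99)$ (p < 0.01) and 26-connectivity clusters
(6 available), sizes tie-broken by peak statistic.

Cluster-extent correction uses Freedman–Lane permutation: fit the
reduced model (design without the contrast column), permute its
residual rows, add them back to the reduced fit, re-fit the full model,
and record the maximum suprathreshold cluster size. The corrected
p-value $(1 + \#\{\text{perm max} \ge s\})/(n_{perm}+1)$ is valid and
slightly conservative; with no covariates the scheme reduces to plain
group-label permutation (verified against exhaustive enumeration on
3 vs 3). `n_perm` defaults to 1000 with a hard floor of 20 and a
required seed; `exhaustive = TRUE` enumerates all assignments for
small covariate-free designs. This permutation scheme replaces
Bayesian mixed-effects estimation deliberately: it is self-contained,
assumption-light, and its calibration is itself testable, while the
voxel p < 0.01 / cluster p < 0.05 thresholds are kept verbatim.

Within-group maps are one-sample t tests across subjects' z maps with
a one-sided p map; voxels with zero between-subject variance are
flagged degenerate with statistic 0.

# Map overlap

Metrics are computed per network against the single-network canonical
mask. With P the canonical-map voxels, N the remaining cerebellar
voxels, TP the group∩canonical voxels, and FP the group voxels outside
the canonical map (group voxels outside the cerebellum are ignored):
accuracy = (TP+TN)/(P+N), sensitivity = TP/P, specificity = TN/N.
Group maps are binarized at one-sided p < 0.05 uncorrected — the
display-map convention — and that choice is configurable
(`binarize_map(alpha = ...)`). Dice is reported as an auxiliary
metric. `winner_take_all` assigns each voxel to the network with the
maximal statistic, ties to the lowest id with a tie counter; it is
used to build canonical-style references and describe map structure,
never re-fed into inference.

On synthetic cohorts the within-group maps recover the planted atlas
with high accuracy driven by specificity, while sensitivity is
essentially 1 — cleaner than real data, where sensitivity of
group-mean maps against an independent canonical atlas is typically
low. That asymmetry is a known limitation of the generator's idealized
territories, not of the metric code.

# Symptom correlations

For each contrast with significant clusters, the clusters are combined,
the mean preprocessed time course of the union is correlated (Pearson)
with the seed time course per subject, and the patients' values are
correlated with the five scales. Cells use pairwise-complete
observations (n recorded per cell; fewer than 3 pairs marks the cell
not computable), two-sided p-values, and Bonferroni control at
$\alpha/m$ with $m$ = scales × contrasts (35 for the 5×7 matrix; exact
0.05/35 ≈ 0.00143 by default, the rounded 0.001 via
`rounded = TRUE`). The per-subject cluster FC is computed on the
same preprocessed series as the first level — the defensible reading,
since the clusters were defined on statistics of exactly that series.

# Numerical choices and degenerate inputs

* Erosion at grid boundaries treats out-of-grid voxels as background.
* Nearest-neighbour resampling returns background for target voxels
  mapping outside the source grid; non-invertible affines error.
* Perfect-fit voxels (zero residual, nonzero beta) map to infinite t
  and are clamped at z = ±38 with a warning; zero-variance series get
  statistic 0 and a flag at both levels.
* Permutation p-values can never be 0 by construction; equal-size
  clusters are ordered by peak statistic.
* The AR(1) generator draws its first sample from the stationary
  marginal, so no burn-in bias enters variance bookkeeping.
* Subject seeds derive deterministically from the master seed and the
  subject index (kept below $2^{31}$), making cohorts reproducible
  file-for-file.

# Problem sizes used by the test suite

The suite exercises the full chain at reduced scale, chosen once as
the smallest sizes at which each property is meaningfully testable:
calibration uses 200 null cohorts of 8 vs 8 subjects on a 20×20×12
grid (3 mm voxels), 120 volumes, 200 permutations, one seed and one
directional contrast per cohort — measuring the per-analysis
family-wise rate, expected near 0.05. Recovery uses 20 replicates of
20 vs 20 subjects at the full 240-volume acquisition length, four
networks with coupling 0.6 in controls and 0.3 in patients for one
network, 500 permutations, requiring a significant HC>SZ cluster with
Dice ≥ 0.5 against the planted territory and quiet unplanted networks.
The full series length matters for the specificity half: band-limited
latents at 120 volumes carry only ≈ 20 effective in-band degrees of
freedom, so chance cross-network sample correlations are large enough
to push the unplanted-network flag rate toward the bound. Map fidelity runs the default 12-per-group,
ten-network cohort and requires accuracy ≥ 0.85 for every network and
group. Reduced grids keep territories proportionally larger
(cortical 150 voxels) so eroded seeds stay non-trivial.

# Known limitations

* OLS with homoskedastic errors at both levels; heavy-tailed or
  heteroskedastic subjects are handled only through the permutation
  null, not modeled.
* The generator's latent time courses are band-limited white noise; at
  120 volumes two independent networks show sample correlations of
  ±0.2 routinely (≈ 20 effective in-band dof), so cross-network
  leakage into first-level maps is real and the group stage must - and
  does - absorb it. Short real acquisitions share this property.
* Chlorpromazine dose is nearly group-separating (0 for all controls),
  so including it as a covariate costs power on the group contrast;
  the medication-free variant (`include_cpz = FALSE`) quantifies that.
* Symptom scores are generated, and analyzed, for patients only.
* No surface geometry, no multi-site harmonization, no hemodynamic
  response modeling.
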