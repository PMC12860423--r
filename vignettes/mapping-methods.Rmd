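---
title: "Dual-arm statistical mapping under resampling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-arm statistical mapping under resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sammri)
```

This vignette is the package's own account of its methods: the statistical
models in both mapping arms, the generative model behind the synthetic
cohorts, the parameters that matter and their defaults, the numerical
choices, and the limits of what the test suite can show about real data.

## The two mapping arms

### The region-level agnostic statistic

The region-level arm treats group inference as a learning problem. For a
region with voxel matrix $X$ (subjects $\times$ voxels) and labels
$y \in \{-1, +1\}$ (controls vs cases):

1. **Voxel selection.** Each voxel is scored with a two-sample Welch $t$;
   the $k = 50$ voxels with the largest $|t|$ are kept (all voxels if the
   region is smaller). Welch rather than pooled variance because group
   variances routinely differ in multi-site data; ties break by ascending
   voxel index so results are reproducible bit-for-bit.
2. **Feature extraction.** One partial-least-squares dimension:
   the weight vector is the normalized cross-covariance
   $w \propto X_c^\top y$ of the column-centered matrix, scores are
   $s = X_c w$. Additional components, if requested, follow NIPALS
   deflation.
3. **Classifier and empirical accuracy.** A linear soft-margin SVM
   ($C = 1$, features standardized) is trained and evaluated on the same
   sample; its resubstitution ("replacement") accuracy is the empirical
   accuracy. No cross-validation is used by design: the correction for
   optimism is analytic, not empirical.
4. **Worst-case correction.** The true accuracy is lower-bounded with
   probability $1 - \alpha$ by $acc_{wc} = acc_{emp} - \Delta(n, \alpha)$,
   where $n$ counts all subjects in the comparison.
5. **Decision.** $z = (acc_{wc} - 0.5) / \sqrt{0.25 / n}$, significant when
   $z > \Phi^{-1}(1 - \alpha)$. The test is one-sided: accuracy below
   chance is not evidence of a group difference under this framing.

**Choice of concentration bound.** Two families are implemented. The plain
two-sided Hoeffding test-set bound, $\Delta = \sqrt{\ln(2/\alpha)/(2n)}$,
is the canonical distribution-free bound *for an accuracy measured on data
the classifier never saw*. Resubstitution accuracy after selecting the best
50 of a few hundred voxels is not such a quantity: under a true null at
$n = 200$ the pipeline's resubstitution accuracy sits around 0.79, an
optimism of about 0.3 that the Hoeffding $\Delta \approx 0.096$ cannot
absorb — with it, every region of a null cohort is declared significant.
The default is therefore a Vapnik-style bound that charges for the capacity
of the fitted rule, $\Delta = \sqrt{(h(\ln(2n/h) + 1) + \ln(4/\alpha))/n}$
with VC dimension $h = 2$ (a linear rule in the one-dimensional score
space), $\Delta \approx 0.29$ at $n = 200$. With it, null cohorts produce
sparse flags concentrated in the largest regions — which is also the
qualitative behaviour expected of this statistic on real multi-site data —
while strongly affected regions remain far above threshold. The bound
family is a config option (`bound = "vapnik"` or `"hoeffding"`) and is
recorded in the output attributes.

Known consequence, stated plainly: even with the capacity term, the
selection step is not fully paid for, so the per-region null flag rate
grows with region size (more candidate voxels, more selection optimism) and
with $n$ (the bound shrinks faster than the optimism). The control-control
design exists precisely to measure this residual rate rather than assume it
away.

### The voxelwise parametric arm

The parametric arm is the two-group special case of the mass-univariate
GLM: per-voxel pooled-variance two-sample $t$ with $df = n_1 + n_2 - 2$,
contrasts $+1/-1$ selecting the tested direction. Before testing, each map
is smoothed with an axis-separable Gaussian (default 8 mm FWHM at 2 mm
voxels, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ voxels per axis).

Cluster-level inference replaces random-field theory with a permutation
null: threshold the one-sided $t$-map at the Student quantile for the
cluster-forming $p$ (default 0.001; 0.05 available as an exploratory
preset), form connected components (26-connectivity by default, 6/18
config-exposed), and compare each observed cluster's size with the null
distribution of the *maximum* cluster size over group-label permutations of
the identical pipeline: $p_{corr} = (1 + \#\{\max_{null} \ge size\})/
(n_{perm} + 1)$. The permutation null is exact under exchangeability of
group labels, requires no smoothness estimation, and controls family-wise
error by construction of the max statistic. Smoothing does not depend on
labels, so it is applied once per subject, never per permutation.

Numerical details: voxels with zero pooled variance get $t = 0$ so flat
background can never seed clusters; the smoothing kernel is truncated at
$4\sigma$ and row-renormalized (constants are preserved exactly; an
interior impulse integrates to 1 up to the $\sim 6\times10^{-5}$ truncated
tail per axis); inside a brain mask the kernel is renormalized over the
mask ($S(vm)/S(m)$), avoiding the edge attenuation that zero-padding
produces exactly where registration artifacts concentrate.

## The resampling engine

Each experiment repeats `n_iterations` times: draw a subsample, run one
mapping arm, record which regions it flags. The per-region flag frequency
is the probability of detection (PD) under the case-control design and the
false-positive (FP) rate under the control-control design, where any
detection is false by construction. Two designs × two arms give the four
surfaces a study compares.

Two distinct uses of "permutation" are implemented explicitly, because
frequencies and p-values answer different questions: the *outer* loop
resamples subjects (without replacement within an iteration, independently
across iterations) to estimate PD/FP; the *inner* loop shuffles group
labels within one label-faithful draw to compute a permutation p-value per
region, $p = (\#\{T_\pi \ge T\} + 1)/(M + 1)$, with ties counted in the
numerator so the test is valid at any $M$. The statistic $T$ is the
worst-case accuracy for the region arm and the largest
supra-threshold-cluster size touching the region for the voxelwise arm. A
third arm, `"ttest"`, runs a calibrated two-sample test on region-mean GM —
exact level $\alpha$ per region under the null — and serves as the
yardstick: with 1000 null iterations at $\alpha = 0.05$ it flags each
region about 50 times, which is the chance band against which the mapping
arms' counts are read. `pvalue_table()` applies that band (strictly more
than $\alpha R$ flags) when deciding which regions are worth listing.

Subsample sizes follow group-wise fraction rules: pooled over all sites,
one fifth of each group (about 100 per group for a ~500-per-group cohort);
within a single site, one third of each of the site's groups, so a
100-control/75-case site yields 33 + 25 per draw. The control-control
design draws two *disjoint* control subsets. Iterations that cannot be
completed (a site too small to subsample) are counted and reported as
failures, not raised: failed iterations are data about the design, not
bugs. An optional `p_per_iteration` mode also evaluates the inner p-value
in every outer iteration and reports the across-iteration mean alongside
the single-draw p-value; both are labelled, since which of the two a study
reports is a genuine reporting choice.

All randomness in an experiment derives from the config seed; identical
configs reproduce PD/FP maps bit-for-bit.

## The synthetic cohort generator

The generator emulates the statistical structure of a multi-site GM-map
cohort, not its anatomy:

* **Parcellation** — Voronoi cells grown from uniformly random seeds inside
  an ellipsoidal mask (~35% of the grid). Cells are contiguous and their
  sizes naturally heterogeneous (coefficient of variation ≈ 0.4), which is
  what the region-size-versus-power analyses need. Default 116 regions on a
  40×48×40 grid (a desk-scale stand-in for 79×95×79 at 2 mm; both are
  parameters).
* **Baseline** — a smooth radially decaying field from 0.8 at the centre to
  0.2 at the rim, keeping values inside the valid probability range after
  noise.
* **Site effects** — additive scalar intensity offsets per site: the
  simplest structure that reproduces the multi-site heterogeneity concern.
  Per-site noise-variance scaling was considered and left out of the
  default model.
* **Noise** — i.i.d. Gaussian per voxel, `noise_sd = 0.05` GM-probability
  units by default (roughly the within-tissue variability scale of
  segmented GM maps); an optional `noise_smooth_fwhm` smooths the noise
  field to induce spatial correlation, rescaled to keep the marginal sd.
  No claim is made that either matches the spatial covariance of real GM
  maps — that covariance is simply unknown here.
* **Effects** — cases receive `effect_size_d × noise_sd` at every voxel of
  the chosen regions, so `effect_size_d` is per-voxel Cohen's d. Values
  are clipped to [0, 1] after everything is added.
* **Corruption** — a `corruption_rate` fraction of subjects have exactly
  `round(corruption_frac × n_voxels)` voxels shifted by
  `±corruption_magnitude × noise_sd` (default 10), emulating failed
  preprocessing; the injected list is kept as ground truth for QC tests.

What passing tests on these cohorts show: the pipeline's calibration
(level, FWER, p-value validity), its power ordering, and its QC recovery
are correct *under the generative model*. What they cannot show: behaviour
under realistic anatomy, registration error, spatially structured noise, or
site-by-effect interactions — on real data the FP maps must be estimated,
not assumed, which is the point of the control-control design.

## Quality control

For every voxel, each subject's value is standardized against the cohort
(mean and $n-1$ sd across subjects, groups pooled — pooling is the only
choice that does not presuppose the group structure being tested; a
`by_site` flag restricts the reference population to the subject's site). A
subject's flagged fraction is the share of in-mask voxels with $|z| > 5$;
strictly more than 3% flags the subject as suspicious, and exclusion
additionally requires confirmation — modelled as an explicit override list
standing in for visual inspection, defaulting to confirm-all so the
pipeline runs unattended. Zero-variance voxels give $z = 0$ for everyone.

One structural fact worth knowing: with $n$ subjects the largest attainable
$|z|$ is $(n-1)/\sqrt{n}$, so the $|z| > 5$ criterion can only ever fire
for cohorts of at least ~27 subjects; in smaller cohorts the rule is
vacuously clean, which is the conservative direction.

## Problem sizes and numerical conventions

The shipped tests and the calibration script run at desk scale, chosen as
the smallest sizes at which the asserted statistics are stable: a 40×48×40
grid (≈25k in-mask voxels) with 30 or 116 regions; 1000 resampling
iterations for the null-calibration check; 200 null datasets with 199
permutations each for the FWER check (on a 20×24×20 grid in the test
suite); 10 replicate experiments of 20 iterations each for planted-effect
recovery at $d = 1.2$, $n = 100$/group. Defaults in
`resampling_config()` (1000 iterations, 1000 permutations) state the
reference experimental design, not a runtime recommendation.

Other conventions: region ids are consecutive positive integers and region
names unique; subsampling errors name the offending site; `frac = 0`
corruption is the identity; negating a contrast negates the $t$-map
exactly; swapping all group labels leaves $|t|$ rankings, accuracies and
decisions unchanged.

## Known limitations

* The worst-case bound does not fully absorb voxel-selection optimism (see
  above); region-level FP rates under the null grow with region size and
  must be read against the control-control map.
* The soft-margin SVM at $C = 1$ can trade training accuracy for margin; on
  1-D scores its resubstitution accuracy is bounded above by, but not
  always equal to, the best threshold rule (gaps up to ~0.05 at $n = 100$
  with clear separation, larger on small noisy samples).
* No covariate modelling (age/sex regressors), no stratified subsampling,
  no random-field p-values, and no simulation of acquisition, segmentation
  or registration: the package consumes finished GM probability maps.
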