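---
title: "Model-free reliability mapping of multi-run task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free reliability mapping of multi-run task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Clinical task fMRI — presurgical mapping in particular — is usually acquired
as $N$ repetitions ("runs") of a short block paradigm with identical timing.
Model-based analysis (the GLM) assumes the response follows a canonical
hemodynamic response function (HRF) convolved with the task boxcar. Near
pathology, after vasoactive substances, or simply across brain regions, that
assumption fails: responses can be delayed, transient, or negative, and the
GLM then misses activation that is perfectly reproducible.

This package takes the model-free route: **a voxel's "model" is its own time
course in another run**. For voxel $i$ and run pair $(j, k)$, the detrended
time course $s_{i,k}(t)$ is regressed on $s_{i,j}(t)$ by ordinary least
squares with an intercept,

$$s_{i,k}(t) = a + \beta_{i,jk}\, s_{i,j}(t) + \varepsilon(t),
\qquad t_{i,jk} = \beta_{i,jk} / \mathrm{SE}(\beta_{i,jk}),$$

with $T - 2$ residual degrees of freedom. Over all $N(N-1)/2$ non-identical
pairs this gives per-voxel triangular matrices of $\beta$ and $t$. The final
statistic is the **reliability**: the percentage of good run pairs whose $t$
exceeds the upper-tail Student quantile at an uncorrected $p < 0.001$. Any
response shape that repeats across runs — delayed, transient, or negative —
produces positive inter-run slopes and scores exactly like a canonical one.

Three design choices deserve comment:

* **Intercept in the pairwise model.** With an intercept, the pair $t$ equals
  $r\sqrt{T-2}/\sqrt{1-r^2}$ for the inter-run correlation $r$ and is
  symmetric in $(j,k)$, matching the unordered use of the pairs. Detrended
  data are near zero-mean, so the intercept costs essentially nothing.
* **Positive tail only.** Consistent responses of either BOLD sign yield
  positive slopes; a *negative* slope means the voxel behaved inconsistently
  between the two runs, which should not count as reliable.
* **Degeneracies.** Zero-variance time courses give $\beta = t = 0$;
  zero-residual (perfect) fits clamp $|t|$ at $10^6$ so percentiles and
  Welch tests downstream stay finite.

## Automatic exclusion of bad runs

A run degraded by motion, artefacts or absent task performance lowers the
subject-level $t$ values in the activation foci. Each pass of
`detect_bad_runs()`:

1. computes the subject t-map (one-sample $t$ over pair betas) from all
   current good runs;
2. derives an *activation mask*: voxels above the top 1 percentile of
   in-mask $t$, Gaussian-smoothed (FWHM 2 voxels) and re-binarised at 0.5
   (the smoothing keeps compact foci and discards isolated voxels; if it
   empties the set, the unsmoothed percentile set is used and logged);
3. for each candidate run $n$, tests with a one-sided Welch two-sample $t$
   test whether the leave-$n$-out subject t-map *exceeds* the all-runs map
   inside that mask;
4. flags runs with $p < \alpha / n_\mathrm{tested}$ (Bonferroni within the
   pass, $\alpha = 0.05$) and excludes exactly one — by default the flagged
   run with the smallest mean subject-level $t$ computed from only the pairs
   involving it (bad runs show the lowest $t$ in the foci; a `selection =
   "welch"` switch picks the largest Welch statistic instead, and the two
   agree on clear-cut cases).

Passes repeat until nothing is flagged. A leave-one-out subject t-map needs
at least three remaining runs (two or more pairs), so testing requires at
least four current good runs; sessions of two or three runs are analysed
without exclusion and the report says so. The subject-level one-sample test
feeds this step unthresholded — its nominal $p = 0.05$ level plays no
gating role, since the Welch comparison works on the full $t$ maps.

## The reference GLM and fit comparison

`glm_session()` fits each run separately with a single regressor: the task
boxcar convolved with the canonical double-gamma HRF
($g(t;6,1) - g(t;16,1)/6$ on $[0, 32]$ s, peak-normalised, oversampled at
$dt = 0.1$ s before sampling at the volume times) and no derivatives.
Per-run fitting keeps the degrees of freedom comparable with the pairwise
fits, and both routes see identically preprocessed (quadratically
detrended) data, so their goodness of fit can be compared voxelwise:

$$r = \frac{R^2_\mathrm{consistency} - R^2_\mathrm{GLM}}
           {R^2_\mathrm{consistency} + R^2_\mathrm{GLM}} \in [-1, 1],$$

where $R^2_\mathrm{consistency}$ is the mean pairwise $R^2$ over good pairs
(a pooled variant is available via `r2_unbiased(pooled = TRUE)`). Clusters
of $r > 0$ (26-connected, minimum size 10) mark consistent responses the
model does not capture; `roi_mean_timecourse()` extracts 5×5×5-voxel cube
averages for visual inspection of their shape.

One caveat the comparison map user should know: for *model-conform* data
both series of a pair are noisy while the GLM regressor is noiseless, so
$E[R^2_\mathrm{consistency}] \approx \rho^4$ against
$E[R^2_\mathrm{GLM}] \approx \rho^2$ (with $\rho^2$ the per-run
signal-variance fraction), and $r$ in canonical regions sits near
$(\rho^2 - 1)/(\rho^2 + 1) < 0$ at moderate contrast-to-noise, approaching
0 only for strong responses. The comparison is therefore most meaningful in
the high-CNR regime; the packaged experiments use visual-strength (7% peak)
responses when exercising it.

## Preprocessing and shifts

Drift removal subtracts the least-squares quadratic in the volume index
from each voxel's time course, per run (`detrend_poly2()`); it is idempotent
and leaves residuals orthogonal to $\{1, t, t^2\}$. The GLM route reuses the
same detrending rather than a high-pass filter so that the two fits remain
comparable.

`shift_sensitivity()` probes timing robustness by circularly shifting every
run by the same number of volumes (positive shifts move the final volumes
to the front) and re-running both analyses. Shifts are applied to the
*detrended* series: quadratic detrending is not shift-equivariant, and
applying the shift after it makes the pairwise fits see exactly the same
set of $(x_t, y_t)$ points at every shift, so the reliability map is
reproduced *exactly* — the invariance the method promises — while the GLM's
regressor-to-response alignment, and hence its $t$ values, swing strongly.
(Within floating point, sums taken in rotated order can differ in the last
ulp; the reliability map is a quantised pair count and is asserted
bitwise-identical, pair betas to $10^{-10}$.)

## What the synthetic generator emulates

`generate_session()` builds sessions with known ground truth:

* **Designs**: the 20 s ABABABA motor block design (56 volumes, TR 2.5 s)
  and the visuomotor design (10 s task / 20 s rest × 5 after 10 s rest;
  160 volumes, TR 1 s).
* **Signal**: baseline 1000 arbitrary units inside a box-shaped "brain"
  (15% margins in-plane, one-slice margin in z; outside is exactly zero);
  regions respond with canonical, delayed, transient onset/offset, negative
  or absent shapes, scaled to a peak amplitude in percent signal change.
* **Nuisance**: per-run quadratic drift with coefficients drawn from
  $\mathcal N(0, (10, 0.5, 0.01))$ per volume-index power — a few tens of
  units over a run, comparable to the task signal — and white Gaussian
  noise at a target temporal SNR (baseline / noise SD).
* **Bad runs**: listed runs have their task templates zeroed, emulating a
  run in which no task was performed.
* **Reproducibility**: one master seed spawns per-run noise and drift
  streams, so the same seed gives a bitwise-identical session and adding
  regions does not perturb the noise.

Defaults are **4% peak signal change at temporal SNR 70**, chosen once as
typical of strong primary motor/visual activation in 7 T gradient-echo EPI.
An a-priori power analysis fixed this operating point: the per-timepoint
task signal SD is about 0.45 × amplitude, so the expected inter-run
correlation is $\rho^2 = \sigma_s^2 / (\sigma_s^2 + \sigma_n^2) \approx
0.6$ and the expected pair $t \approx 5$, comfortably above the $p < 0.001$
threshold ($t \approx 3.27$ at 54 df); at 1% amplitude and tSNR 50 the same
algebra gives $\rho^2 \approx 0.05$ and pair $t \approx 0.3$, a regime in
which *no* consistency-based method can score voxels reliable — the
low-CNR bad-run experiment in the acceptance suite documents exactly this
floor, and its detection half is expected to fail there.

The generator deliberately does **not** emulate physiological (cardiac or
respiratory) noise, motion, spatial noise correlation, EPI distortion or
ghosting, Rician background noise, or between-run response variability.
Passing tests on these simulations therefore show algorithmic correctness
and calibration, not robustness to every artefact of real 7 T data; on real
data, stimulus-correlated motion in particular is a known source of false
positives at high-contrast tissue boundaries for any consistency-based
score.

## Numerical conventions

* Quantiles (activation-mask percentile, brain-mask intensity cut) use R's
  default linear interpolation; the percentile cut is strict, with ties
  admitted only when the strict cut is empty (constant maps).
* The brain-mask rule (temporal mean at or above the 0.25 quantile of
  nonzero temporal means, positive temporal SD in every run) is inclusive
  at the threshold so exactly separable phantoms are recovered in full.
* Count-matched GLM thresholds break ties at the cut lexicographically by
  voxel index, making split-half tables deterministic.
* Welch tests on two zero-variance samples (identical-run sessions reach
  this) are defined as $t = 0$, $p = 0.5$ for equal means.
* Dice between two empty masks is defined as 1 and flagged, keeping
  threshold tables total at unattainable reliability levels.
* The split uses 1-based acquisition positions (runs 1, 3, 5, … vs
  2, 4, 6, …); within-half bad-run exclusion is off by default so the halves
  keep matched pair counts.

## Problem sizes

The packaged tests and the acceptance script run on desk-scale grids chosen
as the package's own working sizes: 24×24×8 to 32×32×8 voxel grids with
1,500–2,400 brain voxels, 10-run sessions (20 for split-half), 56 or 160
volumes, and 20-seed repetitions for the detection-rate experiments. These
reproduce every structural property of the method (pair counts, level
quantisation, exact shift invariance, null calibration at the 0.1% pair
rate) at a fraction of the cost of scanner-sized grids.

## Limitations

The method needs at least two runs with identical task timing; it cannot
separate multiple tasks within a session, and its advantage disappears if
response dynamics vary *between* runs (learning, changing strategy). With
two runs the reliability map is binary (0 or 100); gradation grows with the
pair count. Bad-run testing needs at least four runs. Group-level inference
and event-related designs with run-varying timing are out of scope.
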