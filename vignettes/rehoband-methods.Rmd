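---
title: "Frequency-resolved ReHo state comparison: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-resolved ReHo state comparison: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rehoband)
```

This vignette is the package's own account of the science it implements:
the statistical model at each stage, the parameters that matter and their
defaults, what the synthetic phantom does and does not emulate, and the
choices we made where the design was genuinely open. No empirical claim
here goes beyond what the test suite and `scripts/acceptance.R` compute.

## Regional homogeneity

For each in-mask voxel, ReHo is Kendall's coefficient of concordance
between the voxel's band-filtered time series and those of its in-mask
neighbors. With k series of length n, per-timepoint rank sums $R_t$, and
tie terms $T_j = \sum (t^3 - t)$ over tie groups within series j,

$$W = \frac{12 \sum_t \left(R_t - k(n+1)/2\right)^2}{k^2(n^3-n) - k\sum_j T_j}.$$

$W \in [0,1]$; under independence $E[W] = 1/k$ exactly (the rank sums
have mean $k(n+1)/2$ and variance $k(n^2-1)/12$), and $(n-1)kW$
approximately follows $\chi^2_{n-1}$ — both are checked by simulation in
the test suite. Ties are handled with average ranks plus the corrected
denominator: BOLD data rarely tie, but quantized fixtures and phantoms
can, and the correction makes W exact there. A voxel whose whole
neighborhood is constant has a vanishing denominator and returns W = 0
with a warning.

Three neighborhood schemes are supported (6, 18, 26 = faces, +edges,
+corners); 26 is the classical ReHo choice and the default. At mask
borders we use the in-mask subset of the neighborhood (k varies, so the
map covers the full mask) rather than dropping border voxels; this
matches common toolbox behavior. Because $E[W] = 1/k$, raw W is higher
near borders — one reason the maps are z-standardized per subject
(within-mask mean 0, SD 1, sample SD with $n-1$) before group analysis.
"Within the mask" is our reading of whole-brain standardization; the
analysis mask is the only voxel set the pipeline ever sees.

ReHo is always computed on unsmoothed data; the 4 mm FWHM Gaussian
smoothing (per-axis $\sigma = \mathrm{FWHM}/(v \cdot 2\sqrt{2\ln 2})$
voxels at voxel size $v$, i.e. $\sigma \approx 0.566$ voxels at 3 mm) is
applied to the standardized map, following the compute → standardize →
smooth order of the emulated processing stream. Smoothing uses zero
padding and re-applies the mask afterwards.

## Band decomposition

The 0–0.25 Hz fluctuation range is partitioned into slow-6 … slow-2. The
filter is the ideal rectangular DFT filter (the REST/DPABI convention):
per voxel, remove the best-fit line, transform, zero all bins outside the
band, invert. A bin at frequency f belongs to a band iff
$f_{low} < f \le f_{high}$; the shared printed edge goes to the lower
band (slow-6 keeps 0.01 Hz, slow-5 starts strictly above). Under this
convention the named bands tile $(0, \mathrm{Nyquist}]$ exactly, so the
per-voxel band variances sum to the variance of the detrended series to
machine precision (Parseval) — a suite invariant at 1e-8 relative.

Two numerical subtleties are worth recording. First, the rectangular
filter is an orthogonal projection and hence exactly idempotent, but the
*detrending* step is a different projection: a band-limited series still
has a small nonzero best-fit line (spectral leakage of the finite
window), so re-running detrend + filter perturbs a filtered series at the
percent level. `bandpass()` therefore exposes `detrend` as an argument;
re-filtering with `detrend = FALSE` is an exact identity and is what the
idempotence test asserts. Second, a sinusoid that does not sit on a DFT
bin leaks into neighboring bands; the leakage equals the periodogram
fraction of the windowed sinusoid outside the band (about 1.1% into
slow-5 for a 0.05 Hz sinusoid at 154 points, TR 2 s). The filter tests
assert agreement with that analytic oracle rather than pretending
leakage away.

Analyses default to slow-5 … slow-2; slow-6 mostly carries scanner drift
and is available but excluded by default.

## Temporal preprocessing

The order is fixed as trim → nuisance regression → detrend + band-pass.
Trimming drops leading volumes (e.g. 46 resting / 9 task volumes to
equate both states at 154 volumes). Nuisance regression removes an
intercept, six rigid-body motion parameters, and global / white-matter /
CSF means by least squares; residuals are exactly orthogonal to the
regressors (suite invariant, 1e-8 relative) and collinear columns are
dropped with a warning. Motion QC fails a scan iff any translation's
absolute excursion reaches 3 mm (strict "less than" rule), and summarizes
motion as mean framewise displacement (sum of absolute backward
differences of the six parameters, rotations converted at a 50 mm
radius) — the field-standard scalar where the design only says "head
motion" as a covariate.

## Group × state interaction

The 2 (group) × 2 (state) repeated-measures interaction with
subject-level covariates is fitted on difference scores: per voxel,
$d_i = z^{task}_i - z^{rest}_i$ is regressed on [intercept | group |
age, sex, education, motion, (optional GM intensity)], and the
interaction F is the squared t of the group coefficient, df
$(1, N - q)$. For a balanced 2 × 2 design with subject-constant
covariates this is algebraically the mixed-model interaction:
differencing removes subject and state main effects, and the group effect
on the difference *is* the interaction. The equivalence to the pooled
two-sample t (no covariates) is asserted at 1e-10, and adding a constant
to all maps of one state provably changes nothing (also asserted). F-map
p-values are inherently one-tailed; no two-tailed splitting is applied.

Cluster-extent correction is Monte-Carlo (AlphaSim-style): fill the mask
with white Gaussian noise, smooth to the analysis FWHM, re-standardize
within the mask, binarize at the upper `p_voxel` quantile, label
clusters, record the maximal size; over `n_iter` (default 1000, seeded)
iterations, k* is the smallest extent whose exceedance frequency is ≤
alpha. The smoothness fed to the simulation is the applied smoothing
FWHM (4 mm): the phantom's noise carries no intrinsic smoothness, so the
applied kernel is the correct model; for real data with intrinsic
smoothness a residual-based estimate would be larger and k* conservative
in the same direction. Cluster connectivity defaults to 18
(faces + edges — the 5 mm edge-distance rule at 3 mm voxels); peak ties
break to the first voxel in column-major grid order.

## Seed-based connectivity

Surviving clusters seed voxel-wise Pearson correlation maps against the
seed's mean time course, computed on the same band-filtered series in
which the cluster was found (the band semantics stay coherent; the
choice is logged per seed). Fisher z uses clipping at $|r| = 1 - 10^{-7}$
so self-correlations stay finite. Group contrasts are two-sample t maps
per state, state contrasts paired t maps per group; both reuse the
cluster-extent machinery for thresholding. Negative connectivity is
retained in the raw maps but only positive summaries are emitted by
default.

## Behavior

DMST logs are scored as: hit rate (match responses to targets), false
alarm rate (match responses to distractors), accuracy = hit − FA, RT =
mean over all answered test stimuli, performance = accuracy / RT (1/ms;
the reciprocal of the inverse efficiency score — about 1.5e-3 for 90%
accuracy at 600 ms). Omitted responses count as non-hits and are excluded
from RT averaging; the source design is silent on omissions and this is
the conservative reading. Brain-behavior coupling is Pearson correlation
of the per-cluster state-related z-ReHo change (task minus rest) with
performance, computed within each group separately and never pooled, with
a seeded percentile bootstrap CI (default B = 1000, 95%). Percentile
rather than BCa because only the count and level are part of the design;
percentile is the minimal-assumption choice, and its small undercoverage
at n ≈ 17 (≈ 93% measured) is documented rather than corrected away.

## The phantom: what it emulates, and what it does not

`phantom_config()` defaults define the study conditions: 16 + 17
subjects, two states with 154 volumes each at TR 2 s, 3 mm voxels on a
24 × 24 × 16 grid with an ellipsoidal mask (~3500 voxels), covariates
drawn to match the emulated cohort's demographics, and one planted
slow-5 cluster with a crossed weight pattern (NC falls from rest to
task, MCI rises).

Voxel series are $\sqrt{w}\,\ell(t) + \sqrt{1-w}\,\varepsilon(t)$, with a
shared latent $\ell$ synthesized by passing white noise through the same
ideal band-pass used in preprocessing (one filter definition in the whole
package) and i.i.d. wide-band noise $\varepsilon$. Two generator choices
deserve explanation:

- **The weights look small.** w is the shared fraction of *wide-band*
  variance. After filtering into slow-5 only ~6.5% of the white noise
  survives, so the within-band shared fraction — what ReHo sees — is
  roughly ten times larger: w = 0.022 gives ≈ 0.25 in-band. Large w
  (say 0.6) would drive cluster W toward 1 and, because the cluster is
  ~7% of the phantom mask, shift the within-mask mean and SD enough that
  the z-standardization itself induces opposite-signed apparent
  interactions in background voxels. That artifact is intrinsic to
  global standardization and negligible in real brains (where any
  cluster is a tiny mask fraction); the default weights keep the phantom
  in the regime where it is small.
- **The planted box is 7 × 7 × 5 (245 voxels).** ReHo erodes a planted
  region by one neighborhood radius (border voxels mix cluster and
  background neighbors), so the recoverable core is the 5 × 5 × 3 = 75
  voxel interior — comfortably above the Monte-Carlo extent threshold
  (k* ≈ 8 under the default settings).

Subject individuality enters as an antisymmetric jitter on the weights
(+j/2 task, −j/2 rest, $j \sim N(0, 0.006)$): each subject has their own
state-change magnitude while cell means stay at the configured weights.
(A symmetric jitter would cancel in the task−rest difference and leave
no within-group variance for behavior coupling to correlate with.)
Behavioral performance is baseline + coupling × state-change + noise;
RT is drawn per subject and accuracy set to performance × RT (clipped to
[0, 1]), so performance = accuracy/RT holds exactly by construction. The
defaults (baseline 1.35e-3 /ms, coupling −1.2e-2, noise 1.2e-4) put the
two groups' mean performance near the printed 1.5e-3 vs 1.2e-3 /ms and
make higher task-related ReHo increases go with worse performance.

The phantom deliberately omits: anatomical structure, spatial
autocorrelation of the noise, scanner drift and physiological noise
spectra, slice-timing and motion artifacts (volumes are pre-aligned by
construction), and task hemodynamics. Consequently, passing tests show
that the *statistical machinery* is calibrated and recovers planted
effects under the design conditions — they do not certify performance on
real data with intrinsic smoothness and structured noise. One phantom
consequence worth knowing: with ~10 effective temporal degrees of freedom
in slow-5, per-subject cluster-mean W estimates are noisy, so the
imaging-derived brain-behavior correlation is attenuated relative to the
planted population coupling; the coupling-recovery experiment therefore
measures the behavioral generator directly, and the pipeline-level
correlation is reported as-is.

## Problem sizes and runtimes of the validation experiments

Chosen to give stable Monte-Carlo estimates: null calibration uses 200
independence phantoms (12 × 12 × 8, 154 volumes) for mean W and 4 null
cohorts (~4600 voxel tests) for the type-I rate; the cluster-threshold
checks use 1000 iterations on a 10648-voxel mask; planted-effect
recovery uses 50 replicate cohorts at the full default phantom size;
behavior recovery uses 200 replicates for the mean and 500 (B = 1000)
for CI coverage. The whole acceptance script runs in roughly 7 minutes
on one CPU.

## Known limitations

- Exact numerical parity with SPM's flexible-factorial implementation is
  not claimable; the difference-score ANCOVA covers the balanced 2 × 2
  case and is verified against its own algebraic oracles.
- The Monte-Carlo correction models stationary Gaussian smoothness; no
  random-field or permutation alternative is provided.
- Global-standardization leakage (above) bounds how large a planted
  effect can be relative to the mask before background voxels acquire
  compensatory apparent effects.
- The bootstrap CI is percentile, with the coverage noted above; BCa is
  out of scope.
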