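# rehoband

Frequency-resolved regional homogeneity (ReHo) analysis of BOLD fMRI
across resting and task states, with a synthetic phantom module that makes
every stage of the pipeline testable without access to subject scans.

## The scientific problem

Regional homogeneity measures the local temporal synchrony of the BOLD
signal: for each voxel, Kendall's coefficient of concordance (KCC, or
Kendall's W) between the voxel's time series and those of its 26 nearest
neighbors,

    W = 12 S / ( k^2 (n^3 - n) - k * sum_j T_j )

where k is the number of series (voxel + in-mask neighbors), n the number
of time points, S the sum of squared deviations of the per-timepoint rank
sums from their mean, and T_j the tie-correction term of series j. W is 1
for perfectly concordant series and has expectation 1/k under
independence.

Because different frequency bands of the BOLD fluctuation reflect
different physiology, the analysis is frequency-resolved: the 0–0.25 Hz
range (Nyquist at TR = 2 s) is partitioned into the canonical slow bands —
slow-6 (0–0.01 Hz), slow-5 (0.01–0.027), slow-4 (0.027–0.073), slow-3
(0.073–0.198), slow-2 (0.198–0.25) — by an ideal (rectangular DFT)
band-pass filter, and ReHo maps are computed per band.

The package implements the full comparison of two groups (e.g. patients
with mild cognitive impairment, MCI, vs. normal controls, NC) scanned in
two states (rest vs. a working-memory task):

- temporal preprocessing: volume trimming, head-motion QC (exclusion at
  ≥ 3 mm excursion; mean framewise displacement as a covariate), nuisance
  regression (motion, global, white-matter, CSF signals), band-pass;
- per-band ReHo maps, z-standardized within the brain mask and smoothed
  with a 4 mm FWHM Gaussian kernel (ReHo always computed on unsmoothed
  data);
- voxel-wise group × state interaction mapping via covariate-adjusted
  difference scores (algebraically the repeated-measures interaction for
  a 2 × 2 design), with Monte-Carlo (AlphaSim-style) cluster-extent
  correction, cluster tables and post-hoc t-tests;
- seed-based functional connectivity for surviving clusters with Fisher-z
  transformation and group/state contrast maps;
- behavioral scoring of delayed match-to-sample (DMST) logs — accuracy =
  hit rate − false-alarm rate, performance = accuracy / RT — and
  per-group correlation of cluster-wise state-related ReHo changes with
  performance, with percentile-bootstrap confidence intervals.

The phantom module generates complete synthetic cohorts (4D NIfTI volume
pairs, covariates, nuisance tables, DMST schedules and response logs)
with band-limited locally synchronized signal planted in known clusters
under a crossed group × state weight pattern, so calibration, power and
coupling recovery can all be measured.

## Worked example

A small two-band analysis on a simulated cohort (8 + 8 subjects,
16 × 16 × 10 grid, 154 volumes per state at TR = 2 s; about two minutes):

```r
library(rehoband)
cfg <- run_config(
  phantom = list(n_per_group = c(8, 8), grid_shape = c(16, 16, 10),
                 n_volumes = 154, mask_shape = "full"),
  bands = c("slow-5", "slow-4"), mc_iter = 500, bootstrap_B = 1000,
  seed = 42, out_dir = "demo_run")
res <- run_pipeline(cfg)
res$k_star
#> [1] 7
res$clusters
#>  label size peak_x peak_y peak_z peak_stat   band
#>      1   63      9     10      3  66.07820 slow-5
#>      1    8     12     11      9  22.10869 slow-4
res$posthoc[res$posthoc$band == "slow-5", c("comparison", "t", "p", "direction")]
#>       comparison         t            p direction
#>    MCI-NC (rest) -6.074593 0.0000286412    MCI<NC
#>    MCI-NC (task)  4.270606 0.0007765004    MCI>NC
#>  task-rest (MCI)  4.315025 0.0035014680 task>rest
#>   task-rest (NC) -6.483503 0.0003393628 task<rest
```

The Monte-Carlo correction estimated a minimum cluster extent of k* = 7
voxels at voxel p < 0.01 and family-wise alpha = 0.05. The 63-voxel
slow-5 cluster is the planted one: its peak sits inside the planted box,
and the post-hoc tests recover the planted crossed pattern — ReHo falls
from rest to task in NC and rises in MCI. (The 8-voxel slow-4 cluster is
a family-wise false positive; at alpha = 0.05 those appear in about one
run in twenty, which is what the correction promises.) The behavior table
(`res$behavior`) correlates each cluster's state-related ReHo change with
working-memory performance per group; in this run the MCI group shows
r = −0.64 (bootstrap 95% CI −0.92 to −0.04) in the slow-5 cluster while
the NC correlation is near zero — the planted coupling links performance
deficits to the state-change magnitude.

All artifacts (NIfTI maps, TSV tables, JSON manifest with checksums and a
parameter log) are written under `out_dir`; rerunning with the same seed
reproduces them byte for byte.

A command-line wrapper is installed at
`system.file("scripts", "run_pipeline.R", package = "rehoband")`:

```sh
Rscript run_pipeline.R --config cfg.json --seed 42 --out demo_run
```

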