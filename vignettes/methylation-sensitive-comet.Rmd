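---
title: "Estimating global CpG methylation from methylation-sensitive comet assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating global CpG methylation from methylation-sensitive comet assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscomet)
```

## The measurement model

The methylation-sensitive comet assay infers the genome-wide fraction of
methylated 5'-CCGG-3' sites from three single-cell electrophoresis
measurements per sample: nucleoids digested with HpaII, nucleoids
digested with MspI, and undigested controls. Both isoschizomers cut
CCGG; HpaII is blocked when either cytosine is methylated (and cuts
hemimethylated sites at a reduced rate), MspI tolerates
internal-cytosine methylation but is blocked by external-cytosine
methylation. Per comet, the scored quantity is the tail intensity: the
percentage of that cell's DNA fluorescence in the comet tail.

With group mean tail intensities `HpaII`, `MspI` and `control`, the
sample-level statistic is

    % CpG methylation = (100 − 100 · HpaII / MspI) − control

The ratio term measures the fraction of MspI-accessible sites that HpaII
could *not* cut (methylation); subtracting the control mean compensates
for strand breaks present before digestion. The statistic is
deliberately unclipped: values below 0 (heavy baseline damage) or above
100 are reported as-is and flagged, since silently clipping would hide a
failed digestion or damaged batch.

Because MspI recognition sites fall predominantly outside CpG islands,
the estimate describes global methylation of the CCGG fraction of the
genome, not island-resolution methylation.

## Estimation pipeline

`estimate_methylation()` runs, per sample:

1. **Outlier rejection** per treatment group with the modified Thompson
   tau rule: iteratively remove the single observation with the largest
   absolute deviation while it exceeds `τ·SD`, where
   `τ = t·(n−1)/(√n·√(n−2+t²))` and `t` is the two-sided Student-t
   critical value at level `alpha_tau` (default 0.05, mirroring the
   assay's 95% convention) on `n−2` df. Groups smaller than 3 are left
   untouched with a warning (the SD-based test is undefined), and
   zero-variance groups stop immediately. Filtering is applied per
   treatment group — the only level at which the three-group statistic
   remains well defined.
2. **Point estimate**: the statistic of the filtered group means.
3. **Bootstrap inference**: each replicate resamples comets within each
   *original* treatment group with replacement (same sizes) and re-runs
   the full pipeline — tau filter, means, statistic. The confidence
   interval is the percentile interval (default 10,000 replicates, 95%).

Two design points deserve comment. The resampling unit is the individual
comet: the assay's design (≥400 scored comets per sample) makes the
comet the natural exchangeable unit, and well-level resampling with ~9
wells would give unstable intervals. And the bootstrap re-runs the
*whole* estimator rather than resampling the already-filtered values and
taking plain means: the tau rule at `alpha = 0.05` trims aggressively on
large clean groups (it removes every point beyond roughly `1.96·SD`,
iteratively), so resampling trimmed data understates the estimator's
sampling variance — in our simulations that variant covered the analytic
expectation in well under 90% of runs, while bootstrapping the full
pipeline achieves ~95% empirical coverage.

Replicates whose resampled MspI mean is zero have an undefined ratio;
they are discarded and counted, and more than 1% of them aborts
inference (it signals a failed MspI digestion, not sampling noise).

`compare_conditions()` contrasts two samples (untreated minus treated)
and builds the difference interval by differencing the two independent
bootstrap replicate streams percentile-wise.

## The forward simulator

`simulate_cell_population()` generates per-cell data with known truth.
A nucleoid is abstracted as `S` CCGG sites (default 1000 — an effective,
scaled count, not a genomic census). Per cell:

* baseline breaks `B0 ~ Poisson(lambda0)`, shared by all three groups of
  a sample (same cell batch), so the control subtraction is meaningful;
* MspI adds `Binomial(S·(1−e), d)` cuts; HpaII adds
  `Binomial(S·(1−m−e−h), d) + Binomial(S·h, d·d_hemi_factor)`, encoding
  full blocking at internally methylated sites, reduced-rate digestion
  of hemimethylated sites (default factor 0.5) and MspI blocking by
  external-cytosine methylation (`e`, default 0);
* tail intensity = `clip(100·(1 − exp(−B/kappa)) + N(0, sigma), 0, 100)`.

The saturating-exponential response was chosen because it is monotone,
bounded in `[0, 100)`, and linear at low break counts — the regime in
which the ratio statistic is interpretable; a single constant `kappa`
(breaks at ~63% tail) controls saturation. Noise is additive Gaussian on
the percentage scale, clipped after addition so the output invariant
holds.

Defaults emulate the assay's study design: 9 wells × 50 comets per
treatment group (450 comets per treatment, satisfying the ≥400-comet
design), `d = 0.8`, `lambda0 = 50`, `kappa = 4000`, `sigma = 5`, and
truths of `m = 0.6` (untreated) vs `0.35` (demethylated) for the
two-condition convenience wrapper. With these defaults the MspI groups
show clearly elevated tails (~20%) over controls (~1%), as real
digestions do, at the cost of a few points of saturation bias in the
point estimate — visible in the README example. Validation settings use
the linear regime instead (`S = 200`, `d = 0.9`, `kappa = 20000 ≥
100·S·d`, `lambda0 = sigma = 0`), where
`expected_methylation_statistic()` gives the exact analytic expectation
of each group's tail intensity via the moment generating functions of
the break counts, and the estimator recovers `100·m` to well within 2
percentage points at 2000 cells per group.

What the simulator does *not* emulate: well-level random effects (only
cell-level variation is modelled; inter-well variability of real gels
would widen intervals), electrophoresis physics, staining chemistry, or
sequence-level site distributions. Passing tests on synthetic data
therefore validate the statistical machinery, not the wet-lab assay.

The CEA simulator shares the enzyme-susceptibility model: incorporation
counts are `background + Poisson(scale·S·(accessible fraction)·d)`, so
`cea_methylation()` recovers `100·(m + h·(1−d_hemi_factor))/(1−e)` in
the large-count limit, which reduces to `100·m` for the clean scenarios.

## Image scoring

`simulate_comet_image()` renders a comet with known tail fraction: an
isotropic Gaussian head plus a tail band extending toward increasing
column index (the anode side — a fixed convention the scorer assumes)
with an exponential column profile and Gaussian row profile, both
kernels normalised over the frame so the head/tail signal split is
exact. `score_comet()` subtracts the corner-median background, segments
the largest connected above-background component (dilated slightly to
recapture the sub-threshold fringe), locates the head (brightest
smoothed pixel, or a symmetric 2-D Gaussian fit), and reports

    tail % = 100 · signal(outside the head disk, columns > head centre) / total

with the head disk of radius `1.5 × FWHM` of the head Gaussian. Head and
tail percentages sum to exactly 100. The head SD is estimated from the
pure-head half of the comet (columns left of the centre), which the
one-sided tail geometry guarantees is uncontaminated.

Geometry defaults (head SD 2 px, tail decay length 450 px in a 128×1024
frame) keep the unavoidable misclassification — tail signal inside the
head disk — below 2 percentage points at every tail fraction; the
multiplier 1.5 makes a pure-head image score ≈ 0.1%. The scorer is
deterministic, invariant to uniform background offsets up to 10% of
peak, and recovers truth within 2 points noise-free and 4 points under
Poisson noise at 10^5 total counts. Against a commercial scorer no
validation is possible (their head/tail delimitation is proprietary);
synthetic ground truth is the only oracle used.

## Numerical choices and degenerate inputs

* Bootstrap trimmed means use a sorted incremental implementation (the
  extreme deviation is always at an end of the sorted sample), centred
  to keep running sums well conditioned; it matches the reference
  iterative filter up to ties between the two ends.
* Groups of size 1 resample to themselves: width-zero intervals, by
  construction, matching the degenerate-input contract.
* `sample_id`/`well` are labels, never arithmetic; wells are 1–12
  mirroring the 12-well gasket.
* Seeds: every stochastic entry point takes an explicit seed and
  restores the caller's RNG state; identical seeds give byte-identical
  CSV and serialised estimates.
* Validation problem sizes (200 coverage samples at 2000 bootstrap
  replicates, 2000-cell analytic-limit samples, 500 oracle datasets, a
  9-point imaging grid) were chosen as the smallest runs whose
  Monte-Carlo error is negligible relative to the tolerances they check.

## Known limitations

* The statistic inherits the assay's saturation bias outside the linear
  regime; the package reports what the assay would measure, it does not
  de-bias it.
* Hemimethylation and external-cytosine methylation are simulated but
  not separately identifiable from the three-group design; the estimator
  returns the HpaII-blocked fraction as seen through the statistic.
* No well-level mixed modelling: if real inter-well variability is
  large, comet-level bootstrap intervals will be anticonservative.
* The tau rule over-trims large clean samples by construction (a known
  property of the method at fixed `alpha`); we keep it because it is the
  assay's stated convention, and the full-pipeline bootstrap accounts
  for its variance contribution.
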