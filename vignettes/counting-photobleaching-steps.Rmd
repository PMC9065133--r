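---
title: "Counting LEDGF/p75 photobleaching steps on immobilized intasomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting LEDGF/p75 photobleaching steps on immobilized intasomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bleachsteps)
```

## The measurement

The maedi-visna virus (MVV) intasome is a nucleoprotein assembly of sixteen
integrase subunits synapsing the two viral DNA ends. It offers up to sixteen
binding sites for the host chromatin adaptor LEDGF/p75, and how many of those
sites are occupied, and how occupancy responds to ionic strength, is measured
by single-molecule photobleaching: intasomes carrying a Cy3 label on the viral
DNA are immobilized in a TIRF flow cell, LEDGF/p75 carries a SNAP-Surface649
(Surf649) label, and each intasome spot's Surf649 fluorescence is recorded at
5 Hz for three minutes while the fluorophores irreversibly bleach. Every
discrete downward step of the trace is one destroyed fluorophore, so the
number of steps reports the number of labeled LEDGF/p75 molecules bound to
that single complex. Per salt condition, counts from three 512 x 512 pixel
fields of view (160 nm pixels, about 400 spots per field) are pooled into
box-and-whisker summaries.

`bleachsteps` implements this analysis end to end — and, because no raw
imaging data for the experiment is public, a synthetic-data generator with
known ground truth against which every stage is validated.

## The generative model

`sim_config()` fixes the trace-level model:

* **Occupancy.** Each of the `n_sites = 16` binding sites is occupied
  independently with probability `occupancy_p`, so the labeled-subunit count
  is Binomial(16, `occupancy_p * labeling_efficiency`). The structure
  identifies sixteen equivalent sites and nothing in the data constrains
  cooperativity, so independence is the natural minimal model.
  `condition_preset()` calibrates `occupancy_p` to the measured mean
  stoichiometries — 6/16, 4/16 and 2/16 at 0.2, 0.5 and 1 M NaCl.
* **Photobleaching.** Each active fluorophore survives each frame with
  probability `1 - bleach_rate`; its bleach frame (the last frame in which it
  emits) is geometric with mean `1/bleach_rate - 1`. The default
  `bleach_rate = 0.005`/frame gives `1 - 0.995^900 = 98.9%` completeness
  within the 900-frame movie, comfortably beyond the >95% the experiment
  relies on. The rate itself is not reported, so it is set by that
  completeness constraint.
* **Intensities.** Each fluorophore contributes a unit intensity drawn once
  from Normal(`unit_step_mean` = 20, CV `unit_step_cv` = 0.15, truncated
  positive) and holds it until bleaching; Gaussian read noise of
  `noise_sd = 0.15 * unit_step_mean` is added per frame. Neither value is
  reported; they are chosen so that individual steps are resolvable but not
  trivially clean, and both are configuration fields.
* **Cy3 reference.** A single intasome's Cy3 intensity is Normal(100, 25),
  truncated positive. This calibration makes the 200 arb. unit
  bright-spot cutoff meaningful: two coincident complexes sum to about twice
  the single-complex intensity and land beyond the cutoff.
* **Arbitrary units.** Only ratios matter anywhere in the analysis; the step
  counter is invariant to positive rescaling of a trace by construction.

`simulate_field()` adds the imaging layer: a Poisson number (mean 400) of
intasomes at uniform subpixel positions in a 512 x 512 field, each rendered
as a 2-D Gaussian (PSF sigma 0.15 um) whose integrated intensity follows the
trace model, over a constant background, a linear gradient, a camera offset,
and per-pixel Gaussian read noise (`read_noise_sd = 0.1` arb. units). The
generator does not emulate an EMCCD gain register, TIRF evanescent-depth
variation, drift, or Surf649 blinking; an optional re-brightening injector
(`simulate_trace(inject_jump = TRUE)`) exists to exercise the unstable-trace
filter. Passing tests on these simulations therefore demonstrates the
correctness of the analysis chain under the stated noise model, not
robustness to every artifact of real EMCCD data.

Reproducibility: each trace or field derives its own RNG substream from the
root seed and its index, so results are bit-identical regardless of batch
size, and `run_pipeline()` re-runs byte-identically from a config echo and
seed.

## Image processing

The processing chain mirrors the acquisition software settings, with each
printed constant a `detection_params()` default:

* **Denoising.** The instrument's proprietary "advanced denoising at 5" is
  re-specified as Gaussian smoothing with sigma = strength/5 px, so the
  printed setting means a 1 px blur; strength 0 is the identity.
* **Background.** Rolling-ball subtraction with r = 0.48 um (3 px at 160 nm
  pixels), implemented as grayscale opening with a hemispherical structuring
  element. The opening is anti-extensive, so the output is never negative;
  flat or smoothly varying structure maps to zero while diffraction-limited
  spots survive.
* **Detection.** Candidate spots are local maxima of a negated
  Laplacian-of-Gaussian response computed at the PSF scale. The 0.78 um
  radius parameterizes the measurement aperture and the non-maximum
  suppression distance (one aperture radius), not the blob filter: an LoG at
  the aperture scale cannot resolve two spots much closer than twice its
  sigma, and at 400 spots per field the expected loss to such merging alone
  is about 20% — detection at the imaged density is only consistent with a
  PSF-scale filter. A candidate is emitted when its robust contrast,
  (aperture mean − annulus median) / annulus MAD, reaches 14.5; the proprietary
  unitless "contrast" score is re-specified as this robust SNR, with the
  simulator calibrated so true spots score far above it and blank noise
  essentially never does. Centroids are refined to subpixel precision by
  intensity-weighted center of mass.
* **Photometry.** Traces are aperture sums minus the local annulus median
  (inner radius aperture + 2 px, width 3 px) scaled by aperture area,
  measured on the *denoised* stacks. The rolling-ball image feeds detection
  only: an opening rises under a bright spot, so flattening before
  photometry would subtract part of the spot itself and attenuate the flux
  scale nonlinearly, which is exactly what the annulus estimate already
  handles robustly. Spots whose aperture or annulus crosses the field edge
  are flagged and excluded downstream.

Coordinates are pixel-centered with the origin at the corner pixel center
(x = column, y = row); all unit conversions go through `um_to_px()` and
`frames_to_seconds()`.

## Counting steps from pairwise differences

For a trace $I(t_0), \dots, I(t_{n-1})$ the analysis forms all
$n(n-1)/2$ pairwise differences between an earlier and a later frame (the
sign chosen so bleaching yields positive values). For equal-size steps $s$
these concentrate at the lattice $s, 2s, \dots, ks$, and the local maxima of
a kernel density over the differences identify the lattice.
`estimate_step_count()` proceeds as:

1. median-smooth the trace (window 5 frames — preserves step edges,
   suppresses single-frame outliers);
2. estimate the noise scale robustly as
   $\hat\sigma = \mathrm{median}(|\Delta I|)/(\sqrt{2}\cdot 0.6745)$ from
   successive differences of the *raw* trace (after median filtering most
   successive differences are exactly zero, which would collapse the
   bandwidth);
3. build the pairwise-difference density with bandwidth
   $h = \max(\hat\sigma,\ 0.05\,\hat s)$, where $\hat s$ is the largest
   single-frame drop — the floor keeps the density non-degenerate for
   noiseless traces; find its positive-side local maxima beyond
   $d_{\min} = \max(3\hat\sigma, 0.5h)$, keep peaks at ≥10% of the tallest
   positive peak, and merge peaks closer than one bandwidth;
4. calibrate the unit step from the first qualifying peak, then recalibrate
   it as the median of the measured plateau-to-plateau drops classified as
   singles (the density's first rung is biased low by pair values involving
   smeared step edges, and with fast early bleaching it can even sit at a
   multiple of the unit; a halving guard handles that case);
5. count: group frames falling by more than a quarter unit into transition
   regions (frames closer than the smoothing window belong to one region),
   measure each region's net drop between the plateau medians on either
   side, and report $k = \sum_r \mathrm{round}(\mathrm{drop}_r / s)$ over
   regions exceeding half a unit. Raw end-frame checks rescue the
   single-frame plateaus at either end that the median filter's end rule
   destroys.

**Why quantized transitions rather than counting density peaks.** Reading
$k$ directly as the number of qualifying density peaks fails at high
occupancy for a structural reason: with plateaus of comparable dwell, the
pair mass feeding the peak at $m\,s$ is proportional to $k + 1 - m$, so the
top rung of a 16-step ladder carries ~1/16 the mass of the first and falls
below any fixed relative prominence long before the steps themselves become
unresolvable. The local-maxima analysis is therefore used for what it
determines reliably — the unit step size — and the count comes from the
trace's own transitions quantized in that unit. This preserves exactness for
noiseless staircases of all occupancies 0–16 and is invariant to positive
scaling and additive offsets of the trace.

Two refinements were evaluated and rejected: lattice-fit scans over divisor
candidates of the unit step (both drop-weighted least squares and robust
median scoring). With only a handful of noisy drops per trace the half-step
lattice fits as well as the true one whenever measurement error is
appreciable, and both variants systematically overcounted; the shipped
single-pass recalibration does not have that failure mode.

## Exclusion rules

`count_steps()` applies the filters in a fixed order so each excluded trace
carries exactly one reason: edge-clipped aperture → Cy3 reference above
200 arb. units (likely overlapping complexes) → unstable profile → no
photobleaching steps. A profile is unstable when the smoothed trace rises by
more than `instability_jump_factor` (default 1) unit steps — re-brightening
or late binding — or when the mean of its final 10% of frames exceeds 20% of
the mean of its initial 10%, i.e. bleaching did not run to completion. Both
thresholds are `filter_params()` fields. The bookkeeping identity
`n_detected = n_included + sum(per-reason exclusions)` is asserted in the
tests and auditable from the run log.

## The change-point oracle

`oracle_step_count()` validates the estimator by an independent route: an
exact dynamic-programming segmentation of the raw trace into piecewise
constant levels (globally RSS-optimal for every number of change points
$m \le 20$, in compiled code), with $m$ selected by
$\mathrm{BIC}(m) = n\ln(\mathrm{RSS}_m/n) + (2m+1)\ln n$. Downward level
transitions are then converted to steps by quantizing each against the
median of the smallest-transition cluster, with biased-down rounding (a
transition counts as $m \ge 2$ steps only beyond $m - 0.3$ units). The
quantization matters: two fluorophores bleaching in the same frame are two
steps but one transition, and at high occupancy such coincidences affect
5–8% of traces — counting raw transitions would misgrade the estimator on
exactly the traces it gets right.

On equal-step traces at the default noise (0.15 of a step), estimator and
oracle agree exactly on ≥95% of traces with one to eight fluorophores. Under
the full default preset, which also draws unit intensities with CV 0.15,
agreement drops to roughly 85–90%: when step sizes are themselves dispersed,
a merged double step of two small fluorophores is genuinely ambiguous
against one large fluorophore, and the two methods resolve such cases
differently. Cohort-level means are much better behaved than per-trace
counts — the residual per-trace errors are nearly symmetric — which is why
the salt-series means are recovered within ±0.2 subunits while per-trace
exact-recovery sits near 90% under dispersed unit intensities.

## Stoichiometry statistics

`summarize_conditions()` reproduces the reporting convention: box between
the 25th and 75th percentiles with the median marked, whiskers at the 10th
and 90th percentiles, outliers (beyond the whiskers, not Tukey fences)
listed individually, plus the arithmetic mean — "average" stoichiometry is
read as the mean of included counts. Percentiles use linear interpolation
between closest ranks (`quantile()` type 7; the convention is switchable as
the original analysis software does not state one). `compare_conditions()`
adds a distribution-free cross-condition comparison: Wilcoxon rank-sum,
computed by exhaustive permutation enumeration for pooled sizes up to 12 and
by the normal approximation with tie correction above that; no particular
test is named in the source analysis, so this is artifact plumbing, chosen
to be exact where exactness is cheap.

## Problem sizes and numerical choices

The test-suite and acceptance runs use the full 900-frame, 5 Hz movies
throughout; cohort recoveries use 500 traces per condition, completeness
10,000 fluorophores, and detection density twenty full 512 x 512 fields.
Image-pipeline unit tests run on 96–160 px fields at the same spot density
(≈1.5 x 10⁻³ spots/px²) so that crowding effects are representative while
end-to-end tests stay fast. Degenerate inputs are handled explicitly: a
constant trace yields zero steps and an undefined step size (excluded as
`zero_steps`), an all-zero pairwise set gets a bandwidth floor rather than a
degenerate density, detection on an empty or blank image returns an empty
table, and a cohort with no included traces raises a typed empty-cohort
error that `run_pipeline()` converts into an `empty_conditions` entry.

## Known limitations

* Per-trace exact recovery degrades when unit intensities are strongly
  dispersed (CV ≳ 0.15) and at occupancies approaching 16, where fast early
  bleaching leaves single-frame plateaus; cohort means remain accurate to
  within ±0.2 subunits at the study's operating points.
* About 1% of fluorophores outlive the movie at the default bleach rate;
  their steps are unobservable in principle, so counts are validated against
  the steps that occur on camera, and strongly incomplete traces are
  excluded by the stability filter.
* The field simulator treats 400 spots/field as the true density; since
  spots closer than one aperture merge optically, mean detections per field
  sit slightly below 400 (≈385 at default settings).
* No EMCCD gain-register noise, blinking, drift, or chromatic registration
  error is modeled; conclusions about real data rest on the adequacy of the
  Gaussian-noise, Gaussian-PSF approximation.
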