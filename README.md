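# bleachsteps

Single-molecule photobleaching analysis for counting LEDGF/p75 molecules
bound to surface-immobilized MVV intasomes — and a synthetic two-channel
TIRF data generator with known ground truth to validate every stage of that
analysis.

## The problem

The maedi-visna virus intasome carries sixteen integrase subunits and offers
up to sixteen binding sites for the host factor LEDGF/p75. In the TIRF
experiment this package models, intasomes labeled with Cy3 on their viral
DNA are immobilized in a flow cell, LEDGF/p75 carries a Surf649 label, and
each intasome spot's Surf649 fluorescence is sampled at 5 Hz for three
minutes while its fluorophores photobleach. Each discrete downward step in a
trace is one destroyed fluorophore, so the step count per spot reports the
number of labeled LEDGF/p75 bound to that single complex; pooled over
conditions, the counts measure how occupancy falls with ionic strength
(means of 6, 4 and 2 subunits per intasome at 0.2, 0.5 and 1 M NaCl, with
up to 16 at the lowest salt).

The step count is obtained from the pairwise intensity-difference
distribution: for all frame pairs with $t_i > t_j$ the differences
$\Delta I_{ij} = I(t_j) - I(t_i)$ (sign chosen so bleaching is positive)
concentrate at integer multiples $s, 2s, \dots, ks$ of the unit step $s$;
local maxima of their smoothed density identify the unit step, and the
trace's downward transitions quantized in that unit give $k$. An exact
dynamic-programming change-point oracle (BIC-selected piecewise-constant
fit, in compiled code) provides an independent validation path.

The package is tidyverse-native: simulation and extraction return tibbles
(one row per trace, list-column intensities), `count_steps()` and
`summarize_conditions()` are data-frame-in/tibble-out, fitted objects have
`tidy()`/`glance()` methods and `autoplot()` plots.

## Worked example

Simulate one intasome with six labeled subunits and count its bleaching
steps:

```r
library(bleachsteps)

cfg   <- condition_preset("salt_0.2M")   # occupancy 6/16 per site
trace <- simulate_trace(6, cfg, seed = 8, complete_bleach = TRUE)
fit   <- estimate_step_count(trace$intensity)
fit
#> <step_fit> 6 photobleaching steps (unit step 21.02 arb. units); noise sd 3.08 over 900 frames
```

The six steps are recovered and the unit step (true mean 20 arb. units) is
calibrated from the pairwise-difference density; `glance(fit)` reports the
404,550 pairwise differences of the 900-frame trace, the density bandwidth,
and the qualifying-peak count, and `autoplot(fit)` / `autoplot(fit$pdd)`
draw the trace and the difference density.

A trace-level salt series, filtered and summarized:

```r
library(dplyr)
counts <- bind_rows(lapply(salt_series(), function(p) {
  count_steps(simulate_traces(200, condition_preset(p), seed = 101))
}))
summarize_conditions(counts)
#> # A tibble: 3 x 14
#>   condition  n_included n_unstable n_zero_steps  mean median   q25   q75   p10   p90 max_count
#> 1 0.2 M NaCl        194          6            0  5.94      6     5     7     4     8        12
#> 2 0.5 M NaCl        195          4            1  3.94      4     3     5     2     6         9
#> 3 1 M NaCl          173          3           24  2.16      2     1     3     1     4         7
```

The recovered means track the 6 / 4 / 2 subunits-per-intasome series, the
box (25th–75th percentiles), whiskers (10th/90th) and outliers match the
reporting convention (`autoplot()` on the summary draws the box-whisker
figure), and the zero-step exclusions concentrate at 1 M NaCl where a
binomial-occupancy intasome is most likely to carry no label at all.
A distribution-free comparison of the extreme conditions:

```r
compare_conditions(counts$k_steps[counts$included & counts$condition == "0.2 M NaCl"],
                   counts$k_steps[counts$included & counts$condition == "1 M NaCl"])
#>   statistic  p.value method                                     n_a   n_b
#> 1      15.1 3.36e-51 normal approximation with tie correction   194   173
```

`run_pipeline(run_config(...))` runs the image-level version end to end —
render two-channel fields, denoise (Gaussian, printed setting 5), subtract
rolling-ball background (r = 0.48 um), detect Cy3 spots (0.78 um aperture,
contrast 14.5), extract aperture-photometry traces, filter (Cy3 > 200
arb. units, unstable, zero-step, edge-clipped), count and summarize — and
writes `traces.csv`, `counts.csv`, `summary.json` and a config echo that
reproduces the run byte for byte.

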