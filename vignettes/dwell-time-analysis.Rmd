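---
title: "Single-molecule dwell-time analysis: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule dwell-time analysis: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfdwell)
```

## The measurement

A substrate protein carrying a C-terminal degron is captured from solution
by an AAA+ unfoldase (ClpX) immobilized on a passivated coverslip.  Under
total internal reflection illumination only the ~100 nm above the glass is
excited, so each captured, fluorophore-labelled substrate appears as a
diffraction-limited punctum that persists until the substrate dissociates.
When unfolding is blocked (a methotrexate-stabilized DHFR domain cannot be
threaded), dissociation is the only exit from the bound state and the
complex lifetime is a single-exponential variable.  The analysis therefore
reduces to: find puncta, follow each one across frames, measure how long it
lived, and fit the survival of those lifetimes.

`tirfdwell` implements that chain — detection, tracking, censoring filters,
robust exponential-CDF fitting — together with a ground-truth-annotated
movie simulator, so that every stage can be validated quantitatively
without access to raw imaging data.  Two bulk assays that complement the
single-molecule picture (photobleach-corrected degradation kinetics and the
NADH-coupled ATPase assay) and the SEG-style compositional complexity score
used to classify tail sequences are implemented as well.

## The movie simulator

`simulate_movie()` draws binding events as a spatio-temporal Poisson
process: arrival times uniform over the movie at
`arrival_rate_per_um2_s` events per square micron per second, positions
uniform over the field (with a margin so every punctum carries a complete
fit window), and dwell times exponential with mean `tau_true_s`.  Each
event is rendered in every frame it occupies for at least half the frame
interval, as a symmetric 2D Gaussian of width `psf_sigma_px` and a
per-event amplitude drawn once from
`Normal(amp_mean, amp_sd)`.  Pixel noise is Poisson on signal plus
background followed by additive Gaussian read noise.  Optional blinking
switches a present punctum dark per frame with probability
`blink_off_prob`, with dark runs capped at `blink_max_consecutive` frames
(3 by default — longer runs would defeat the 3-frame gap bridging rule and
are warned about).

Defaults are chosen to resemble the instrument class this emulates rather
than any particular data set: 0.065 um pixels (100x objective, 6.5 um
sensor pixels), 1 s frames, PSF sigma 1.3 px, amplitude 400 counts over a
100-count background with 2 counts read noise (peak signal-to-background
noise ratio ~40).  No public raw movies exist to calibrate against, so
these values are declared, not fitted; everything downstream is exercised
across a range of them in the test suite.  The generator refuses
configurations whose steady-state density `arrival_rate * tau` exceeds
1 punctum/um^2, the crowding bound the imaging regime is designed to stay
under.

What the simulator deliberately does **not** emulate: stage drift, uneven
(TIRF-fringe) illumination, fluorophore photophysics beyond simple
blinking, dye photobleaching (experimentally excluded as a contributor to
punctum decay), camera gain structure, and aggregates.  Tests passing on
synthetic movies therefore validate the *algorithms under the stated
model*, not robustness to every instrumental artifact.

## Detection

Each frame is scanned with a scale-normalized Laplacian-of-Gaussian filter
(`sigma^2 * -LoG`, five scales in 1–2 px by default).  For a Gaussian spot
the matched-scale response peaks at about half the spot amplitude, so the
candidate threshold is expressed relative to the frame's intensity range
(`log_threshold`, default 0.1).  Because that reference collapses on
frames that contain no real structure, candidates must additionally exceed
a noise floor of `log_noise_floor_k` (default 6) robust standard
deviations (1.4826 x MAD) of the response map.  Local maxima across scales
are merged within `2 sigma`, keeping the stronger.

Candidates are refined by Levenberg–Marquardt least squares of the
6-parameter Gaussian `A exp(-(x-x0)^2/(2 sx^2) - (y-y0)^2/(2 sy^2)) + b`
over a 13x13 px window.  A fit is invalidated when the window is clipped
by the image edge, the optimizer fails, the amplitude is non-positive, the
widths land outside 0.3–3x the detected blob scale, or the centre drifts
out of the window.  Two refined fits can land on the same punctum when two
scale-space maxima of one blob both survive candidate merging; fits within
`dedup_radius_px` (1 px) of a better fit in the same frame are therefore
dropped as duplicates.  Finally, per frame, detections brighter than
`max_amp_factor` (5) times the median fitted amplitude — aggregates,
multi-fluorophore particles — or with width ratio above `circ_ratio_max`
(2) — non-circular — are rejected.  The brightness and circularity cutoffs
operationalize qualitative criteria ("too bright", "extreme width
ratios"); both are configurable, and the filter is idempotent because the
median is always taken over all successfully fitted detections of the
frame.

## Tracking and the censoring filters

Detections are linked frame to frame by greedy nearest-neighbour
assignment within `link_radius_px` (2 px).  The molecules are
surface-immobilized, so distance is measured to the trace's *running
centroid* rather than its last fitted position; this makes linking robust
to single-frame localization disturbances when a transient neighbour
perturbs the fit.  A trace survives up to `max_gap_frames` (3) consecutive
missing frames — blinking, or a transiently failed fit — and then closes.
Ties are broken deterministically (lower detection row, then lower trace
id).

Four exclusion rules then set each trace's status, every removal carrying
a machine-readable reason:

1. **boundary** — traces touching the first or last movie frame have
   censored dwells;
2. **single_frame** — one-frame traces are likelier non-specific sticking
   or impurities than binding events;
3. **concurrent** — a trace born within 1 um of a trace alive on that
   frame is discarded: its punctum may be confused with its neighbour;
4. **repeat_site** — traces sharing a site (centroids within
   `same_site_radius_px`, default = link radius, since "the same
   coordinates" is necessarily a tolerance at sub-pixel precision) at
   *non-overlapping* times are all discarded: a repeatedly used site casts
   doubt on the uniqueness of every event there.

Each rule is evaluated against the full pre-filter trace set, so the kept
set is independent of evaluation order (the order only decides which
reason a multiply-excluded trace carries).

One design point deserves emphasis.  For rule 3 it is tempting to remove
*both* members of a concurrent pair.  But the resident member is then
removed at a rate proportional to its own lifetime: a trace alive for L
seconds is killed whenever any newcomer lands within the exclusion disc
during those L seconds, so survivors are selected for shortness and the
kept dwell distribution acquires an extra factor `exp(-lambda L)`
(`lambda = arrival density x pi r^2`).  At a steady-state density of
0.12 puncta/um^2 this deflates the fitted mean dwell by roughly 25% —
a large, density-dependent artifact.  Removing only the newborn trace
censors independently of the resident's dwell and is unbiased; it is the
default (`concurrent_both = FALSE`), with the both-removal variant
available as a configuration switch for sensitivity analysis.

The dwell of a kept trace is `(last_frame - first_frame + 1)` frame
intervals; bridged gap frames count as present (the punctum is deemed
bound while dark), switchable via `count_gap_frames`.

## The dwell model

`build_ecdf()` compiles dwells strictly below 120 s into an empirical
cumulative distribution evaluated at each *unique* dwell value (ties are
tallied, so each distinct dwell contributes one fitting point).
`fit_exponential_cdf()` fits

    F(t) = 1 - exp(-t / tau) + c,   |c| <= 0.025

by minimizing the sum of absolute residuals: iteratively reweighted least
squares with weights `1/max(|resid|, 1e-6)`, each weighted subproblem
solved by box-constrained quasi-Newton, initialized at the ECDF's mean
dwell, declared converged when tau moves by less than 1e-8 relative; a
derivative-free Nelder–Mead search on the raw L1 objective takes over on
IRLS non-convergence.  Internally the time axis is normalized by the mean
dwell so the optimizer sees the same problem whatever the units — this
makes tau-hat exactly equivariant under rescaling of the dwells.  `r2` is
the coefficient of determination over the ECDF points with uniform
weights.  No truncation correction is applied for the 120 s cutoff; for
`tau` around 30 s and above this biases tau-hat downward by a few percent,
and the bias grows quickly for longer dwells.

### The one-frame inflation

A structural property of this estimator is worth knowing about.  Removing
single-frame traces (rule 2) combines with the memorylessness of the
exponential so that, whatever convention decides in which frames an event
is visible, the kept dwells measured in frames are distributed as

    P(k <= t | k >= 2) = 1 - exp(-(t - 1) / tau)     (t in frames)

— an exponential shifted by exactly one frame.  (Any visibility-rule shift
cancels in the conditional distribution.)  Fitting the *unshifted* model
therefore inflates tau-hat by about one frame interval: roughly +20% at
tau = 5 s with 1 s frames, +10% at tau = 10 s, +3% at tau = 30 s.  The
package reproduces the method faithfully rather than correcting it, and
the parameter-recovery test measures exactly this: across simulated movies
(220 px field, steady-state density 0.12 puncta/um^2, ~1000 arrivals per
movie, 10 seeds per condition) recovered tau at 1 s frames carries the
predicted positive bias, comfortably within 15% at tau = 30 s but not at
tau = 5 s.  The practical mitigation is the one experimentalists already
use: shorten the frame interval when dwells are short, so that the
one-frame shift is small relative to tau.

`compare_taus()` wraps the standard inference used on replicate tau
estimates: a two-sample t test for two conditions, one-way ANOVA with
Tukey honest-significant-difference pairwise comparisons for three or
more, and a Bonferroni-adjusted per-contrast threshold `alpha/m` when m
planned contrasts are requested.

## Bulk kinetics

Degradation: fluorescence is normalized within each well to its first
point and divided by the matched bleach-control ratio
(`(F_t/F_0) / (F_t^ctrl/F_0^ctrl)`), which cancels the readout-flash
photobleaching exactly; the corrected fraction is fitted with the linear
model `F(t) = -k t + B` over the early time window (default: the first
20 percent of the course, where the linear model holds).  ATPase: the
optical pathlength is calibrated from an NADH standard series through
`Abs340 = 6.22 * lightpath * [NADH]` (extinction 6.22 per mM per cm), the
sample and PK/LDH-background slopes of Abs340 against time are fitted by
ordinary least squares, and the net rate is
`(|slope_sample| - |slope_bg|) / (6.22 * lightpath)` in mM/min — one NADH
oxidized per ATP hydrolyzed.  Dividing by the enzyme (hexamer)
concentration gives ATP/min/hexamer, and `atp_cost()` is the quotient of
the ATPase and degradation rates, the energy expenditure per substrate
degraded.  Time is minutes, concentrations mM throughout.

## Sequence complexity

`complexity()` scores a motif by the Shannon entropy of its residue
composition over the 20-letter amino-acid alphabet,

    K = -sum_i (n_i / L) log2(n_i / L)      (bits),

the entropy-form compositional complexity used by the SEG low-complexity
detector.  (SEG also defines a multinomial count-based variant; the
entropy form is the one whose values match the benchmark motifs this
implementation was validated against, e.g. GLGARSAGITH = 2.85,
AGAGGAAGAGG = 0.99, AKPSTEDLGDK = 3.10, homopolymers = 0.)  The score
depends only on the composition — scrambled and reversed variants score
identically — and is bounded by `log2(min(20, L))`.  Sequences above 2.5
bits (strict, on the unrounded score) are classified high-complexity;
display values are rounded to two decimals, the conventional reporting
precision.  The full SEG segmentation machinery (trigger and extension
windows, probability-based masking) is out of scope; `window_complexity()`
provides a plain sliding-window profile.

## Numerical choices and degenerate inputs

* Frames and pixel coordinates are 0-based; x is the column, y the row,
  with the origin at the centre of pixel (0, 0).  Microns enter only
  through `pixel_size_um`.
* The Gaussian fitter caps widths at 0.05 px from below during iteration
  and accepts a step only if it reduces the residual sum of squares
  (Levenberg damping grows 4x on rejection, shrinks 3x on acceptance).
* Flat fit windows (zero amplitude range) are reported as failed fits, not
  errors; an image smaller than the fit window yields an empty detection
  set with a warning.
* `build_ecdf()` refuses inputs with no dwell under 120 s; the fitter
  requires three distinct dwell values.
* Negative simulated plate values truncate the series at the last
  non-negative point with a warning, mirroring what a practitioner would
  do with a run-off assay.
* All randomness in a simulation flows from the single integer `seed` in
  its parameter object; identical parameters give bit-identical output.

## Problem sizes used in the checks

The validation suite runs entirely on synthetic data at deliberately
moderate scales: oracle-equality movies of 256 px / ~65 events, a
parameter-recovery study of 220 px movies with ~1000 arrivals each (10
seeds x tau in {5, 10, 30} s), detection-accuracy studies of 500 spots,
and 200-replicate noise studies for the plate fits.  These sizes were
chosen so each property is measured with useful statistical resolution;
all are configuration, not code, and scale up directly.

## Known limitations

* No correction for the 120 s truncation, the one-frame inflation, or
  events shorter than the temporal resolution (sub-second binding is
  invisible at 1 s frames); the method is reproduced as practised.
* Exact agreement between the image-level pipeline and the truth-table
  brute-force filter holds only while puncta are optically resolvable;
  two events closer than about two PSF widths while simultaneously bound
  are detected as one blob, a physical resolution limit rather than a
  rule disagreement (the 1 um concurrent-exclusion removes most such
  pairs from the kept set in any case).
* The tracker assumes immobilized molecules: no motion model, no
  merge/split handling, no drift correction.
* Single-exponential dwell model only; no censoring-corrected survival
  or multi-exponential mixtures.
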