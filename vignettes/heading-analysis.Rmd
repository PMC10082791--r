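---
title: "Analysing heading coding in rotating-chamber calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing heading coding in rotating-chamber calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headingcells)
```

## The experimental model this package analyses

A head-fixed animal sits at the centre of a walled chamber carrying visual
cues while two-photon calcium imaging records somatic and neuropil
fluorescence. In controlled-rotation sessions the chamber rotates around the
animal in blocks of roughly 90--120 s at 3--7 rpm, separated by 5 s
stationary rests during which the room lights may be switched; the first
block is always lit. Each completed 360° sweep is one *trial*. Because the
chamber (not the head) moves, the angle between animal and environment —
the *heading* — is fully controlled, and every trial samples the complete
circle of headings.

Three functional cell classes organise the analysis:

* **heading cells** — one tuning peak, present with lights on or off;
* **landmark cells** — two peaks 180° apart (the cue walls are two-fold
  symmetric), collapsing to baseline in darkness;
* **alignment cells** — two peaks in light, one surviving peak in darkness
  that coincides with one of the lit peaks.

The package implements the full path from raw fluorescence to population
statistics, and ships a synthetic-session generator with ground truth so
that every stage is testable end to end.

## The synthetic generator

`generate_session()` produces the per-frame chamber state (time, position,
speed, heading, light state, trial labels) at 10 Hz. Rotation speed
carries a small frame-to-frame jitter (2% by default): a perfectly rigid
rotation would sample the same 3° heading lattice on every trial, which
aliases against the 6° analysis bins and biases occupancy; physical
chambers show minor speed variation, which is exactly why the decoding
stage resamples trials to a common length. Voluntary (floating-chamber)
sessions are emulated as a bounded angular random walk with a persistence
parameter — the trajectory statistics of real voluntary navigation are not
modelled beyond giving irregular, full-coverage heading paths.

`generate_population()` draws cells with class labels, preferred directions
(uniform on the circle), and fluorescence parameters. Defaults are chosen
to be realistic for cortical GCaMP imaging and are stated in the function
signature rather than hard-coded: peak rate 10 spikes/s (20 in the high-SNR
benchmarks), baseline 0.5 spikes/s, circular-Gaussian tuning width 35°,
AR(1) calcium coefficient 0.85--0.95 at 10 Hz, neuropil contamination
fraction 0.3--0.7. The default class mix makes 12.1% of cells tuned, split
33% landmark / 28% alignment / 22% heading (the tuned remainder is folded
into the heading class as the nearest archetype). The secondary
(cue-symmetric) peak of landmark and alignment cells has 0.7 of the primary
amplitude: two exactly equal peaks are a degenerate configuration in which
no decoder can beat 50% on single frames, and freely fitted peak amplitudes
in real bimodal cells are unequal.

`simulate_traces()` is the forward model: Poisson spikes from the class-
and light-dependent rate map, AR(1) calcium convolution, somatic
fluorescence = baseline + calcium + Gaussian noise + alpha times the shared
neuropil signal. The neuropil trace is a slow (about 2 s correlation time)
background process common to all cells but independent of any one cell's
spiking. What the generator does **not** emulate: motion and derotation
artifacts, slow drift and bleaching, correlated network noise, skewed
firing-rate distributions, and ROI segmentation errors. Tests passing on
this generator therefore validate the statistical machinery, not robustness
to those real-data nuisances.

## Trace processing

*Neuropil correction* subtracts the scaled, mean-centred neuropil trace,
with the scale factor chosen in [0, 1] to minimise the absolute Pearson
correlation between corrected and neuropil traces (golden-section search;
the objective has a single interior minimum, and the endpoints are checked).
With a somatic signal independent of the background this recovers the true
mixing fraction; note that over a finite session any slow somatic signal has
non-zero sample correlation with a slow background, so estimates on strongly
modulated cells carry a positive bias of order the chance correlation — an
intrinsic property of correlation-based correction rather than an
implementation artifact.

*dF/F* uses the mode of the corrected-fluorescence density (Gaussian kernel,
Silverman bandwidth, argmax on a 2048-point grid) as the baseline F0. The
mode is robust to activity transients, which inflate the mean and skew the
median upward.

*Deconvolution* inverts the AR(1) kernel (`s_t = y_t − γ y_{t−1}`) and keeps
innovations above a noise threshold (2 robust SDs of the innovation series;
zero for noiseless input, making the inversion exact). The decay coefficient
defaults to a fixed γ = 0.9 (≈1 s indicator decay at 10 Hz) rather than an
autocorrelation-based estimate: when firing is dominated by a tuning bump
swept at rotation speed, the trace autocorrelation mixes the calcium decay
with the (slower) rate modulation, and the acf-ratio estimator saturates
near 1, leaving residual temporal smear that biases preferred directions in
the direction of rotation. The estimator remains available as
`gamma = "auto"` for data without stimulus-locked slow structure.

*Deduplication* groups ROIs whose dF/F correlation exceeds 0.5 into
connected components and keeps the highest-variance member of each — a
conservative reading of "all but one excluded" that never leaves two
correlated survivors.

## Tuning curves and selectivity

Tuning curves use 60 bins of 6°, per-trial spike rates, and a circular
moving-average filter. The nominal 15° window is not an integer number of
6° bins; it is realised as a 3-bin (18°) boxcar, the closest odd-width
choice, and the width is configurable. The preferred direction is the argmax
of the smoothed mean curve refined by parabolic interpolation through the
peak bin and its neighbours; without the sub-bin refinement, grid
quantisation alone contributes ±3° of error, which is most of the one-bin
recovery budget.

Two selectivity tests serve the two session types. For voluntary sessions,
the Rayleigh vector length of the tuning curve is compared with the 99th
percentile of curves recomputed after circular time-shifts of the spike
series. This shuffle assumes an irregular trajectory: under strictly
periodic rotation a time shift preserves tuning and the test has no power
by construction, so rotation sessions instead use the trial-based test:

1. *Reliability.* Trials are repeatedly split in half and the two half
   curves correlated ("real" distribution); the null repeats this after
   circularly shifting each trial's curve by an independent random lag. The
   distributions are compared by a two-sample KS test (must reject at
   p < 0.1) and Cohen's d (pooled SD, must exceed 0.8), both strict.
2. *Shape.* A one-term (single cue) or two-term (dual cue) Gaussian is fit
   to the trial-averaged curve; its r² must exceed the 90th percentile of
   fits to shuffled trial averages.

Because the verdict is a conjunction, the Gaussian stage is skipped when
reliability already failed, and the shuffle loop stops as soon as enough
shuffle fits reach the real r² to fix the verdict — both shortcuts are
exact. One calibration property deserves note: under the null, the "real"
distribution (fixed data, split randomness only) is systematically narrower
than the shuffle distribution (fresh shift randomness each repetition), so
the KS stage rejects for almost every cell regardless of tuning, and the
false-positive rate is effectively governed by the Cohen's d and r² stages,
whose null exceedances are positively dependent. The package's acceptance
benchmark (`benchmark_null_selectivity()`) measures the realised rate
rather than assuming the nominal product of stage levels.

Cross-validated alignment rotates each trial by the peak of the remaining
trials' mean curve onto a common reference bin; light-off curves (which may
have a different trial count) are rotated by the cell's overall light-on
peak offset, so both conditions share one circular offset.

## Remapping and bimodality

The per-cell phase offset between two cue contexts is the circular
difference of preferred directions; the *delta phase offset* subtracts the
population's expected offset estimated from all other cells. The default
aggregates leave-one-out per-cell offsets with a circular median
(difference-then-aggregate), which is invariant to a common rotation of
either context; the aggregate-then-difference variant (difference of
leave-one-out medians of the preferred directions themselves) is exposed
behind `method = "pref_median"` but is not rotation-invariant for circular
data. The circular median minimises mean circular absolute deviation over
the data angles, with exact ties resolved by the circular mean. For the
leave-one-out medians a stability anchor is added: when two minimisers are
tied within the influence a single removed point can exert (2·180/(n−1)),
the candidate nearest the full-sample median is taken. On concentrated
(scientifically meaningful) offset distributions the anchor never fires; on
near-uniform data it prevents the leave-one-out median from flipping
between distant minimisers in a way that correlates with the held-out cell
and distorts the shuffled-pair control.

The flip score quantifies 180° symmetry as the circular autocorrelation at
180° minus the mean of the 90° and 270° autocorrelations — exactly lags 30,
15 and 45 on the 60-bin grid. Closed forms anchor the scale: cos 2θ gives
2, cos θ gives −1. Group comparisons of flip scores use a one-way
variance-ratio (ANOVA) F-test with df (1, n₁+n₂−2). The V-test for circular
clustering around a hypothesised direction uses the projected resultant
V = n·R̄·cos(θ̄−μ₀) with the one-sided normal approximation of
u = V·√(2/n).

## Functional classification

Each cell's aligned, light-on-peak-normalised mean curves (both conditions
share the light-on normalisation, so responses that collapse in darkness
keep small dark amplitudes) are fit with the sum of two circular Gaussians;
the clustering feature vector is (a1, c1, a2, c2) for light-on followed by
light-off — 8 dimensions, with peak locations deliberately excluded so that
preferred direction cannot drive membership.

The free two-term fit is unidentifiable on unimodal or flat curves: the
second term can shadow the first peak or model baseline with an arbitrary
width. Coefficients are therefore canonicalised before clustering: a second
term counts as a genuine second peak only if its amplitude is at least 0.1,
its location at least 60° from the first peak, and its width at most 120°;
otherwise the curve is refit with one term, a2 is 0, and the undefined
width is recorded at the neutral 30°. Near-flat conditions have their width
neutralised the same way. Without this step, junk width coefficients either
merge the landmark and alignment classes or spawn a spurious extra cluster.

Gaussian mixtures are fit for k = 2..8 and k selected by mean silhouette
width. Distances use natural units — amplitudes as-is (order one after
normalisation), widths divided by 100 — rather than z-scores, which would
inflate pure-noise dimensions to unit variance and drown the informative
amplitude contrasts. Cells whose minimum squared Mahalanobis distance to
any component exceeds the 0.99 chi-square quantile (df = feature dimension)
form the null cluster; `classify_new_cells()` applies the same rule to
held-out data such as axonal features.

Archetypal curves are reconstructed per cluster from cluster-mean
coefficients (first peak at the reference bin, second at its antipode), and
cells are labelled by the archetype with the smallest summed cosine
distance over both conditions. Because the dual-cue world is 180°
symmetric, a cell's surviving dark peak may sit at either lit peak, so the
light-off distance takes the minimum over the archetype curve and its 180°
rotation. Archetype semantics are decided only by measurable shape — the
light-on bimodality ratio a2/a1 (threshold 0.5) and the light-off amplitude
(threshold 0.35) — never by cluster index. An LDA projection of the
features provides a 2-D visualisation; it plays no role in assignment.

## Population decoding

Full-rotation trials are resampled to 200 time bins (linear interpolation;
heading unwrapped before interpolation so the 359°→1° crossing is clean).
Decoding uses a naive Bayes decoder over the 60 heading bins: even time
bins train per-cell, per-bin activity models; odd bins are decoded to the
maximum-posterior bin under a uniform prior, and only test bins are
reported. The default likelihood is Poisson on inferred spikes (the natural
model for deconvolved activity); a Gaussian variant on continuous traces is
available behind `likelihood = "gaussian"` for parity checks.

Decoder error is the absolute circular difference (in [0, 180]); accuracy
is the fraction of frames with error below 18°, computed per trial, giving
a chance level of 36/360 = 0.10. Class-wise decoding samples bootstrap
pseudopopulations — each iteration draws, with replacement, as many cells
as the smallest class, or across classes at their empirical proportions for
the "all tuned" mode — and summarises accuracies with percentile 95% CIs;
significance against chance is CI exclusion, and the median-performance
iteration is identified for representative plotting.

One structural caveat: with a single decoder trained across both light
conditions, alignment cells whose dark peak coincides with the *secondary*
lit peak dilute their own light-on maps, so under equal class signal-to-
noise the light-on ordering is heading > landmark > alignment. Real
recordings show landmark > alignment > heading instead, which implies
weaker real heading-cell SNR; the generator makes no such class asymmetry
because no quantitative basis for it is available, and the benchmark
reports the pattern actually measured.

## Problem sizes and numerical choices

The shipped tests and benchmarks run at desk scale, chosen to finish a full
check in minutes on one core: sessions of 4--6 repeats (about 8--48 trials),
populations of 60--150 cells for classification and decoding, 200
split/shuffle repetitions (the full protocol value of 1000 is a
configuration switch), 2000 null cells for the selectivity calibration, 20
seeds for cluster-number and remapping calibrations, and 10^6 frames for
the decoder chance level. Degenerate inputs are handled explicitly:
constant traces (dF/F defined via the constant baseline; shuffle tests
declare no selectivity), zero-spike cells (flagged undefined), zero-variance
curves (flip score 0 with a degenerate flag), empty heading bins (excluded
from trial averages), and unvisited decoder bins (excluded from the state
space with a warning).

## Known limitations

* The generator's simplifications listed above mean calibration results
  transfer to real data only to the extent that real nuisances (drift,
  correlated noise, segmentation artifacts) do not interact with the tested
  statistics.
* The trial-based selectivity test inherits the width asymmetry between its
  real and shuffle distributions; its realised false-positive rate is an
  empirical property measured by the benchmarks, not a nominal level.
* Neuropil-alpha estimates on strongly tuned cells carry the chance-
  correlation bias discussed above; the recovery benchmark quantifies the
  estimator on independent-signal mixtures.
* The classification thresholds (bimodality ratio 0.5, flat amplitude 0.35,
  canonicalisation limits 0.1 / 60° / 120°) are stated constants; they were
  chosen from the geometry of the archetypes, and sensitivity to them is
  not explored automatically.
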