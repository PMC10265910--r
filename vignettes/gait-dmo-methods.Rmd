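---
title: "Methods: gait detection, cadence and stride length from a lower-back accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait detection, cadence and stride length from a lower-back accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdmo)
```

## The problem

A single accelerometer on the lower back, close to the body's centre of
mass, records hours of unsupervised daily life. Extracting digital mobility
outcomes from such data is a cascade: classify which stretches of signal
are walking at all (gait sequences), locate the foot-strike events inside
them (initial contacts, ICs), and derive cadence and stride length per
walking bout. Each stage has several published algorithms; this package
implements a representative, optimized suite of them plus the statistical
machinery used to compare algorithms against a reference system.

All signals are triaxial acceleration in g — vertical (positive up,
including the +1 g gravity component), anterior–posterior (positive
forward) and medio-lateral — at a nominal 100 Hz. Every event time is in
seconds from the start of the recording; the sample index of time $t$ is
$\mathrm{round}(t \cdot F_s)$.

A **walking bout** (the reference-side unit of comparison) contains at
least two strides per foot, each stride lasting 0.2–3 s and covering at
least 0.15 m, with consecutive bouts separated by rests of 3 s or more.
Strides violating these rules are dropped on load, not clipped.

## Detection algorithms

### Gait sequences

*Frequency-domain route ("a").* The vertical and AP axes are band-passed to
the gait band (0.5–3 Hz, zero-phase windowed-sinc FIR) and convolved with a
one-cycle 2 Hz sine template — a matched filter for a gait cycle. Windows
of 3 s, hopped by 1.5 s, are flagged when the template response exceeds the
activity threshold (0.01 g standard deviation) and shows at least two
gait-band maxima. Flagged windows are unioned; because windows are
hop-quantized, each sequence is then trimmed to where the response envelope
actually exceeds the threshold, with hysteresis at one third of the
sequence peak so that filter ringing does not pad the edges. Sequences
separated by less than 3 s merge.

*Time-domain routes ("b", "c").* The acceleration norm is low-passed
(FIR, 3.2 Hz), the median norm (≈ 1 g) subtracted, and peaks above a fixed
threshold — 0.1 g for "b", 0.15 g for "c" — are taken as step candidates.
Consecutive peaks group into a sequence while the inter-peak gap stays
below an adaptive step-duration threshold,
$\min(\max(1.5 \cdot \mathrm{med}_5, 0.5), 3)$ s with $\mathrm{med}_5$ the
running median of the last five inter-peak intervals; groups need at least
four peaks (two strides per foot). Sequence boundaries extend a fixed
0.3 s beyond the first/last peak: an earlier data-driven margin (half the
median inter-peak interval) grew when weak steps dropped out and thereby
broke the property that raising the peak threshold never increases total
detected gait time.

### Initial contacts

*Vertical-axis wavelet route ("a").* Inside a gait sequence the vertical
acceleration is detrended, low-passed (FIR 3.2 Hz), integrated
(cumulative trapezoid), and differentiated by convolution with a
derivative-of-Gaussian wavelet at scale 9 samples (rescaled by
$F_s/100$). ICs are the positive maxima between consecutive
zero-crossings.

The wavelet order deserves a note, because the literature is loose about
it. Integrating once and differentiating once returns the
Gaussian-*smoothed acceleration*, whose maxima coincide with the
IC-aligned acceleration peak — a zero-phase operation. Differentiating the
integrated signal *twice* (a second-derivative wavelet) instead yields an
odd net derivative of the acceleration; for any near-periodic signal its
positive peaks sit a quarter step period away from the acceleration peak,
a systematic ≈ 0.1–0.15 s timing bias that is irreconcilable with the
≈ 0.05 s absolute errors this algorithm family is validated to. We
therefore use the first-derivative wavelet for IC timing (second-derivative
wavelets belong to final-contact detection).

All filters in timing-sensitive paths are zero-phase (symmetric FIR
kernels, or forward–backward Butterworth), because IC validation uses a
±0.25 s half-tolerance and any phase lag would eat directly into it.

*AP-axis route ("b").* Same skeleton on the AP axis with a zero-phase
2nd-order Butterworth low-pass at 10 Hz; the wavelet scale is estimated
from the data as $F_s / (2\pi f_{dom})$, with $f_{dom}$ the periodogram
maximum in 0.5–3 Hz.

*Impairment-adaptive route ("c").* Dispatches on the symmetry index (below):
above 0.5 the vertical route runs unchanged; between 0.25 and 0.5 one
0.15 s moving-average pass is added after the wavelet; below 0.25, two
passes. The 0.15 s window sits below the 0.2 s minimum step interval so
true events survive the smoothing.

*Norm zero-crossing route ("d").* The norm is denoised with a 0.1 s moving
sum and the gravity baseline removed with a differential high-pass
(subtraction of a 1 s moving average); ICs are the upward zero-crossings —
the instants the norm rises through its local mean toward the impact peak.
A one-sample first difference was considered for the baseline removal, but
upward zero-crossings of a derivative mark local *minima* of the norm
(mid-swing), half a step away from every IC; the moving-average reading
keeps the event on the rising flank, a quarter step before the peak, inside
the matching tolerance. Event counts and cadence are identical under both
readings.

*Symmetry index.* Step-to-stride regularity from the unbiased
autocorrelation of the detrended vertical acceleration:
$SI = A(\tau_{step}) / A(\tau_{stride})$ clipped to $[0, 1]$, where the
step lag comes from the dominant gait frequency and both autocorrelation
values snap to the nearest local peak (±20% of the step lag). Degenerate
signals return NA and callers fall back to 1. For an amplitude-modulated
step train with alternate-step ratio $a$ (modulation depth
$m = (1-a)/(1+a)$) the index is approximately $(1 - m^2/2)/(1 + m^2/2)$ —
mild asymmetry barely moves it, which is why only strongly asymmetric gait
(ratio below ≈ 0.2) reaches the smoothing branches.

*Refinement.* A sequence refined by its ICs starts 1 s before the first IC
(floored at 0) and ends 1 s after the last (capped at the recording end).
Detectors read at most this 1 s margin beyond the bout they are given — a
contract the tests enforce by corrupting samples outside it. IC lists are
strictly increasing; events closer than 0.2 s (the stride-validity floor)
merge to the earlier event.

### Cadence

Strides are built from alternate events of the unlabeled IC train
($t_{k+2} - t_k$, so left and right strides interleave). Stride frequency
is the mean of $60 / d_k$ over stride durations $d_k$; cadence in
steps/min is exactly twice that — an identity the tests assert bout by
bout. The per-second trace (no method is prescribed for it) assigns the
instantaneous step rate $60/\Delta t$ to each step midpoint, interpolates
linearly, and averages within 1 s tiles.

Route "b" segments steps directly: norm → FIR 3.2 Hz → detrend →
Savitzky–Golay (order 7, 21-sample frame, frame rescaled by $F_s/100$ and
forced odd) → Gaussian smoothing (20 ms) → Mexican-hat wavelet at scale 10
→ grayscale morphological opening then closing with a flat 0.1 s element →
maxima between zero-crossings. The element length was originally
specified at 0.25 s; that erases the entire step train above ≈ 120
steps/min (the positive wavelet lobe of a 0.43 s step is ≈ 0.21 s wide),
so 0.1 s is used: it still suppresses sub-0.1 s artifacts — the spike-
rejection job the stage exists for — while preserving the shortest valid
step. Note that a ≥ 0.05 s spike is mostly neutralized before morphology
anyway: the 3.2 Hz band limit spreads it into a low bump that the wavelet
and opening absorb.

### Stride length

All models convert to m/s² internally (1 g = 9.80665 m/s²); integration
needs SI units.

*Inverted pendulum ("a", "b").* The vertical axis is detrended and
high-passed at 0.1 Hz, integrated to velocity, high-passed at 1 Hz,
integrated to position (all zero-phase, cumulative trapezoid). Per step,
$h$ is the max–min of vertical position between consecutive ICs, and the
stride length is $k \sqrt{2 l h - h^2}$ with leg length $l$. The
calibration factor's algebraic placement is not printed in its source; we
place it at stride level, where $k \approx 4.7$–$5.0$ with typical
$h \approx 0.02$ m and $l \approx 0.9$ m yields strides of ≈ 0.9 m,
matching the magnitudes reported for these cohorts. Route "a" uses
$k = 4.739$ for all cohorts; route "b" uses $k = 4.99$, or $4.587$ for the
MS cohort. Steps with $h \ge 2l$ are clipped to zero and flagged, as are
steps shorter than 0.1 s.

The 1 Hz velocity high-pass is part of the printed cascade and has a
deterministic cost: zero-phase filtering squares the magnitude response,
so the step-frequency component is attenuated by
$1/(1 + (1\,\mathrm{Hz}/f_{step})^4)$ — about 50% at 60 steps/min, 12% at
100, 3.5% at 120. Stride length inherits roughly half that error (square
root). This is why slow-cadence fixtures carry a ≈ 20–25% negative bias
that no implementation of the printed filters can remove, and why
suite-level stride-length accuracy is summarized by the median over bouts
(the error analyses in this field are median-based) rather than the worst
bout.

*Intensity models ("c", "d").* Route "c": per step,
$t \cdot \bar{|a_v|}^{1/3} + p$ with $t = 0.93$ and $p$ = foot length.
Route "d": the mean of the AP double-integration displacement (same filter
cascade) and the geometric model $t \cdot (a_{max}-a_{min})^{1/4} + p$
with $t = 0.85$; the vertical range is taken on the 3.2 Hz band-limited
signal so that impact transients do not dominate it. The printed formulas
are unit-ambiguous; we evaluate them in m/s² as printed and note that the
resulting absolute values are implausible (1 m/s² mean intensity gives a
1.18 m "step"), which is consistent with these routes ranking last — the
suite's tests assert the ordering (pendulum best, hybrid worst), not an
absolute accuracy these formulas cannot deliver.

Per-step lengths sum to the covered distance (asserted); a stride length
is the sum of two consecutive step lengths; per-second values tile the
bout like the cadence trace.

## Validation framework

*Windowed classification.* The recording is tiled into 0.1 s windows; a
window is gait for a system when more than half of it lies inside a gait
interval (majority overlap — the boundary convention is not prescribed, and
majority is the symmetric choice). TP/TN/FP/FN then feed accuracy,
sensitivity, specificity and PPV; undefined ratios are NA, never 0. The
implementation is checked against an exhaustive per-window enumerator on
random interval configurations.

*IC matching.* Each reference IC owns a 0.5 s tolerance window centred on
it (±0.25 s, about a step duration). Reference events are processed in
time order; the nearest unused detected event inside the window is the
true positive, ties break toward the earlier detected event, and every
detected event is consumed at most once. Leftover reference events are
FN, leftover detected events FP; true negatives are undefined for event
detection. Absolute errors are recorded per TP; relative errors divide by
the bout's mean reference step duration. Equivalence with a brute-force
matcher is asserted on 500 random instances.

*Agreement.* Bland–Altman bias and bias ± 1.96 SD limits; mean absolute
error; relative error with a t-based 95% CI; ICC(2,1) — two-way
random-effects, absolute-agreement, single-measure — computed from
hand-rolled ANOVA mean squares and verified to 1e-10 against R's ANOVA
machinery, with the standard F-based confidence interval.

*Error-versus-covariate curves.* Per-bout absolute relative errors are
binned by walking speed (0.05 m/s) or bout duration (2 s); bin medians are
weighted by their observation share and fitted with
$y = a e^{b x}$ (log-linear start, `nls` refinement), reporting $a$, $b$
and weighted $R^2$.

## Ranking

A decision matrix holds one row per algorithm and one column per measure,
each tagged benefit (larger better: accuracy, sensitivity, specificity,
PPV, ICC) or cost (errors). Costs are inverted to benefits by min–max
normalization across algorithms (constant columns map to 1); the
performance index is the weighted mean over non-missing measures, in
[0, 1], ranked descending with alphabetical tie-break. The original
study's exact weights live in a supplement that is not part of the main
text, so weights are configuration-driven with equal weights as the
shipped default; whether costs should be normalized per cohort or globally
is likewise open — we normalize within each decision matrix, i.e. per
ranking call.

## The simulator: a stated world

`generate_recording()` synthesizes what the detectors assume and nothing
more. During a bout the vertical CoM position is
$-\frac{h}{2}\cos(2\pi f_{step} t)$ — lowest at each IC — with $h$ solved
from the inverted-pendulum relation for the requested stride length and
leg length (default 0.9 m) using the generative constant
$k_{gen} = 4.739$; vertical acceleration is the exact second derivative
plus gravity. Each IC also carries a 30 ms, 0.3 g Ricker-shaped impact
transient. The transient is zero-mean with zero first moment on purpose: a
unipolar pulse would inject ≈ 0.02 m/s of net velocity per step, which
corrupts the pendulum ground truth and makes forward/inverse consistency
(double integration recovering $h$ within 2%, a tested invariant)
impossible. AP acceleration oscillates at step frequency (braking peak at
IC, amplitude 0.6 × vertical + 0.02 g floor), ML sway at stride frequency
(0.02 g). Asymmetry multiplies all amplitudes by a stride-frequency
envelope with mean 1 whose alternate-step ratio is the requested value.
Rest is gravity plus white noise; noise is seeded per protocol, so equal
seeds give bit-identical recordings and truth is always noise-free.

The standard fixture suite crosses cadence {60, 80, 100, 120, 140}
steps/min, stride length {0.45, 1.2} m (walking speeds 0.225–1.4 m/s,
including the < 0.5 m/s regime), nominal durations {5, 10, 30, 60, 120} s,
asymmetry {1.0, 0.5} and noise {0, 0.02, 0.05} g — 300 single-bout
recordings with 8 s rest margins.

What the simulator does *not* emulate — turning, stopping mid-bout,
postural transitions, walking aids, sensor misplacement, soft-tissue
artifact — bounds what a green test establishes: correct implementation of
the signal-processing chain and exact bookkeeping, not clinical
performance. Conversely, two red acceptance expectations encode limits of
the stated world itself rather than defects:

1. **Slow bouts are invisible to the 0.1 g peak detector.** Pendulum
   physics ties $h$ to stride length; short slow strides give
   $h \approx 4$–10 mm and vertical amplitudes of 0.01–0.07 g. After the
   3.2 Hz low-pass (which also annihilates the zero-mean impact
   transients) nothing crosses the fixed 0.1 g threshold, so the
   time-domain gait detector cannot reach 0.95 sensitivity over a suite
   containing such bouts — consistent with the 0.60–0.73 sensitivities
   reported for the slowest real cohorts. The detector does reach ≥ 0.95
   sensitivity and specificity on the fixtures whose weakest step exceeds
   the threshold, which is asserted separately.
2. **2 s duration bins confound composition with duration.** The suite's
   nominal duration levels land in different 2 s bins per cadence (a 6 s
   bin holds only 60 steps/min bouts — the worst-error cadence), and the
   stride-length error of steady-state gait is duration-flat, so
   bin-median monotonicity fails on tenth-of-a-point wiggles. Under
   matched composition (grouping by nominal duration level) the cadence
   error decreases cleanly with duration, which is asserted as a regular
   test.
3. **Stride-length error is speed-flat in a factorial world.** The
   dominant stride-length error is the cadence-dependent high-pass
   attenuation, and the fixture grid crosses cadence with stride length,
   so both speed groups contain every cadence and their medians coincide
   (7.0% below 0.5 m/s vs 7.3% above). Real slow walking couples slow
   speed with slow cadence and unsteady gait — a correlation the grid
   deliberately removes — which is where the reported slow-speed
   degradation of stride length comes from. The cadence errors do degrade
   with slow speed here (low-amplitude signals under noise), and that
   direction is asserted and green.

## Numerical choices

- FIR filters: Hamming-windowed sinc, order $\lceil F_s \rceil$ (order
  $3 F_s$ for the 0.5 Hz band edge), unit DC gain, applied by centred
  FFT convolution with reflection padding — zero-phase by symmetry.
- IIR: 2nd-order Butterworth via bilinear transform (coefficients frozen
  in tests against an independent design), forward–backward.
- Integration: cumulative trapezoid; drift control only via the stated
  high-pass cutoffs.
- Peak picking: strict-left/weak-right local maxima; minimum-distance
  pruning keeps the larger peak, ties to the earlier.
- Degenerate inputs short-circuit: flat segments return empty event lists
  rather than amplifying numerical noise through the wavelet stage.
- Tie-breaks: IC matching ties to the earlier detected event; ranking
  ties alphabetically.

## Known limitations

- Left/right foot attribution and final contacts (toe-off) are out of
  scope; strides from unlabeled IC trains rely on alternation.
- The intensity-based stride-length routes reproduce printed formulas
  whose units are ambiguous at source; treat their absolute outputs as
  relative-comparison material only.
- The simulator's pendulum link between speed and vertical amplitude is
  deliberate physics, but it makes slow-gait amplitudes smaller than real
  recordings, where posture and tissue dynamics add low-frequency power;
  real-world sensitivity of the threshold-based gait detector will exceed
  the simulated one at equal speeds.
- Cohort-level clinical results require the real multi-centre dataset and
  reference hardware and are not reproducible here; the package reproduces
  the machinery, not the cohort numbers.
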