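---
title: "Methods: eye-movement analysis of visual search for spatial-frequency-defined targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye-movement analysis of visual search for spatial-frequency-defined targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesearch)
```

# Overview

`gazesearch` implements the analysis chain of a visual-search experiment in
which observers look for small artificial targets — differing in spatial
frequency and orientation — embedded in natural scenes, while their gaze is
recorded at 1000 Hz. The package covers five analysis stages plus a
synthetic-data generator used for end-to-end validation:

1. **Target synthesis and embedding** — six parametric stimuli (Gaussian
   blob, positive/negative Mexican hat, vertical/horizontal Gabor, Gabor
   cross), contrast-calibrated luminance embedding, and placement on a
   grid of candidate positions.
2. **Saccade detection** — a velocity-based algorithm with median-based
   standard-deviation thresholds; the epochs between saccades are
   fixations.
3. **Scanpath dynamics** — saccade-amplitude and fixation-duration
   aggregates by target type and session, ordinal time-courses
   (coarse-to-fine), and intersaccadic-angle analyses.
4. **Fixation-density estimation** — Gaussian-kernel density maps on a
   128 x 128 grid with leave-one-subject-out (LOSO) cross-validated
   bandwidth, scored as mean log-likelihood relative to a uniform map.
5. **Patch spectra** — 79 x 79-pixel luminance patches at fixated
   locations versus cyclically shifted control locations, compared via
   2-D amplitude spectra.

All length units are degrees of visual angle (dva); the pixel scale
defaults to 1200 px / 31.1 dva = 38.585 px/dva (a 1200 x 960 px image
spanning 31.1 x 24.9 dva). Durations are milliseconds, velocities dva/s,
spatial frequencies cyc/deg.

# Target synthesis

Each target is rendered on an odd-sized pixel grid centred on its peak,
then normalized to unit amplitude, `max(abs(T)) == 1`:

* **Gaussian blob** — isotropic Gaussian, spatial SD 0.4 dva. Its
  amplitude spectrum is again Gaussian with frequency SD
  $\sigma_f = 1 / (2\pi\,0.4) = 0.3979$ cyc/deg, which the package
  recovers from the rendered patch to within a fraction of a percent
  (`spectrum_gaussian_sigma()`).
* **Mexican hats** — difference of two isotropic Gaussians with SDs 0.2
  and 0.4 dva; the negative hat is the elementwise negation of the
  positive one and shares its amplitude spectrum exactly. The components
  are *unit-integral* Gaussians, which makes the stimulus zero-mean in
  the continuum (and near zero-mean on the finite grid) and places the
  spectral peak at $\sqrt{\ln 4 / (2\pi^2 (0.4^2 - 0.2^2))} \approx
  0.77$ cyc/deg. Unit-peak components would give a different (smaller)
  band-pass peak; we chose unit-integral because only it yields the
  stated near-zero mean without an explicit DC correction.
* **Gabors** — cosine carrier at 8 cyc/deg times an elliptic Gaussian
  envelope with SDs 0.06 dva (across the bars) and 0.32 dva (along
  them); the horizontal Gabor is the transpose of the vertical one, and
  the cross is their mean (each at half contrast). The spectral peak
  sits at 8 cyc/deg with a broad bandwidth of
  $1/(2\pi\,0.06) \approx 2.7$ cyc/deg across the carrier axis.

The default patch support covers ±4 SD of the widest Gaussian component,
so truncation error is below $10^{-3}$ of the peak; rendering fails if
the support cannot hold ±3 SD.

**Luminance embedding.** Backgrounds are converted from 8-bit gray to
luminance by a power function $L = L_{max} (g/255)^{\gamma}$ (gamma
configurable, default 2.2 as a generic CRT value), rescaled to
$[\alpha, 1-\alpha] L_{max}$ and combined with the target $T$ at
luminance amplitude $\alpha L_{max}$:

$$I_{fin} = \alpha L_{max} + (1 - 2\alpha)\, I_L + \alpha L_{max}\, T,$$

which never leaves $[0, L_{max}]$ for $\alpha \in [0, 0.5]$ (verified by
a 1000-case property test). In experiments of this kind the per-target
contrast $\alpha$ is calibrated in a pilot so that detection sits near
threshold (around 75–80% correct); the package default of 0.15 is an
arbitrary mid-range choice — treat $\alpha$ as a required configuration
parameter for any quantitative use.

**Placement.** A 4 x 2 grid of rectangles is laid over the image and one
integer pixel position is drawn uniformly per rectangle, at least 100 px
from every image border. Pixel coordinates are 1-based (R convention),
with x rightward (columns) and y downward (rows).

# Saccade detection

Velocities are estimated per component with a centred moving-window
least-squares slope (default window 5 samples), which also smooths
sample noise; edges use truncated symmetric windows. A sample is
saccadic when it exceeds the per-trial threshold of $\lambda = 6$
median-based standard deviations,
$\sigma = \sqrt{\langle v^2\rangle_{med} - \langle v\rangle_{med}^2}$,
around the median velocity — jointly over both components by the
elliptic criterion
$((v_x - m_x)/\lambda\sigma_x)^2 + ((v_y - m_y)/\lambda\sigma_y)^2 > 1$
(a pure speed-magnitude criterion is available). "Average velocity" is
read as the median, the robust centre consistent with the median-based
spread; the arithmetic mean is an option. A constant trace has zero
median-based dispersion and raises an error rather than producing a
zero threshold.

Supra-threshold runs separated by less than 12 ms are merged (avoiding
splits on single sub-threshold samples), runs of at least 6 samples
(6 ms at 1000 Hz) become candidates, and candidates below 0.5 dva are
discarded. Event boundaries are then refined by walking outward to the
nearest local minimum of the speed profile, and the event's start/end
positions are averaged over a few settled fixation samples strictly
outside the event (samples 2–6 beyond each boundary). This matters
quantitatively: threshold crossings alone clip the slow tails of the
velocity profile and bias amplitudes several percent low, while the
refined estimate recovers generator ground truth with a maximum error
below 0.2 dva in the round-trip tests.

Fixations are the epochs between saccades (plus the leading and trailing
epochs); fixations shorter than 50 ms are removed as glissades, and the
first fixation of each trial is flagged so time-course analyses can
exclude the experimentally enforced initial fixation (125 ms at a random
position, used to counter the central fixation bias).

Velocity-threshold detectors of this family vary in their smoothing
window and threshold-centre conventions; both are exposed as parameters
rather than hard-coded.

# Scanpath dynamics

Trial-level summaries (mean saccade amplitude, mean fixation duration,
search time, detection) are aggregated per target kind or per
spatial-frequency class (blob and hats = low; Gabors and cross = high;
trials with unknown target identity form their own class) and per
session. By default trials are first averaged within subject and the SEM
is taken over subjects — the usual error-bar convention for
repeated-measures designs; pooled aggregation is available. Detection is the hit
proportion among target-present trials; false alarms are reported
separately over absent trials.

The change in saccadic direction between successive saccades is the
absolute angular difference folded to [0, 180]° — 0° means direction
maintained ("saccadic momentum"), 180° a reversal ("return saccade") —
and is binned into nine 20° bins by default. Per bin the package reports
the successive saccade's amplitude, the duration of the fixation lying
between the two saccades, and (when maps are supplied) the density or
saliency value at the successive saccade's endpoint. An optional
amplitude window (e.g. 3–8 dva) removes small corrective and rare large
saccades from the endpoint analysis.

# Fixation-density maps and likelihood scoring

The empirical density is an isotropic Gaussian kernel sum over fixation
positions, evaluated at the cell centres of a 128 x 128 grid spanning
the image and renormalized to unit mass (the renormalization is also the
edge correction: kernel mass falling outside the image is redistributed;
an uncorrected variant would simply skip nothing here because cell
values are defined only inside the window). The implementation is
verified against a brute-force per-cell double loop to $10^{-10}$
relative error.

The bandwidth is chosen per image by LOSO cross-validation over
candidates 0.5–2.0 dva in steps of 0.1 dva: each subject's fixations are
scored under the KDE of all other subjects and the candidate maximizing
the *summed* held-out log-likelihood is selected (equivalent to the mean
when subjects contribute equally), ties breaking toward the larger —
smoother — bandwidth.

Scores are reported as the mean over fixations of
$\log p(\text{cell}) - \log(1/128^2)$: positive values beat a uniform
map, negative values fall below chance. Natural log is the default, with
base-2 ("bits") as an option — both conventions are common in the
gaze-prediction literature. Cell masses are floored at $10^{-12}$ and renormalized
before taking logs so an empty cell never propagates $-\infty$; the
floor changes likelihoods by at most $\sim 10^{-8}$ relative. Whether to
average per fixation or first within trial is exposed as an option
(`per = "fixation"` or `"trial"`). External priority maps (e.g. from a
saliency model) are consumed as plain matrices and looked up at saccade
endpoints without rescaling; cells are half-open with a deterministic
boundary rule.

# Patch spectra

79 x 79-pixel patches (about 2.05 dva at the default scale) are cut
around each fixated pixel, keeping only patches that lie entirely inside
the image (fixations within 39 px of a border are dropped and counted).
Control patches reuse the same fixation coordinates on the *next* image
in cyclic order, preserving the spatial statistics of gaze while
decoupling patch content. Patches are analyzed in luminance units. The
amplitude spectrum is the magnitude of the unnormalized 2-D DFT,
zero-frequency centred; no windowing is applied before the transform (a
Hann taper is available but off by default, since the reference
procedure describes none). Ratios are formed on amplitude, not power:
condition mean over control mean, and condition mean over the grand mean
across conditions. Patch variability is summarized as SD/M per frequency
plus a scalar (its mean over frequencies); on real recordings this
statistic is dominated by patch-to-patch contrast variation, so its
absolute level is dataset-specific and not meaningful at synthetic
scale.

# The synthetic generator

The generator exists to give every analysis stage a ground truth; it
emulates the statistical *structure* the analyses assume, not the
physiology behind it.

* **Backgrounds** are random-phase noise with a radial amplitude
  spectrum $f^{-\text{slope}}$ (slope 1 by default, the natural-scene
  decline) and an optional amplitude boost of horizontal/vertical
  orientations, rescaled to [0, 255] gray.
* **Designs** enumerate 10 participants x 8 sessions x 6 blocks (one
  target each, order randomized) x 25 images = 12,000 trials; 3–7 trials
  per 25-image block are target-absent (~20%); target positions are
  drawn uniformly among the 8 grid positions per present trial; in
  session 7 the target is drawn per trial and its identity marked
  unknown.
* **Scanpaths** alternate fixations and saccades until a 10 s cap.
  Classes differ by construction: low-SF searches use mean amplitude
  5.5 dva and mean fixation duration 260 ms versus 4.5 dva / 220 ms for
  high-SF (SDs 2 dva and 60 ms) — values chosen to reproduce the
  direction and rough size of the empirical effects at realistic search
  dynamics of three to four saccades per second. Each saccade is
  direction-maintaining ("forward") with probability 0.45, otherwise a
  reversal with probability 0.35, else uniformly random, with 15°
  jitter; forward saccades follow shorter fixations (x 0.8) and are
  smaller (x 0.85), returns follow longer fixations (x 1.3) and are
  larger (x 1.2) — the two-mode structure the direction-change analysis
  is designed to expose. Durations drift +8 ms and amplitudes
  -0.15 dva per ordinal step (coarse-to-fine). A fixation landing
  within 1.5 dva of the target ends a present trial as a detection;
  absent trials ring a false alarm with probability 0.034.
* **Traces** render fixations as stationary positions and saccades as
  minimum-jerk ramps whose durations follow the main sequence
  (21 ms + 2.2 ms/dva), with isotropic Gaussian position noise of SD
  0.05 dva at 1000 Hz. Minimum-jerk kinematics exercise the velocity
  threshold the way real saccades do; every generated saccade must span
  at least 6 samples and 0.5 dva so the round trip is well-posed.

What the generator does *not* emulate: image-content-driven fixation
selection (scanpaths ignore the background), binocular disparities,
blinks and tracking dropouts, smooth pursuit, glissades with realistic
post-saccadic oscillation shapes, and any decision process behind search
termination beyond the capture radius. Passing round-trip tests
therefore demonstrates the correctness of the event-detection and
statistics machinery under known ground truth — not that the detector is
optimal for every idiosyncrasy of real recordings.

# Numerical choices and degenerate inputs

* Median-based SD is zero for constant traces (error, by design); it is
  also degenerate for any odd-length non-negative sample, which is why
  thresholds are computed on signed velocity components.
* Empty saccade lists yield one whole-trial fixation; empty groups in
  aggregation keep a row with `n = 0` and an `NA` mean; a single value
  yields an `NA` SEM.
* Density cells are half-open with the outer edge assigned to the last
  cell; the tie rule is deterministic and tested.
* The KDE mass floor is $10^{-12}$ per cell, applied at scoring time
  only, so density maps themselves stay exact kernel sums.
* FFTs use the unnormalized convention (`stats::fft`); Parseval's
  identity `sum(|F|^2)/n^2 = sum(x^2)` is tested.
* Spectral estimates of rendered targets use zero-padding to 512 px,
  giving 0.075 cyc/deg frequency resolution at the default pixel scale;
  the Gabor peak is therefore reported at the nearest grid frequency
  (7.988 cyc/deg).
* All randomness flows through per-call seeds; the ambient RNG state is
  saved and restored, and identical seeds give byte-identical outputs
  (tested on the pipeline's CSVs).

# Problem sizes in the test suite

The suite validates at sizes chosen to finish in minutes while keeping
estimates stable: 200 trials for the detection round trip (about 28
fixations each at the 10 s cap), 100 replicate cohorts of 48 trials for
the amplitude-gap power check, 20 replicates for bandwidth-ordering and
planted-spectrum sign tests, 25–30 fixations for brute-force KDE
equality, and a 2-subject x 12-trial end-to-end pipeline run. The full
default design (12,000 trials) is enumerated but only its structure is
asserted; scanpaths are simulated for subsets.

# Known limitations

* Monocular processing: traces carry one position per sample. Binocular
  recordings should be split per eye upstream; no binocular-overlap
  consensus rule is implemented.
* The per-target contrast $\alpha$ and the original detection-threshold
  pilot are out of scope; detection *rates* on synthetic data follow the
  generator's capture rule, not a psychophysical model.
* Saliency models are consumed only as precomputed maps; no model is
  bundled.
* The direction-change analysis assigns the intervening fixation by
  exact epoch containment; if the 50 ms filter removed it, the pair
  contributes no duration (NA) rather than a neighbouring fixation.
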