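---
title: "Models and methods behind rgcadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rgcadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Retinal ganglion cells (RGCs) are routinely characterized with
spatiotemporal white noise, whose flat spatial power spectrum makes
receptive-field (RF) estimation straightforward.  Natural scenes are very
different stimuli: their spatial power falls roughly as $1/f^2$, so most of
their energy sits at low spatial frequencies.  Efficient-coding theory
predicts that a neuron transmitting such input through a limited-capacity
channel should adapt — strengthening its antagonistic surround (to whiten,
i.e. flatten, the transmitted spectrum) and, when high-frequency
signal-to-noise is poor, enlarging its center (a lower cutoff frequency).

`rgcadapt` implements the full analysis chain for asking whether spatial
RFs measured under white noise generalize to naturalistic stimulation:
constrained linear–nonlinear (LN) model fitting on both ensembles,
out-of-domain evaluation with frozen spatial filters, three independent
estimators of center size and surround amplitude, and a spectral whitening
analysis.  Because the package is exercised end-to-end on synthetic
LN–Poisson neurons with known ground truth, every stage is testable
without recordings.

# The encoding models

## Rank-two difference-of-Gaussians LN model

The primary model is a space–time separable, rank-two LN model.  Its
linear stage is built from two spatial Gaussians $G_1$ (center) and $G_2$
(surround) and two temporal filters $T_1$, $T_2$ of 30 frames each:

$$R(x, y, t) = G_1(x, y)\,T_1(t) - G_2(x, y)\,T_2(t).$$

Constraints make the difference a meaningful center–surround RF: the two
Gaussians share one center location, their amplitudes share the cell's
polarity sign, and the temporal filters are kept at unit Euclidean norm so
that the Gaussian amplitudes carry the scale.  The linear drive at bin $t$
is the inner product of $R$ with the 30-frame stimulus history on a
15 × 15 pixel crop around the cell (valid-mode: the first 29 bins of each
contiguous segment carry no prediction), passed through a two-parameter
softplus

$$f(x) = \alpha \log(1 + e^{x + \beta}), \qquad \alpha > 0 ,$$

whose output is the predicted rate.  Training minimizes the Poisson loss
$\sum_i p_i - r_i \log(p_i + \varepsilon)$ with $\varepsilon = 10^{-12}$.

Constrained quantities are reparameterized so plain gradient steps can
never violate them: covariances are stored as Cholesky-like factors with
softplus-positive diagonals (always symmetric positive definite),
amplitude magnitudes and $\alpha$ pass through a softplus, polarity is a
fixed sign taken from the spike-triggered average (STA), and temporal
filters are stored as unnormalized vectors divided by their norm (exact
unit norm at every step, rather than post-hoc renormalization).  All
gradients are analytic; they are verified against central finite
differences in the test suite.

## Rank-one alternative

Because the Gaussian parameterization could be too rigid, a second model
learns a free 15 × 15 spatial filter (225 parameters, no Gaussian form)
with one unconstrained 30-frame temporal filter and the same softplus.
Its RF estimates feed the two nonparametric size/surround estimators.

## Conventions

Coordinates are 1-based `(row, column)` with pixel centers at integers,
in stimulus-pixel units (one stimulus pixel is `stim_pixel_factor`
screen pixels of `pixel_pitch` µm each; areas convert via
`px2_to_um2()`).  The temporal axis is most-recent-frame first.

# Training protocol

The crop center is the pixel of largest temporal variance in the STA
(30-frame window, matching the model's temporal support; ties break
toward the smallest `(row, col)`).  Non-repeating trial segments are
shuffled and split 80/20 into training and validation; repeating segments
are reserved for testing.  Adam minimizes the Poisson loss on mini-batches
of contiguous valid bins; after every epoch the Pearson correlation
between prediction and the held-out validation counts is logged.  The
learning rate starts at 0.009 (white noise), 0.005 (movie surrogate) or
0.001 (adaptation), decays by 10× on a 15-epoch validation plateau with a
floor of $10^{-7}$, and training stops after 30 epochs (500 maximum)
without validation improvement, restoring the best epoch's weights.
An undefined validation correlation (constant response) counts as
no improvement.

Three training choices deserve explanation because they were genuinely
open and the obvious defaults fail:

* **Batch size is ensemble-dependent** (256 bins for white noise and
  adaptation, 2048 for the movie surrogate).  Under a $1/f^2$ stimulus
  the likelihood is nearly flat in the center-width direction, so with
  small batches the covariance gradients are noise-dominated; Adam's
  per-parameter normalization then turns that flat direction into a
  random walk that never leaves the initialization.  Averaging gradients
  over 2048 bins restores a usable signal: in calibration runs,
  generative center sizes of 28 px² were recovered to within a few
  percent, versus ~45% shortfall at 256 bins.  White-noise fits, whose
  likelihood is well conditioned, instead profit from many small-batch
  updates.
* **Covariance initialization at a realistic RF scale** (center
  $\sigma_0 = 1.5$ px, surround $2\sigma_0$; `init_center_sigma` in
  `fit_config()`).  An identity initialization corresponds to a center
  area of $4\pi \approx 12.6$ px², below any realistic cell.  Because the
  movie ensemble identifies center width only weakly, estimates anchor
  near their starting point when data are modest; a start below every
  true size would then masquerade as a systematic "white-noise RFs are
  larger" effect in null (non-adapting) populations.  Initializing at a
  typical midget scale places the anchor inside the population rather
  than outside it.
* **Remaining initialization**: shared mean at the crop center,
  amplitude magnitudes 0.5, unit-normalized standard-normal temporal
  filters, $\alpha = 1$, $\beta = 0$; the rank-one spatial filter starts
  from $N(0, 0.1^2)$ entries.

Out-of-domain adaptation freezes every spatial parameter: the spatial
filters are rendered once from the fitted parameters and treated as fixed
data, so only the temporal filters and $(\alpha, \beta)$ are optimized,
and the returned parameter object reuses the input's spatial fields —
byte-identical by construction, which the tests assert through
serialization.  Both models are always trained on equal numbers of
non-repeating frames per ensemble (`equalize_training_frames()` trims
trailing non-repeating frames only).

# The synthetic data generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is checked.

**White noise** draws independent binary ±contrast values per stimulus
pixel and frame (a Gaussian marginal is available); frames are stored on
the stimulus-pixel grid and `expand_frames()` reproduces the
screen-resolution view of constant 4 × 4 blocks.

**The naturalistic-movie surrogate** emulates the two properties the
analysis depends on: a $1/f^2$ spatial power spectrum and eye-movement
temporal structure.  Frames are views through a jittered window onto a
larger latent pink-noise image (amplitude $\propto 1/f$, uniform random
phases, periodic boundary, unit pixel variance).  The gaze follows a
seeded random walk with integer steps of standard deviation `jitter_sd`
(default 2 stimulus pixels) while the latent content evolves as a
stationary AR(1) process with per-frame correlation `temporal_corr`
(default 0.9).  These two defaults were chosen once, for identifiability:
with nearly frozen content and little jitter the movie ensemble carries
almost no mid-frequency spatiotemporal energy over a 15 × 15 crop, and
the spatial scale of a filter is then not recoverable at desk scale —
model fits simply cannot move off their initialization.  The defaults
emulate the combined effect of fixational gaze shifts and scene dynamics;
they do not reproduce the higher-order statistics (edges, objects,
occlusions) of real movies, so passing tests speak to spectral content,
not to full natural-scene statistics.

**Ground-truth cells** are LN–Poisson neurons of the same
difference-of-Gaussians form the models fit (the simulation is exactly
the model class, so maximum likelihood is asymptotically unbiased).
Groups loosely follow primate RGC types: midget-like OFF cells with
center $\sigma \in [1.2, 1.8]$ px, ON parasol-like cells
($\sigma \in [2.0, 2.6]$), and a large-OFF-like group.  Under
`adapt = TRUE`, movie-ensemble parameters get a 1.3× wider center
(midget-like groups only) and a stronger relative surround
(amplitude ratio 0.35–0.55 versus 0.05–0.12 under white noise) — the
qualitative pattern the analysis is designed to detect; under
`adapt = FALSE` the two parameter sets are field-for-field identical,
giving the null population used for calibration.  Amplitudes are scaled
so the linear drive has standard deviation 1.5 on unit-contrast white
noise, and softplus gains give mean rates of roughly 10–40 Hz (movies
drive stronger responses through the same cells, as low-frequency power
accumulates over the center).  Poisson counts are drawn per bin at
`rate / frame_rate` with fresh noise on every repeating trial.

**Trial structure** follows the recording protocol: each trial is a
non-repeating segment (training/validation) followed by a repeating
segment (test) whose content is identical across trials.  The desk-scale
default is a 120 × 160 screen (30 × 40 stimulus pixels), 85 Hz, 6 trials
of 20 s + 5 s.  All randomness flows from one master seed through named
per-stage child seeds (`stage_seed()`).

# Receptive-field quantification

Center size is always reported as $S = 4\pi\sqrt{\lambda_1\lambda_2}$,
the area of the two-standard-deviation ellipse of a center covariance
(eigenvalues $\lambda_i$), in px² and optionally µm².

The surround is measured on the full spatiotemporal RF.  The *max frame*
is the slice where the center pixel is extremal in the cell's polarity;
the *surround frame* is chosen within ±6 frames of it (clipped at the
temporal edges, ties toward the earlier frame), among frames whose center
pixel retains the polarity sign, as the one holding the largest-magnitude
opposite-polarity pixel anywhere in the crop.  Before measuring, the RF
is normalized so the center pixel of the max frame has magnitude 1 — the
softplus absorbs overall filter scale, so only normalized surround depths
are comparable across cells and models.  Surround amplitudes below
$10^{-4}$ are reported as 0 in summary outputs.

Two independent estimators operate on a spatial slice alone:

* **Post-hoc DoG fit** (`fit_dog_posthoc()`): bounded Levenberg–Marquardt
  least squares of a shared-mean, same-sign difference of Gaussians,
  started from $A_c = A_s = 0.5$, $\sigma_c = 1.2$, $\sigma_s = 1.5$ px,
  off-diagonals $10^{-3}$, mean at the crop center; non-SPD candidate
  covariances are rejected through a residual penalty.  An optional
  5-start multistart exists but is off by default.  Its domain of
  validity is surrounds that substantially overlap the 15 × 15 crop
  (surround $\sigma \lesssim 5$ px); far beyond that the surround
  component is unconstrained in-crop and the fit degenerates.
* **Smoothing/threshold method** (`threshold_center_size()`,
  `smoothed_surround_amplitude()`): the slice is windowed with a
  separable Kaiser window ($\beta = 7$) against edge artifacts,
  normalized by its maximum absolute value, and binarized at 20% of the
  polarity peak; the 8-connected component containing the peak (a
  declared, configurable choice) is the center area — an integer pixel
  count, so areas are quantized to whole pixels.  The surround amplitude
  is the opposite-polarity extremum after Gaussian smoothing
  ($\sigma = 1.5$ px, zero-padded separable convolution).

Aligned mean RFs per cell type rescale each cell's RF so its center
temporal trace peaks at +1 (ON) or −1 (OFF), take the surround-frame
slice (max frame when no surround frame exists), shift it by integer
pixels to a common center with vacated pixels set to mean gray (0), and
average.

# Spectral analysis

Spatial power spectra are 2-D FFTs of center-cropped frames, radially
averaged into unit-width annuli by rounded radial distance (all samples
binned, so total power is conserved; the Parseval identity is a test),
then averaged over frames.  The DC bin reflects mean luminance, not
spatial structure, so "normalized to the first data point" always means
the first non-DC bin.  Transfer functions zero-pad a filter into the
crop-sized field and radially average the Fourier magnitude (placement
affects only phases, asserted by a test).  No window is applied before
the FFT.

A filtered-stimulus spectrum can be computed by circular convolution of
each frame or by multiplying per-frame power spectra with the squared
transfer magnitude; the two are identical by the convolution theorem and
agree to near machine precision in the tests.  An amplitude-domain switch
(multiplying by the unsquared magnitude) is provided for comparability
with analyses phrased that way.

**Whitening** is quantified in the log domain.  With spectra normalized
to their first non-DC bin, the distance of spectrum $s$ from flat at
frequency $f$ is $D(s, f) = \lvert\log_{10} s(f)\rvert$.  Within a band —
by default from the second radial bin to where the filter's transfer
magnitude drops to 10% of its peak, the RF-relevant range — the reported
percentage is $100\,(D_u - D_f)/D_u$ at the frequency maximizing
$D_u - D_f$: 100% means the filter flattened the spectrum completely at
its most-affected frequency, 0% no effect, negative values steepening.

**Simulated efficient-coding filters** take the central Gaussian of a DoG
fit to a mean RF, normalize its amplitude to 1, and make it circular by
setting both diagonal covariance entries to the larger one: a small
("white-noise-like") and a large ("low-pass") center.  A subtracted
surround Gaussian is then tuned by grid search — amplitude 0.05–1 in
steps of 0.05, width 1.2–4× the center in steps of 0.2 — to minimize the
in-band maximum $\lvert\log_{10}\rvert$ of the filtered movie spectrum, a
reproducible stand-in for manual tuning.  On the synthetic $1/f^2$
surrogate the surround-augmented filters whiten by well over 50% while
the surroundless centers achieve under 15% (often negative): the
qualitative contrast predicted by efficient coding, and the property the
acceptance suite checks.

# The pipeline

`run_all()` chains simulate → fit → adapt → evaluate → RF metrics →
spectra → report from one declarative YAML/Rlist configuration carrying
every constant as a named default.  Each stage records completion and its
child seed in `manifest.json` (updated atomically), writes tables as
CSV/JSON, and caches R objects as RDS so `resume()` re-runs only missing
stages and refuses a configuration whose hash does not match.  Identical
configuration and seed give byte-identical result files.  Evaluation
reports both directions of the in-domain/out-of-domain comparison
(white-noise side and movie side) with paired two-sided Wilcoxon
signed-rank tests; groups with fewer than five valid pairs are flagged
underpowered, and undefined correlations are dropped pairwise with
logged counts.

# Problem sizes used by the tests

The test and acceptance suites run at desk scale, chosen so the whole
analysis completes in minutes on one CPU while every property remains
measurable: a 30 × 40 (or smaller) stimulus-pixel grid; 5 minutes of
white noise for single-cell recovery (median center-location error
≈ 0.1 px, size error well under 15% across seeds); 20-cell adapted
populations on the 6 × (20 s + 5 s) default trials for the
in-domain/out-of-domain contrast, evaluated on the white-noise side where
the effect of non-transferring spatial filters is largest (on the movie
side most predictable variance is low-frequency, which a re-tuned
temporal stage captures regardless of spatial filter shape, so margins
there are intrinsically small); and twenty 6-cell null populations for
the false-positive calibration of the size comparison.  Real recording
sessions supply one to two orders of magnitude more data per cell;
desk-scale estimates are therefore noisier, which the calibration
properties take into account by testing medians and error-rate bounds
rather than single fits.

# Known limitations

* The movie surrogate reproduces second-order (spectral) statistics and
  eye-movement-like dynamics only; conclusions about real natural movies'
  higher-order structure are outside what the synthetic experiments can
  establish.
* Under the movie ensemble, center size remains weakly identified at
  desk scale even with the large-batch default; single-cell movie size
  estimates carry substantially more variance than white-noise ones.
* The threshold size estimator quantizes to whole pixels, so cells
  closer than ~1 px² in 20%-level-set area can tie or swap ranks.
* The post-hoc DoG fit uses the single prescribed initialization by
  default; strongly non-Gaussian or crop-exceeding filters can require
  the multistart option.
* No regularization is used anywhere (by design), so very short
  recordings overfit; the history logs make this visible.
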