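---
title: "Simulated diffraction and single-image quality inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated diffraction and single-image quality inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggnet)
```

## The problem

High-frame-rate crystallography beamlines (serial XFEL experiments,
fast-rotation synchrotron collection) produce diffraction images far faster
than a crystallographer can inspect them. Two per-image questions dominate
triage: *what resolution is this crystal diffracting to?* and *is more than
one lattice contributing (a split or cracked crystal)?* braggnet implements a
simulation-to-model pipeline for both: a kinematic forward simulator is the
training-data source (every image is born labeled), a fixed conditioning
scheme compresses raw detector frames into beam-anchored quadrants, and
regression/classification models map a quadrant to an inverse resolution or
an overlap probability.

## The B-factor / resolution trend

Diffracted intensity decays with scattering angle as the Debye-Waller factor
$\exp(-B / 2d^2)$, where $B$ (&#8491;&#178;) measures crystal disorder and
$d$ (&#8491;) is the Bragg resolution. Across deposited structures, overall
$B$ and reported resolution follow a monotone quadratic trend
$B(d) = a d^2 + b d + c$. The shipped default is the classic rule of thumb
$(a, b, c) = (4, 0, 12)$, i.e. $B = 4d^2 + 12$: the published figure this
trend summarizes does not print its fitted coefficients, so the package
ships the well-known analytic form and exposes `fit_trend()` to refit from
any `(d, mean B)` summary table. The trend is treated as calibrated on
1&ndash;4.5 &#8491; and unreliable beyond 5.5 &#8491;; inversions beyond the
limit are *flagged* (`low_confidence` attribute), never silently clamped,
because clamping would hide exactly the images a beamline operator should
look at. Whether the underlying relationship should be fit as $B(d)$ or
$d(B)$ is ambiguous; we fit $B(d)$ and invert the quadratic, which keeps the
forward map (used for labeling) exact.

Simulated images are labeled in *inverse* resolution: a scene simulated with
$B = B(2.0\,\text{&#8491;})$ carries the label $0.5$ &#8491;&#8315;&#185;.
Inverse units avoid division-by-zero pathologies during training and make
the accuracy metric (below) uniform across the resolution range.

## The forward simulator

`render_spots()` implements kinematic (single-scattering) diffraction
directly: Miller indices are enumerated out to the resolution sphere
subtended by the detector corner, each reciprocal-lattice point gets an
excitation error $\varepsilon$ (its distance from the Ewald sphere), and a
still exposure weights each reflection by
$\exp(-\varepsilon^2 / 2\sigma_E^2)$ with
$\sigma_E = \sigma_0 + (\eta + \Delta\lambda/2\lambda)\,|q|$ combining a
divergence floor, the mosaic spread $\eta$ and the spectral bandwidth.
Rotation exposures (`delta_phi > 0`) instead accept, at full weight, every
reflection whose excitation error changes sign across the wedge &mdash; the
simplest model consistent with a rotation pass, with no partiality profile.
Expected intensity is
$I = A \cdot F^2 \cdot \exp(-B/2d^2) \cdot w$, with $F^2$ drawn per
reflection from the exponential (Wilson) distribution: the learning targets
depend on intensity *statistics*, not on any particular protein, so
structure factors are random draws rather than atomic-model calculations.
Spots are splatted as photon-conserving isotropic 2-D Gaussians
(default width 1.2 raw pixels).

Background is `background_scale` times a fixed radial profile: a steep
low-angle falloff plus a broad diffuse ring centered near 3.7 &#8491; (the
water ring), with optional sharp ice rings at 3.90/3.67/3.44 &#8491;. The
published work leaves its background profile and normalization unspecified;
ours is a documented stand-in that reproduces the two qualitative features a
model must learn to ignore (a bright center and a mid-resolution ring), and
the 0.01&ndash;1.25 scale range follows the published table of example
scenes. The detector stage adds Poisson photon counting times gain plus
Gaussian read noise, clips to `[0, saturation]`, casts to integers, zeroes
the beamstop disk, writes `-1` sentinels into rectangular bad-pixel regions
and saturates a Poisson-distributed number of hot pixels.

Every randomized quantity is drawn in `sample_scene()` from a
`simulation_config()`: detector model, distance (uniform 200&ndash;300 mm),
wavelength fixed at 0.9795 &#8491;, beam-center jitter (uniform &plusmn;3 raw
pixels on each axis &mdash; the training distribution of beam-center error is
not published, so this is the package's choice), beamstop radius, unit cell,
orientation, mosaic spread, B factor, background, masks. The overlap task
draws 1, 2 or 3 lattices with probabilities 0.5/0.25/0.25, keeps mosaic
spread below 0.01&deg;, and misorients the extra lattices about the first by
a random-axis rotation with angle $\sim N(0, \sigma)$, $\sigma$ chosen per
scene from {0.1&deg;, 1&deg;, 10&deg;}. A scene records its seed; `(config,
seed)` determines every image byte (single-threaded R RNG), which the test
suite asserts.

Two deliberate simplifications relative to a full physical simulator:
no polarization/absorption/point-spread corrections and no pink-beam
spectra; and unit cells are cubic with edges drawn from a small discrete
library (60/70/80 &#8491; by default) so reflection-grid caching keeps a
toy-detector image under ~0.2 s on one CPU. What the generator consequently
does *not* emulate: anisotropic diffraction, salt/ice parasitic lattices as
distinct classes, detector-specific artifacts. Models trained on these
simulations demonstrate that the pipeline learns the physics it encodes;
passing desk-scale tests does not certify accuracy on real beamline data.

## Image conditioning

`condition_image()` applies, in fixed order: block-maximum downsampling by
the detector's factor $N$ ($N = 2$ or 4 for the shipped large-detector
presets), square-root quantization with an integer floor, and extraction of
four 512&times;512 quadrants oriented so the beam center is element (1,1)
and radius grows with the indices. Block-*maximum* (not mean) pooling
preserves sharp Bragg maxima; the square root stabilizes photon-counting
variance and compresses the dynamic range into small integers. Edge blocks
with fewer than $N^2$ pixels reduce over the pixels present, keeping the
full field of view. Quadrants whose downsampled half-extent is not 512 are
zero-padded (0 &asymp; no signal; a third padding class would complicate
training) or truncated. The `-1` mask sentinel survives pooling only where a
whole block is masked, and passes through quantization unchanged. When the
beam center falls exactly on a pixel center that row/column is shared by the
adjacent quadrants, which makes point-symmetric patterns yield four
identical quadrants &mdash; a convenient exactness check. "Upper left" is
defined in memory convention (lower indices on both axes); the training
quadrant is configurable.

## Models

All models share one architecture: a single-channel backbone producing 1000
features, FC1 (1000&rarr;100, bias), a rectified-linear activation with
optional dropout, FC2 (100&rarr;1, bias), and a task head. FC1 always
carries $10^5 + 100 = 100{,}100$ parameters and FC2 $10^2 + 1 = 101$.

The deep backbones are the standard 18/34/50-layer residual networks with
the stem convolution reshaped to one input channel (removing exactly
$64 \cdot 7 \cdot 7 \cdot 2 = 6272$ weights relative to the RGB stem).
`count_parameters()` reproduces the published accounting exactly &mdash;
25,550,760 backbone / 25,650,961 total for the depth-50 resolution model and
21,791,400 / 21,891,601 for the depth-34 overlap model &mdash; and those
counts are what pins the depths: no other standard depth matches them. No
deep-learning framework is a dependency of this package, so the deep
backbones are buildable and exactly countable but not trainable here;
training them is a GPU-cluster exercise outside the package's scope.

The `"toy"` depth is the trainable, desk-scale member of the family: its
backbone is a *fixed* feature stage &mdash; 125 radial shells about the
beam-anchored origin &times; 8 summary statistics (mean, SD, max, 90th and
99th percentiles, fraction of pixels >3 SD above the shell mean, non-zero
fraction, log total) = 1000 features &mdash; followed by the same trainable
FC1/FC2 head. Radial shells are the natural coordinate for this physics:
resolution is a radial cutoff, and extra lattices multiply the spot density
within each shell. The head is trained by minibatch SGD with momentum and
weight decay, with backpropagation implemented in plain matrix algebra and
the task head differentiated through.

The resolution head is geometry-aware: the network's scalar is interpreted
as an effective radial extent $s$ in downsampled-pixel units and converted
by flat-detector Bragg geometry,
$1/d = (2/\lambda) \sin\!\big(\tfrac12 \arctan(s\,p_{\mathrm{eff}}/D)\big)$,
using each image's wavelength, effective pixel size and distance. The
functional form of the published geometry stage is not printed; this is the
package's definition, verified for self-consistency (it exactly inverts the
geometry module's conversions, to 1e-9) rather than for equivalence with the
original. Internally the network predicts the dimensionless ratio
$u = s\,p_{\mathrm{eff}}/D$, which keeps gradients O(1) across the distance
range; non-positive outputs map to 0 &#8491;&#8315;&#185; with the
right-hand derivative used as subgradient so training can leave the clipped
region. The overlap head is a sigmoid on the logit.

### Hyperparameters and conventions

Published values are the defaults: SGD; resolution &mdash; learning rate
6&times;10&#8315;&#179;, momentum 0.9, mean-absolute loss, no dropout;
overlap &mdash; learning rate 1.04&times;10&#8315;&#179;, momentum 0.9983,
weight decay 2.5&times;10&#8315;&#8308;, binary cross-entropy, FC1 dropout
(probability 0.5, a package default; the published probability is unstated).
The prose description of the resolution loss (mean squared) and the
hyperparameter table (MAE) disagree; both are implemented and the table's
choice is the default, on the principle that the hyperparameter ledger is
the more deliberate record. 10% of images are held out; after each epoch
train/test loss and accuracy are recorded and the weights at the best
held-out accuracy are checkpointed (the published stopping rule is visual
&mdash; curves diverging &mdash; so checkpoint-at-best is this package's
concrete rule). Dropout is inactive at inference, standard practice.
Regression accuracy is the fraction of images predicted within 0.07
&#8491;&#8315;&#185; of the truth; batch size defaults to 32, learning rate
is constant. Every run derives all randomness (split, initialization,
shuffling, dropout masks) from one seed and is bit-reproducible.

## Inference and aggregation

`infer_image()` evaluates 1 or 4 quadrants. Per-quadrant inverse
resolutions aggregate to $d_{\min}$ (reciprocal of the largest inverse
resolution: the best quadrant) and $d_{\text{mean}}$; "mean across
quadrants" is ambiguous between averaging $d$ or $1/d$, and we average in
inverse units &mdash; the model's native space &mdash; and report the
reciprocal. $B_{\min}$ is derived from $d_{\min}$ through the trend rather
than inferred separately, consistent with viewing the model as a B-factor
inferrer. Overlap probabilities threshold at $p \ge 0.5$ (overlapped); the
boundary value 0.5 labels overlapped, matching the published single-lattice
criterion $p < 0.5$. `sort_and_split()` orders records by any key and cuts
near-equal groups (remainder to earlier groups); `summarize_dataset()`
computes the bracketed per-data-set averages
$\langle B_{\min}\rangle, \langle d_{\min}\rangle$ and the overlap fraction.

## Numerical choices and degenerate inputs

* Forward scattering ($r = 0$, or $s \le 0$ in the head) reports an infinite
  resolution sentinel / zero inverse resolution, never an exception, so
  vectorized maps are total.
* The trend inverter requires $B \ge c$ (the quadratic's value at
  $d \to 0^+$); smaller values are a domain error rather than a complex
  root.
* Excitation-envelope cutoff is 3.5&sigma;; spot stamps truncate at
  3&sigma; and renormalize, conserving photons per reflection exactly.
* Feature shells with no pixels yield zero features; feature columns with
  zero training variance get unit scale in standardization.
* Ties in checkpoint selection (equal held-out accuracy) resolve to the
  lower loss, then the earlier epoch.
* The toy detector preset (512&times;512 raw pixels, 0.35 mm pitch, N = 2)
  was sized so the default 200&ndash;300 mm distance range puts the
  2.3&ndash;5.5 &#8491; toy label band partially on-detector &mdash; close
  distances resolve the full band, far distances truncate its
  high-resolution end &mdash; mirroring how real geometry limits observable
  resolution.

## Problem sizes in the shipped tests

The test suite trains the toy model on 2,000 simulated toy-detector images
for resolution and 1,000 (with 10&deg; misorientation only, the
well-separated case) for overlap, a deliberate desk-scale analogue of the
published 292,500/117,000-image runs; it also verifies that a 50-image set
is memorized (training accuracy 1.0) and that the Debye-Waller decay of
noise-free renders regresses to the configured $B$ within 10%. These sizes
were chosen as the smallest at which the statistical checks are stable, and
they are the package's definition of "desk scale".

## Known limitations

* The kinematic renderer is a deliberately simplified stand-in for a full
  physical simulator: no detector point spread, polarization, absorption,
  pink-beam spectra, or mosaic-block shape transforms.
* The toy backbone's radial features discard azimuthal structure except
  through within-shell statistics; it cannot learn anisotropy, and its
  accuracy ceiling is well below a trained deep convolutional backbone.
* The trend is a population-level approximation; per-crystal deviations
  (radiation dose, solvent content) are not modeled.
* Real-detector container formats are out of scope; images enter as plain
  integer matrices plus a flat geometry config.
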