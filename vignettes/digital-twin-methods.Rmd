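---
title: "Methods: a digital-twin pipeline for chromatic feature detection in the retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a digital-twin pipeline for chromatic feature detection in the retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`rgctwin` implements an end-to-end, simulation-backed version of a
now-standard workflow in sensory neuroscience: record a population of
retinal ganglion cells (RGCs) responding to a natural movie, train a
convolutional "digital twin" that predicts every cell's response, and then
interrogate the twin *in silico* — synthesising each cell's maximally
exciting input (MEI), mapping its tuning in targeted stimulus subspaces,
and asking what the cell's selectivity is good for (here: detecting
ground-to-sky visual context changes by their chromatic signature, a UV
increase with a simultaneous green decrease).

Because the original two-photon recordings are not required, every input is
produced by a ground-truth generator. That choice turns each downstream
stage into a testable claim: receptive-field locations can be compared to
where the generator put them, MEI opponency can be compared to the
generator's chromatic weights, and detection performance can be compared
across families whose response functions are known exactly.

## The synthetic study

**Movie.** The stimulus is a clip-structured dichromatic (green/UV) movie:
by default 113 clips of 150 frames at 30 Hz on an 18 x 16 pixel canvas,
with 5 clips forming a fixed test sequence presented three times and 15 of
the 108 training clips held out for validation. Per-clip mean intensities
are drawn within [0.04, 0.22] (on a [0, 1] scale); "sky" clips have a
higher UV than green mean and "ground" clips the reverse, with the
dominant and subordinate channels drawing from disjoint halves of the
intensity range — so *every* ground-to-sky clip transition increases UV
and decreases green (the opponent quadrant), regardless of which clips
adjoin. The spatiotemporal texture inside a clip is low-pass-filtered
Gaussian noise with short correlation scales (1.2 px, 0.7 frames by
default — textures that decorrelate quickly relative to the cells' ~0.7 s
temporal integration, so movie-driven filter outputs accumulate
incoherently while a deliberately matched stimulus can still drive a cell
hard; this separation between the movie's operating range and the range a
norm-budgeted optimal stimulus can reach is what makes the
contrast-dependent opponency analysable, see below). Two further
stylisations keep the generator exact: the texture has zero spatial mean
in every frame, so full-field luminance equals the clip mean exactly and
transition contrasts are set by the clip means alone; and the texture
amplitude is scaled down where needed (2.5 SD headroom, rare excursions
clipped) so intensities stay inside [0, 1]; dim clips get proportionally
weaker texture, as dim scenes do. Real footage differs in obvious ways — 1/f spatial statistics,
correlated channels, global luminance dynamics — so passing tests show the
*pipeline* recovers what the generator put in, not that the generator is a
retina.

**Cells.** Each simulated cell is a linear-nonlinear unit: unit-norm
Gaussian spatial filters (SD 1.6-2.4 px) at a common location per channel,
zero-mean unit-norm biphasic temporal filters (21 taps), signed chromatic
weights and a rectifying output stage. Families: fast ON, OFF, ON-OFF
(full-wave rectifier), slow ON (slower kernel), and the colour-opponent
suppressed-by-contrast family (`opponent-SbC`). Receptive-field centres are
kept inside the 8 x 6 region the model core sees after valid convolution;
a fixed drive gain of 8 puts movie-driven activations in a realistic
working range.

**The opponent family.** The opponent response is

    r = gain * relu( w_uv d_uv + w_lin d_g
                     - k relu(d_g - theta_s) + k_off relu(-d_g - theta_g)
                     - theta )

UV increments excite linearly; green increments beyond `theta_s` suppress
(with weight `k = |w_green|`, 2.0-2.8); green decrements beyond `theta_g`
excite strongly (`k_off` about 3 k); and a weak positive linear green term
acts at all contrasts. The geometry is set relative to the movie-driven
green drive (SD near 2.3 in gain units): the suppression threshold sits
near 1.4 SD, the green-OFF threshold near 2 SD — so the rectified terms
engage in only a few percent of movie frames — and `w_lin` is computed
analytically as the value that cancels the rectified legs' average
regression slope under a Gaussian drive of that SD. The cell's
*high-contrast* green sensitivity is then strongly green-OFF while the
*time-averaged* linear sensitivity is near zero and burst-dominated — too
little for a linear encoding model to commit to (a Poisson/softplus
linear fit trades the rare huge green-OFF bursts against the bulk of the
data and settles on a weakly positive green weight). The family uses the slow sustained kernel
(suppressed-by-contrast cells are slow types). The construction was
verified directly against its defining invariants before any model was
trained: a norm-budgeted, kernel-matched UV-ON/green-OFF stimulus
out-drives both the green-ON and UV-only variants of itself, and a
full-field UV-ON/green-OFF step beats UV-ON/green-ON severalfold.
Chromatic selectivity that reverses with contrast in this way cannot be
captured by one linear filter — which is exactly the property the
CNN-vs-LN comparison is designed to expose. The stored
`chromatic_weights` carry the high-contrast preference (green negative,
UV positive).

**Recording.** Ground-truth rates are low-pass filtered with an exponential
calcium kernel (1 s decay), sampled at 7.8125 Hz, and corrupted with slow
sinusoidal drift and white noise; the test sequence is rendered as three
independent-noise repeats of the identical stimulus. A 10 s pre-stimulus
baseline is prepended for SD normalisation during detrending.

## Preprocessing

Detrending subtracts a Savitzky-Golay smooth (3rd order, 60 s window),
clips below the 2.5th percentile, subtracts that percentile and divides by
the pre-stimulus SD. Spike inference is deliberately simple — the package's
stand-in is a non-negative first-order deconvolution assuming the
exponential kernel (`r_t = max(0, c_t - gamma c_{t-1})`), plus a
ground-truth passthrough mode used when the study is noiseless; rate
inference quality is not this pipeline's subject. Rates are linearly
interpolated from 7.8125 to 30 Hz. Quality filtering follows the standard
sequence: response reliability (QI_MB > 0.6 or QI_chirp > 0.35, both
computed here from the repeated test segments, the synthetic recording's
only repeated stimulus), classifier confidence >= 0.25 (a stand-in fed
from the generator's family labels; the type classifier itself is out of
scope), mean single-trial test correlation > 0.3, and a DoG goodness-of-fit
cost < 0.11 in both channels for the MEI-property analysis.

## The encoding model

The core is a two-layer CNN shared across neurons: sixteen 2 x 11 x 11 x 21
space-time separable kernels applied as valid convolution, then sixteen
16 x 5 x 5 x 11 kernels zero-padded spatially and valid in time, each layer
followed by batch normalisation and an ELU. Temporal kernels are Fourier
series — the first k sines and cosines with trainable weights on an evenly
spaced grid in [0, 1], k = floor(21/3) = 7 in layer 1 and floor(11/3) = 3
in layer 2 — multiplied per recording by a trainable time stretch `tau` and
masked by the logistic envelope `eps(tau) = 1/(1 + exp(-(t + 21*0.95*tau)))`.
Two notational choices are deliberate: the harmonic index multiplies the
phase (a `harmonics` switch restores the degenerate single-frequency
variant), and the envelope is implemented exactly as written, constants
configurable, even though for `tau` near 1 its argument is so large that
the mask is effectively 1 (its printed argument grouping is likely a
typographical slip; keeping it verbatim is harmless and reproducible).

Each neuron reads the core output through an isotropic Gaussian over the
8 x 6 feature grid (density-weighted sum), a linear combination of the 16
features, a bias and a softplus. The LN control is the same network with
identity activations — exactly linear before the softplus, which the test
suite asserts by superposition.

With valid temporal convolutions the model consumes 31 frames of history
per output frame; a 50-frame chunk yields 20 output frames, which is
exactly the MEI optimisation window (frames 31-50 of a 50-frame input).

**Training.** Poisson loss, Adam, learning rate 0.01, batch 32, chunk 50,
early stopping (patience 5) on mean validation correlation, four
restore-and-decay cycles with factor 0.3, and a 5-member ensemble — all the
reference schedule. At the CPU scale used in the tests and analysis
(28-clip movie, 36 cells, single member, 60 epochs, chunk stride 25,
patience 4, 3 cycles) two adjustments matter and are exposed in
`train_schedule()`: a x10 learning-rate multiplier on the readout location
and size (with Adam, `mu` moves at most `lr` pixels per step, and a few
hundred steps would otherwise not let receptive fields travel across the
canvas), and a floor of 1 px on the readout SD (with the 8 x 6 grid, a
collapsed readout concentrates on a single grid node and loses sub-pixel
identifiability of `mu`; keeping the Gaussian spanning neighbouring nodes
recovers locations to well under a pixel). Batch-norm statistics are
frozen (running averages) for every analysis-time forward pass.

All forward/backward passes are hand-written matrix algebra plus two small
compiled gathers (im2col and its adjoint); temporal convolutions are banded
matrix products. Analytic gradients for every parameter and for the input
are verified against central differences in the test suite.

## MEI synthesis and characterisation

MEIs maximise the model neuron's mean response over the optimisation window
by plain gradient ascent (learning rate 10) from Gaussian-noise
initialisation, with the readout location recentred on the canvas. After
each step the stimulus is rescaled to an L2 budget of 30 jointly over both
channels and then clipped per channel to the z-scored range of the training
movie (rescale-then-clip guarantees range feasibility; the norm may
undershoot after clipping, recorded per MEI). Optimisation runs at least
100 and at most 1000 iterations, stopping after 10 consecutive activation
changes below 0.001. Batched synthesis freezes converged stimuli so each
neuron's trajectory is identical to a solo run.

Characterisation per channel: SVD of the [50 x 288] flattened tensor, the
first left/right singular pair giving temporal and spatial components (sign
fixed so the spatial component is positive at its dominant pixel — the
effective centre — before any fit; the temporal sign follows). The spatial
component is fit with a concentric anisotropic difference of Gaussians
under a soft-L1 robust loss (`sum(sqrt(1 + r^2) - 1)`), initialised at
whichever extremum is closer to the canvas centre, seeded by a
single-Gaussian pre-fit, and bounded (centre in canvas, widths positive).
Two textual fixes are applied to the printed parameterisation: widths enter
the exponent as `2 sigma^2` (SDs, squared), and the rotation cross-term is
the standard `sin(2 theta) (1/(4 sigma_y^2) - 1/(4 sigma_x^2))` (the
printed cross-term cancels identically). Centre size is
`(sigma_x + sigma_y) * px_to_um` with a default scale of 6.25 um/px (a
100 um field across the 16-px canvas; the simulated canvas has no physical
scale of its own, so this is configurable). The centre mask is the filled
level-set ellipse of the centre Gaussian at its value one SD out along both
axes. Temporal frequency is the power-weighted mean FFT frequency after a
5th-order 10 Hz Butterworth low-pass. Chromatic contrast takes the last two
peaks of the *UV* temporal component (local maxima with prominence at
least 5% of the component's range — the reference names no parameters) and
differences the masked mean of the raw tensor between those two times, per
channel; opponency is an opposite-sign pair.

## MEI validation and chromatic tuning

Rank-1 reconstructions (`S11 * temporal %o% spatial`) are presented on a
5 x 5 spatial grid to the ground-truth cells (50 stimulus frames plus 10
frames of inter-stimulus grey appended after each presentation). Responses
are z-scored per cell, weighted by the Gaussian density of the cell's
readout at each grid node (weights deliberately not renormalised — the
plain weighted sum as defined; the factor cancels in the selectivity
index), time-averaged over the optimisation window, and summarised by the
selectivity index: the standardized response to the cell's own MEI minus
the mean standardized response to the others. The inter-setup calibration
transform `x' = B^-1 A x` uses the printed cone-activation matrices
verbatim.

The chromatic-contrast subspace is spanned by the green MEI component
(times -1) in the green channel and the UV component in the UV channel,
scaled so both channel norms equal `sqrt((|g|^2 + |u|^2)/2)` — per-channel
contrasts equalised while the stimulus at (-1, 1), a contrast-scaled MEI,
keeps the original's total L2 norm (that is this package's reading of
"preserving the contrast of the stimulus as a whole", isolated in
`build_basis()`). Responses and input gradients are evaluated on an
11 x 11 grid in [-1, 1]^2; the projected gradient components are plain
inner products with the basis vectors, which makes them directly comparable
to central differences of the response surface (asserted within 5%).

## Context-change detection

Inter-clip transition contrast is the post-minus-pre mean full-field
luminance per channel over 1 s windows (a Michelson variant is exposed as
an option); the response to a transition at `t0` is the mean rate over the
following 30 frames minus the rate at `t0`. ROC curves sweep 40 equally
spaced thresholds over the cell's pooled response range; AUC integrates TPR
over FPR by the trapezoid rule with endpoints appended, and agrees with the
exact pairwise probability within the threshold-discretisation error.

The moving-window simulation slides a 72 x 64 window along a square
trajectory with 220-px edges (90.6 degrees of visual angle; 50/150/250/350
deg/s map to 4/12/20/28 px per frame) over a synthetic sky/ground scene,
downsampling crops 4-fold to 18 x 16 and padding to 60 frames. Horizontal
edges stay within a region (no context change); vertical edges cross the
horizon (sky-to-ground and ground-to-sky), with `t0` at the frame whose
window centre crosses the horizon. Both traversal directions are generated;
on a uniform scene they are exact temporal mirrors, which the tests assert.
Detection here is computed on the ground-truth cells' responses — the
family ranking (the opponent family attains the highest ground-to-sky AUC
at every velocity) is a property of the response functions and needs no
trained model; the trained twin enters through the MEI/opponency analyses.

## Statistics

The two-sample permutation test shuffles group labels (default 100,000
times; the analysis scripts use 10,000) for the statistic |mean a - mean b|
and reports the proportion of null samples strictly larger than the
observed value, as defined. Two guards: an observed statistic of exactly 0
reports p = 1 (the strictly-larger rule would otherwise report a *small*
p for identical groups), and the finite-sample-safe
`(sum(null >= obs) + 1)/(n + 1)` is always reported alongside. Bootstrap
CIs are percentile intervals over 100 resamples (noisy by construction;
`n_boot` is configurable and kept at the reference value by default).
Cohen's d uses the pooled-SD formula; the Bonferroni helper reports
`alpha/m` at 4 decimals.

## Problem sizes and limitations

The test suite and the acceptance script run the full study at a reduced
scale chosen once: 28 clips, 36 cells, single-member ensembles, 60 epochs.
At this scale the qualitative results are stable: readout locations are
recovered to well under 1 px on noiseless linear-nonlinear cells, about
half of the opponent-SbC cells yield UV-ON/green-OFF MEIs under the CNN
(the reference fraction on real data is about two thirds; marginal cells
sit near the sign boundary at this training scale) while the LN control
recovers strictly fewer — typically none — and the opponent family wins
the ground-to-sky detection ranking at all four velocities. Known limitations:
single-member "ensembles" forgo the smoothing that averaging five members
gives MEI landscapes; the synthetic movie's texture statistics are
Gaussian, not natural; the LN control shares the CNN's batch-norm layers
(frozen at analysis time, so it remains exactly linear pre-softplus); and
the per-recording time stretch is trained but weakly constrained at small
scale (a single recording cannot separate `tau` from the Fourier weights,
which is also true of the reference parameterisation).
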