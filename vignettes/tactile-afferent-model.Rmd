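---
title: "Modelling tactile afferent spiking with an electromechanical circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tactile afferent spiking with an electromechanical circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactsim)
```

## The model

Cutaneous touch is carried by three major afferent classes with distinct
selectivity: slowly adapting type 1 (SA1) units respond to sustained
pressure and low-frequency vibration, rapidly adapting type 1 (RA1) units
to stimulus change in the tens of hertz, and Pacinian (PC) units to
high-frequency vibration up to several hundred hertz. `tactsim` treats one
receptor end-organ plus its nerve fiber as a single input–output system
that converts a skin-indentation waveform $x(t)$ (mm) into a spike train,
through four stages.

**Receptor: two-channel filter.** The mechanical selectivity of the
receptor is a parallel pair of linear filters,

$$H(s) = \underbrace{\frac{\sum_{k=1}^{n} K_{bk}\, s^{k}}
        {s + 2\pi f_{BL}}
        \left(\frac{2\pi f_{BH}}{s + 2\pi f_{BH}}\right)^{n+1}}_{\text{band-pass}}
      + \underbrace{K_u \frac{2\pi f_L}{s + 2\pi f_L}}_{\text{low-pass}},$$

where the band-pass channel differentiates the stimulus up to order $n$
(1, 2, 3 for SA1, RA1, PC) between cutoffs $f_{BL}$ and $f_{BH}$, and the
low-pass channel passes the static component with weight $K_u$. RA1 and PC
units adapt completely to static indentation, so $K_u = f_L = 0$ for them.
The filter output $s_m$ is rectified with a weighted negative lobe,
$q_m = \max(s_m, 0) - w\,\min(s_m, 0)$ with $w = 0$ for SA1. The mean of a
rectified sinusoid of amplitude $A$ is then $A(1+w)/\pi$, which is what
ties the time-domain pipeline to the closed-form rate surface used for
training (below).

**Fiber: transducer and diode normalizer.** The rectified signal is scaled
to volts by the transducer coefficient $A_s$ (V/mm). Two diode-like
nonlinearities implement the neural threshold: no firing below
$V_L = 15$ mV (the distance from resting to threshold potential) and
saturation at $V_H = 1$ V. With $V_H = 1$ V the clipped voltage is
numerically the normalized firing rate $v_{nf} \in [0, 1]$. We do not
subtract $V_L$ inside the pass region: the closed-form rate equation used
for training treats $A_s |H| x (1+w)/\pi$ itself as the normalized rate,
and the mapping here must agree with it, so the gate returns 0 below
$V_L$ and $v/V_H$ above.

**Spike synthesizer.** $v_{nf}$ is sampled-and-held every $T_a = 4$ ms
into $v_s$; a triangular carrier with instantaneous frequency
$f_c = K_f v_s$ is generated by a phase accumulator; the comparator output
$v_r = [v_f > 0.5]$ yields one rising edge per carrier cycle; each rising
edge is a spike onset at which a stereotyped action-potential template is
superposed onto the membrane trace $v_a$. $K_f$ is the class's maximum
firing rate: 180, 200, 300 ips for SA1, RA1, PC. The phase is *not* reset
at hold boundaries, so rate changes are phase-continuous and produce no
spurious edges. Because PC's maximum carrier period (3.33 ms) is shorter
than the 4 ms template, overlapping templates are summed relative to the
resting potential. The template itself is not prescribed by physiology in
tabulated form, so it is parameterized (`spike_template()`): rest −70 mV,
peak +40 mV at 1 ms, undershoot −90 mV at 2.5 ms, rest again at 4 ms,
joined by cosine segments.

**Noise.** Mechanical noise (Gaussian, SD 0.1 µm) is added to the
indentation and neural noise (Gaussian, SD 10 mV) to the membrane trace,
both shaped by a first-order 1 kHz low-pass. Spike onsets are read from
the comparator *before* neural noise, so noise perturbs waveforms, never
spike times.

## Numerical realization

The continuous filter is discretized with the bilinear transform
(`signal::bilinear`) on its zero–pole–gain form and applied as
direct-form-II-transposed IIR sections with explicit per-unit state, so
long signals can be filtered block-by-block and afferent batches
(units × samples) are processed in one pass. The derivative terms $s^k$
are realized inside the filter (the numerator zeros), never by numerical
differentiation of the input, which would amplify noise. Bilinear warping
is negligible at the sampling rates used here (the package refuses
$1/dt < 4 f_{BH}$; its steady-state gain matches $|H(j2\pi f)|$ within 2%
over each class's band, which the test suite verifies against an
independent complex evaluation). Default rates: 10 kHz for waveform-level
work (resolving the 4 ms template), 1 kHz for throughput experiments.

## Training the filter from firing-rate surfaces

For a sinusoid of peak amplitude $x$ at frequency $f$ the model's
normalized rate has the closed form
$$h_\theta(x, f) = A_s\, |H(j 2\pi f)|\, x\, \frac{1 + w}{\pi},$$
and the parameters
$\theta = [K_{b1..bn}, K_u, f_{BL}, f_{BH}, f_L, A_s, w]$ are fitted by
minimizing $J(\theta) = \tfrac12 \sum_i (h_\theta(x_i, f_i) - y_i)^2$ over
a firing-rate dataset, with per-class constraints ($K_u = f_L = 0$ for
RA1/PC, $w = 0$ for SA1) and rates feature-scaled to $[0, 1]$.

The optimizer is a BFGS quasi-Newton update applied at a *fixed* step size
$\alpha = 0.55$ on central-difference gradients for 1100 iterations.
Several design choices make this fixed-step scheme dependable, and they
are deliberate package decisions:

- **Scaled coordinates.** Frequencies are optimized in units of the
  geometric-mean data frequency and $K_{bk}$ in units of
  $(2\pi f_{geo})^{-(k-1)}$, so all coordinates are $O(1)$ and the initial
  identity inverse-Hessian is a reasonable metric.
- **Initialization.** $\theta = 0$ is a stationary point of this loss —
  $h_\theta$ is a product of parameters, so every partial derivative
  vanishes there and no gradient method can leave it. Free gains start at
  $O(1)$ in scaled units and the band edges at $f_{geo}/s$ and
  $f_{geo} \cdot s$.
- **Safeguards.** The scaled step norm is capped at 0.25 per iteration
  (unbounded first steps overshoot into the clipped all-zero region, which
  is absorbing); after each update constrained entries are set to 0,
  negative entries are clipped to 0 and the band edges are swapped if
  needed so $f_{BL} \le f_{BH}$. A fixed-step quasi-Newton pass has no
  line search to reject bad steps, so its curvature model can go stale and
  destabilize a run that had already converged; whenever an iteration
  increases the loss the metric is reset to the identity, and the returned
  parameters are the best iterate seen (the loss trace itself is kept
  untouched, so the fitting-precision definition below still reads the
  trace tail).
- **Deterministic multi-start.** The loss is multimodal; roughly one noisy
  dataset in ten sends a single run into a high-loss local minimum. Each
  fit therefore runs from four spread factors
  $s \in \{1.25, 1.5, 2, 3\}$ and keeps the lowest final loss.

The fitting precision reported with a fit is
$K_f \cdot \mathrm{mean}_{t=1000..1100} \sqrt{J_t / m}$, the tail RMS rate
error in impulses per second; for converged fits on data with rate noise
SD $\sigma$ it is close to $K_f \sigma / \sqrt 2$.

Because $h_\theta$ depends on the gains only through the product
$A_s \cdot K_b \cdot (1 + w)$, individual gains are not identifiable from
rate surfaces; the package reports them but only the product and the
frequency parameters are meaningful recovery targets.

## What the synthetic data emulate — and what they do not

`synth_rate_dataset()` stands in for neurophysiological rate datasets
recorded under sinusoidal vibration: per class, 20 log-spaced frequencies
across the sensitive range (1–500 Hz; 10–500 Hz for PC, which is
insensitive below ~10 Hz) × 10 linear amplitudes scaled so the noiseless
rate stays below 0.9 (no saturation), with additive Gaussian rate noise
(SD 0.01) clipped to $[0, 1]$. Repeated fits differ by the noise seed.
These choices emulate the *structure* of such experiments, not any
particular recording: real data have unequal trials per cell, saturating
amplitudes, and physiological rather than additive-Gaussian variability.
Passing recovery tests therefore demonstrates that the training procedure
inverts the model's own rate equation under realistic noise — not that it
would reproduce a specific laboratory dataset.

Two statistical effects of these study conditions are worth knowing.
First, clipping at 0 censors negative noise where the true rate is ~0 (the
low-frequency tail), slightly inflating observed rates there and pulling
the fitted lower band edge down; this is most visible for PC, whose
amplitude grid (scaled to the peak gain, reached near the upper band edge)
leaves the low-frequency tail with almost no signal: the mean fitted PC
$f_{BL}$ sits roughly 5–15% below the generating value depending on the
noise seeds, while its loss is *below* the loss at the generating
parameters — an estimator property, not an optimization failure. Second, close band edges (SA1's 8 and 10 Hz) are
only weakly separated at noise SD 0.01, so their individual estimates
scatter a few percent even though the fitted gain curve matches the data
at the noise floor.

## Evaluation tools

**Threshold curves.** The smallest sinusoid amplitude that drives firing
is $T(f) = V_L / (A_s |H(j2\pi f)|)$, undefined where the gain is zero
(RA1/PC at DC). The minimum threshold is evaluated at the band center
$(f_{BL} + f_{BH})/2$. (For PC's asymmetric band the true minimum of
$T(f)$ lies at the upper band edge, about 22% below the center value; the
center-frequency expression is kept as the definition.) The composite
"human" curve is the pointwise minimum across classes, taking the minimum
over the defined ones.

**Spike-timing comparison.** Train similarity uses the time-averaged ISI
distance: at each instant the current interspike intervals $x_a, x_b$ of
the two trains give $I(t) = x_a/x_b - 1$ (sign-flipped if $x_b < x_a$) and
the distance is the window average of $|I|$. Trains are edge-corrected
with auxiliary spikes at the window bounds; the classic (non-adaptive)
time-averaged form is used. `timing_precision()` jitters reference trains
with Gaussian SDs of 1–10 ms (20 realizations per SD by default), fits a
quadratic to the mean of $d(\text{sim}, \text{ref}) -
d(\text{jittered ref}, \text{ref})$ against SD, and reports the smallest
positive root in range: the jitter level at which jittered references
match the reference as well as the simulation does. Averaging across
pairs is done before the quadratic fit.

## Degenerate inputs and edge behaviour

Zero-amplitude stimuli, zero drive ($v_{nf} \equiv 0$), zero-noise
settings and single-level staircases all reduce to their obvious limits
and are tested. A ramp time of 0 is a step; staircase segments are
phase-continuous, so equal adjacent levels leave no boundary artifact.
`isi_distance` errors on a train with no spikes inside the window.
Thresholds error (scalar form) or return `NA` (curve form) where
$|H| = 0$. The fit reports an error with the iteration index if the loss
becomes non-finite.

## Problem sizes

The bundled tests and the acceptance script run the full recovery
experiment at its native size — 3 classes × 10 noise seeds × 4 starts ×
1100 iterations on 200-point datasets, about a minute — and keep
waveform simulations to a few seconds of signal at 10 kHz with small unit
batches, which is ample for every property checked. Population-scale
batches (hundreds to thousands of units) use the same code path; only
wall-clock time grows.

## Known limitations

- No skin-mechanics (continuum) stage: the input is indentation depth at
  the receptor site, not pressure on the skin surface; spatially extended
  stimuli and population responses are out of scope.
- SA2 units are not modelled (insufficient published data; they encode
  stretch rather than indentation).
- The spike generator is deterministic given $v_{nf}$; there is no
  stochastic (e.g. Poisson) firing mode.
- Individual gain parameters are reported but non-identifiable from rate
  surfaces (see above); only frequency parameters and the gain product
  should be interpreted.

## A worked example

```{r example, eval = FALSE}
p <- afferent_params("RA1")
g <- time_grid(dt = 1e-4, n_samples = 15000)
stim <- make_ramp_hold(g, depth = 0.5, ramp_time = 0.05, hold_time = 1,
                       release_time = 0.05, delay = 0.05)
sim <- simulate_unit(stim, p$receptor, p$fiber)
sim$spikes[[1]]  # onset burst, silent hold, offset burst

ds <- synth_rate_repeats("RA1", n_seeds = 10, noise_sd = 0.01,
                         master_seed = 1)
fit <- fit_rate_model(ds, fit_config("RA1"))
fit$theta_mean[c("f_bl", "f_bh")]
```
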