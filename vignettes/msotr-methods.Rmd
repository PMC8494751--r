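---
title: "Models and methods behind msotr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msotr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The imaging model

Multispectral optoacoustic tomography (MSOT) illuminates tissue with
nanosecond laser pulses and records the resulting thermoelastic pressure
waves on an array of ultrasound transducers. Under pulsed illumination the
initial pressure is proportional to the absorbed optical energy,

$$p_0(\vec r, \lambda) \;=\; \Gamma\,\phi(\vec r,\lambda)\,
  \mu_a(\vec r,\lambda), \qquad
  \mu_a(\vec r,\lambda) = \sum_{i=1}^{N_c} C_i(\vec r)\,
  \varepsilon_i(\lambda),$$

and an ideal point detector at $\vec r_d$ records the time derivative of
the spherical mean of $p_0$ at radius $\nu_s t$. `msotr` works in the 2D
analogue of this geometry: integration surfaces are circles, and the
package adopts one fixed scale convention,

$$s_d(t) \;=\; \frac{1}{2\pi\nu_s}\,\frac{d}{dt}
  \oint_{|\vec r-\vec r_d| = \nu_s t} p_0(\vec r)\, dl,$$

used identically by the analytical phantom generator and by every
discretized forward model, so model outputs and analytical signals are
directly comparable without per-method scale fudging. The Grueneisen
coefficient and fluence are not modelled: images are in arbitrary units,
and fluence variation is assumed negligible for unmixing, which is the
standard simplification for this pipeline topology and is listed under
limitations below.

## Analytical phantoms

The phantom primitive is a paraboloid absorber,
$p_0(\vec r) = A\,(1 - |\vec r - \vec c|^2/R^2)$ on the disc
$|\vec r-\vec c| \le R$. Its circular line integral about any detector
position has a closed form, and so does the radial derivative of that
integral: the terms multiplying $d\varphi_{\max}/d\rho$ cancel because the
integrand vanishes at the arc end points. The package therefore evaluates
the analytical detector signal by exact differentiation at *every* radius,
including the tangency radii $|D\pm R|$ where the closed form tends
continuously to zero; no finite-difference fallback is required. Tests
verify the derivative against a central-difference probe at $h = dt/100$
and the quadrature of the line integral against `stats::integrate`.

Random phantoms draw the source count, radii, amplitudes and centres
uniformly (defaults: 1-8 sources, $R \in [2\%, 15\%]$ of the field of
view, $A \in [0.5, 2]$), rejection-sampling until all sources fit in the
field of view and are pairwise disjoint -- disjointness is what makes the
total signal the plain sum of per-source closed forms.

# Forward-model discretizations

Both model matrices factor as
$M = \tfrac{1}{2\pi\nu_s} D_t W$, where each row of $W$ approximates the
circular line integral for one (detector, time) pair and $D_t$ is a
per-detector temporal stencil (symmetric central differences, one-sided at
the record ends; the stencil is recorded in the model metadata).

* **dIMMI** (curve sampling): points are placed uniformly in angle along
  the portion of each circle inside the field of view -- the in-FOV
  angular intervals are clipped analytically, so row sums are exact -- and
  each point spreads its share of arc length onto the four surrounding
  pixel centres by bilinear interpolation. The default sampling density is
  `2 * max(nx, ny)` points per arc, at least Nyquist along the longest
  chord. Dense sampling acts as an anti-aliasing filter, which is why this
  model is more accurate at coarse grids.
* **CDMMI** (exact arc length): each entry is the exact length of the
  circle inside one pixel cell, obtained by slicing the circle at every
  crossing with a cell-edge line and classifying each angular segment by
  its midpoint. Row sums equal the in-FOV arc length to machine precision
  (a partition identity the tests check against an independently coded
  clipping oracle).

The two discretizations model the *image* differently -- piecewise
constant per cell versus bilinearly interpolated -- so on a coarse grid
their outputs differ at the $O(h)$ interpolation level even with
arbitrarily fine curve sampling; they converge to each other, and to the
analytical signal, only as the grid refines. The forward-model benchmark
(`benchmark_forward_models()`) quantifies exactly this convergence.

# Inverse solvers

**LSQR** implements the Golub-Kahan bidiagonalization recurrence on
$\min_I \lVert MI - d\rVert_2$, with optional Tikhonov damping
$\sqrt\lambda\,\lVert I\rVert$ folded into the standard extra plane
rotation. The tracked residual norm is non-increasing by construction.
The defaults (tolerance $10^{-6}$ on the relative residual, 50 iterations)
are this package's mapping of a generic library default; early stopping
doubles as regularization for the ill-conditioned tomographic system.

**Non-negative solver** (`nnapcg_solve()`): the cited constrained
conjugate-gradient scheme is not specified to reproducible detail in the
literature we target, so the package implements the *contract* --
non-negativity of every iterate, a non-increasing objective, and agreement
with exact non-negative least squares on small systems -- via
Nesterov-accelerated projected gradient descent (FISTA-style) with a
function-value restart and a step size from a power-iteration estimate of
$\lVert M^\top M\rVert$. Tests compare it against a Lawson-Hanson
active-set oracle on small dense systems.

**Universal backprojection** adapts the direct inversion weighting
$2p_d(t) - 2t\,\partial_t p_d(t)$ along time-of-flight circles, with
per-detector weights defaulting to $1/n_d$ and linear interpolation in
time; the absolute output scale is arbitrary, consistent with images in
arbitrary units.

# Preconditioning chain

Each raw frame passes through a fixed-order chain -- energy calibration,
per-transducer mean subtraction, Wiener deconvolution of the transducer
impulse response, zero-phase band-pass (50 kHz - 7 MHz default), Beer's-law
water-absorption compensation (3 cm default path), and interpolation onto
the solver's time axis. Deconvolution precedes band-pass because Wiener
deconvolution assumes white noise, an assumption band-pass filtering would
destroy. Every stage is linear, so the composite is linear; each stage can
be toggled but never reordered.

Two implementation notes. The default impulse response is a delta (the
stage is skipped unless the user supplies a kernel), because transducer
responses are instrument-specific. And the band-pass is realized as the
squared-magnitude response of an order-4 Butterworth applied per FFT bin
rather than as a recursive forward-backward filter: at a 40 MS/s sampling
rate the 50 kHz corner sits at $10^{-3}$ of the sample rate, where the
recursive filter's pole cluster hugs the unit circle and demonstrably
leaks DC at the $10^{-2}$ level and violates linearity at $10^{-7}$. The
spectral implementation is exactly linear, exactly zero-phase, nulls DC
identically, and meets the attenuation contract (< 1 dB at band centre,
> 20 dB at $f_{lo}/10$ and $10 f_{hi}$). It applies circularly; frames are
mean-subtracted and compactly supported in time, so wrap-around effects
are confined to the record edges.

The shipped water-absorption table follows the standard pure-water
compilation of Hale & Querry (Appl. Opt. 12, 555, 1973) on a 25-nm grid
over 700-900 nm; the shipped hemoglobin spectra follow the widely used
tabulated molar extinction compilation (Prahl, Oregon Medical Laser
Center) on a 10-nm grid. Both are linearly interpolated and both can be
overridden by user CSVs. For synthetic end-to-end studies only
self-consistency matters, since the simulator and the unmixer share one
table.

# Multispectral filtering and unmixing

Acquisitions cycle through wavelengths one laser shot at a time, so a
full spectral stack must be estimated at each instant. The
**sliding-window** assembler emits, at every frame, the most recent frame
of each wavelength (nothing is emitted until each wavelength has been seen
once). The **Kalata filters** instead track a per-pixel, per-wavelength
level (and, for the $\alpha\beta$ variant, trend): every frame advances
the whole state by the frame interval, then measurement-updates only the
incoming channel.

Gains derive from the tracking index $\Lambda$, the ratio of process to
measurement noise scales per sample period. For $\alpha\beta$ we use
Kalata's closed forms
$r = (4 + \Lambda - \sqrt{8\Lambda + \Lambda^2})/4$,
$\alpha = 1 - r^2$, $\beta = 2(2-\alpha) - 4\sqrt{1-\alpha}$. For the
first-order filter the steady-state scalar Riccati recursion for a
random-walk level gives $\alpha^2/(1-\alpha) = \Lambda$, i.e.
$\alpha = (-\Lambda + \sqrt{\Lambda^2 + 4\Lambda})/2$. Three closed-form
consequences are tested: the steady-state white-noise variance gain
$\alpha/(2-\alpha)$, the constant ramp lag
$\text{slope}\cdot\Delta t\,(1-\alpha)/\alpha$ of the $\alpha$ filter, and
the vanishing steady-state ramp lag of $\alpha\beta$. The trade-off is
intrinsic: the $\alpha$ filter assumes a static level, so it smooths more
but lags dynamics; $\alpha\beta$ follows ramps at the cost of noise
suppression.

How that trade-off resolves depends entirely on the *per-channel revisit
cadence* relative to the signal's transition constant. When each
wavelength is revisited much faster than the dynamics (dense in vivo
acquisitions), even a heavily smoothing $\alpha$ filter lags by a
negligible absolute time and its noise suppression dominates. When a
channel is revisited only a handful of times per transition -- as in the
packaged 36-frame reference study, where each wavelength recurs every
180 s against a 20 s transition constant -- the $\alpha$ filter's lag
spans a sizeable fraction of a breathing phase: its waveform correlation
then approaches the sliding-window value from below as the tracking index
grows (the $\alpha \to 1$ limit *is* the sliding window) and cannot
exceed it, while the $\alpha\beta$ filter still wins because its trend
estimate compensates the lag. The reference study therefore runs the
$\alpha\beta$ filter as its primary constrained chain and reports the
$\alpha$ variant alongside; its default tracking index (2, gains
$\alpha = 0.75$, $\beta = 0.5$) is the operating point at which the
filter settles within one to two revisits of each channel.

Unmixing inverts $I = E\,C$ per pixel, either by the Moore-Penrose
pseudoinverse (unconstrained) or by non-negative least squares solved for
all pixels simultaneously with the same accelerated projected-gradient
scheme as the image solver (the problem is separable per pixel, so the
matrix form is just a vectorization). Oxygen saturation is
$\mathrm{SO_2} = \mathrm{HbO_2}/(\mathrm{HbO_2}+\mathrm{Hb})$, NA-flagged
where total hemoglobin is zero. With non-negative concentrations
$\mathrm{SO_2} \in [0,1]$ by construction; the unconstrained path may
leave that range, which is reported (flag and count), never clipped.

# The synthetic gas-challenge generator

`dynamic_spectral_spec()` emulates the structure of a dynamic small-animal
gas-challenge acquisition: a smooth tissue map of total hemoglobin (broad
background disc plus two brighter blobs by default), a rectangular
inhaled-O2 waveform, and a saturation that relaxes mono-exponentially
toward the plateau dictated by the waveform,
$dS/dt = k\,(S_{\text{target}} - S)$, evaluated in closed form phase by
phase. Each laser shot rasterizes
$\mu_a = \mathrm{Hb_{tot}}(\vec r)\,[S\,\varepsilon_{\mathrm{HbO_2}} +
(1-S)\,\varepsilon_{\mathrm{Hb}}]$ at the shot's wavelength, projects it
through a CDMMI model, and adds i.i.d. Gaussian noise. Ground truth
(tissue map, per-frame saturation, waveform, frame times) is stored next
to the data.

Reference conditions (the generator defaults): six wavelengths
(715-850 nm) cycled six times at one frame per 30 s (36 frames, 18 min),
oxygen over the middle third (6 min air / 6 min O2 / 6 min air), a 20 s
transition time constant, plateaus 0.6 (air) and 0.9 (oxygen), and noise
at a sinogram SNR of 10. The scaling is deliberate about what it
compresses: the frame cadence is ~300x slower than a real acquisition
(36 frames must span the whole challenge), but the physiological
constants are not scaled -- each breathing phase spans 18 transition
constants, so the saturation plateaus as it does in vivo. Compressing the
phases instead would make the rectangular-waveform correlation
meaningless, since the response would never settle and any filter lag
would dominate the statistic. What the generator does **not** emulate: fluence
inhomogeneity and its spectral coloring, acoustic attenuation and
heterogeneous speed of sound, finite transducer apertures, motion, and
physiological variability. End-to-end tests passing on this data
demonstrate the internal consistency of the chain (model, solvers,
filters, unmixing, statistics), not robustness to those real-data effects.

# Validation protocol and problem sizes

The packaged validation suite runs on one CPU at deliberately scaled-down
sizes: 64 detectors on a 270 degree arc of 40 mm radius, 512 time samples,
a 2.5 cm field of view, image resolutions 30/50/100 with 10 seeded
phantoms each, and the 36-frame, 50x50 gas challenge above. Forward
models are memoized per session so the benchmark, solver and end-to-end
stages share their operators.

One protocol observation is worth recording. Data-space accuracy improves
monotonically with grid refinement for both models, and the curve-sampling
model is clearly better at coarse grids -- both reproduced by the
benchmark. Image-space SSIM of *reconstructions*, however, need not rise
monotonically with resolution when the detector count and bandwidth are
fixed: at coarse grids the reconstruction inherits the model's aliasing
error, while at fine grids the inverse problem becomes less determined
and fine-scale artifacts depress local-window SSIM even as the data
residual keeps falling. The suite therefore reports both the data-space
and image-space similarity trends alongside the relative-residual trend.
Relatedly, at a coarse grid the converged relative residual is bounded
below by the forward-discretization error (analytical data are not in the
range of a coarse model), so the "residual below 0.1" check is meaningful
only at the finest grid in the sweep.

# Dataset store and reproducibility

Datasets live in a simple directory store -- float64 `data.bin` with one
chunk per frame, JSON metadata and geometry, a TSV acquisition table --
giving lazy, seekable per-frame access with byte-identical reads, plus an
optional `truth/` group for synthetic ground truth. Loaders for vendor
formats can be added behind `open_dataset()` without touching the rest of
the pipeline. Pixel coordinates use a *pixel-centre* convention (centres
on a uniform grid symmetric about the array centre), chosen deliberately
because it simplifies bilinear interpolation; frame and detector indices
are 0-based at the store interface.

Pipelines are configuration-driven: every field has a default, unknown
keys are rejected, and each run writes a provenance record (resolved
configuration, package version, input content hash, per-stage wall clock,
seeds) before its output arrays, so a run can be replayed bit-exactly
from its record. Stateless stages are parallelized by static contiguous
frame partitioning, which makes outputs independent of the worker count;
the state-carrying Kalata stage always runs serially in timestamp order.
Stage timings are logged but never asserted -- they are
hardware-dependent.

# The 7-parameter gas-response fit

The per-pixel response model is a piecewise mono-exponential,

$$y(t) = b + A_1\,(1 - e^{-k_1 (t-\tau_1)})\,H(t-\tau_1)
           - A_2\,(1 - e^{-k_2 (t-\tau_2)})\,H(t-\tau_2),$$

with baseline $b$, rise and fall amplitudes/rates, and two switching
times bounded to the record -- seven parameters fit by bounded
Levenberg-Marquardt (`minpack.lm`). This parameterization is this
package's reconstruction of a "switching-time" exponential response model
from its named outputs; the exact historical form it emulates was not
published in reproducible detail, so the fit should be read as a
representative member of that family. Fitted switching times earlier than
the known stimulus onset are flagged `noncausal`; constant series are
flagged degenerate rather than raised.

# Known limitations

* 2D geometry with ideal point detectors; no aperture integration, no
  acoustic attenuation, homogeneous speed of sound.
* No fluence model: quantities are relative, and spectral coloring of
  fluence will bias unmixing on real data.
* The unconstrained chain can and does produce negative concentrations
  and out-of-range saturations on noisy data; that is reported, not
  repaired -- use the constrained chain when physical outputs matter.
* Statistical maps apply no multiple-testing correction across pixels.
* The store format is package-defined; vendor binary formats require an
  external conversion step.
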